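test_that("the exact conditional p-value matches enumeration", {
  expect_equal(conditional_binomial_p(5, 5, 0.5), 1)
  # both 10-0 splits are equally extreme: p = 2 / 2^10
  expect_identical(conditional_binomial_p(10, 0, 0.5), 0.001953125)
  set.seed(7)
  for (i in 1:300) {
    n <- sample(1:200, 1)
    x <- sample(0:n, 1)
    prob <- runif(1, 0.02, 0.98)
    expect_equal(conditional_binomial_p(x, n - x, prob),
                 enum_binom_p(x, n, prob), tolerance = 1e-12)
  }
  expect_error(conditional_binomial_p(1, 1, 0), "null_prop")
  expect_error(conditional_binomial_p(1, 1, 1), "null_prop")
})

test_that("moving beyond the mode never increases the p-value", {
  for (prob in c(0.3, 0.5, 0.8)) {
    n <- 60
    mode <- floor((n + 1) * prob)
    p <- vapply(mode:n, function(x)
      conditional_binomial_p(x, n - x, prob), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("null proportion calibration recovers symmetric and scaled nulls", {
  set.seed(42)
  # identical counts, equal libraries: the null proportion must be 1/2
  x <- rpois(60, 200)
  prop <- estimate_null_proportion(data.frame(x_a = x, x_b = x),
                                   1e6, 1e6)
  expect_equal(as.numeric(prop), 0.5, tolerance = 0.01)

  # doubling species B counts at equal library sizes: c approx 1/2
  prop2 <- estimate_null_proportion(data.frame(x_a = x, x_b = 2L * x),
                                    1e6, 1e6)
  expect_equal(attr(prop2, "c"), 0.5, tolerance = 0.05)

  expect_error(estimate_null_proportion(
    data.frame(x_a = 1:5, x_b = 1:5), 1e6, 1e6), "at least 10")
})

test_that("the calibrated test holds its level on a Poisson null", {
  set.seed(19)
  lam <- rlnorm(1000, 5, 1)
  x_a <- rpois(1000, lam)
  x_b <- rpois(1000, 2 * lam)  # species B sequenced twice as deep
  prop <- estimate_null_proportion(
    data.frame(x_a = x_a[1:100], x_b = x_b[1:100]), 1e6, 2e6)
  p <- vapply(seq_along(x_a), function(i)
    conditional_binomial_p(x_a[i], x_b[i], as.numeric(prop)), numeric(1))
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("median replicate p and log2 fold change behave as documented", {
  expect_equal(median_replicate_p(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(median_replicate_p(c(0.1, 0.3)), 0.2)
  expect_equal(median_replicate_p(0.77), 0.77)
  expect_equal(log2_fold_change(10, 10), 0)
  expect_equal(log2_fold_change(30, 1, 1), log2(31 / 2))
  expect_equal(log2_fold_change(30, 1, 1), -log2_fold_change(1, 30, 1))
})

test_that("classification applies strict dual-p and fold-change rules", {
  cfg <- test_config()
  tests <- data.frame(
    scbn_p = c(1e-7, 1e-6, 1e-7, 1e-7, 0.5),
    median_p = c(1e-7, 1e-7, 1e-7, 1e-7, 0.5),
    log2fc = c(3, 3, -3, 1, 0))
  got <- classify_pairs(tests, cfg)
  # the threshold is strictly below 1e-6: equality is not enough
  expect_equal(got$status,
               c("SIG_UP_A", "NS", "SIG_UP_B", "DEG_SMALL_FC", "NS"))

  # species-unique pairs are recognized from replicate TPM profiles
  repl_a <- rbind(c(5, 6, 7), c(5, 6, 7), c(2, 2, 2), c(2, 2, 2),
                  c(0, 0, 0))
  repl_b <- rbind(c(0, 0, 0), c(0.05, 0, 0), c(2, 2, 2), c(2, 2, 2),
                  c(3, 4, 5))
  got2 <- classify_pairs(tests, cfg, repl_a, repl_b)
  expect_equal(got2$status[c(1, 2, 5)],
               c("UNIQUE_A", "UNIQUE_A", "UNIQUE_B"))
})

test_that("fold-change bins partition significant calls per direction", {
  tests <- data.frame(
    scbn_p = 1e-9, median_p = 1e-9,
    log2fc = c(4.2, 9.9, 10, 12, -2.5, -10),
    status = c("SIG_UP_A", "SIG_UP_A", "SIG_UP_A", "UNIQUE_A",
               "SIG_UP_B", "SIG_UP_B"))
  b <- fold_change_bins(tests)
  up_a <- b[b$direction == "up_A", ]
  expect_equal(up_a$count, c(1, 1, 2))  # 10.0 sits in the closed [10, Inf)
  expect_equal(sum(up_a$proportion), 1)
  up_b <- b[b$direction == "up_B", ]
  expect_equal(up_b$count, c(1, 0, 1))
  # no significant calls: counts zero, proportions undefined
  none <- fold_change_bins(data.frame(scbn_p = 1, median_p = 1,
                                      log2fc = 0, status = "NS"))
  expect_true(all(none$count == 0))
  expect_true(all(is.na(none$proportion)))
})

test_that("swapping the two species mirrors the full test output", {
  fx <- small_pipeline_fixture(seed = 31, n_genes = 500L,
                               conserved_core_n = 120L,
                               lib_depth = 2e5)
  tpm <- list(A = compute_tpm(fx$sim$counts_a),
              B = compute_tpm(fx$sim$counts_b))
  norm <- normalize_conserved(tpm, fx$cons)
  de <- de_test(fx$sim$counts_a, fx$sim$counts_b, norm$scaled,
                fx$pairs, fx$cons)
  # swapped orientation: B becomes the first species
  pairs_sw <- data.frame(gene_a = fx$pairs$gene_b,
                         gene_b = fx$pairs$gene_a,
                         evalue = fx$pairs$evalue,
                         pident = fx$pairs$pident,
                         bitscore = fx$pairs$bitscore,
                         stringsAsFactors = FALSE)
  cons_sw <- data.frame(gene_a = fx$cons$gene_b, gene_b = fx$cons$gene_a,
                        evalue = fx$cons$evalue, pident = fx$cons$pident,
                        bitscore = fx$cons$bitscore,
                        stringsAsFactors = FALSE)
  de_sw <- de_test(fx$sim$counts_b, fx$sim$counts_a,
                   list(A = norm$scaled$B, B = norm$scaled$A),
                   pairs_sw, cons_sw)
  ord <- match(de$gene_a, de_sw$gene_b)
  expect_equal(de_sw$log2fc[ord], -de$log2fc, tolerance = 1e-9)
  expect_equal(de_sw$scbn_p[ord], de$scbn_p, tolerance = 1e-9)
  map <- c(SIG_UP_A = "SIG_UP_B", SIG_UP_B = "SIG_UP_A",
           UNIQUE_A = "UNIQUE_B", UNIQUE_B = "UNIQUE_A",
           DEG_SMALL_FC = "DEG_SMALL_FC", NS = "NS")
  expect_equal(unname(map[de$status]), de_sw$status[ord])
})
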