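test_that("the inner-quartile filter keeps the middle of the positive values", {
  x <- setNames(c(1, 2, 3, 4, 5), paste0("g", 1:5))
  # Q1 = 2, Q3 = 4 under linear interpolation
  expect_setequal(iqr_gene_set(x), c("g2", "g3", "g4"))
  # zeros are excluded before the quartiles are computed
  x2 <- setNames(c(0, 0, 1, 2, 3, 4, 5), paste0("g", 0:6))
  expect_setequal(iqr_gene_set(x2), c("g3", "g4", "g5"))
  # all equal positive values are all retained (Q1 = Q3 = value)
  x3 <- setNames(c(2, 2, 2, 2, 0), paste0("g", 1:5))
  expect_setequal(iqr_gene_set(x3), c("g1", "g2", "g3", "g4"))
  expect_error(iqr_gene_set(setNames(c(1, 2, 0, 0), paste0("g", 1:4))),
               "fewer than 4")
})

cons2 <- data.frame(gene_a = c("a2", "a3"), gene_b = c("b2", "b3"),
                    evalue = 1e-20, pident = 99, bitscore = 100,
                    stringsAsFactors = FALSE)

test_that("anchor sets intersect IQR genes with the conserved core per species", {
  iqr <- list(sA = c("a1", "a2"), sB = c("b3", "b9"))
  species <- c(sA = "A", sB = "B")
  anch <- per_sample_anchor_set(iqr, cons2, species)
  expect_equal(anch, list(sA = "a2", sB = "b3"))
  expect_error(
    per_sample_anchor_set(list(sA = "a9"), cons2, species), "sA")
  # conserved genes all inside the IQR set: anchors = conserved genes
  anch2 <- per_sample_anchor_set(list(sA = c("a1", "a2", "a3")), cons2,
                                 species)
  expect_setequal(anch2$sA, c("a2", "a3"))
})

test_that("scaling factors are medians over the geometric mean", {
  # one gene per sample makes the medians explicit: 10, 20, 40
  ea <- matrix(c(10, 20), 1, 2, dimnames = list("a1", c("s1", "s2")))
  eb <- matrix(40, 1, 1, dimnames = list("b1", "s3"))
  anchors <- list(s1 = "a1", s2 = "a1", s3 = "b1")
  sf <- compute_scaling_factors(list(A = ea, B = eb), anchors)
  expect_equal(sf$factor, c(0.5, 1, 2))
  expect_equal(exp(mean(log(sf$factor))), 1, tolerance = 1e-12)
  expect_equal(sf$median, c(10, 20, 40))
  # all-equal medians give unit factors
  sf2 <- compute_scaling_factors(
    list(A = matrix(c(7, 7), 1, 2, dimnames = list("a1", c("s1", "s2"))),
         B = matrix(7, 1, 1, dimnames = list("b1", "s3"))), anchors)
  expect_equal(sf2$factor, rep(1, 3))
})

test_that("applying factors equalizes anchor medians and is idempotent", {
  fx <- small_pipeline_fixture(seed = 21, n_genes = 400L,
                               conserved_core_n = 120L)
  tpm <- list(A = compute_tpm(fx$sim$counts_a),
              B = compute_tpm(fx$sim$counts_b))
  norm <- normalize_conserved(tpm, fx$cons)
  anchors <- attr(norm$factors, "anchor_genes")
  sp <- setNames(norm$factors$species, norm$factors$sample)
  meds <- vapply(norm$factors$sample, function(s)
    median(norm$scaled[[sp[[s]]]][anchors[[s]], s]), numeric(1))
  expect_equal(unname(meds / meds[1]), rep(1, length(meds)),
               tolerance = 1e-6)
  # factors recomputed on already-scaled data are unity
  sf2 <- compute_scaling_factors(norm$scaled, anchors)
  expect_equal(sf2$factor, rep(1, nrow(sf2)), tolerance = 1e-9)
  # a global rescaling of all samples leaves the factors unchanged
  tpm_scaled <- lapply(tpm, function(m) m * 13.7)
  norm2 <- normalize_conserved(tpm_scaled, fx$cons)
  expect_equal(norm2$factors$factor, norm$factors$factor,
               tolerance = 1e-12)
  expect_error(apply_scaling(list(A = tpm$A[, 1, drop = FALSE],
                                  B = tpm$B), norm$factors[-1, ]),
               "A_rep1")
})

test_that("factors stay near unity on null data with equal depths", {
  # no differential signal, equal library depths: the conserved-median
  # factors should deviate from 1 only by anchor-median sampling noise
  for (seed in c(3, 13)) {
    fx <- small_pipeline_fixture(seed = seed, n_genes = 2000L,
                                 de_fraction = 0, unique_fraction = 0)
    tpm <- list(A = compute_tpm(fx$sim$counts_a),
                B = compute_tpm(fx$sim$counts_b))
    norm <- normalize_conserved(tpm, fx$cons)
    expect_lt(max(abs(norm$factors$factor - 1)), 0.10)
  }
})
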