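mk_hit <- function(q, s, bitscore = 200, evalue = 1e-20, pident = 90) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 100L,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
             sstart = 1L, send = 100L, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("best_hits keeps the top-scoring hit with a deterministic tie chain", {
  h <- rbind(mk_hit("a1", "b1", bitscore = 200),
             mk_hit("a1", "b2", bitscore = 150),
             mk_hit("a2", "b3", bitscore = 90))
  b <- best_hits(h)
  expect_equal(b$sseqid[b$qseqid == "a1"], "b1")
  expect_equal(nrow(b), 2L)

  # exact ties on bitscore/evalue/pident fall back to smallest subject id
  tie <- rbind(mk_hit("a1", "b2"), mk_hit("a1", "b1"))
  expect_equal(best_hits(tie)$sseqid, "b1")

  # lower e-value wins before pident is consulted
  ev <- rbind(mk_hit("a1", "b1", evalue = 1e-10, pident = 99),
              mk_hit("a1", "b2", evalue = 1e-30, pident = 80))
  expect_equal(best_hits(ev)$sseqid, "b2")

  # duplicate HSP rows for one query-subject pair collapse to the best
  hsp <- rbind(mk_hit("a1", "b1", bitscore = 120),
               mk_hit("a1", "b1", bitscore = 180),
               mk_hit("a1", "b2", bitscore = 150))
  expect_equal(best_hits(hsp)$bitscore, 180)

  # hits above the e-value cutoff are invisible
  expect_equal(nrow(best_hits(mk_hit("a1", "b1", evalue = 1e-3))), 0L)
})

test_that("reciprocal best hits form a partial bijection with symmetric summaries", {
  ab <- rbind(mk_hit("a1", "b1", evalue = 1e-30, pident = 95),
              mk_hit("a2", "b2", bitscore = 100))
  ba <- rbind(mk_hit("b1", "a1", evalue = 1e-10, pident = 85),
              mk_hit("b2", "a3", bitscore = 100))
  pairs <- reciprocal_best_hits(ab, ba)
  # a2 -> b2 is not reciprocated (b2 -> a3)
  expect_equal(pairs$gene_a, "a1")
  expect_equal(pairs$evalue, 1e-30)
  expect_equal(pairs$pident, 90)
})

test_that("RBH matches the brute-force oracle and is direction-symmetric", {
  for (seed in 1:20) {
    ht <- random_hit_tables(30, 30, 150, seed)
    got <- reciprocal_best_hits(ht$ab, ht$ba)
    want <- brute_rbh(ht$ab, ht$ba)
    expect_equal(got, want)
    # swapping the two directions exchanges the roles exactly
    rev <- reciprocal_best_hits(ht$ba, ht$ab)
    expect_setequal(paste(rev$gene_a, rev$gene_b),
                    paste(got$gene_b, got$gene_a))
  }
})

test_that("conserved pair selection sorts by identity and applies strict cuts", {
  pairs <- data.frame(gene_a = c("a1", "a2", "a3", "a4"),
                      gene_b = c("b1", "b2", "b3", "b4"),
                      evalue = c(1e-40, 1e-9, 1e-8, 1e-50),
                      pident = c(97, 98, 99.5, 99),
                      bitscore = c(100, 110, 120, 130),
                      stringsAsFactors = FALSE)
  sel <- suppressWarnings(select_conserved_pairs(pairs, k = 2))
  # a3 is excluded: its e-value equals the cut and the bound is strict
  expect_equal(sel$gene_a, c("a4", "a2"))
  expect_true(all(diff(sel$pident) <= 0))
  sel1 <- suppressWarnings(select_conserved_pairs(pairs, k = 100))
  expect_equal(nrow(sel1), 3L)
  expect_warning(select_conserved_pairs(pairs, k = 2), "unstable")
  expect_error(select_conserved_pairs(pairs, evalue_cut = 1e-60),
               "no ortholog pair")
})

test_that("the top-k cap returns exactly k pairs when more qualify", {
  n <- 150L
  pairs <- data.frame(gene_a = sprintf("a%03d", 1:n),
                      gene_b = sprintf("b%03d", 1:n),
                      evalue = rep(1e-40, n),
                      pident = seq(99.9, 80, length.out = n),
                      bitscore = rep(100, n), stringsAsFactors = FALSE)
  sel <- select_conserved_pairs(pairs, k = 100)
  expect_equal(nrow(sel), 100L)
  expect_equal(sel$gene_a[1], "a001")
})
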