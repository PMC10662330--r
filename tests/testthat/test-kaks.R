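test_that("global protein alignment handles identity and forced gaps", {
  a <- global_protein_align("MKVL", "MKVL")
  expect_equal(a$a, "MKVL")
  expect_equal(a$b, "MKVL")
  g <- global_protein_align("MKV", "MV")
  expect_equal(nchar(g$a), 3L)
  expect_equal(sum(strsplit(g$b, "")[[1]] == "-"), 1L)
  expect_error(global_protein_align("", "MV"), "empty")
})

test_that("codon threading maps residues to source codons and drops gaps", {
  # gapless: codon lists are just the chunked CDS
  aln <- thread_codons("MK", "MK", "ATGAAA", "ATGAAG", "x", "y")
  expect_equal(aln$codons_a, c("ATG", "AAA"))
  expect_equal(aln$codons_b, c("ATG", "AAG"))
  # a gap column disappears from the output
  aln2 <- thread_codons("MKV", "M-V", "ATGAAAGTT", "ATGGTC", "x", "y")
  expect_equal(aln2$codons_a, c("ATG", "GTT"))
  expect_equal(aln2$codons_b, c("ATG", "GTC"))
  # terminal stop codons are stripped before threading
  aln3 <- thread_codons("MK", "MK", "ATGAAATAA", "ATGAAG", "x", "y")
  expect_equal(aln3$n_codons, 2L)
  expect_error(thread_codons("MK", "MK", "ATGAAAG", "ATGAAG", "x", "y"),
               "multiple of 3")
  expect_error(thread_codons("MW", "MK", "ATGAAA", "ATGAAG", "x", "y"),
               "translate")
})

test_that("NG86 reproduces the four-fold degenerate worked example", {
  aln <- structure(list(gene_a = "a", gene_b = "b",
                        codons_a = c("GGG", "GGG"),
                        codons_b = c("GGA", "GGG"), n_codons = 2L),
                   class = "codon_alignment")
  r <- ng86_kaks(aln)
  expect_equal(r$S, 2)
  expect_equal(r$N, 4)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ks, -0.75 * log(1 / 3), tolerance = 1e-12)
  expect_equal(r$ka, 0)
  expect_equal(r$ratio, 0)

  ident <- structure(list(gene_a = "a", gene_b = "b",
                          codons_a = c("ATG", "AAA"),
                          codons_b = c("ATG", "AAA"), n_codons = 2L),
                     class = "codon_alignment")
  ri <- ng86_kaks(ident)
  expect_equal(c(ri$Sd, ri$Nd, ri$ka, ri$ks), c(0, 0, 0, 0))
  expect_true(is.na(ri$ratio))
})

test_that("NG86 counts equal exhaustive pathway enumeration", {
  for (seed in 1:40) {
    aln <- random_codon_alignment(sample(5:30, 1), seed)
    r <- ng86_kaks(aln)
    o <- oracle_ng86_counts(aln$codons_a, aln$codons_b)
    expect_equal(r$S, unname(o["S"]), tolerance = 1e-12)
    expect_equal(r$N, unname(o["N"]), tolerance = 1e-12)
    expect_equal(r$Sd, unname(o["Sd"]), tolerance = 1e-12)
    expect_equal(r$Nd, unname(o["Nd"]), tolerance = 1e-12)
    expect_equal(r$S + r$N, 3 * aln$n_codons)
    # the estimator is symmetric in the two sequences
    sw <- structure(list(gene_a = "b", gene_b = "a",
                         codons_a = aln$codons_b, codons_b = aln$codons_a,
                         n_codons = aln$n_codons),
                    class = "codon_alignment")
    rsw <- ng86_kaks(sw)
    expect_equal(rsw[c("S", "N", "Sd", "Nd", "ka", "ks")],
                 r[c("S", "N", "Sd", "Nd", "ka", "ks")],
                 tolerance = 1e-12)
  }
})

test_that("Fisher significance matches hypergeometric enumeration", {
  rec <- data.frame(S = 100, N = 300, Sd = 0, Nd = 0)
  expect_equal(fisher_significance(rec), 1)
  rec2 <- data.frame(S = 2, N = 2, Sd = 1, Nd = 1)
  expect_equal(fisher_significance(rec2), 1)
  set.seed(3)
  for (i in 1:30) {
    S <- sample(20:200, 1); N <- sample(20:600, 1)
    rec <- data.frame(S = S, N = N,
                      Sd = sample(0:min(S, 50), 1),
                      Nd = sample(0:min(N, 80), 1))
    tab <- matrix(c(rec$Sd, rec$S - rec$Sd, rec$Nd, rec$N - rec$Nd),
                  2, 2, byrow = TRUE)
    expect_equal(fisher_significance(rec), enum_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("the selection filter applies the significance and Ks rules", {
  recs <- data.frame(
    gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4),
    S = 100, N = 300, Sd = 20, Nd = 10,
    ka = c(0.05, 0.05, 0.9, 0.2), ks = c(0.0005, 0.3, 0.3, 0.3),
    ratio = c(0.2, 0.2, 3, 1), fisher_p = c(0.005, 0.005, 0.005, 0.001),
    selection_class = NA_character_, stringsAsFactors = FALSE)
  got <- filter_and_classify(recs)
  # a Ks at 0.0005 fails the Ks > 0.001 requirement outright
  expect_equal(got$selection_class,
               c("FILTERED", "PURIFYING", "POSITIVE", "NEUTRAL_OR_NA"))
  # insufficient significance also filters
  recs$fisher_p <- 0.5
  expect_true(all(filter_and_classify(recs)$selection_class == "FILTERED"))
})

test_that("kaks_screen runs end to end on simulated codon pairs", {
  rows <- lapply(1:6, function(i) {
    cp <- simulate_codon_pair(80, 0.2, 0.3, seed = 100 + i)
    list(cds_a = data.frame(id = paste0("a", i), description = "",
                            sequence = cp$cds_a),
         cds_b = data.frame(id = paste0("b", i), description = "",
                            sequence = cp$cds_b))
  })
  cds_a <- do.call(rbind, lapply(rows, `[[`, "cds_a"))
  cds_b <- do.call(rbind, lapply(rows, `[[`, "cds_b"))
  tr <- function(df) transform(df, sequence = vapply(
    sequence, orthoscale:::translate_cds, character(1)))
  pairs <- data.frame(gene_a = cds_a$id, gene_b = cds_b$id)
  axt <- withr::local_tempfile(fileext = ".axt")
  recs <- kaks_screen(pairs, cds_a, cds_b, tr(cds_a), tr(cds_b),
                      axt_path = axt)
  expect_equal(nrow(recs), 6L)
  expect_true(all(recs$S > 0 & recs$N > 0))
  expect_true(all(recs$fisher_p > 0 & recs$fisher_p <= 1))
  expect_true(file.exists(axt))
  blocks <- readLines(axt)
  expect_equal(blocks[1], "a1-b1")
})
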