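# Counts -> TPM conversion and replicate-concordance QC.

#' Compute TPM from a count table
#'
#' Transcripts Per Million: each count is divided by transcript length in
#' kilobases, and the resulting per-kilobase rates are rescaled so each
#' sample column sums to 1e6. A sample with no reads yields an all-zero
#' column.
#'
#' @param tab A `count_table` (see [count_table()]).
#' @return Numeric matrix (genes x samples) of TPM values.
#' @export
compute_tpm <- function(tab) {
  rate <- rate_matrix(tab)
  totals <- colSums(rate)
  scale <- ifelse(totals > 0, 1e6 / totals, 0)
  sweep(rate, 2L, scale, "*")
}

#' Per-kilobase rate matrix (length-normalized counts)
#'
#' Counts divided by transcript length in kb, with no per-sample sum
#' normalization. Unlike TPM this retains between-sample depth
#' differences, which is useful when known per-sample scale distortions
#' must remain visible to the conserved-ortholog scaling step.
#'
#' @param tab A `count_table`.
#' @return Numeric matrix (genes x samples).
#' @export
rate_matrix <- function(tab) {
  tab$counts / (tab$lengths / 1000)
}

#' Pairwise Spearman correlation between samples
#'
#' Replicate-concordance QC: Spearman's rank correlation between every
#' pair of sample columns, computed on per-sample gene ranks with average
#' ranks for ties. Constant columns have no defined rank correlation and
#' produce `NA` entries with a warning.
#'
#' @param expr Numeric matrix (genes x samples), e.g. TPM.
#' @return Symmetric samples x samples matrix of rank correlations with a
#'   unit diagonal.
#' @export
spearman_qc <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L)
  const <- apply(expr, 2L, function(x) length(unique(x)) == 1L)
  rs <- suppressWarnings(stats::cor(expr, method = "spearman"))
  if (any(const)) {
    warning("constant sample column(s): ",
            paste(colnames(expr)[const], collapse = ", "),
            "; their correlations are undefined (NA)")
    rs[const, ] <- NA_real_
    rs[, const] <- NA_real_
  }
  diag(rs) <- 1
  rs
}
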