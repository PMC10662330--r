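# Conserved-ortholog median scaling: per-sample factors that equalize the
# median expression of high-identity ortholog anchors across all samples of
# both species, making the two expression profiles comparable.

#' Genes inside a sample's inner quartile range
#'
#' Returns the genes whose expression lies within the closed interval
#' \[Q1, Q3\] of the sample's positive expression values. Zeros are
#' excluded before computing the quartiles: including the zero mass would
#' pull Q1 to 0 and admit unexpressed genes as normalization anchors.
#' Quartiles use linear interpolation between order statistics
#' (`quantile()` type 7).
#'
#' @param expr_column Named numeric vector of per-gene expression for one
#'   sample (names = gene ids).
#' @return Character vector of gene ids in the IQR window.
#' @export
iqr_gene_set <- function(expr_column) {
  stopifnot(!is.null(names(expr_column)))
  pos <- expr_column[expr_column > 0]
  if (length(pos) < 4L)
    stop("fewer than 4 genes with positive expression; ",
         "quartiles are unstable")
  q <- stats::quantile(pos, probs = c(0.25, 0.75), names = FALSE, type = 7)
  names(pos)[pos >= q[1L] & pos <= q[2L]]
}

#' Per-sample anchor gene sets
#'
#' Intersects each sample's IQR gene set with the conserved ortholog genes
#' of that sample's species, yielding the anchor genes whose median drives
#' that sample's scaling factor.
#'
#' @param iqr_sets Named list: sample id -> character vector of gene ids
#'   (from [iqr_gene_set()]).
#' @param conserved Conserved pair set from [select_conserved_pairs()].
#' @param species Named character vector mapping each sample id to
#'   `"A"` or `"B"`.
#' @return Named list: sample id -> character vector of anchor gene ids.
#' @export
per_sample_anchor_set <- function(iqr_sets, conserved, species) {
  stopifnot(all(names(iqr_sets) %in% names(species)))
  out <- lapply(names(iqr_sets), function(s) {
    pool <- if (species[[s]] == "A") conserved$gene_a else conserved$gene_b
    hit <- intersect(iqr_sets[[s]], pool)
    if (length(hit) == 0L)
      stop("sample '", s, "': no conserved ortholog gene falls in its ",
           "inner quartile range")
    hit
  })
  names(out) <- names(iqr_sets)
  out
}

#' Scaling factors from conserved-ortholog medians
#'
#' For each sample, takes the median expression of its anchor genes, then
#' divides every median by the geometric mean of all medians. The
#' resulting factors multiply to 1 and scale-equivariantly capture
#' between-sample differences in the conserved core.
#'
#' @param expr Named list of expression matrices, `list(A = , B = )`
#'   (genes x samples per species; sample ids unique across the two).
#' @param anchors Named list: sample id -> anchor gene ids (from
#'   [per_sample_anchor_set()]).
#' @return Data frame (class `scaling_factors`) with columns `sample`,
#'   `species`, `n_anchors`, `median`, `factor`; anchor gene sets kept in
#'   attribute `anchor_genes`.
#' @export
compute_scaling_factors <- function(expr, anchors) {
  stopifnot(is.list(expr), all(c("A", "B") %in% names(expr)))
  samples <- c(colnames(expr$A), colnames(expr$B))
  stopifnot(all(names(anchors) %in% samples))
  species <- stats::setNames(rep(c("A", "B"),
                                 c(ncol(expr$A), ncol(expr$B))), samples)
  meds <- vapply(samples, function(s) {
    g <- anchors[[s]]
    if (is.null(g) || length(g) == 0L)
      stop("sample '", s, "' has an empty anchor set")
    stats::median(expr[[species[[s]]]][g, s])
  }, numeric(1))
  if (any(meds <= 0))
    stop("zero anchor median for sample(s): ",
         paste(samples[meds <= 0], collapse = ", "))
  gm <- exp(mean(log(meds)))
  out <- data.frame(sample = samples,
                    species = unname(species),
                    n_anchors = vapply(anchors[samples], length, integer(1)),
                    median = unname(meds),
                    factor = unname(meds) / gm,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "anchor_genes") <- anchors[samples]
  class(out) <- c("scaling_factors", "data.frame")
  out
}

#' Apply scaling factors to expression matrices
#'
#' Divides each sample column by its scaling factor. After scaling, the
#' anchor-gene medians are equal across all samples.
#'
#' @param expr Named list of expression matrices, `list(A = , B = )`.
#' @param sf `scaling_factors` from [compute_scaling_factors()].
#' @return List of matrices with the same shapes, scaled.
#' @export
apply_scaling <- function(expr, sf) {
  fac <- stats::setNames(sf$factor, sf$sample)
  lapply(expr, function(m) {
    missing <- setdiff(colnames(m), names(fac))
    if (length(missing) > 0L)
      stop("no scaling factor for sample(s): ",
           paste(missing, collapse = ", "))
    sweep(m, 2L, fac[colnames(m)], "/")
  })
}

#' Conserved-ortholog scaling in one call
#'
#' Runs the full normalization chain: per-sample IQR filter, intersection
#' with the conserved ortholog genes, median-based factors, scaling.
#'
#' @param expr Named list of expression matrices, `list(A = , B = )`.
#' @param conserved Conserved pair set from [select_conserved_pairs()].
#' @return List with elements `factors` (`scaling_factors`) and `scaled`
#'   (list of scaled matrices).
#' @export
normalize_conserved <- function(expr, conserved) {
  stopifnot(is.list(expr), all(c("A", "B") %in% names(expr)))
  samples <- c(colnames(expr$A), colnames(expr$B))
  species <- stats::setNames(rep(c("A", "B"),
                                 c(ncol(expr$A), ncol(expr$B))), samples)
  iqr_sets <- lapply(samples, function(s) {
    m <- expr[[species[[s]]]]
    iqr_gene_set(stats::setNames(m[, s], rownames(m)))
  })
  names(iqr_sets) <- samples
  anchors <- per_sample_anchor_set(iqr_sets, conserved, species)
  sf <- compute_scaling_factors(expr, anchors)
  list(factors = sf, scaled = apply_scaling(expr, sf))
}
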