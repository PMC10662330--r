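# Reciprocal-best-hit orthology and selection of the conserved anchor pairs
# used for cross-species normalization.

#' Best hit per query from one search direction
#'
#' For every query, keeps the single hit with the highest bit score among
#' hits passing the e-value cutoff. Tabular output may carry several HSP
#' rows per query-subject pair; those are collapsed to the highest-scoring
#' row first. Ties are resolved deterministically: lower e-value, then
#' higher percent identity, then lexicographically smallest subject id.
#'
#' @param hits Data frame from [read_blast6()] (one search direction).
#' @param evalue_cut Maximum e-value for a hit to be considered
#'   (inclusive; default `1e-5`).
#' @return Data frame with one row per query that has a passing hit
#'   (columns as in the input), ordered by `qseqid`.
#' @export
best_hits <- function(hits, evalue_cut = 1e-5) {
  hits <- hits[hits$evalue <= evalue_cut, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  # deterministic selection: order so the preferred row comes first per
  # query, then keep the first occurrence
  ord <- order(hits$qseqid,
               -hits$bitscore,
               hits$evalue,
               -hits$pident,
               hits$sseqid,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  # collapse duplicate query-subject HSPs (best row already first)
  hits <- hits[!duplicated(paste0(hits$qseqid, "\r", hits$sseqid)), ,
               drop = FALSE]
  best <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Reciprocal best hits between two species
#'
#' Pairs gene `a` (species A) with gene `b` (species B) when each is the
#' other's best hit in the respective search direction. The resulting
#' pairing is a partial bijection: each gene appears in at most one pair.
#'
#' @param hits_ab Hit table with species-A genes as queries.
#' @param hits_ba Hit table with species-B genes as queries.
#' @param evalue_cut Per-direction e-value cutoff (default `1e-5`).
#' @return Data frame with columns `gene_a`, `gene_b`, `evalue` (minimum
#'   of the two directions), `pident` and `bitscore` (means of the two
#'   directions), sorted by `gene_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cut = 1e-5) {
  ba <- best_hits(hits_ab, evalue_cut)
  bb <- best_hits(hits_ba, evalue_cut)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), pident = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE)
  if (nrow(ba) == 0L || nrow(bb) == 0L) return(empty)
  back <- stats::setNames(bb$sseqid, bb$qseqid)   # b -> best a
  keep <- !is.na(back[ba$sseqid]) & back[ba$sseqid] == ba$qseqid
  keep[is.na(keep)] <- FALSE
  ab <- ba[keep, , drop = FALSE]
  if (nrow(ab) == 0L) return(empty)
  rev_idx <- match(ab$sseqid, bb$qseqid)
  out <- data.frame(
    gene_a = ab$qseqid,
    gene_b = ab$sseqid,
    evalue = pmin(ab$evalue, bb$evalue[rev_idx]),
    pident = (ab$pident + bb$pident[rev_idx]) / 2,
    bitscore = (ab$bitscore + bb$bitscore[rev_idx]) / 2,
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the conserved ortholog anchor pairs
#'
#' From reciprocal-best-hit pairs, keeps those with e-value strictly below
#' `evalue_cut`, sorts them by percent identity (descending; ties broken
#' by higher bit score, then lexicographic `gene_a`) and returns the top
#' `k`. These high-identity pairs are assumed equally expressed in both
#' species and anchor the scaling-factor computation.
#'
#' @param pairs Data frame from [reciprocal_best_hits()].
#' @param evalue_cut Strict e-value upper bound (default `1e-8`).
#' @param k Number of pairs to keep (default 100).
#' @return Data frame of at most `k` pairs (same columns as input),
#'   pident non-increasing; attributes `evalue_cut` and `k` record the
#'   selection parameters.
#' @export
select_conserved_pairs <- function(pairs, evalue_cut = 1e-8, k = 100L) {
  qual <- pairs[pairs$evalue < evalue_cut, , drop = FALSE]
  if (nrow(qual) == 0L)
    stop("no ortholog pair passes e-value < ", evalue_cut,
         "; cannot build a conserved anchor set")
  if (nrow(qual) < 10L)
    warning("only ", nrow(qual), " ortholog pairs pass e-value < ",
            evalue_cut, "; scaling factors may be unstable")
  ord <- order(-qual$pident, -qual$bitscore, qual$gene_a, method = "radix")
  qual <- qual[ord, , drop = FALSE]
  out <- utils::head(qual, k)
  rownames(out) <- NULL
  attr(out, "evalue_cut") <- evalue_cut
  attr(out, "k") <- as.integer(k)
  out
}
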