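# Ka/Ks selection screen for ortholog CDS pairs: global protein alignment,
# codon threading, Nei-Gojobori (1986) site/difference counting with
# equal-weight pathway averaging and Jukes-Cantor correction, a Fisher
# exact test on the count table, and the significance/Ks filters.

.codon_cache <- new.env(parent = emptyenv())

# Precomputed per-codon tables under the standard genetic code:
#   aa       codon -> amino acid ("*" = stop)
#   stops    stop codons
#   syn_site codon -> NG86 synonymous site count (sum over the three
#            positions of the fraction of synonymous changes among the
#            single-nucleotide changes that do not create a stop)
#   changes  codon -> data.frame(pos, to, codon2, type) for the 9 single
#            nucleotide changes, type in {syn, nonsyn, stop}
codon_info <- function() {
  if (!is.null(.codon_cache$info)) return(.codon_cache$info)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- stats::setNames(unname(gc_tab), codons)
  bases <- c("A", "C", "G", "T")
  changes <- vector("list", length(codons))
  names(changes) <- codons
  syn_site <- stats::setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    ch <- strsplit(cd, "")[[1L]]
    rows <- list()
    s_total <- 0
    for (pos in 1:3) {
      alt_rows <- list()
      for (b in setdiff(bases, ch[pos])) {
        ch2 <- ch
        ch2[pos] <- b
        cd2 <- paste(ch2, collapse = "")
        type <- if (aa[[cd2]] == "*") "stop"
                else if (aa[[cd2]] == aa[[cd]]) "syn" else "nonsyn"
        alt_rows[[length(alt_rows) + 1L]] <-
          data.frame(pos = pos, to = b, codon2 = cd2, type = type,
                     stringsAsFactors = FALSE)
      }
      alt <- do.call(rbind, alt_rows)
      rows[[pos]] <- alt
      viable <- alt$type != "stop"
      if (any(viable))
        s_total <- s_total + sum(alt$type == "syn") / sum(viable)
    }
    changes[[cd]] <- do.call(rbind, rows)
    syn_site[[cd]] <- s_total
  }
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  .codon_cache$info <- list(aa = aa, stops = codons[unname(aa) == "*"],
                            syn_site = syn_site, changes = changes,
                            perms = perms)
  .codon_cache$info
}

#' Global protein alignment
#'
#' Needleman-Wunsch global alignment of two protein sequences under
#' BLOSUM62 with affine gaps (open 10, extend 0.5). A trailing stop
#' symbol (`*`) is stripped before alignment.
#'
#' @param prot_a,prot_b Amino-acid sequences (character scalars or
#'   single rows from [read_fasta()]).
#' @return List with `a`, `b` (aligned sequences, `-` for gaps) and
#'   `score`.
#' @export
global_protein_align <- function(prot_a, prot_b) {
  sa <- as_seq_string(prot_a)
  sb <- as_seq_string(prot_b)
  sa <- sub("\\*$", "", sa)
  sb <- sub("\\*$", "", sb)
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("cannot align an empty protein sequence")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = get("BLOSUM62"),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

as_seq_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(x$sequence)
  }
  as.character(x)
}

#' Thread codons through a protein alignment
#'
#' Replaces each aligned residue by its source codon, drops columns with
#' a gap in either row, and strips a terminal stop codon. Codon columns
#' containing ambiguous bases (anything outside ACGT) are also dropped,
#' since substitution counting is undefined for them.
#'
#' @param aligned_a,aligned_b Aligned protein strings (from
#'   [global_protein_align()]).
#' @param cds_a,cds_b Coding sequences (character scalars or single
#'   [read_fasta()] rows) whose translations match the ungapped proteins.
#' @param gene_a,gene_b Ids used in error messages and the output record.
#' @return List of class `codon_alignment` with `gene_a`, `gene_b`,
#'   `codons_a`, `codons_b` (equal-length character vectors of 3-mers)
#'   and `n_codons`.
#' @export
thread_codons <- function(aligned_a, aligned_b, cds_a, cds_b,
                          gene_a = "a", gene_b = "b") {
  ca <- prep_cds(cds_a, aligned_a, gene_a)
  cb <- prep_cds(cds_b, aligned_b, gene_b)
  cols_a <- strsplit(aligned_a, "")[[1L]]
  cols_b <- strsplit(aligned_b, "")[[1L]]
  if (length(cols_a) != length(cols_b))
    stop("aligned sequences have different lengths")
  ia <- cumsum(cols_a != "-")
  ib <- cumsum(cols_b != "-")
  keep <- cols_a != "-" & cols_b != "-"
  codons_a <- ca[ia[keep]]
  codons_b <- cb[ib[keep]]
  clean <- grepl("^[ACGT]{3}$", codons_a) & grepl("^[ACGT]{3}$", codons_b)
  codons_a <- codons_a[clean]
  codons_b <- codons_b[clean]
  if (length(codons_a) == 0L)
    stop("no ungapped codon columns for pair ", gene_a, "-", gene_b)
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 codons_a = codons_a, codons_b = codons_b,
                 n_codons = length(codons_a)),
            class = "codon_alignment")
}

# Splits a CDS into codons, strips a terminal stop, and checks that the
# translation matches the ungapped aligned protein.
prep_cds <- function(cds, aligned, gene) {
  s <- toupper(as_seq_string(cds))
  s <- gsub("U", "T", s, fixed = TRUE)
  if (nchar(s) %% 3 != 0L)
    stop("CDS length of '", gene, "' is not a multiple of 3")
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  info <- codon_info()
  last <- codons[length(codons)]
  if (last %in% info$stops) codons <- codons[-length(codons)]
  prot <- gsub("-", "", aligned, fixed = TRUE)
  if (length(codons) != nchar(prot))
    stop("CDS of '", gene, "' has ", length(codons),
         " codons but the protein has ", nchar(prot), " residues")
  aas <- vapply(codons, function(cd) {
    if (grepl("^[ACGT]{3}$", cd)) info$aa[[cd]] else "X"
  }, character(1), USE.NAMES = FALSE)
  res <- strsplit(prot, "")[[1L]]
  mism <- which(aas != res & aas != "X" & res != "X")
  if (length(mism) > 0L)
    stop("CDS of '", gene, "' does not translate to its protein at ",
         "residue ", mism[1L])
  codons
}

# Pathway-averaged synonymous/nonsynonymous differences for one codon
# pair: all orderings of the differing positions are enumerated with
# equal weight; orderings that pass through a stop codon are excluded.
# Should every ordering be blocked (not realizable between two sense
# codons at 2 differences; vanishingly rare at 3), the pair contributes
# no differences.
codon_pair_diffs <- function(c1, c2, info) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  ch1 <- strsplit(c1, "")[[1L]]
  ch2 <- strsplit(c2, "")[[1L]]
  pos <- which(ch1 != ch2)
  d <- length(pos)
  paths <- info$perms[[as.character(d)]]
  res <- matrix(NA_real_, length(paths), 2L)
  valid <- logical(length(paths))
  for (i in seq_along(paths)) {
    cur <- ch1
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in pos[paths[[i]]]) {
      prev_cd <- paste(cur, collapse = "")
      cur[p] <- ch2[p]
      new_cd <- paste(cur, collapse = "")
      if (info$aa[[new_cd]] == "*") { ok <- FALSE; break }
      if (info$aa[[new_cd]] == info$aa[[prev_cd]]) sd <- sd + 1
      else nd <- nd + 1
    }
    res[i, ] <- c(sd, nd)
    valid[i] <- ok
  }
  if (!any(valid)) return(c(sd = 0, nd = 0))
  c(sd = mean(res[valid, 1L]), nd = mean(res[valid, 2L]))
}

#' NG86 Ka/Ks estimate for a codon alignment
#'
#' Nei-Gojobori (1986) counting: per-codon synonymous site fractions
#' (stop-creating changes excluded from numerator and denominator),
#' `S` averaged over the two sequences, `N = 3 n_codons - S`;
#' synonymous/nonsynonymous differences averaged with equal weight over
#' all minimal substitution pathways (pathways through stop codons
#' excluded); Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)`,
#' undefined (`NA`) when `p >= 3/4`. The ratio is `NA` when `ks` is 0 or
#' undefined.
#'
#' @param aln A `codon_alignment` from [thread_codons()].
#' @return One-row data frame: `gene_a`, `gene_b`, `n_codons`, `S`, `N`,
#'   `Sd`, `Nd`, `ka`, `ks`, `ratio`, `fisher_p` (NA; see
#'   [fisher_significance()]), `selection_class` (NA).
#' @export
ng86_kaks <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"), aln$n_codons >= 1L)
  info <- codon_info()
  s_a <- sum(info$syn_site[aln$codons_a])
  s_b <- sum(info$syn_site[aln$codons_b])
  S <- (s_a + s_b) / 2
  N <- 3 * aln$n_codons - S
  diffs <- mapply(function(c1, c2) codon_pair_diffs(c1, c2, info),
                  aln$codons_a, aln$codons_b)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ks <- jc_correct(if (S > 0) Sd / S else NA_real_)
  ka <- jc_correct(if (N > 0) Nd / N else NA_real_)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  data.frame(gene_a = aln$gene_a, gene_b = aln$gene_b,
             n_codons = aln$n_codons, S = S, N = N, Sd = Sd, Nd = Nd,
             ka = ka, ks = ks, ratio = ratio, fisher_p = NA_real_,
             selection_class = NA_character_, stringsAsFactors = FALSE)
}

# Jukes-Cantor multiple-hit correction of a proportion of differences.
jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  if (p == 0) return(0)
  -0.75 * log(1 - 4 * p / 3)
}

#' Fisher exact test on NG86 counts
#'
#' Two-sided Fisher exact p-value on the 2x2 table
#' `[[round(Sd), round(S - Sd)], [round(Nd), round(N - Nd)]]` — do the
#' synonymous and nonsynonymous sites differ in their substitution
#' proportions? Uses the hypergeometric minimum-likelihood two-sided
#' rule.
#'
#' @param rec One-row data frame with `S`, `N`, `Sd`, `Nd` (from
#'   [ng86_kaks()]).
#' @return p-value in (0, 1].
#' @export
fisher_significance <- function(rec) {
  tab <- matrix(c(round(rec$Sd), round(rec$S - rec$Sd),
                  round(rec$Nd), round(rec$N - rec$Nd)),
                nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) stop("negative cell in the Fisher table after rounding")
  stats::fisher.test(tab)$p.value
}

#' Filter Ka/Ks records and classify selection
#'
#' Retains records with `fisher_p < p_cut` and `ks > ks_min`; everything
#' else (including undefined Ks) is `FILTERED`. Retained records are
#' classified `PURIFYING` (ratio < 1), `POSITIVE` (ratio > 1) or
#' `NEUTRAL_OR_NA` (ratio undefined or exactly 1).
#'
#' @param records Data frame of Ka/Ks records with `fisher_p` set.
#' @param p_cut Fisher p-value threshold (default 0.01).
#' @param ks_min Strict lower bound on Ks (default 0.001).
#' @return `records` with `selection_class` filled in.
#' @export
filter_and_classify <- function(records, p_cut = 0.01, ks_min = 0.001) {
  stopifnot(all(!is.na(records$fisher_p)))
  keep <- !is.na(records$ks) & records$ks > ks_min &
    records$fisher_p < p_cut
  cls <- rep("FILTERED", nrow(records))
  r <- records$ratio
  cls[keep & !is.na(r) & r < 1] <- "PURIFYING"
  cls[keep & !is.na(r) & r > 1] <- "POSITIVE"
  cls[keep & (is.na(r) | r == 1)] <- "NEUTRAL_OR_NA"
  records$selection_class <- cls
  records
}

#' Ka/Ks screen over ortholog pairs
#'
#' For each ortholog pair with CDS and protein sequences available:
#' protein alignment, codon threading, NG86 estimation, Fisher test and
#' classification.
#'
#' @param pairs Data frame with `gene_a`, `gene_b`.
#' @param cds_a,cds_b,prot_a,prot_b FASTA data frames (from
#'   [read_fasta()]) keyed by gene id.
#' @param p_cut,ks_min Filters passed to [filter_and_classify()].
#' @param axt_path Optional path; when given, codon alignments are also
#'   written as axt-style blocks.
#' @return Data frame of classified Ka/Ks records, one row per pair with
#'   sequence data (input pair order).
#' @export
kaks_screen <- function(pairs, cds_a, cds_b, prot_a, prot_b,
                        p_cut = 0.01, ks_min = 0.001, axt_path = NULL) {
  have <- pairs$gene_a %in% cds_a$id & pairs$gene_b %in% cds_b$id &
    pairs$gene_a %in% prot_a$id & pairs$gene_b %in% prot_b$id
  pairs <- pairs[have, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no ortholog pair has CDS and protein data")
  alns <- vector("list", nrow(pairs))
  recs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    pa <- prot_a$sequence[match(ga, prot_a$id)]
    pb <- prot_b$sequence[match(gb, prot_b$id)]
    aln_p <- global_protein_align(pa, pb)
    aln <- thread_codons(aln_p$a, aln_p$b,
                         cds_a$sequence[match(ga, cds_a$id)],
                         cds_b$sequence[match(gb, cds_b$id)],
                         gene_a = ga, gene_b = gb)
    rec <- ng86_kaks(aln)
    rec$fisher_p <- fisher_significance(rec)
    alns[[i]] <- aln
    recs[[i]] <- rec
  }
  out <- do.call(rbind, recs)
  out <- filter_and_classify(out, p_cut = p_cut, ks_min = ks_min)
  if (!is.null(axt_path)) write_axt(alns, axt_path)
  rownames(out) <- NULL
  out
}
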