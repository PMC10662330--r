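# Between-species differential expression: an exact conditional binomial
# test on pooled counts whose null proportion embeds a scale factor fitted
# on the conserved ortholog genes, a replicate-level median p-value, and
# the dual-threshold DEG classification.

#' Differential-expression test configuration
#'
#' @param p_cut Dual p-value threshold; a pair is a DEG when both the
#'   pooled-count p-value and the replicate-median p-value fall strictly
#'   below it (default `1e-6`).
#' @param lfc_cut Absolute log2 fold-change threshold for a significant
#'   DEG (default 2).
#' @param pseudocount Pseudocount (TPM units) added to both means before
#'   the log2 ratio so species-unique genes get a finite fold change
#'   (default 1).
#' @param unique_low A gene counts as undetected in a species when all its
#'   replicate TPM values are below this (default 0.1).
#' @param unique_high A gene counts as expressed in a species when all its
#'   replicate TPM values are at or above this (default 1).
#' @param alpha0 Calibration level for the null-proportion fit on
#'   conserved genes (default 0.05).
#' @return List of class `de_config`.
#' @export
test_config <- function(p_cut = 1e-6, lfc_cut = 2, pseudocount = 1,
                        unique_low = 0.1, unique_high = 1, alpha0 = 0.05) {
  stopifnot(p_cut > 0, p_cut < 1, lfc_cut > 0, pseudocount >= 0,
            unique_low < unique_high, alpha0 > 0, alpha0 < 1)
  structure(list(p_cut = p_cut, lfc_cut = lfc_cut,
                 pseudocount = pseudocount, unique_low = unique_low,
                 unique_high = unique_high, alpha0 = alpha0),
            class = "de_config")
}

#' Exact two-sided conditional binomial p-value
#'
#' Conditional on the total `n = x_a + x_b`, tests `x_a ~ Binomial(n,
#' null_prop)` with the minimum-likelihood two-sided rule: the p-value
#' sums `P(X = k)` over every `k` whose point probability does not exceed
#' that of the observed `x_a` (up to a relative tolerance of 1e-7, the
#' usual guard against floating-point ties). The rejection region is the
#' union of two tails, so only the two flank boundaries are searched; the
#' result equals full enumeration over `k = 0..n`.
#'
#' @param x_a,x_b Non-negative integer counts; `x_a + x_b >= 1`.
#' @param null_prop Null proportion for species A, strictly in (0, 1).
#' @return p-value in (0, 1].
#' @export
conditional_binomial_p <- function(x_a, x_b, null_prop) {
  stopifnot(length(x_a) == 1L, length(x_b) == 1L,
            x_a >= 0, x_b >= 0, x_a + x_b >= 1)
  conditional_binomial_p_vec(x_a, x_b, null_prop)
}

# Vectorized over count pairs (null_prop scalar). dbinom is unimodal in
# k: nondecreasing on [0, mode], nonincreasing on [mode, n]; both flank
# boundaries are located by a lockstep binary search across all pairs.
# Pairs with zero total get p = 1.
conditional_binomial_p_vec <- function(x_a, x_b, null_prop) {
  if (length(null_prop) != 1L || !is.finite(null_prop) ||
      null_prop <= 0 || null_prop >= 1)
    stop("null_prop must be a single value strictly inside (0, 1)")
  n_all <- x_a + x_b
  out <- rep(1, length(n_all))
  ok <- n_all >= 1
  if (!any(ok)) return(out)
  n <- n_all[ok]
  x <- x_a[ok]
  relerr <- 1 + 1e-7
  dx <- stats::dbinom(x, n, null_prop)
  mode <- pmin(floor((n + 1) * null_prop), n)
  thr <- dx * relerr
  act <- thr < stats::dbinom(mode, n, null_prop)
  p <- rep(1, length(n))
  if (any(act)) {
    na <- n[act]; tha <- thr[act]; ma <- mode[act]
    # left flank: largest k in [0, mode] with dbinom(k) <= thr (-1: none)
    lo <- ifelse(stats::dbinom(0, na, null_prop) <= tha, 0, -1)
    hi <- ifelse(lo < 0, -1, ma)
    while (any(lo < hi)) {
      run <- lo < hi
      mid <- (lo + hi + 1) %/% 2
      le <- stats::dbinom(mid, na, null_prop) <= tha
      lo[run & le] <- mid[run & le]
      hi[run & !le] <- mid[run & !le] - 1
    }
    a <- lo
    # right flank: smallest k in [mode, n] with dbinom(k) <= thr
    lo2 <- ifelse(stats::dbinom(na, na, null_prop) <= tha, ma, na + 1)
    hi2 <- ifelse(lo2 > na, lo2, na)
    while (any(lo2 < hi2)) {
      run <- lo2 < hi2
      mid <- (lo2 + hi2) %/% 2
      le <- stats::dbinom(mid, na, null_prop) <= tha
      hi2[run & le] <- mid[run & le]
      lo2[run & !le] <- mid[run & !le] + 1
    }
    b <- lo2
    pv <- ifelse(a >= 0, stats::pbinom(a, na, null_prop), 0) +
      ifelse(b <= na, stats::pbinom(b - 1, na, null_prop,
                                    lower.tail = FALSE), 0)
    # for small totals, sum the point probabilities directly: bit-identical
    # to full enumeration (pbinom's tail algorithm differs in the last ulp)
    small <- which(na <= 256)
    for (i in small) {
      left <- if (a[i] >= 0) sum(stats::dbinom(0:a[i], na[i], null_prop))
              else 0
      right <- if (b[i] <= na[i])
        sum(stats::dbinom(b[i]:na[i], na[i], null_prop)) else 0
      pv[i] <- left + right
    }
    p[act] <- pmin(pmax(pv, dx[act]), 1)
  }
  out[ok] <- p
  out
}

#' Calibrate the null proportion on conserved ortholog counts
#'
#' The exact test conditions each pair's species-A count on the pair
#' total under a null proportion `pi = c * lib_a / (c * lib_a + lib_b)`,
#' where `c` is a scale factor that absorbs between-species differences
#' not explained by library size. `c` is chosen on a log-spaced grid to
#' minimize the excess of the conserved (assumed non-differential)
#' false-positive fraction over `alpha0` — i.e. the test is calibrated so
#' its rejection rate on the genes believed null does not exceed the
#' nominal level. Ties (typically a plateau where the rate is already
#' within the level) are resolved toward the `c` implied by the median
#' conserved count ratio.
#'
#' @param conserved_counts Data frame or matrix with columns `x_a`, `x_b`:
#'   pooled counts of the conserved pairs.
#' @param lib_a,lib_b Total library sizes (pooled over replicates) for
#'   species A and B.
#' @param alpha0 Calibration level (default 0.05).
#' @param c_range Range of the scale-factor grid (default `c(1/50, 50)`).
#' @param grid_size Number of log-spaced grid points (default 2001).
#' @return The fitted null proportion (numeric scalar) with attributes
#'   `c` (fitted scale factor) and `objective` (achieved
#'   `|fraction - alpha0|`).
#' @export
estimate_null_proportion <- function(conserved_counts, lib_a, lib_b,
                                     alpha0 = 0.05, c_range = c(1 / 50, 50),
                                     grid_size = 2001L) {
  stopifnot(lib_a > 0, lib_b > 0)
  cc <- as.data.frame(conserved_counts)
  stopifnot(all(c("x_a", "x_b") %in% names(cc)))
  cc <- cc[cc$x_a + cc$x_b >= 1, , drop = FALSE]
  if (nrow(cc) < 10L)
    stop("need at least 10 conserved pairs with nonzero totals to ",
         "calibrate the null proportion (have ", nrow(cc), ")")
  cs <- exp(seq(log(c_range[1L]), log(c_range[2L]), length.out = grid_size))
  obj <- vapply(cs, function(cv) {
    prop <- cv * lib_a / (cv * lib_a + lib_b)
    frac <- mean(conditional_binomial_p_vec(cc$x_a, cc$x_b, prop) < alpha0)
    max(frac - alpha0, 0)
  }, numeric(1))
  best <- which(obj <= min(obj) + 1e-12)
  if (length(best) > 1L) {
    # tie-break toward the c implied by the median conserved count ratio
    r_med <- stats::median((cc$x_a + 0.5) / (cc$x_b + 0.5))
    c_med <- r_med * lib_b / lib_a
    best <- best[which.min(abs(log(cs[best]) - log(c_med)))]
  }
  c_star <- cs[best]
  prop <- c_star * lib_a / (c_star * lib_a + lib_b)
  attr(prop, "c") <- c_star
  attr(prop, "objective") <- obj[if (length(best) == 1L) best else best[1L]]
  prop
}

#' Median of per-replicate p-values
#'
#' @param per_replicate_p Non-empty numeric vector of p-values.
#' @return Their median (average of the central two for even length).
#' @export
median_replicate_p <- function(per_replicate_p) {
  stopifnot(length(per_replicate_p) >= 1L)
  stats::median(per_replicate_p)
}

#' Log2 fold change with pseudocount
#'
#' @param mean_a,mean_b Non-negative mean expression (scaled TPM) of the
#'   two species.
#' @param pseudocount Value added to both means (default 1).
#' @return `log2((mean_a + pseudocount) / (mean_b + pseudocount))`.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Classify ortholog pairs into DEG status
#'
#' Applies the dual p-value rule — both the pooled-count p-value and the
#' replicate-median p-value strictly below `p_cut` — and the fold-change
#' threshold. Species-unique pairs (all replicates expressed in one
#' species, all undetected in the other) are classified `UNIQUE_A` /
#' `UNIQUE_B` and count as significant in their direction.
#'
#' @param tests Data frame with columns `scbn_p`, `median_p`, `log2fc`.
#' @param cfg A `de_config` (see [test_config()]).
#' @param repl_a,repl_b Optional matrices of per-replicate scaled TPM
#'   (pairs x replicates) used for the unique-gene rule; without them no
#'   pair is labelled unique.
#' @return `tests` with a `status` column added, levels `SIG_UP_A`,
#'   `SIG_UP_B`, `DEG_SMALL_FC`, `NS`, `UNIQUE_A`, `UNIQUE_B`.
#' @export
classify_pairs <- function(tests, cfg = test_config(), repl_a = NULL,
                           repl_b = NULL) {
  stopifnot(all(c("scbn_p", "median_p", "log2fc") %in% names(tests)))
  n <- nrow(tests)
  status <- rep("NS", n)
  deg <- tests$scbn_p < cfg$p_cut & tests$median_p < cfg$p_cut
  status[deg] <- "DEG_SMALL_FC"
  status[deg & tests$log2fc > cfg$lfc_cut] <- "SIG_UP_A"
  status[deg & tests$log2fc < -cfg$lfc_cut] <- "SIG_UP_B"
  if (!is.null(repl_a) && !is.null(repl_b)) {
    stopifnot(nrow(repl_a) == n, nrow(repl_b) == n)
    on_a <- rowSums(repl_a >= cfg$unique_high) == ncol(repl_a)
    off_a <- rowSums(repl_a < cfg$unique_low) == ncol(repl_a)
    on_b <- rowSums(repl_b >= cfg$unique_high) == ncol(repl_b)
    off_b <- rowSums(repl_b < cfg$unique_low) == ncol(repl_b)
    status[on_a & off_b] <- "UNIQUE_A"
    status[on_b & off_a] <- "UNIQUE_B"
  }
  tests$status <- status
  tests
}

#' Fold-change distribution of significant DEGs
#'
#' Counts significant DEGs per direction (up in A / up in B, including
#' species-unique pairs) in absolute log2 fold-change bins `[2, 5)`,
#' `[5, 10)` and `[10, Inf)`. Pairs whose pseudocount-damped fold change
#' falls below 2 (possible only for unique pairs) are counted in the
#' lowest bin.
#'
#' @param tests Classified test table (from [classify_pairs()]).
#' @return Data frame with columns `direction`, `bin`, `count`,
#'   `proportion` (NA when a direction has no significant DEGs).
#' @export
fold_change_bins <- function(tests) {
  stopifnot("status" %in% names(tests))
  bins <- c("[2,5)", "[5,10)", "[10,Inf)")
  one_direction <- function(sel) {
    lfc <- abs(tests$log2fc[sel])
    idx <- findInterval(lfc, c(5, 10)) + 1L
    counts <- tabulate(idx, nbins = 3L)
    tot <- sum(counts)
    data.frame(bin = bins, count = counts,
               proportion = if (tot > 0) counts / tot else NA_real_,
               stringsAsFactors = FALSE)
  }
  up_a <- one_direction(tests$status %in% c("SIG_UP_A", "UNIQUE_A"))
  up_b <- one_direction(tests$status %in% c("SIG_UP_B", "UNIQUE_B"))
  out <- rbind(cbind(direction = "up_A", up_a),
               cbind(direction = "up_B", up_b))
  rownames(out) <- NULL
  out
}

#' Differential expression across ortholog pairs
#'
#' Full between-species DE analysis. Counts are pooled over replicates per
#' species; the null proportion is calibrated on the conserved pairs; each
#' pair receives an exact pooled-count p-value (`scbn_p`), the median of
#' per-replicate exact p-values computed at per-replicate library sizes
#' with the same fitted scale factor (`median_p`), a pseudocounted log2
#' fold change on scaled TPM means, and a status call.
#'
#' @param counts_a,counts_b `count_table` objects for species A and B
#'   (replicate columns paired by position).
#' @param scaled Named list of scaled expression matrices,
#'   `list(A = , B = )` (from [apply_scaling()]).
#' @param pairs Ortholog pairs from [reciprocal_best_hits()].
#' @param conserved Conserved pairs from [select_conserved_pairs()].
#' @param cfg A `de_config`.
#' @return Data frame with one row per ortholog pair: `gene_a`, `gene_b`,
#'   `sum_a`, `sum_b`, `mean_a`, `mean_b`, `log2fc`, `scbn_p`, `median_p`,
#'   `status`; fitted null proportion and scale factor in attributes
#'   `null_prop` and `scale_c`.
#' @export
de_test <- function(counts_a, counts_b, scaled, pairs, conserved,
                    cfg = test_config()) {
  stopifnot(inherits(counts_a, "count_table"),
            inherits(counts_b, "count_table"))
  n_rep <- min(ncol(counts_a$counts), ncol(counts_b$counts))
  if (ncol(counts_a$counts) != ncol(counts_b$counts))
    warning("unequal replicate numbers; pairing the first ", n_rep,
            " replicates by position")
  ca <- counts_a$counts[pairs$gene_a, , drop = FALSE]
  cb <- counts_b$counts[pairs$gene_b, , drop = FALSE]
  if (anyNA(ca) || anyNA(cb))
    stop("ortholog pair gene(s) missing from the count tables")
  sum_a <- rowSums(ca)
  sum_b <- rowSums(cb)
  lib_a <- sum(counts_a$counts)
  lib_b <- sum(counts_b$counts)
  cons_idx <- match(conserved$gene_a, pairs$gene_a)
  if (anyNA(cons_idx))
    stop("conserved pairs must be a subset of the tested pairs")
  fit <- estimate_null_proportion(
    data.frame(x_a = sum_a[cons_idx], x_b = sum_b[cons_idx]),
    lib_a, lib_b, alpha0 = cfg$alpha0)
  c_star <- attr(fit, "c")
  scbn_p <- conditional_binomial_p_vec(sum_a, sum_b, as.numeric(fit))
  rep_p <- matrix(1, nrow(pairs), n_rep)
  for (i in seq_len(n_rep)) {
    la <- sum(counts_a$counts[, i])
    lb <- sum(counts_b$counts[, i])
    prop_i <- c_star * la / (c_star * la + lb)
    rep_p[, i] <- conditional_binomial_p_vec(ca[, i], cb[, i], prop_i)
  }
  median_p <- apply(rep_p, 1L, median_replicate_p)
  repl_a <- scaled$A[pairs$gene_a, , drop = FALSE]
  repl_b <- scaled$B[pairs$gene_b, , drop = FALSE]
  mean_a <- rowMeans(repl_a)
  mean_b <- rowMeans(repl_b)
  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    sum_a = unname(sum_a), sum_b = unname(sum_b),
                    mean_a = unname(mean_a), mean_b = unname(mean_b),
                    log2fc = log2_fold_change(unname(mean_a),
                                              unname(mean_b),
                                              cfg$pseudocount),
                    scbn_p = unname(scbn_p), median_p = unname(median_p),
                    stringsAsFactors = FALSE)
  out <- classify_pairs(out, cfg, repl_a, repl_b)
  rownames(out) <- NULL
  attr(out, "null_prop") <- as.numeric(fit)
  attr(out, "scale_c") <- c_star
  out
}
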