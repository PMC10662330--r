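# Independent brute-force oracles used to validate the fast
# implementations, plus small fixture builders. All oracles are written
# as direct enumerations and share no code with the package internals.

# Two-sided minimum-likelihood binomial p-value by full enumeration.
enum_binom_p <- function(x, n, prob) {
  d <- dbinom(0:n, n, prob)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Reciprocal best hits by exhaustive double loop over queries.
brute_rbh <- function(hits_ab, hits_ba, evalue_cut = 1e-5) {
  pick_best <- function(h) {
    h <- h[h$evalue <= evalue_cut, , drop = FALSE]
    out <- list()
    for (q in unique(h$qseqid)) {
      rows <- h[h$qseqid == q, , drop = FALSE]
      rows <- rows[order(-rows$bitscore, rows$evalue, -rows$pident,
                         rows$sseqid), , drop = FALSE]
      out[[q]] <- rows[1L, ]
    }
    out
  }
  ba <- pick_best(hits_ab)
  bb <- pick_best(hits_ba)
  res <- list()
  for (q in names(ba)) {
    s <- ba[[q]]$sseqid
    if (!is.null(bb[[s]]) && bb[[s]]$sseqid == q) {
      res[[q]] <- data.frame(
        gene_a = q, gene_b = s,
        evalue = min(ba[[q]]$evalue, bb[[s]]$evalue),
        pident = (ba[[q]]$pident + bb[[s]]$pident) / 2,
        bitscore = (ba[[q]]$bitscore + bb[[s]]$bitscore) / 2,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), pident = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res[order(names(res))])
  rownames(out) <- NULL
  out
}

# Random bidirectional hit tables for RBH stress tests.
random_hit_tables <- function(n_a, n_b, n_hits, seed) {
  set.seed(seed)
  mk <- function(qs, ss) {
    data.frame(
      qseqid = sample(qs, n_hits, replace = TRUE),
      sseqid = sample(ss, n_hits, replace = TRUE),
      pident = round(runif(n_hits, 50, 100), 2),
      length = sample(100:500, n_hits, replace = TRUE),
      mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
      sstart = 1L, send = 100L,
      evalue = 10^(-sample(0:50, n_hits, replace = TRUE)),
      bitscore = sample(seq(50, 500, by = 10), n_hits, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  list(ab = mk(sprintf("a%02d", 1:n_a), sprintf("b%02d", 1:n_b)),
       ba = mk(sprintf("b%02d", 1:n_b), sprintf("a%02d", 1:n_a)))
}

# --- NG86 oracle: explicit per-codon enumeration ------------------------

.gc <- Biostrings::GENETIC_CODE

oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; viable <- 0
    for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      ch2 <- ch; ch2[pos] <- b
      alt <- paste(ch2, collapse = "")
      if (.gc[[alt]] == "*") next
      viable <- viable + 1
      if (.gc[[alt]] == .gc[[codon]]) syn <- syn + 1
    }
    if (viable > 0) total <- total + syn / viable
  }
  total
}

# Recursive enumeration of all substitution orderings between two codons,
# skipping orderings that pass through a stop (fallback: all orderings).
oracle_pair_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  pos <- which(ch1 != ch2)
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd, blocked) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd,
                                        blocked = blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- ch2[p]
      cdn <- paste(nxt, collapse = "")
      hit_stop <- .gc[[cdn]] == "*"
      syn <- !hit_stop &&
        .gc[[cdn]] == .gc[[paste(cur, collapse = "")]]
      walk(nxt, setdiff(remaining, p),
           sd + as.numeric(isTRUE(syn)),
           nd + as.numeric(!isTRUE(syn) && !hit_stop),
           blocked || hit_stop)
    }
  }
  walk(ch1, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, "blocked"] == 0
  if (!any(ok)) return(c(sd = 0, nd = 0))
  c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
}

oracle_ng86_counts <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
          sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  d <- mapply(oracle_pair_diffs, codons_a, codons_b)
  c(S = S, N = N, Sd = sum(d["sd", ]), Nd = sum(d["nd", ]))
}

sense_codons <- names(.gc)[.gc != "*"]

random_codon_alignment <- function(n_codons, seed, mut_prob = 0.4) {
  set.seed(seed)
  a <- sample(sense_codons, n_codons, replace = TRUE)
  b <- vapply(a, function(cd) {
    if (runif(1) > mut_prob) return(cd)
    repeat {
      ch <- strsplit(cd, "")[[1]]
      k <- sample.int(3, sample.int(3, 1))
      for (p in k) ch[p] <- sample(c("A", "C", "G", "T"), 1)
      out <- paste(ch, collapse = "")
      if (.gc[[out]] != "*") return(out)
    }
  }, character(1), USE.NAMES = FALSE)
  structure(list(gene_a = "a", gene_b = "b", codons_a = a, codons_b = b,
                 n_codons = n_codons), class = "codon_alignment")
}

# Two-sided Fisher exact p by hypergeometric enumeration.
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  d <- dhyper(lo:hi, m, n, k)
  sum(d[d <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
}

# Small two-species dataset through the whole front of the pipeline.
small_pipeline_fixture <- function(seed = 11, n_genes = 600L, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
  sim <- simulate_count_tables(cfg)
  hits <- simulate_hit_tables(sim$truth, cfg)
  pairs <- reciprocal_best_hits(hits$hits_ab, hits$hits_ba)
  cons <- select_conserved_pairs(pairs)
  list(cfg = cfg, sim = sim, hits = hits, pairs = pairs, cons = cons)
}
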