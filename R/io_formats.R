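# File readers/writers for the formats the pipeline touches: FASTA,
# 12-column tabular alignment hits ("outfmt 6"), count tables and result TSVs.

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a data frame of records.
#' Sequences are stored uppercase and `U` is mapped to `T` so that one
#' canonical nucleotide alphabet is used throughout.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (header token before the first
#'   whitespace), `description` (remainder of the header, possibly empty)
#'   and `sequence` (uppercase residue string), one row per record, in
#'   file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with `id`, `description`, `sequence` columns
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$description) && nzchar(records$description[i]))
      hdr <- paste(hdr, records$description[i])
    seq <- records$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    lines <- substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
    writeLines(c(paste0(">", hdr), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read a 12-column tabular alignment hit file
#'
#' Parses the standard tab-separated hit table (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query/subject
#' coordinates, e-value, bit score). Scientific-notation e-values are
#' parsed; row order is preserved.
#'
#' @param path Path to the tab-separated file (no header).
#' @return Data frame with the 12 standard columns.
#' @export
read_blast6 <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("expected 12 tab-separated columns but found ", nf[bad],
         " at line ", bad, " of ", path)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  out <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  num_bad <- which(is.na(out$pident) | is.na(out$evalue) | is.na(out$bitscore))
  if (length(num_bad) > 0L)
    stop("non-numeric field at line ", num_bad[1L], " of ", path)
  if (any(out$pident < 0 | out$pident > 100))
    stop("pident outside [0,100] in ", path)
  if (any(out$evalue < 0)) stop("negative e-value in ", path)
  out
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits Data frame with the 12 standard columns (see [read_blast6()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_blast6 <- function(hits, path) {
  stopifnot(all(BLAST6_COLS %in% names(hits)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(hits) > 0L) {
    rows <- paste(hits$qseqid, hits$sseqid,
                  format(hits$pident, digits = 6, trim = TRUE),
                  hits$length, hits$mismatch, hits$gapopen,
                  hits$qstart, hits$qend, hits$sstart, hits$send,
                  format(hits$evalue, digits = 6, scientific = TRUE,
                         trim = TRUE),
                  format(hits$bitscore, digits = 6, trim = TRUE),
                  sep = "\t")
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Read a gene count table
#'
#' Reads a TSV with gene ids in the first column, a mandatory `length`
#' column (transcript length in bp) and one column of non-negative integer
#' counts per sample.
#'
#' @param path Path to the TSV file.
#' @return A `count_table`: list with `counts` (integer matrix, genes x
#'   samples, dimnames set), and `lengths` (named numeric vector of
#'   transcript lengths in bp).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("count table needs gene id, length and >=1 sample column: ", path)
  gene_col <- names(df)[1L]
  if (!"length" %in% names(df))
    stop("count table is missing the 'length' column: ", path)
  gene_ids <- as.character(df[[gene_col]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  lengths <- as.numeric(df$length)
  if (any(is.na(lengths) | lengths <= 0)) {
    bad <- gene_ids[which(is.na(lengths) | lengths <= 0)[1L]]
    stop("non-positive or missing length for gene '", bad, "'")
  }
  sample_cols <- setdiff(names(df), c(gene_col, "length"))
  cm <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(cm) <- "numeric"
  bad <- which(is.na(cm) | cm < 0 | cm != round(cm), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("invalid count for gene '", gene_ids[bad[1L, 1L]], "', sample '",
         sample_cols[bad[1L, 2L]], "' (must be a non-negative integer)")
  storage.mode(cm) <- "integer"
  dimnames(cm) <- list(gene_ids, sample_cols)
  count_table(cm, stats::setNames(lengths, gene_ids))
}

#' Construct a count table
#'
#' @param counts Integer matrix of non-negative counts, genes in rows
#'   (rownames = gene ids), samples in columns (colnames = sample ids).
#' @param lengths Named numeric vector of transcript lengths (bp),
#'   aligned to `rownames(counts)`.
#' @return A `count_table` object.
#' @export
count_table <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("negative counts")
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths) | lengths <= 0))
    stop("every gene needs a positive transcript length")
  structure(list(counts = counts, lengths = lengths), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  samples: ", paste(colnames(x$counts), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write a count table to TSV
#'
#' @param tab A `count_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(tab, path) {
  df <- data.frame(gene_id = rownames(tab$counts),
                   length = unname(tab$lengths),
                   tab$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_results_table(df, path)
}

#' Write a results table as TSV
#'
#' Writes any data frame of results as a TSV with header, UTF-8, Unix
#' newlines, numbers at >= 6 significant digits, preserving row order, so
#' that repeated runs produce byte-identical files.
#'
#' @param records Data frame (rows share a schema).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "wb")
  on.exit(close(con))
  cols <- lapply(records, function(col) {
    if (is.numeric(col)) {
      vapply(col, function(v) {
        if (is.na(v)) "NA"
        else if (v == round(v) && abs(v) < 1e15) sprintf("%.0f", v)
        else format(v, digits = 9, scientific = NA, trim = TRUE)
      }, character(1))
    } else as.character(col)
  })
  header <- paste(names(records), collapse = "\t")
  if (nrow(records) == 0L) {
    writeLines(header, con, sep = "\n")
  } else {
    body <- do.call(paste, c(cols, sep = "\t"))
    writeLines(c(header, body), con, sep = "\n")
  }
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write codon alignments as axt-style blocks
#'
#' Each block is a name line (`geneA-geneB`), the two aligned nucleotide
#' sequences, then a blank line.
#'
#' @param alignments List of codon alignments (see [thread_codons()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_axt <- function(alignments, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (aln in alignments) {
    writeLines(c(paste0(aln$gene_a, "-", aln$gene_b),
                 paste(aln$codons_a, collapse = ""),
                 paste(aln$codons_b, collapse = ""),
                 ""), con, sep = "\n")
  }
  invisible(path)
}
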