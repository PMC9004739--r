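# Unique-read x sample count table: construction, counts-per-million
# normalization, and the rare-read filter.

new_count_table <- function(sequences, samples, raw, norm = NULL) {
  raw <- as.matrix(raw)
  dimnames(raw) <- list(NULL, samples)
  structure(list(sequence = as.character(sequences),
                 samples = as.character(samples),
                 raw = raw,
                 norm = norm),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(x$sequence), "unique reads x",
      length(x$samples), "samples\n")
  cat("  raw library sizes:",
      paste(format(colSums(x$raw)), collapse = " "), "\n")
  if (!is.null(x$norm)) cat("  CPM normalization: present\n")
  invisible(x)
}

#' Build the unique-read count table
#'
#' One row per distinct sequence observed in any sample; the entry is the
#' read's multiplicity in that sample. Rows are ordered by descending total
#' raw count, ties broken lexicographically by sequence, so output tables
#' are deterministic and human-scannable.
#'
#' @param per_sample_reads named list, one character vector of reads per
#'   sample.
#' @return a `count_table` (raw counts only; see [normalize_cpm()]).
#' @export
build_count_table <- function(per_sample_reads) {
  if (!length(per_sample_reads)) stop("at least one sample is required")
  samples <- names(per_sample_reads)
  if (is.null(samples) || any(!nzchar(samples)) || anyDuplicated(samples)) {
    stop("per_sample_reads must be a named list with unique sample names")
  }
  all_seqs <- sort(unique(unlist(per_sample_reads, use.names = FALSE)))
  raw <- matrix(0, nrow = length(all_seqs), ncol = length(samples))
  for (j in seq_along(samples)) {
    tab <- table(factor(per_sample_reads[[j]], levels = all_seqs))
    raw[, j] <- as.integer(tab)
  }
  ord <- order(-rowSums(raw), all_seqs, method = "radix")
  new_count_table(all_seqs[ord], samples, raw[ord, , drop = FALSE])
}

#' Normalize each sample to one million reads (CPM)
#'
#' `norm[i, j] = raw[i, j] / colsum_j * 1e6`. An all-zero column stays
#' all-zero rather than raising a division error.
#'
#' @param table a `count_table`.
#' @return the table with its `norm` matrix (re)computed.
#' @export
normalize_cpm <- function(table) {
  stopifnot(inherits(table, "count_table"))
  cs <- colSums(table$raw)
  scale <- ifelse(cs > 0, 1e6 / cs, 0)
  table$norm <- sweep(table$raw, 2L, scale, `*`)
  dimnames(table$norm) <- dimnames(table$raw)
  table
}

#' Remove rare reads (likely sequencing errors)
#'
#' A read is removed when its normCount -- the total of its CPM-normalized
#' counts across samples -- is strictly less than n, the number of samples
#' in the analysis. After filtering, CPM is recomputed on the kept table so
#' that its columns again sum to one million.
#'
#' @param table a `count_table` with `norm` computed.
#' @return list with elements `kept` and `removed` (both `count_table`s,
#'   re-normalized), and `all` (the intact pre-filter table).
#' @export
filter_rare_reads <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$norm)) table <- normalize_cpm(table)
  n <- length(table$samples)
  keep <- rowSums(table$norm) >= n
  subset_ct <- function(idx) {
    normalize_cpm(new_count_table(table$sequence[idx], table$samples,
                                  table$raw[idx, , drop = FALSE]))
  }
  list(kept = subset_ct(keep), removed = subset_ct(!keep), all = table)
}

#' Read a count table from TSV
#'
#' Dialect: first column `sequence`, remaining columns integer raw counts,
#' one column per sample. This is also the supported entry point when
#' starting the pipeline from a pre-built counts table.
#'
#' @param path TSV path.
#' @return a `count_table` (raw counts; not yet normalized).
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("count table needs `sequence` plus >=1 sample column")
  seqs <- toupper(as.character(df[[1L]]))
  if (anyDuplicated(seqs)) stop("count table has duplicate sequences")
  raw <- as.matrix(df[, -1L, drop = FALSE])
  if (any(raw < 0) || any(raw != round(raw))) {
    stop("raw counts must be non-negative integers")
  }
  ord <- order(-rowSums(raw), seqs, method = "radix")
  new_count_table(seqs[ord], colnames(df)[-1L], raw[ord, , drop = FALSE])
}

#' Write a count table as TSV
#'
#' @param table a `count_table`.
#' @param path output path.
#' @param what `"raw"` or `"norm"` values.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, what = c("raw", "norm")) {
  what <- match.arg(what)
  m <- if (what == "raw") table$raw else table$norm
  if (is.null(m)) stop("normalized counts not computed; run normalize_cpm()")
  df <- data.frame(sequence = table$sequence, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
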