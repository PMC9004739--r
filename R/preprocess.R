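# Simplified read cleanup: UMI stripping, exact 5'/3' adapter removal and
# mode-dependent length filtering. Fuzzy trimming parity with external
# trimmers is deliberately out of scope; pre-trimmed input can skip this
# stage entirely.

#' Trimming configuration
#'
#' @param three_prime_adapter 3' adapter; everything from its first exact
#'   occurrence to the read end is removed. Default `"TCCGACGATC"`.
#' @param five_prime_adapters character vector of 5' adapters removed when
#'   found as an exact prefix (longest match wins). Default none.
#' @param umi_length_5p number of 5' bases stripped before adapter removal
#'   (fixed-length UMI scheme). Default 0.
#' @param mode `"risc"` (keep reads >= 7 nt, i.e. long enough to carry a
#'   seed) or `"total"` (keep 18-25 nt).
#' @return object of class `trim_config`.
#' @export
trim_config <- function(three_prime_adapter = "TCCGACGATC",
                        five_prime_adapters = character(),
                        umi_length_5p = 0L,
                        mode = c("risc", "total")) {
  mode <- match.arg(mode)
  umi_length_5p <- as.integer(umi_length_5p)
  stopifnot(umi_length_5p >= 0L, nzchar(three_prime_adapter))
  structure(list(three_prime_adapter = toupper(three_prime_adapter),
                 five_prime_adapters = toupper(as.character(five_prime_adapters)),
                 umi_length_5p = umi_length_5p,
                 mode = mode),
            class = "trim_config")
}

#' Trim reads: UMI, then 5' adapters, then the 3' adapter
#'
#' Removal order: (1) the first `umi_length_5p` bases; (2) any 5' adapter
#' occurring as an exact prefix (longest wins); (3) everything from the
#' first exact occurrence of the 3' adapter onwards. An empty result is
#' legal; the length filter disposes of it.
#'
#' @param reads character vector of read sequences.
#' @param cfg a [trim_config()].
#' @return character vector of trimmed inserts.
#' @export
trim_reads <- function(reads, cfg) {
  stopifnot(inherits(cfg, "trim_config"))
  reads <- toupper(as.character(reads))
  if (cfg$umi_length_5p > 0L) {
    reads <- substr(reads, cfg$umi_length_5p + 1L, nchar(reads))
  }
  if (length(cfg$five_prime_adapters)) {
    for (ad in cfg$five_prime_adapters[order(-nchar(cfg$five_prime_adapters))]) {
      is_prefix <- startsWith(reads, ad)
      reads[is_prefix] <- substr(reads[is_prefix], nchar(ad) + 1L,
                                 nchar(reads[is_prefix]))
    }
  }
  pos <- regexpr(cfg$three_prime_adapter, reads, fixed = TRUE)
  hit <- pos > 0L
  reads[hit] <- substr(reads[hit], 1L, pos[hit] - 1L)
  reads
}

#' Mode-dependent read length filter
#'
#' Total small RNA-seq mode keeps 18-25 nt reads (shorter and longer reads
#' have a reduced chance of entering the RISC); RISC-bound mode keeps every
#' read long enough to carry a seed (>= 7 nt). Order is preserved.
#'
#' @inheritParams trim_reads
#' @return filtered character vector.
#' @export
length_filter <- function(reads, cfg) {
  stopifnot(inherits(cfg, "trim_config"))
  len <- nchar(reads)
  keep <- if (cfg$mode == "total") len >= 18L & len <= 25L else len >= 7L
  reads[keep]
}

#' Read small-RNA sequences from FASTQ or FASTA
#'
#' Reads containing characters outside \{A,C,G,T\} (e.g. N calls) are
#' dropped, as the downstream seed alphabet is strict.
#'
#' @param path file path; format inferred from the extension
#'   (`.fastq`/`.fq` vs `.fasta`/`.fa`), gzip allowed.
#' @return character vector of read sequences (one element per read).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- sub("\\.gz$", "", tolower(path))
  fmt <- if (grepl("\\.(fastq|fq)$", ext)) "fastq" else "fasta"
  x <- as.character(Biostrings::readDNAStringSet(path, format = fmt))
  x <- toupper(unname(x))
  x[grepl("^[ACGT]+$", x)]
}

#' Write reads as FASTQ
#'
#' Constant quality (`I`); read ids are `read_1..n` or supplied names.
#'
#' @param reads character vector of read sequences.
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    writeLines(paste0("@", ids, "\n", reads, "\n+\n",
                      vapply(nchar(reads), function(n)
                        strrep("I", n), character(1))), con)
  }
  invisible(path)
}
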