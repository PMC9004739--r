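# Identity-based read annotation. The external aligner of the original
# workflow is replaced by a bespoke ungapped identity matcher implementing
# the two stated criteria directly: >= 18 nt of complete identity for
# mature-miRNA assignment, and >= 95% ungapped identity over the read for
# the small-RNA ("RNA world") catalog. Artifact entries are purged by
# keyword on the RNA-world assignment name.

ARTIFACT_KEYWORDS <- c("Tuschl", "artifical", "marker", "adapter", "artificial")

#' Construct a reference sequence set
#'
#' @param kind `"mirna"` (mature miRNAs) or `"rnaworld"` (catalog of
#'   cellular small RNAs: tRNA/rRNA fragments etc.).
#' @param names unique entry names.
#' @param sequences DNA sequences, one per name.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(kind = c("mirna", "rnaworld"), names, sequences) {
  kind <- match.arg(kind)
  names <- as.character(names)
  sequences <- toupper(as.character(sequences))
  if (length(names) != length(sequences)) stop("names/sequences length mismatch")
  if (anyDuplicated(names)) stop("reference names must be unique within a set")
  if (any(!nzchar(sequences))) stop("reference sequences must be non-empty")
  structure(list(kind = kind, names = names, sequences = sequences),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set (", x$kind, "): ", length(x$names), " entries, lengths ",
      paste(range(nchar(x$sequences)), collapse = "-"), " nt\n", sep = "")
  invisible(x)
}

#' Read a reference set from FASTA
#'
#' @param path FASTA path.
#' @inheritParams reference_set
#' @return a [reference_set()].
#' @export
read_reference_fasta <- function(path, kind = c("mirna", "rnaworld")) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  reference_set(match.arg(kind), names(x), as.character(x))
}

#' Write a reference set as FASTA
#'
#' @param refs a [reference_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  stopifnot(inherits(refs, "reference_set"))
  x <- Biostrings::DNAStringSet(refs$sequences)
  names(x) <- refs$names
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Assign mature-miRNA identity to reads
#'
#' A reference qualifies when it shares an ungapped, exactly identical
#' substring of at least 18 nt with the read. Among qualifying references
#' the longest shared substring wins; remaining ties go to the earlier
#' alignment start on the read, then to the lexicographically smaller name.
#'
#' @param reads character vector of read sequences.
#' @param refs a [reference_set()] of kind `"mirna"`.
#' @param min_identity_nt minimum shared-substring length (default 18).
#' @return character vector of assigned names; `NA` where no hit.
#' @export
match_mirna <- function(reads, refs, min_identity_nt = 18L) {
  stopifnot(inherits(refs, "reference_set"), refs$kind == "mirna")
  ref_seqs <- refs$sequences
  name_ord <- order(refs$names, method = "radix")
  max_ref_len <- max(nchar(ref_seqs))
  vapply(as.character(reads), function(read) {
    L <- nchar(read)
    top <- min(L, max_ref_len)
    if (top < min_identity_nt) return(NA_character_)
    for (len in seq(top, min_identity_nt)) {
      for (start in seq_len(L - len + 1L)) {
        pat <- substr(read, start, start + len - 1L)
        hits <- grepl(pat, ref_seqs, fixed = TRUE)
        if (any(hits)) {
          return(refs$names[name_ord[hits[name_ord]]][1L])
        }
      }
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Assign small-RNA ("RNA world") identity to reads
#'
#' The full read is slid ungapped along each reference; a window is a hit
#' when identity (matching positions / read length, mismatches only, no
#' indels) is at least `min_identity`. The best hit has the highest
#' identity; ties are broken by lexicographic name.
#'
#' @param reads character vector of read sequences.
#' @param refs a [reference_set()] of kind `"rnaworld"`.
#' @param min_identity identity threshold as a fraction of read length
#'   (default 0.95; a 20 nt read tolerates exactly one mismatch).
#' @return character vector of assigned names; `NA` where no hit.
#' @export
match_rnaworld <- function(reads, refs, min_identity = 0.95) {
  stopifnot(inherits(refs, "reference_set"), refs$kind == "rnaworld")
  subject <- Biostrings::DNAStringSet(refs$sequences)
  name_ord <- order(refs$names, method = "radix")
  vapply(as.character(reads), function(read) {
    L <- nchar(read)
    mm_max <- floor(L * (1 - min_identity))
    pat <- Biostrings::DNAString(read)
    for (mm in 0:mm_max) {
      n_hits <- Biostrings::vcountPattern(pat, subject, max.mismatch = mm,
                                          with.indels = FALSE)
      if (any(n_hits > 0L)) {
        hits <- n_hits > 0L
        return(refs$names[name_ord[hits[name_ord]]][1L])
      }
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Is an RNA-world assignment an artifact sequence?
#'
#' Case-sensitive substring test against the fixed keyword list
#' `Tuschl, artifical, marker, adapter, artificial` (the historical
#' misspelling is part of the list on purpose: catalog entries carry it).
#' Reads whose assignment matches are removed from all downstream outputs.
#'
#' @param names character vector of RNA-world assignment names (`NA` =
#'   unassigned, never purged).
#' @return logical vector.
#' @export
purge_artifacts <- function(names) {
  out <- rep(FALSE, length(names))
  ok <- !is.na(names)
  for (kw in ARTIFACT_KEYWORDS) {
    out[ok] <- out[ok] | grepl(kw, names[ok], fixed = TRUE)
  }
  out
}

#' Annotate a count table with seed, viability and RNA identities
#'
#' Every kept row gains its 6mer seed, species-averaged % seed viability,
#' miRNA hit, RNA-world hit, and a display name (miRNA hit if present, else
#' RNA-world hit, else `"unknown"`). Rows whose RNA-world assignment is an
#' artifact are dropped; counts are otherwise untouched.
#'
#' @param table a `count_table` (rare-read-filtered; rows must be >= 7 nt).
#' @param mirna_refs a [reference_set()] of kind `"mirna"`.
#' @param rnaworld_refs a [reference_set()] of kind `"rnaworld"`.
#' @param viability a [seed_viability_table()].
#' @return object of class `annotated_count_table`: a `count_table` plus
#'   `seed`, `viability`, `mirna`, `rnaworld`, `name` row vectors and an
#'   `artifacts` count table of the dropped rows.
#' @export
annotate_table <- function(table, mirna_refs, rnaworld_refs, viability) {
  stopifnot(inherits(table, "count_table"),
            inherits(viability, "seed_viability_table"))
  if (is.null(table$norm)) table <- normalize_cpm(table)
  seed <- extract_seed(table$sequence)
  viab <- lookup_viability(viability, seed)
  mirna <- match_mirna(table$sequence, mirna_refs)
  rnaworld <- match_rnaworld(table$sequence, rnaworld_refs)
  artifact <- purge_artifacts(rnaworld)
  keep <- !artifact
  kept <- normalize_cpm(new_count_table(table$sequence[keep], table$samples,
                                        table$raw[keep, , drop = FALSE]))
  nm <- ifelse(!is.na(mirna[keep]), mirna[keep],
               ifelse(!is.na(rnaworld[keep]), rnaworld[keep], "unknown"))
  structure(
    c(kept,
      list(seed = seed[keep], viability = viab[keep],
           mirna = mirna[keep], rnaworld = rnaworld[keep], name = nm,
           artifacts = new_count_table(table$sequence[artifact], table$samples,
                                       table$raw[artifact, , drop = FALSE]))),
    class = c("annotated_count_table", "count_table"))
}

#' @export
print.annotated_count_table <- function(x, ...) {
  cat("annotated_count_table:", length(x$sequence), "reads x",
      length(x$samples), "samples;",
      sum(!is.na(x$mirna)), "miRNA-assigned,",
      length(x$artifacts$sequence), "artifact rows dropped\n")
  invisible(x)
}

subset_annotated <- function(x, idx) {
  stopifnot(inherits(x, "annotated_count_table"))
  x$sequence <- x$sequence[idx]
  x$raw <- x$raw[idx, , drop = FALSE]
  x$norm <- if (!is.null(x$norm)) x$norm[idx, , drop = FALSE]
  for (f in c("seed", "viability", "mirna", "rnaworld", "name")) {
    x[[f]] <- x[[f]][idx]
  }
  if (!is.null(x$extra)) x$extra <- x$extra[idx, , drop = FALSE]
  x
}
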