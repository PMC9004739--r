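# Core value types: read sequences, 6mer seeds, and the seed-viability lookup.

NUC_DNA <- c("A", "C", "G", "T")
NUC_RNA <- c("A", "C", "G", "U")

#' Extract the 6mer seed of a small RNA read
#'
#' The seed of a RISC-loaded guide strand is positions 2-7 from the 5' end.
#' Reads are DNA as sequenced; seeds are reported in the RNA alphabet, so T
#' is transliterated to U here and nowhere else.
#'
#' @param reads character vector of read sequences over \{A,C,G,T\}.
#' @return character vector of 6mer seeds over \{A,C,G,U\}.
#' @examples
#' extract_seed("AGGGGGCAAA")        # "GGGGGC"
#' extract_seed("TGAGGTAGTAGGTTG")   # "GAGGUA"
#' @export
extract_seed <- function(reads) {
  reads <- as.character(reads)
  if (any(nchar(reads) < 7)) {
    stop("cannot extract a 6mer seed from reads shorter than 7 nt; ",
         "apply a length filter first")
  }
  chartr("T", "U", substr(reads, 2L, 7L))
}

#' Enumerate all 4096 possible 6mer seeds
#'
#' @return character vector of length 4096, lexicographic in A < C < G < U.
#' @export
enumerate_seed_space <- function() {
  g <- expand.grid(p6 = NUC_RNA, p5 = NUC_RNA, p4 = NUC_RNA,
                   p3 = NUC_RNA, p2 = NUC_RNA, p1 = NUC_RNA,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3, g$p4, g$p5, g$p6)
}

#' Construct a seed-viability table
#'
#' Maps every 6mer seed to the % cell viability measured after transfecting
#' an siRNA carrying that seed (low viability = toxic seed), per cell line,
#' plus the species average across cell lines. The table must be complete:
#' exactly one row per possible seed. Values above 100 are legal (growth
#' stimulation); negative values are not.
#'
#' @param seeds character vector of 4096 distinct 6mer seeds (RNA alphabet;
#'   T is accepted and transliterated).
#' @param viability numeric matrix (4096 x n_cell_lines) of % viability.
#' @param species `"human"` or `"mouse"`.
#' @return object of class `seed_viability_table` with elements `seeds`,
#'   `per_line` (matrix), `averaged` (named numeric), `species`.
#' @export
seed_viability_table <- function(seeds, viability, species = c("human", "mouse")) {
  species <- match.arg(species)
  seeds <- chartr("T", "U", toupper(as.character(seeds)))
  viability <- as.matrix(viability)
  if (length(seeds) != 4096L || anyDuplicated(seeds) ||
      !setequal(seeds, enumerate_seed_space())) {
    stop("viability table must contain each of the 4096 possible 6mer seeds ",
         "exactly once (got ", length(unique(seeds)), " distinct seeds)")
  }
  if (nrow(viability) != length(seeds)) {
    stop("viability matrix must have one row per seed")
  }
  if (any(viability < 0)) stop("% viability values must be non-negative")
  avg <- rowMeans(viability)
  ord <- order(seeds, method = "radix")
  structure(
    list(seeds = seeds[ord],
         per_line = viability[ord, , drop = FALSE],
         averaged = stats::setNames(avg[ord], seeds[ord]),
         species = species),
    class = "seed_viability_table")
}

#' @export
print.seed_viability_table <- function(x, ...) {
  cat("seed_viability_table:", length(x$seeds), "seeds,",
      ncol(x$per_line), x$species, "cell lines\n")
  cat("  averaged % viability: median",
      format(stats::median(x$averaged), digits = 4),
      "range", paste(format(range(x$averaged), digits = 4), collapse = " .. "),
      "\n")
  invisible(x)
}

#' Look up species-averaged % viability for seeds
#'
#' @param table a [seed_viability_table()].
#' @param seeds character vector of 6mer seeds (RNA alphabet).
#' @return numeric vector of species-averaged % viability.
#' @export
lookup_viability <- function(table, seeds) {
  stopifnot(inherits(table, "seed_viability_table"))
  v <- table$averaged[chartr("T", "U", as.character(seeds))]
  if (anyNA(v)) {
    bad <- unique(seeds[is.na(v)])
    stop("seed(s) absent from viability table (malformed table?): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  unname(v)
}

#' Read a seed-viability resource from TSV
#'
#' Expected format: header `seed<TAB>cellline1<TAB>...`, one row per seed,
#' 4096 rows.
#'
#' @param path TSV file path.
#' @inheritParams seed_viability_table
#' @return a [seed_viability_table()].
#' @export
read_viability_table <- function(path, species = c("human", "mouse")) {
  species <- match.arg(species)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("viability TSV needs a seed column plus >=1 cell line")
  seed_viability_table(df[[1L]], as.matrix(df[, -1L, drop = FALSE]), species)
}

#' Write a seed-viability table as TSV
#'
#' @param table a [seed_viability_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_viability_table <- function(table, path) {
  stopifnot(inherits(table, "seed_viability_table"))
  df <- data.frame(seed = table$seeds, table$per_line, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
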