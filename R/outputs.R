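# The six keyed output families. A: annotated counts; B: collapsed by
# (seed, assigned name) with the seed-keyed intermediary; C: 1%-viability
# bins (Seed Tox profile); D/E/F: row expansions (toxicity value, seed
# string, per-position nucleotide) after dividing counts by 1000.

# round half away from zero: 0.5 -> 1, 1.5 -> 2, -0.5 -> -1 (base round()
# would give banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Write an Output A table (annotated counts)
#'
#' TSV columns: sequence, seed, viability, miRNA, RNAworld, then one value
#' column per sample (raw or CPM) or the differential statistics.
#'
#' @param table an `annotated_count_table`.
#' @param path output path; conventional prefixes are `A_rawCounts`,
#'   `A_normCounts` and `A_diff`.
#' @param flavor `"rawCounts"`, `"normCounts"` or `"diff"` (requires a
#'   table produced by [select_differential()]).
#' @return `path`, invisibly.
#' @export
write_output_a <- function(table, path, flavor = c("normCounts", "rawCounts", "diff")) {
  flavor <- match.arg(flavor)
  stopifnot(inherits(table, "annotated_count_table"))
  base <- data.frame(sequence = table$sequence, seed = table$seed,
                     viability = table$viability,
                     miRNA = ifelse(is.na(table$mirna), "", table$mirna),
                     RNAworld = ifelse(is.na(table$rnaworld), "", table$rnaworld),
                     stringsAsFactors = FALSE, check.names = FALSE)
  vals <- switch(flavor,
                 rawCounts = as.data.frame(table$raw),
                 normCounts = as.data.frame(table$norm),
                 diff = {
                   if (is.null(table$extra)) stop("diff flavor needs a select_differential() table")
                   table$extra
                 })
  utils::write.table(cbind(base, vals), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse Output A by (6mer seed, assigned name) to Output B
#'
#' Rows sharing both the seed and the display name (the miRNA hit if
#' present, else the RNA-world hit) are summed. For the differential
#' branch (`values = "delta"`) the absolute delta CPM is summed into an
#' `Up` or `Down` column according to the sign of delta; sign is carried as
#' the group label, never as a negative count.
#'
#' @param table an `annotated_count_table`.
#' @param values `"norm"` (default), `"raw"`, or `"delta"`.
#' @return object of class `collapsed_seed_table`: data.frame with `seed`,
#'   `name`, `viability` and one numeric column per sample (or Up/Down).
#' @export
collapse_to_b <- function(table, values = c("norm", "raw", "delta")) {
  values <- match.arg(values)
  stopifnot(inherits(table, "annotated_count_table"))
  m <- switch(values,
              norm = table$norm,
              raw = table$raw,
              delta = {
                if (is.null(table$extra)) stop("delta values need a select_differential() table")
                up <- ifelse(table$extra$direction == "Up", abs(table$extra$delta), 0)
                dn <- ifelse(table$extra$direction == "Down", abs(table$extra$delta), 0)
                cbind(Up = up, Down = dn)
              })
  if (is.null(m)) stop("requested values not present; run normalize_cpm()")
  key <- paste(table$seed, table$name, sep = "\r")
  first <- !duplicated(key)
  summed <- rowsum(m, group = key, reorder = FALSE)
  # rowsum orders by first appearance because reorder = FALSE
  keys_first <- key[first]
  summed <- summed[keys_first, , drop = FALSE]
  out <- data.frame(seed = table$seed[first], name = table$name[first],
                    viability = table$viability[first],
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(summed, check.names = FALSE))
  rownames(out) <- NULL
  ord <- order(-rowSums(summed), out$seed, out$name, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("collapsed_seed_table", "data.frame"),
            value_cols = colnames(summed))
}

#' Reduce Output B to one row per seed (Int_seedKeyed)
#'
#' Each seed is listed only once even if it originates from multiple small
#' RNAs; values are summed across names.
#'
#' @param b a [collapse_to_b()] result.
#' @return a `collapsed_seed_table` keyed by seed only (`name` is `"*"`).
#' @export
int_seed_keyed <- function(b) {
  stopifnot(inherits(b, "collapsed_seed_table"))
  vc <- attr(b, "value_cols")
  if (!nrow(b)) {
    out <- b
    out$name <- character(0)
    return(out)
  }
  summed <- rowsum(as.matrix(b[vc]), group = b$seed, reorder = FALSE)
  first <- !duplicated(b$seed)
  summed <- summed[b$seed[first], , drop = FALSE]
  out <- data.frame(seed = b$seed[first], name = "*",
                    viability = b$viability[first],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(summed, check.names = FALSE))
  rownames(out) <- NULL
  ord <- order(-rowSums(summed), out$seed, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("collapsed_seed_table", "data.frame"),
            value_cols = vc)
}

#' Average Output B value columns within groups
#'
#' @param b a `collapsed_seed_table`.
#' @param groups named character vector mapping value columns to group
#'   labels (e.g. `c(s1 = "wt", s2 = "wt", s3 = "ko")`).
#' @return a `collapsed_seed_table` with one value column per group.
#' @export
collapse_group_average <- function(b, groups) {
  stopifnot(inherits(b, "collapsed_seed_table"))
  vc <- attr(b, "value_cols")
  miss <- setdiff(names(groups), vc)
  if (length(miss)) stop("unknown value columns: ", paste(miss, collapse = ", "))
  glev <- unique(unname(groups))
  avg <- sapply(glev, function(g) {
    rowMeans(as.matrix(b[names(groups)[groups == g]]))
  })
  avg <- matrix(avg, nrow = nrow(b), dimnames = list(NULL, glev))
  out <- cbind(b[c("seed", "name", "viability")],
               as.data.frame(avg, check.names = FALSE))
  structure(out, class = c("collapsed_seed_table", "data.frame"),
            value_cols = glev)
}

#' Bin Output B into 1% seed-viability bins (Output C / Seed Tox profile)
#'
#' Each row's % viability is rounded to the nearest integer (half away from
#' zero) and its counts are added to that bin. A row is emitted for every
#' bin across the full range, even when its count is zero, so the table
#' plots directly as the Seed Tox graph.
#'
#' @param b a `collapsed_seed_table`.
#' @param range integer bin range, conventionally
#'   `c(floor(min), ceiling(max))` of the viability resource; default is
#'   the range of the viabilities present in `b`.
#' @return data.frame with `bin` plus one count column per value column.
#' @export
bin_to_c <- function(b, range = NULL) {
  stopifnot(inherits(b, "collapsed_seed_table"))
  vc <- attr(b, "value_cols")
  bin <- round_half_away(b$viability)
  if (is.null(range)) range <- if (nrow(b)) base::range(bin) else c(0, 0)
  bins <- seq(floor(range[1]), ceiling(range[2]))
  m <- matrix(0, nrow = length(bins), ncol = length(vc),
              dimnames = list(NULL, vc))
  if (nrow(b)) {
    s <- rowsum(as.matrix(b[vc]), group = bin)
    idx <- match(as.integer(rownames(s)), bins)
    if (anyNA(idx)) stop("viability outside the declared bin range")
    m[idx, ] <- s
  }
  data.frame(bin = bins, as.data.frame(m, check.names = FALSE),
             check.names = FALSE)
}

scaled_counts <- function(counts) round_half_away(counts / 1000)

#' Expand Output B rows by toxicity value (Output D)
#'
#' Each row contributes `round(count / 1000)` copies of its % viability
#' (rounding half away from zero); the rescaling keeps downstream
#' statistics tractable. Rows whose count rounds to zero vanish.
#'
#' @param b a `collapsed_seed_table`.
#' @param column which value column (sample or group) to expand.
#' @return numeric vector of viability values, one element per rescaled
#'   seed instance.
#' @export
expand_to_d <- function(b, column) {
  stopifnot(inherits(b, "collapsed_seed_table"), column %in% attr(b, "value_cols"))
  rep(b$viability, times = pmax(0L, scaled_counts(b[[column]])))
}

#' Expand Output B rows by 6mer seed (Output E)
#'
#' As [expand_to_d()] but each instance carries its seed string; this is
#' the sequence-logo input.
#'
#' @inheritParams expand_to_d
#' @return character vector of seeds, one per rescaled instance.
#' @export
expand_to_e <- function(b, column) {
  stopifnot(inherits(b, "collapsed_seed_table"), column %in% attr(b, "value_cols"))
  rep(b$seed, times = pmax(0L, scaled_counts(b[[column]])))
}

#' Expand to per-position nucleotide rows (Output F)
#'
#' Rows with a pre-scaling count below 1000 are omitted. Every remaining
#' row contributes `round(count / 1000)` seed instances; each instance gets
#' a unique id and six rows, one per seed position, holding the nucleotide
#' at that position. The result has exactly `6 * N` rows where `N` is the
#' total scaled seed count.
#'
#' @inheritParams expand_to_d
#' @return data.frame with columns `instance`, `position` (1-6),
#'   `nucleotide` (A/C/G/U) and `seed`.
#' @export
expand_to_f <- function(b, column) {
  stopifnot(inherits(b, "collapsed_seed_table"), column %in% attr(b, "value_cols"))
  counts <- b[[column]]
  keep <- counts >= 1000
  scaled <- scaled_counts(counts[keep])
  seeds <- rep(b$seed[keep], times = scaled)
  n_inst <- length(seeds)
  if (!n_inst) {
    return(data.frame(instance = integer(), position = integer(),
                      nucleotide = character(), seed = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    instance = rep(seq_len(n_inst), each = 6L),
    position = rep(1:6, times = n_inst),
    nucleotide = unlist(strsplit(seeds, ""), use.names = FALSE),
    seed = rep(seeds, each = 6L),
    stringsAsFactors = FALSE)
}

#' Position frequency matrix of expanded seeds
#'
#' Empirical nucleotide distribution per seed position over the instances
#' of an Output E expansion; the logo input. Columns sum to one.
#'
#' @param seeds character vector of 6mer seeds (RNA alphabet), e.g. an
#'   [expand_to_e()] result.
#' @return 4 x 6 numeric matrix, rows A/C/G/U, columns positions 1-6.
#' @export
position_frequency_matrix <- function(seeds) {
  if (!length(seeds)) stop("cannot compute frequencies of an empty expansion")
  chars <- matrix(unlist(strsplit(seeds, ""), use.names = FALSE),
                  nrow = length(seeds), byrow = TRUE)
  out <- sapply(1:6, function(j) {
    tab <- table(factor(chars[, j], levels = NUC_RNA))
    as.numeric(tab) / length(seeds)
  })
  dimnames(out) <- list(NUC_RNA, paste0("pos", 1:6))
  out
}

#' Per-sample miRNA content
#'
#' Percentage of each sample's counts assigned to a mature miRNA.
#'
#' @param table an `annotated_count_table`.
#' @return named numeric vector (% per sample).
#' @export
mirna_content <- function(table) {
  stopifnot(inherits(table, "annotated_count_table"))
  tot <- colSums(table$raw)
  if (any(tot == 0)) stop("sample(s) with zero total counts: ",
                          paste(table$samples[tot == 0], collapse = ", "))
  100 * colSums(table$raw[!is.na(table$mirna), , drop = FALSE]) / tot
}

#' Write a collapsed/binned/expanded table as TSV
#'
#' @param x a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
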