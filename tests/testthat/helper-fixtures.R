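# Shared fixture builders. Everything is generated in code; no stored data.

# A complete viability table where every seed has the same value.
constant_viability <- function(value = 100) {
  seeds <- enumerate_seed_space()
  seed_viability_table(seeds, matrix(value, nrow = 4096, ncol = 3,
                                     dimnames = list(NULL, paste0("cl", 1:3))))
}

random_reads <- function(n, len_range = 18:25, seed = 1) {
  set.seed(seed)
  lens <- if (length(len_range) == 1L) rep(len_range, n)
  else sample(len_range, n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# Brute-force longest-common-substring length oracle (dynamic programming).
lcs_length <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  prev <- integer(length(cb))
  best <- 0L
  for (i in seq_along(ca)) {
    cur <- integer(length(cb))
    match_j <- ca[i] == cb
    cur[match_j] <- c(0L, prev)[which(match_j)] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# Brute-force best ungapped-window identity of read against a reference
# (fraction of read length; windows shorter than the read are skipped).
best_window_identity <- function(read, ref) {
  L <- nchar(read)
  if (nchar(ref) < L) return(0)
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  best <- 0
  for (s in 1:(nchar(ref) - L + 1)) {
    best <- max(best, sum(rd == rf[s:(s + L - 1)]) / L)
  }
  best
}

# Tiny annotated table built through the real pipeline path from explicit
# per-sample reads and references.
build_annotated <- function(per_sample_reads, mirna, rnaworld,
                            viability = constant_viability()) {
  ct <- normalize_cpm(build_count_table(per_sample_reads))
  annotate_table(ct, mirna, rnaworld, viability)
}

# References whose sequences are the reads themselves (every read is a
# perfect miRNA match).
self_mirna_refs <- function(reads, prefix = "mir") {
  reference_set("mirna", paste0(prefix, "-", seq_along(unique(reads))),
                unique(reads))
}

empty_rnaworld <- function() {
  reference_set("rnaworld", "placeholder-no-hit", strrep("A", 60))
}
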