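# Seeded synthetic-data generator. Emulates the structure of small RNA-seq
# experiments (reads drawn from miRNA- and tRNA-fragment-like references,
# group-dependent seed-composition shifts, planted differential reads)
# with recorded ground truth, so every pipeline stage is testable without
# external downloads. It does not attempt to match any real dataset's
# read-level content.

#' Simulation specification
#'
#' Defaults state the simulated world once: two groups of three samples,
#' 8000 reads per sample over 100 miRNA-like and 80 small-RNA-like
#' references (plus 5 adapter/marker artifact entries), mild
#' negative-binomial overdispersion (0.05), a planted G-enrichment of the
#' disease group's seed composition with per-position odds ratio 5 (the
#' scale of effects seen in diseased tissue), and 20% of references planted
#' as 4-fold up in the disease group (logFC 2).
#'
#' @param seed RNG seed; every output is byte-reproducible given it.
#' @param n_samples samples per group.
#' @param groups two group labels (control first).
#' @param n_mirna,n_rnaworld,n_artifact reference counts.
#' @param library_size expected reads per sample.
#' @param dispersion NB dispersion of counts across replicates (0 =
#'   Poisson).
#' @param composition_or planted per-position odds ratio of G vs A in the
#'   second group's seed pool (via biased reference sampling).
#' @param composition_positions seed positions carrying the planted shift
#'   (default 1-3: toxic seeds are G-rich toward the 5' end, so the
#'   emulated disease shift lives in the 5' half of the seed).
#' @param frac_diff fraction of references planted as differential.
#' @param diff_logfc planted log2 fold change (group2 over group1).
#' @param decorate add a 4 nt 5' UMI, the 3' adapter `TCCGACGATC` and
#'   random padding to each read (exercises the trimmer).
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L, n_samples = 3L,
                     groups = c("control", "disease"),
                     n_mirna = 100L, n_rnaworld = 80L, n_artifact = 5L,
                     library_size = 8000L, dispersion = 0.05,
                     composition_or = 5, composition_positions = 1:3,
                     frac_diff = 0.2, diff_logfc = 2,
                     decorate = FALSE) {
  stopifnot(length(groups) == 2L, library_size > 0, dispersion >= 0,
            composition_or > 0, frac_diff >= 0, frac_diff <= 1)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 groups = as.character(groups),
                 n_mirna = as.integer(n_mirna),
                 n_rnaworld = as.integer(n_rnaworld),
                 n_artifact = as.integer(n_artifact),
                 library_size = as.integer(library_size),
                 dispersion = dispersion, composition_or = composition_or,
                 composition_positions = as.integer(composition_positions),
                 frac_diff = frac_diff, diff_logfc = diff_logfc,
                 decorate = isTRUE(decorate)),
            class = "sim_spec")
}

random_dna <- function(n, lengths) {
  vapply(lengths, function(L)
    paste(sample(NUC_DNA, L, replace = TRUE), collapse = ""), character(1))
}

#' Generate reference FASTA sets for a simulation
#'
#' miRNA-like references are 20-23 nt; small-RNA ("RNA world") references
#' are 30-60 nt fragments named like tRNA/rRNA pieces; artifact entries are
#' 18-25 nt and carry the purge keywords in their names.
#'
#' @param spec a [sim_spec()].
#' @return list with `mirna` and `rnaworld` [reference_set()]s (artifact
#'   entries live inside `rnaworld`).
#' @export
make_references <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  mirna <- reference_set(
    "mirna",
    sprintf("sim-mir-%03d", seq_len(spec$n_mirna)),
    random_dna(spec$n_mirna, sample(20:23, spec$n_mirna, replace = TRUE)))
  rw_names <- sprintf("%s-frag-%03d",
                      sample(c("tRNA-Gly-GCC", "tRNA-Glu-CTC", "rRNA-5S",
                               "snoRNA-U3", "YRNA-RNY1"),
                             spec$n_rnaworld, replace = TRUE),
                      seq_len(spec$n_rnaworld))
  rw_seqs <- random_dna(spec$n_rnaworld, sample(30:60, spec$n_rnaworld, TRUE))
  if (spec$n_artifact > 0L) {
    kw <- rep_len(c("Tuschl_spikein", "linker-adapter", "size-marker",
                    "artifical-oligo", "artificial-control"),
                  spec$n_artifact)
    rw_names <- c(rw_names, sprintf("%s-%02d", kw, seq_len(spec$n_artifact)))
    rw_seqs <- c(rw_seqs,
                 random_dna(spec$n_artifact,
                            sample(18:25, spec$n_artifact, TRUE)))
  }
  list(mirna = mirna, rnaworld = reference_set("rnaworld", rw_names, rw_seqs))
}

#' Generate a synthetic seed-viability resource
#'
#' Stands in for the real per-seed viability screen. Viability is a smooth
#' decreasing function of seed G content (and, more weakly, C content) to
#' mimic the published toxicity gradient -- G-rich seeds are the most
#' toxic -- plus per-seed and per-cell-line noise, clamped at 0 and left
#' uncapped above 100. Three pseudo-cell-lines are emitted.
#'
#' @param spec a [sim_spec()].
#' @param species passed through to [seed_viability_table()].
#' @return a complete (4096-seed) [seed_viability_table()].
#' @export
make_viability_table <- function(spec, species = "human") {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  seeds <- enumerate_seed_space()
  n_g <- nchar(seeds) - nchar(gsub("G", "", seeds, fixed = TRUE))
  n_c <- nchar(seeds) - nchar(gsub("C", "", seeds, fixed = TRUE))
  base <- 100 - 12 * n_g - 6 * n_c + stats::rnorm(4096, 0, 5)
  per_line <- sapply(1:3, function(i) pmax(0, base + stats::rnorm(4096, 0, 3)))
  colnames(per_line) <- paste0("cellline", 1:3)
  seed_viability_table(seeds, per_line, species)
}

count_g <- function(x) nchar(x) - nchar(gsub("G", "", x, fixed = TRUE))

#' Simulate per-sample reads with recorded ground truth
#'
#' Each reference contributes one read sequence: the full sequence for
#' miRNA-like and artifact references, a 5'-anchored 18-25 nt fragment for
#' the longer small-RNA references. Per-sample counts are negative
#' binomial around group-specific expected proportions. The disease
#' group's sampling weights are tilted by `composition_or^nG`, where `nG`
#' counts Gs at the planted seed positions (realizing the planted
#' per-position G vs A odds ratio there), and by the planted fold change
#' for differential references.
#'
#' @param spec a [sim_spec()].
#' @param refs a [make_references()] result (built from the same spec if
#'   omitted).
#' @return list: `samples` (named list of read character vectors),
#'   `sample_groups` (named character vector), `truth` (per-reference
#'   data.frame: name, kind, read, seed, n_g, planted_diff, expected CPM
#'   per group), `refs`.
#' @export
simulate_reads <- function(spec, refs = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(refs)) refs <- make_references(spec)
  set.seed(spec$seed + 2L)
  rw_n <- length(refs$rnaworld$names)
  art <- purge_artifacts(refs$rnaworld$names)
  frag_len <- sample(18:25, rw_n, replace = TRUE)
  rw_reads <- substr(refs$rnaworld$sequences, 1L,
                     pmin(nchar(refs$rnaworld$sequences), frag_len))
  truth <- data.frame(
    name = c(refs$mirna$names, refs$rnaworld$names),
    kind = c(rep("mirna", length(refs$mirna$names)),
             ifelse(art, "artifact", "rnaworld")),
    read = c(refs$mirna$sequences, rw_reads),
    stringsAsFactors = FALSE)
  truth <- truth[!duplicated(truth$read), ]
  truth$seed <- extract_seed(truth$read)
  truth$n_g <- count_g(vapply(truth$seed, function(s)
    paste(strsplit(s, "")[[1]][spec$composition_positions], collapse = ""),
    character(1)))
  n_ref <- nrow(truth)
  base_w <- exp(stats::rnorm(n_ref, 0, 1))
  base_w[truth$kind == "artifact"] <- stats::median(base_w) * 0.2
  truth$planted_diff <- FALSE
  cand <- which(truth$kind != "artifact")
  n_diff <- round(spec$frac_diff * length(cand))
  if (n_diff > 0) truth$planted_diff[sample(cand, n_diff)] <- TRUE
  delta <- log(spec$composition_or)
  w_g1 <- base_w
  w_g2 <- base_w * exp(delta * truth$n_g) *
    ifelse(truth$planted_diff, 2^spec$diff_logfc, 1)
  p1 <- w_g1 / sum(w_g1)
  p2 <- w_g2 / sum(w_g2)
  truth$expected_cpm_g1 <- 1e6 * p1
  truth$expected_cpm_g2 <- 1e6 * p2
  samples <- list()
  sample_groups <- character()
  for (g in 1:2) {
    p <- if (g == 1L) p1 else p2
    for (r in seq_len(spec$n_samples)) {
      mu <- spec$library_size * p
      counts <- if (spec$dispersion > 0) {
        stats::rnbinom(n_ref, mu = mu, size = 1 / spec$dispersion)
      } else {
        stats::rpois(n_ref, mu)
      }
      reads <- rep(truth$read, times = counts)
      if (spec$decorate) {
        pad <- random_dna(length(reads), rep(8L, length(reads)))
        umi <- random_dna(length(reads), rep(4L, length(reads)))
        reads <- paste0(umi, reads, "TCCGACGATC", pad)
      }
      nm <- paste0(spec$groups[g], "_rep", r)
      samples[[nm]] <- reads
      sample_groups[nm] <- spec$groups[g]
    }
  }
  list(samples = samples, sample_groups = sample_groups,
       truth = truth, refs = refs)
}

#' Simulate seed-composition data from the mixed model itself
#'
#' Draws per-instance random intercepts `b_ik ~ N(0, sigma2)` for each
#' non-reference category and per-position nucleotides from the
#' baseline-category logit, with a group effect on the log odds that is
#' constant across positions (so the group x position interaction is
#' null). Used for parameter-recovery and calibration checks.
#'
#' @param n_per_group instances per group.
#' @param log_or named numeric (`C`, `G`, `U`): log odds ratio of each
#'   category vs A for group 2 relative to group 1.
#' @param sigma2 random-intercept variance (shared by C, G, U).
#' @param groups group labels.
#' @param beta0 named baseline log odds vs A (default 0: uniform
#'   composition in group 1).
#' @param seed RNG seed.
#' @return data.frame with `group`, `instance`, `position`, `nucleotide`.
#' @export
simulate_composition <- function(n_per_group, log_or = c(C = 0, G = 0, U = 0),
                                 sigma2 = 0, groups = c("g1", "g2"),
                                 beta0 = c(C = 0, G = 0, U = 0), seed = 1L) {
  stopifnot(length(groups) == 2L)
  set.seed(seed)
  out <- vector("list", 2L)
  for (g in 1:2) {
    b <- matrix(stats::rnorm(n_per_group * 3L, 0, sqrt(sigma2)),
                ncol = 3L, dimnames = list(NULL, NONREF_CATS))
    eta <- sweep(b, 2L, beta0[NONREF_CATS] +
                   (g == 2L) * log_or[NONREF_CATS], `+`)
    # per instance: position-independent category probabilities
    expo <- cbind(A = 1, exp(eta))
    pr <- expo / rowSums(expo)
    nuc <- vapply(seq_len(n_per_group), function(i) {
      sample(c("A", NONREF_CATS), 6L, replace = TRUE, prob = pr[i, ])
    }, character(6L))
    out[[g]] <- data.frame(
      group = groups[g],
      instance = rep(seq_len(n_per_group), each = 6L),
      position = rep(1:6, times = n_per_group),
      nucleotide = as.vector(nuc),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
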