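# Differential read abundance between two groups: classic negative-binomial
# exact test with common dispersion estimated by conditional maximum
# likelihood. Library sizes are equalized by scaling raw counts to the
# geometric-mean library size (CPM is the pipeline's normalization; TMM is
# deliberately not implemented). Numerical parity with any particular
# external implementation is not claimed; the dispersion-zero limit is the
# exact binomial test and is checked against a closed-form oracle.

#' Comparison design: sample coding for one pairwise contrast
#'
#' @param name contrast name.
#' @param coding named vector over samples with values 1 (Group1, usually
#'   control), -1 (Group2, perturbed) or 0 (excluded).
#' @return object of class `comparison_design`.
#' @export
comparison_design <- function(name, coding) {
  coding <- unlist(coding)
  if (!all(coding %in% c(1, -1, 0))) stop("coding values must be 1, -1 or 0")
  if (is.null(names(coding)) || any(!nzchar(names(coding)))) {
    stop("coding must be named by sample")
  }
  if (!any(coding == 1) || !any(coding == -1)) {
    stop("a contrast needs at least one sample coded 1 and one coded -1")
  }
  structure(list(name = as.character(name), coding = coding),
            class = "comparison_design")
}

#' Read a comparisons table (one contrast per row)
#'
#' Comma-separated; header = sample names; optional first column `name`
#' labels each contrast; cells are 1 / -1 / 0.
#'
#' @param path CSV path.
#' @return list of [comparison_design()] objects.
#' @export
read_comparisons <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE)
  has_name <- tolower(colnames(df)[1L]) == "name"
  lapply(seq_len(nrow(df)), function(i) {
    nm <- if (has_name) df[i, 1L] else paste0("contrast", i)
    vals <- as.numeric(df[i, (1L + has_name):ncol(df)])
    comparison_design(nm, stats::setNames(vals,
                                          colnames(df)[(1L + has_name):ncol(df)]))
  })
}

# Conditional log-likelihood of counts within one group given their sum,
# for iid NB with size r per sample (Dirichlet-multinomial form). y is a
# reads x samples matrix of (pseudo-)counts.
cond_loglik_group <- function(y, r) {
  n <- ncol(y)
  z <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r)
}

# Common dispersion by conditional ML on pseudo-counts equalized to a
# common library size. Returns phi >= 0.
estimate_common_dispersion <- function(y1, y2) {
  nll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    -sum(cond_loglik_group(y1, r)) - sum(cond_loglik_group(y2, r))
  }
  if (ncol(y1) == 1L && ncol(y2) == 1L) return(0)  # no within-group replication
  opt <- stats::optimize(nll, interval = c(log(1e-6), log(10)))
  phi <- exp(opt$minimum)
  if (nll(log(1e-6)) <= opt$objective) phi <- 0
  phi
}

# Per-read dispersion by weighted conditional likelihood: the per-read
# conditional likelihood is shrunk toward the common one with prior weight
# `prior_n` pseudo-reads (empirical-Bayes moderation).
estimate_tagwise_dispersion <- function(y1, y2, prior_n = 10) {
  G <- nrow(y1)
  common_l <- function(r) {
    (sum(cond_loglik_group(y1, r)) + sum(cond_loglik_group(y2, r))) / G
  }
  vapply(seq_len(G), function(i) {
    nll <- function(log_phi) {
      r <- 1 / exp(log_phi)
      -(cond_loglik_group(y1[i, , drop = FALSE], r) +
          cond_loglik_group(y2[i, , drop = FALSE], r) +
          prior_n * common_l(r))
    }
    opt <- stats::optimize(nll, interval = c(log(1e-6), log(10)))
    if (nll(log(1e-6)) <= opt$objective) 0 else exp(opt$minimum)
  }, numeric(1))
}

# Exact two-sided NB test: P(S1 = s1 | S1 + S2 = s) under H0 of equal
# per-sample means with equalized library sizes. Group sums of n iid
# NB(mu, size r) are NB(n mu, n r), so the conditional law is
# Dirichlet-multinomial (beta-binomial); phi = 0 degenerates to binomial.
# Two-sided p sums the probabilities of all outcomes no more likely than
# the observed one.
nb_exact_pvalue <- function(s1, s, n1, n2, phi) {
  if (s == 0) return(1)
  y <- 0:s
  if (phi <= 1e-8) {  # dispersion-zero limit: exact binomial
    logp <- stats::dbinom(y, s, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    logp <- lgamma(y + r1) - lgamma(y + 1) +
      lgamma(s - y + r2) - lgamma(s - y + 1)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  p_obs <- logp[s1 + 1L]
  min(1, sum(exp(logp[logp <= p_obs + 1e-10])))
}

#' Negative-binomial exact test for differential read abundance
#'
#' Tests each read for a difference between Group2 and Group1 of a
#' [comparison_design()]. Raw counts are used; each sample is scaled to the
#' geometric-mean library size, group pseudo-sums are rounded, and the
#' exact conditional test given the row sum is applied. `logFC` is log2 of
#' Group2 over Group1 mean CPM with a 0.5 pseudo-count on both groups;
#' `delta` is the difference of mean CPM (Group2 - Group1). P-values are
#' Benjamini-Hochberg adjusted across all tested reads.
#'
#' @param table a `count_table` or `annotated_count_table`.
#' @param design a [comparison_design()].
#' @param dispersion_mode `"common"` (default): one conditional-ML
#'   dispersion for all reads; `"tagwise"`: per-read moderated dispersion;
#'   `"poisson"`: dispersion forced to 0.
#' @return data.frame of class `differential_result` with one row per read:
#'   `sequence`, `logFC`, `pvalue`, `padj`, `mean_norm_g1`, `mean_norm_g2`,
#'   `delta`, `significant` (padj < 0.05 and |logFC| > 0.585).
#' @export
test_differential <- function(table, design,
                              dispersion_mode = c("common", "tagwise", "poisson")) {
  dispersion_mode <- match.arg(dispersion_mode)
  stopifnot(inherits(table, "count_table"), inherits(design, "comparison_design"))
  miss <- setdiff(names(design$coding), table$samples)
  if (length(miss)) stop("design samples absent from table: ",
                         paste(miss, collapse = ", "))
  g1 <- names(design$coding)[design$coding == 1]
  g2 <- names(design$coding)[design$coding == -1]
  raw1 <- table$raw[, g1, drop = FALSE]
  raw2 <- table$raw[, g2, drop = FALSE]
  lib <- colSums(table$raw[, c(g1, g2), drop = FALSE])
  if (sum(raw1) == 0 || sum(raw2) == 0) stop("a group has zero total counts")
  lib_target <- exp(mean(log(lib[lib > 0])))
  scale_to <- function(m) {
    cs <- colSums(table$raw)[colnames(m)]
    sweep(m, 2L, ifelse(cs > 0, lib_target / cs, 0), `*`)
  }
  y1 <- round(scale_to(raw1))
  y2 <- round(scale_to(raw2))
  phi <- switch(dispersion_mode,
                poisson = rep(0, nrow(y1)),
                common = rep(estimate_common_dispersion(y1, y2), nrow(y1)),
                tagwise = estimate_tagwise_dispersion(y1, y2))
  s1 <- round(rowSums(y1))
  s2 <- round(rowSums(y2))
  pvals <- vapply(seq_len(nrow(y1)), function(i) {
    nb_exact_pvalue(s1[i], s1[i] + s2[i], length(g1), length(g2), phi[i])
  }, numeric(1))
  cpm <- sweep(table$raw, 2L, ifelse(colSums(table$raw) > 0,
                                     1e6 / colSums(table$raw), 0), `*`)
  m1 <- rowMeans(cpm[, g1, drop = FALSE])
  m2 <- rowMeans(cpm[, g2, drop = FALSE])
  logfc <- log2((m2 + 0.5) / (m1 + 0.5))
  padj <- stats::p.adjust(pvals, method = "BH")
  res <- data.frame(sequence = table$sequence, logFC = logfc,
                    pvalue = pvals, padj = padj,
                    mean_norm_g1 = m1, mean_norm_g2 = m2,
                    delta = m2 - m1,
                    significant = padj < 0.05 & abs(logfc) > 0.585,
                    stringsAsFactors = FALSE)
  attr(res, "design") <- design
  attr(res, "dispersion") <- phi
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Select significantly deregulated reads
#'
#' Keeps rows passing the significance rule (`padj` or raw `pvalue` < 0.05,
#' per `mode`) together with |logFC| > 0.585, and attaches the delta CPM
#' (Group2 - Group1) as the value used by the downstream keyed outputs,
#' split into "Up" (delta > 0, enriched in Group2) and "Down" groups.
#'
#' @param table the tested `annotated_count_table`.
#' @param result the matching [test_differential()] result.
#' @param mode `"padj"` (default) or `"pvalue"`.
#' @return the selected `annotated_count_table` with an `extra` data.frame
#'   (`delta`, `direction`) aligned to its rows.
#' @export
select_differential <- function(table, result, mode = c("padj", "pvalue")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "differential_result"))
  if (!identical(table$sequence, result$sequence)) {
    stop("table and differential result rows do not align")
  }
  crit <- if (mode == "padj") result$padj else result$pvalue
  sel <- crit < 0.05 & abs(result$logFC) > 0.585
  if (!any(sel)) warning("no reads pass the significance rules; empty selection")
  out <- subset_annotated(table, sel)
  out$extra <- data.frame(
    delta = result$delta[sel],
    direction = ifelse(result$delta[sel] > 0, "Up", "Down"),
    logFC = result$logFC[sel], pvalue = result$pvalue[sel],
    padj = result$padj[sel], stringsAsFactors = FALSE)
  out
}
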