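# Statistical comparison of seed toxicity (rank tests on Output D) and of
# positional seed composition (baseline-category mixed-effects logit on
# Output F).
#
# Model: for seed instance i (one random-effect "subject" per rescaled
# instance), position j and nucleotide category k in {C, G, U} (A is the
# reference: A-rich seeds are the least toxic),
#   log P(nuc = k) / P(nuc = A) = x_{gj}' beta_k + b_ik,
#   b_ik ~ N(0, sigma2_k) independent across instances and categories,
# with group, position and their interaction as fixed effects. Estimation
# splits the multinomial into its three conditional binary logits (k vs A
# restricted to positions where the outcome is k or A; the softmax
# denominator cancels in that conditional), each fitted by marginal
# maximum likelihood with adaptive Gauss-Hermite quadrature. The split
# keeps every integral one-dimensional; it is exact for the fixed effects
# in the sigma2 = 0 limit and a standard consistent approximation
# otherwise. Instances are collapsed to distinct (group, outcome-pattern)
# weights, making the likelihood cost independent of abundance.

NONREF_CATS <- c("C", "G", "U")

# Gauss-Hermite nodes/weights (physicists') via the Golub-Welsch
# tridiagonal eigenproblem; no external dependency.
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# Collapse one binary sub-dataset (category k vs reference) to distinct
# (group, pattern) rows. Returns Y (T x 6, NA = position not in {k, ref}),
# group index (T), weights (T).
collapse_patterns <- function(inst_group, inst_outcome_mat, cat) {
  Y <- matrix(NA_real_, nrow = nrow(inst_outcome_mat), ncol = 6L)
  Y[inst_outcome_mat == cat] <- 1
  Y[inst_outcome_mat == "A"] <- 0
  key <- paste(inst_group, apply(Y, 1L, paste, collapse = ","))
  first <- !duplicated(key)
  w <- as.numeric(table(key)[key[first]])
  list(Y = Y[first, , drop = FALSE], group = inst_group[first], w = w)
}

# Precompute the per-pattern structures used by every likelihood
# evaluation: cell index matrix (T x 6), observation mask, 0-filled
# outcomes, and weights.
component_data <- function(pat, X) {
  Tn <- nrow(pat$Y)
  obs <- !is.na(pat$Y)
  list(Tn = Tn,
       cellidx = matrix(rep((pat$group - 1L) * 6L, 6L) + rep(1:6, each = Tn),
                        nrow = Tn),
       obs = obs,
       Y0 = ifelse(obs, pat$Y, 0),
       w = pat$w, X = X)
}

# Per-pattern posterior mode m and curvature h of the random intercept,
# by vectorized Newton iterations (warm-startable).
pattern_modes <- function(cd, mu_cells, sigma, b = NULL) {
  M <- matrix(mu_cells[cd$cellidx], nrow = cd$Tn)
  s2 <- sigma^2
  if (is.null(b)) b <- numeric(cd$Tn)
  for (it in 1:25) {
    p <- 1 / (1 + exp(-(M + b)))
    grad <- rowSums((cd$Y0 - p) * cd$obs) - b / s2
    hess <- -rowSums(p * (1 - p) * cd$obs) - 1 / s2
    step <- grad / hess
    b <- b - step
    if (max(abs(step)) < 1e-10) break
  }
  p <- 1 / (1 + exp(-(M + b)))
  list(m = b, h = rowSums(p * (1 - p) * cd$obs) + 1 / s2)
}

# Adaptive Gauss-Hermite negative marginal log-likelihood (modes refound
# at the supplied parameters). Used for final values and nested-model
# comparisons; the optimizer works on the frozen-grid version below.
binary_agq_nll <- function(mu_cells, sigma, cd, gh) {
  M <- matrix(mu_cells[cd$cellidx], nrow = cd$Tn)
  bern <- function(b) {
    eta <- M + b
    em <- exp(-abs(eta))
    lq <- -eta * (eta > 0) - log1p(em)  # log(1 - p), overflow-safe
    rowSums((cd$Y0 * eta + lq) * cd$obs)
  }
  if (sigma < 1e-8) return(-sum(cd$w * bern(numeric(cd$Tn))))
  md <- pattern_modes(cd, mu_cells, sigma)
  sd_q <- sqrt(2 / md$h)
  ll <- matrix(0, cd$Tn, length(gh$nodes))
  for (q in seq_along(gh$nodes)) {
    bq <- md$m + sd_q * gh$nodes[q]
    ll[, q] <- gh$nodes[q]^2 + log(gh$weights[q]) + bern(bq) +
      stats::dnorm(bq, 0, sigma, log = TRUE)
  }
  mx <- ll[cbind(seq_len(cd$Tn), max.col(ll))]
  -sum(cd$w * (log(sd_q) + mx + log(rowSums(exp(ll - mx)))))
}

# Frozen-grid objective: quadrature nodes b_tq = m_t + s_t * sqrt(2) z_q
# are held fixed, so the objective and its gradient in (beta, sigma) are
# exact for the frozen grid and cheap. Returns nll with gradient
# attribute.
frozen_obj_gr <- function(theta, cd, gh, grid, ridge) {
  p <- ncol(cd$X)
  beta <- theta[1:p]
  sigma <- theta[p + 1L]
  mu_cells <- drop(cd$X %*% beta)
  M <- matrix(mu_cells[cd$cellidx], nrow = cd$Tn)
  Q <- length(gh$nodes)
  logc <- outer(log(grid$sd_q), gh$nodes^2 + log(gh$weights), `+`)
  B <- grid$B  # Tn x Q node matrix
  ll <- logc - 0.5 * (B / sigma)^2 - log(sigma) - 0.918938533204673
  plist <- vector("list", Q)
  YO <- cd$Y0 * cd$obs
  cY <- rowSums(YO * M)
  n1t <- rowSums(YO)
  for (q in seq_len(Q)) {
    eta <- M + B[, q]
    pos <- eta > 0
    em <- exp(-abs(eta))
    a <- em / (1 + em)
    plist[[q]] <- pos + (1 - 2 * pos) * a   # overflow-safe sigmoid
    lq <- -eta * pos - log1p(em)
    ll[, q] <- ll[, q] + cY + n1t * B[, q] + rowSums(lq * cd$obs)
  }
  mx <- ll[cbind(seq_len(cd$Tn), max.col(ll))]
  e <- exp(ll - mx)
  L <- rowSums(e)
  nll <- -sum(cd$w * (mx + log(L))) + ridge * sum(beta^2)
  post <- e / L  # Tn x Q posterior node weights
  A <- matrix(0, cd$Tn, 6L)  # E[y - p | data] per pattern x position
  g_sigma_t <- numeric(cd$Tn)
  for (q in seq_len(Q)) {
    A <- A + post[, q] * (cd$Y0 - plist[[q]]) * cd$obs
    g_sigma_t <- g_sigma_t + post[, q] * (B[, q]^2 / sigma^3 - 1 / sigma)
  }
  s_cell <- rowsum(as.vector(A) * rep(cd$w, 6L), group = as.vector(cd$cellidx))
  s_full <- numeric(nrow(cd$X))
  s_full[as.integer(rownames(s_cell))] <- s_cell
  grad <- c(-drop(crossprod(cd$X, s_full)) + 2 * ridge * beta,
            -sum(cd$w * g_sigma_t))
  attr(nll, "gradient") <- grad
  nll
}

# Fixed-effects logistic fit (sigma2 = 0), Newton-Raphson on cell counts.
fit_logistic_cells <- function(cd, ridge = 0) {
  p <- ncol(cd$X)
  n1 <- n0 <- numeric(nrow(cd$X))
  idx <- as.vector(cd$cellidx)
  n1v <- rowsum(as.vector(cd$Y0 * cd$obs) * rep(cd$w, 6L), group = idx)
  n0v <- rowsum(as.vector((1 - cd$Y0) * cd$obs) * rep(cd$w, 6L), group = idx)
  n1[as.integer(rownames(n1v))] <- n1v
  n0[as.integer(rownames(n0v))] <- n0v
  ntot <- n1 + n0
  beta <- stats::coef(stats::lm.fit(cd$X, log((n1 + 0.5) / (n0 + 0.5))))
  beta[is.na(beta)] <- 0
  for (it in 1:50) {
    mu <- drop(cd$X %*% beta)
    pr <- stats::plogis(mu)
    grad <- drop(crossprod(cd$X, n1 - ntot * pr)) - 2 * ridge * beta
    W <- ntot * pr * (1 - pr)
    H <- crossprod(cd$X * W, cd$X) + diag(2 * ridge, p)
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H), 1))
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- drop(cd$X %*% beta)
  pr <- stats::plogis(mu)
  ll <- sum(n1 * stats::plogis(mu, log.p = TRUE) +
              n0 * stats::plogis(-mu, log.p = TRUE))
  H <- crossprod(cd$X * (ntot * pr * (1 - pr)), cd$X) + diag(2 * ridge, p)
  list(beta = beta, loglik = ll, vcov = solve(H), n1 = n1, n0 = n0)
}

# Fixed-effect design over the 6G cells, treatment coding.
cell_design <- function(G, interaction = TRUE) {
  cells <- expand.grid(position = factor(1:6), group = factor(seq_len(G)))
  f <- if (interaction && G > 1) ~ group * position
  else if (G > 1) ~ group + position
  else ~ position
  X <- stats::model.matrix(f, cells)
  attr(X, "cells") <- cells
  X
}

fit_binary_component <- function(pat, G, interaction, nagq, ridge = 0,
                                 sigma2_fixed = NULL, start = NULL) {
  gh <- gauss_hermite(nagq)
  X <- cell_design(G, interaction)
  p <- ncol(X)
  cd <- component_data(pat, X)
  lfit <- fit_logistic_cells(cd, ridge)
  if (!is.null(sigma2_fixed) && sigma2_fixed == 0) {
    return(list(beta = stats::setNames(lfit$beta, colnames(X)),
                sigma2 = 0,
                vcov = structure(lfit$vcov,
                                 dimnames = list(colnames(X), colnames(X))),
                loglik = lfit$loglik, X = X, convergence = 0L,
                separation = ridge > 0, n1 = lfit$n1, n0 = lfit$n0))
  }
  sigma_fix <- if (!is.null(sigma2_fixed)) sqrt(sigma2_fixed) else NULL
  theta <- c(lfit$beta, if (is.null(sigma_fix)) 0.5 else sigma_fix)
  if (!is.null(start)) {
    # warm start: project supplied cell predictors onto this design
    bs <- stats::coef(stats::lm.fit(X, start$mu_cells))
    bs[is.na(bs)] <- 0
    theta <- c(bs, if (is.null(sigma_fix)) max(start$sigma, 0.02)
               else sigma_fix)
  }
  warm <- NULL
  conv <- 1L
  # outer cycles: re-center the adaptive grid at the current parameters,
  # then optimize the frozen-grid likelihood with exact gradients
  for (cycle in 1:12) {
    md <- pattern_modes(cd, drop(X %*% theta[1:p]), theta[p + 1L], warm)
    warm <- md$m
    grid <- list(sd_q = sqrt(2 / md$h),
                 B = md$m + sqrt(2 / md$h) %o% gh$nodes)
    cache <- new.env(parent = emptyenv())
    evalf <- function(th) {
      key <- paste(th, collapse = ",")
      if (!identical(cache$key, key)) {
        cache$key <- key
        cache$val <- frozen_obj_gr(th, cd, gh, grid, ridge)
      }
      cache$val
    }
    if (is.null(sigma_fix)) {
      opt <- stats::optim(theta, fn = function(th) as.numeric(evalf(th)),
                          gr = function(th) attr(evalf(th), "gradient"),
                          method = "L-BFGS-B",
                          lower = c(rep(-Inf, p), 0.01),
                          upper = c(rep(Inf, p), 10),
                          control = list(maxit = 200, factr = 1e5))
    } else {
      opt <- stats::optim(theta[1:p],
                          fn = function(bb) as.numeric(evalf(c(bb, sigma_fix))),
                          gr = function(bb) attr(evalf(c(bb, sigma_fix)),
                                                 "gradient")[1:p],
                          method = "L-BFGS-B",
                          control = list(maxit = 200, factr = 1e5))
      opt$par <- c(opt$par, sigma_fix)
    }
    delta <- max(abs(opt$par - theta))
    theta <- opt$par
    if (delta < 1e-7) { conv <- 0L; break }
  }
  sigma <- theta[p + 1L]
  nll_at <- function(th) binary_agq_nll(drop(X %*% th[1:p]), th[p + 1L],
                                        cd, gh) + ridge * sum(th[1:p]^2)
  ll_mix <- -nll_at(theta) + ridge * sum(theta[1:p]^2)
  # boundary check: does sigma2 = 0 (plain logistic) beat the interior fit?
  if (is.null(sigma_fix) && sigma <= 0.02 && lfit$loglik >= ll_mix) {
    return(list(beta = stats::setNames(lfit$beta, colnames(X)),
                sigma2 = 0,
                vcov = structure(lfit$vcov,
                                 dimnames = list(colnames(X), colnames(X))),
                loglik = lfit$loglik, X = X, convergence = 0L,
                separation = ridge > 0, n1 = lfit$n1, n0 = lfit$n0))
  }
  # observed information on the frozen grid at the optimum (gradient-based
  # finite differences)
  md <- pattern_modes(cd, drop(X %*% theta[1:p]), sigma, warm)
  grid <- list(sd_q = sqrt(2 / md$h),
               B = md$m + sqrt(2 / md$h) %o% gh$nodes)
  grf <- function(th) attr(frozen_obj_gr(th, cd, gh, grid, ridge), "gradient")
  free <- if (is.null(sigma_fix)) seq_len(p + 1L) else seq_len(p)
  H <- matrix(0, length(free), length(free))
  eps <- 1e-5
  for (r in seq_along(free)) {
    tp <- tm <- theta
    tp[free[r]] <- tp[free[r]] + eps
    tm[free[r]] <- tm[free[r]] - eps
    H[r, ] <- (grf(tp)[free] - grf(tm)[free]) / (2 * eps)
  }
  H <- (H + t(H)) / 2
  vcov_beta <- matrix(NA_real_, p, p)
  V <- try(solve(H), silent = TRUE)
  if (!inherits(V, "try-error") && all(diag(V)[1:p] > 0)) {
    vcov_beta <- V[1:p, 1:p, drop = FALSE]
  } else {
    Vb <- try(solve(H[1:p, 1:p]), silent = TRUE)
    if (!inherits(Vb, "try-error")) vcov_beta <- Vb
  }
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(theta[1:p], colnames(X)),
       sigma2 = sigma^2, vcov = vcov_beta,
       loglik = ll_mix, X = X, convergence = conv,
       separation = ridge > 0, n1 = lfit$n1, n0 = lfit$n0)
}

#' Fit the positional seed-composition mixed model
#'
#' @param data data.frame of per-position nucleotide observations with
#'   columns `group` (factor or character), `instance` (seed-instance id,
#'   unique within group), `position` (1-6) and `nucleotide` (A/C/G/U) --
#'   i.e. stacked Output F expansions, one per group.
#' @param interaction include the group x position interaction (default
#'   `TRUE`).
#' @param nagq number of adaptive Gauss-Hermite quadrature nodes
#'   (default 15).
#' @param sigma2_fixed optionally fix the random-intercept variance
#'   instead of estimating it; `0` gives the fixed-effects multinomial
#'   logit (useful as an oracle/diagnostic).
#' @return object of class `seed_composition_model`: per-category fits
#'   (`beta`, `vcov`, `sigma2`, `loglik`), group levels, and the collapsed
#'   pattern data needed to refit nested models.
#' @export
fit_seed_composition <- function(data, interaction = TRUE, nagq = 15L,
                                 sigma2_fixed = NULL) {
  req <- c("group", "instance", "position", "nucleotide")
  if (!all(req %in% names(data))) {
    stop("data needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(data$nucleotide %in% NUC_RNA)) stop("nucleotides must be A/C/G/U")
  glev <- if (is.factor(data$group)) levels(droplevels(data$group)) else
    sort(unique(as.character(data$group)))
  if (length(glev) < 2L) stop("at least two groups are required")
  gi <- match(as.character(data$group), glev)
  inst_key <- paste(gi, data$instance)
  inst_first <- !duplicated(inst_key)
  inst_ids <- inst_key[inst_first]
  rows_inst <- match(inst_key, inst_ids)
  tab <- table(rows_inst)
  if (any(tab != 6L)) stop("every seed instance must have exactly 6 position rows")
  om <- matrix(NA_character_, nrow = length(inst_ids), ncol = 6L)
  pos <- as.integer(data$position)
  if (any(is.na(pos)) || any(pos < 1L | pos > 6L)) stop("positions must be 1..6")
  om[cbind(rows_inst, pos)] <- as.character(data$nucleotide)
  if (anyNA(om)) stop("each instance needs one row per position 1..6")
  inst_group <- gi[inst_first]
  G <- length(glev)
  fits <- list()
  for (k in NONREF_CATS) {
    pat <- collapse_patterns(inst_group, om, k)
    # separation check on the full-cell cross-tab
    n1 <- n0 <- numeric(6L * G)
    for (t in seq_len(nrow(pat$Y))) {
      o <- which(!is.na(pat$Y[t, ]))
      cell <- (pat$group[t] - 1L) * 6L + o
      n1[cell] <- n1[cell] + pat$w[t] * pat$Y[t, o]
      n0[cell] <- n0[cell] + pat$w[t] * (1 - pat$Y[t, o])
    }
    ridge <- 0
    if (any(n1 + n0 > 0 & (n1 == 0 | n0 == 0))) {
      warning("separation for category ", k,
              " (a nucleotide is absent in a group x position cell); ",
              "applying a weak ridge penalty")
      ridge <- 1e-2
    }
    fits[[k]] <- fit_binary_component(pat, G, interaction, nagq, ridge,
                                      sigma2_fixed)
    fits[[k]]$pattern <- pat
  }
  structure(list(categories = fits, groups = glev, interaction = interaction,
                 nagq = as.integer(nagq), sigma2_fixed = sigma2_fixed,
                 n_instances = as.integer(table(factor(inst_group,
                                                       levels = seq_len(G))))),
            class = "seed_composition_model")
}

#' @export
print.seed_composition_model <- function(x, ...) {
  cat("seed_composition_model:", length(x$groups), "groups (",
      paste(x$groups, collapse = ", "), "),",
      sum(x$n_instances), "seed instances\n")
  cat("  reference category A; sigma2 (C, G, U):",
      paste(format(vapply(x$categories, `[[`, 1, "sigma2"), digits = 3),
            collapse = ", "), "\n")
  cat("  group x position interaction:", x$interaction, "\n")
  invisible(x)
}

# Linear predictor row for (group g, position j) in the cell design.
cell_row <- function(X, G, g, j) X[(g - 1L) * 6L + j, ]

#' Pairwise group odds ratios of nucleotide vs A at a seed position
#'
#' `OR` compares the odds of observing `category` (vs the reference A) at
#' `position` between two groups: `OR = exp(eta_g1j - eta_g2j)`. Wald CIs
#' use the observed-information covariance; p-values over all pairwise
#' group contrasts are adjusted by Tukey's method (studentized range). The
#' display value `or_star` is `1/OR` when `OR < 1` (the circle-plot
#' convention). With two groups the Tukey adjustment reduces to the
#' unadjusted two-sided Wald p.
#'
#' @param model a [fit_seed_composition()] result.
#' @param category `"C"`, `"G"` or `"U"`.
#' @param position seed position 1-6.
#' @param g1,g2 group labels to compare (g1 vs g2).
#' @param conf_level Wald confidence level (default 0.95).
#' @return one-row data.frame: `category`, `position`, `g1`, `g2`, `or`,
#'   `ci_lo`, `ci_hi`, `p`, `p_adj`, `or_star`.
#' @export
pairwise_or <- function(model, category, position, g1, g2, conf_level = 0.95) {
  stopifnot(inherits(model, "seed_composition_model"))
  category <- match.arg(category, NONREF_CATS)
  position <- as.integer(position)
  if (position < 1L || position > 6L) stop("position must be 1..6")
  i1 <- match(as.character(g1), model$groups)
  i2 <- match(as.character(g2), model$groups)
  if (is.na(i1) || is.na(i2)) stop("unknown group label")
  fit <- model$categories[[category]]
  if (i1 == i2) {
    return(data.frame(category = category, position = position,
                      g1 = as.character(g1), g2 = as.character(g2),
                      or = 1, ci_lo = 1, ci_hi = 1, p = 1, p_adj = 1,
                      or_star = 1, stringsAsFactors = FALSE))
  }
  ctr <- cell_row(fit$X, length(model$groups), i1, position) -
    cell_row(fit$X, length(model$groups), i2, position)
  est <- sum(ctr * fit$beta)
  se <- sqrt(drop(t(ctr) %*% fit$vcov %*% ctr))
  z <- est / se
  G <- length(model$groups)
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (G > 2) {
    1 - stats::ptukey(sqrt(2) * abs(z), nmeans = G, df = Inf)
  } else p
  qz <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- exp(est)
  data.frame(category = category, position = position,
             g1 = as.character(g1), g2 = as.character(g2),
             or = or, ci_lo = exp(est - qz * se), ci_hi = exp(est + qz * se),
             p = p, p_adj = p_adj,
             or_star = if (or < 1) 1 / or else or,
             stringsAsFactors = FALSE)
}

#' All pairwise odds ratios (circle-plot table)
#'
#' Tukey-adjusted ORs of C, G and U vs A for every group pair at every
#' position; the table behind the OR circle plots.
#'
#' @inheritParams pairwise_or
#' @return data.frame, one row per (category, position, group pair).
#' @export
or_table <- function(model, conf_level = 0.95) {
  stopifnot(inherits(model, "seed_composition_model"))
  pairs <- utils::combn(model$groups, 2L, simplify = FALSE)
  do.call(rbind, lapply(NONREF_CATS, function(k) {
    do.call(rbind, lapply(1:6, function(j) {
      do.call(rbind, lapply(pairs, function(pr) {
        pairwise_or(model, k, j, pr[2L], pr[1L], conf_level)
      }))
    }))
  }))
}

#' Likelihood-ratio test of the group x position interaction
#'
#' Refits the model without the interaction block and compares summed
#' category log-likelihoods against a chi-square with
#' `3 * (G - 1) * 5` degrees of freedom.
#'
#' @param model a [fit_seed_composition()] result (fitted with
#'   `interaction = TRUE`).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
interaction_test <- function(model) {
  stopifnot(inherits(model, "seed_composition_model"))
  if (!model$interaction) stop("model was fitted without the interaction")
  G <- length(model$groups)
  stat <- 0
  for (k in NONREF_CATS) {
    fit_full <- model$categories[[k]]
    fit_red <- fit_binary_component(
      fit_full$pattern, G, interaction = FALSE, nagq = model$nagq,
      ridge = if (fit_full$separation) 1e-2 else 0,
      sigma2_fixed = model$sigma2_fixed,
      start = list(mu_cells = drop(fit_full$X %*% fit_full$beta),
                   sigma = sqrt(fit_full$sigma2)))
    stat <- stat + 2 * (fit_full$loglik - fit_red$loglik)
  }
  stat <- max(0, stat)
  df <- 3L * (G - 1L) * 5L
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "interaction LRT"),
            class = "seedtox_test")
}

#' @export
print.seedtox_test <- function(x, ...) {
  if (x$method == "interaction LRT") {
    cat(sprintf("interaction LRT: X2 = %.1f on %d df, p = %.3g\n",
                x$statistic, x$df, x$p.value))
  } else if (x$method == "wilcoxon") {
    cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.3g\n",
                x$statistic, x$p.value))
  } else {
    cat(sprintf("Kruskal-Wallis: H = %.3f, p = %.3g\n",
                x$statistic, x$p.value))
  }
  invisible(x)
}

#' Rank test of seed toxicity between groups
#'
#' Compares Output D expansions (per-instance % viability) between groups:
#' two-sided Wilcoxon rank-sum for two groups (exact when sample sizes
#' permit and there are no ties, else the tie-corrected normal
#' approximation), Kruskal-Wallis for more.
#'
#' @param groups named list of numeric vectors (one [expand_to_d()] result
#'   per group).
#' @return list with `method`, `statistic`, `p.value`.
#' @export
toxicity_rank_test <- function(groups) {
  if (length(groups) < 2L) stop("at least two groups are required")
  if (any(!vapply(groups, length, 1L))) stop("empty group in rank test")
  if (length(groups) == 2L) {
    # ties force the tie-corrected normal approximation; the exact
    # distribution is used automatically for small tie-free samples
    ht <- suppressWarnings(
      stats::wilcox.test(groups[[1L]], groups[[2L]],
                         alternative = "two.sided", correct = FALSE))
    out <- list(method = "wilcoxon", statistic = unname(ht$statistic),
                p.value = min(1, ht$p.value))
  } else {
    ht <- stats::kruskal.test(groups)
    out <- list(method = "kruskal-wallis", statistic = unname(ht$statistic),
                p.value = ht$p.value)
  }
  structure(out, class = "seedtox_test")
}
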