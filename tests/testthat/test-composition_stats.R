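# Exact enumeration oracle for the two-sided Wilcoxon rank-sum p-value
# (no ties): distribution of the rank-sum statistic over all
# choose(n1+n2, n1) group assignments.
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  combos <- combn(length(pooled), n1)
  w_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
}

test_that("rank tests: identical, separated, and >2-group cases", {
  g <- list(a = c(10, 20, 30, 40), b = c(10, 20, 30, 40))
  expect_equal(toxicity_rank_test(g)$p.value, 1)
  r <- toxicity_rank_test(list(a = 1:10, b = 101:110))
  expect_true(r$statistic %in% c(0, 100))
  expect_equal(r$p.value, wilcox_exact_oracle(1:10, 101:110), tolerance = 1e-9)
  k <- toxicity_rank_test(list(a = 1:5, b = 1:5, c = 1:5))
  expect_equal(k$method, "kruskal-wallis")
  expect_equal(unname(k$statistic), 0)
  expect_error(toxicity_rank_test(list(a = 1:3, b = numeric())), "empty")
  expect_error(toxicity_rank_test(list(a = 1:3)), "two groups")
})

test_that("wilcoxon agrees with exact enumeration on random n = 10 draws", {
  set.seed(23)
  for (i in 1:5) {
    x <- 2 * sample(500, 10)                 # even values
    y <- 2 * sample(500, 10) + 1 + sample(c(0, 150), 1) * 2  # odd: no ties
    expect_equal(toxicity_rank_test(list(a = x, b = y))$p.value,
                 wilcox_exact_oracle(x, y), tolerance = 1e-9,
                 label = paste("draw", i))
  }
})

test_that("sigma2 = 0 fit equals the fixed-effects multinomial logit", {
  d <- simulate_composition(250, log_or = c(C = 0.4, G = 0.9, U = -0.3),
                            sigma2 = 0, seed = 19)
  m0 <- fit_seed_composition(d, sigma2_fixed = 0)
  # saturated-design oracle: cell-wise empirical log odds k vs A
  cells <- table(d$group, d$position, d$nucleotide)
  for (k in c("C", "G", "U")) {
    fit <- m0$categories[[k]]
    mu <- drop(fit$X %*% fit$beta)
    oracle <- as.vector(vapply(1:2, function(g)
      vapply(1:6, function(j)
        log(cells[g, j, k] / cells[g, j, "A"]), 1), numeric(6)))
    expect_lt(max(abs(mu - oracle)), 1e-3)
  }
})

test_that("null data give ORs near 1 with covering CIs", {
  d <- simulate_composition(500, log_or = c(C = 0, G = 0, U = 0),
                            sigma2 = 0, seed = 29)
  m <- fit_seed_composition(d)
  for (k in c("C", "G", "U")) {
    for (j in c(1, 4)) {
      po <- pairwise_or(m, k, j, "g2", "g1")
      expect_true(po$ci_lo <= 1 && po$ci_hi >= 1,
                  label = sprintf("%s pos %d CI covers 1", k, j))
    }
  }
})

test_that("a planted OR = 5 for G is recovered within its CI", {
  d <- simulate_composition(1000, log_or = c(C = 0, G = log(5), U = 0),
                            sigma2 = 1, seed = 101)
  m <- fit_seed_composition(d)
  po <- pairwise_or(m, "G", 3, "g2", "g1")
  expect_true(po$ci_lo <= 5 && po$ci_hi >= 5)
  expect_gt(po$or, 1)
  expect_lt(po$p_adj, 0.05)
  # sigma2 is estimated in a plausible neighborhood of the truth
  expect_gt(m$categories$G$sigma2, 0.3)
  expect_lt(m$categories$G$sigma2, 2.5)
})

test_that("group-label swap inverts ORs and keeps adjusted p-values", {
  d <- simulate_composition(400, log_or = c(C = 0.5, G = 0.8, U = 0),
                            sigma2 = 0.5, seed = 41)
  d_swapped <- d
  d_swapped$group <- ifelse(d$group == "g1", "zz2", "aa1")
  # relabeling reverses which group is the design reference
  m <- fit_seed_composition(d)
  ms <- fit_seed_composition(d_swapped)
  for (j in c(2, 5)) {
    a <- pairwise_or(m, "G", j, "g2", "g1")
    # "aa1" is the old g2, so (aa1 vs zz2) is the same biological contrast
    # with the design reference swapped
    b <- pairwise_or(ms, "G", j, "aa1", "zz2")
    expect_equal(log(a$or), log(b$or), tolerance = 1e-3)
    expect_equal(a$p_adj, b$p_adj, tolerance = 1e-3)
    inv <- pairwise_or(m, "G", j, "g1", "g2")
    expect_equal(log(inv$or), -log(a$or), tolerance = 1e-9)
    expect_equal(inv$p_adj, a$p_adj, tolerance = 1e-12)
  }
})

test_that("pairwise_or conventions: self-contrast, OR*, errors", {
  d <- simulate_composition(200, log_or = c(C = 0, G = -1.6, U = 0),
                            sigma2 = 0, seed = 43)
  m <- fit_seed_composition(d)
  self <- pairwise_or(m, "G", 1, "g1", "g1")
  expect_equal(self$or, 1)
  expect_equal(self$p_adj, 1)
  po <- pairwise_or(m, "G", 2, "g2", "g1")
  expect_lt(po$or, 1)                      # planted depletion
  expect_equal(po$or_star, 1 / po$or)      # OR* display convention
  expect_error(pairwise_or(m, "G", 7, "g1", "g2"), "position")
  expect_error(pairwise_or(m, "G", 2, "nope", "g1"), "unknown group")
  tab <- or_table(m)
  expect_equal(nrow(tab), 3 * 6 * 1)       # categories x positions x pairs
})

test_that("fitted cell probabilities over A/C/G/U sum to one", {
  d <- simulate_composition(300, log_or = c(C = 0.3, G = 0.5, U = -0.2),
                            sigma2 = 0, seed = 47)
  m <- fit_seed_composition(d, sigma2_fixed = 0)
  mus <- sapply(c("C", "G", "U"), function(k)
    drop(m$categories[[k]]$X %*% m$categories[[k]]$beta))
  denom <- 1 + rowSums(exp(mus))
  probs <- cbind(A = 1 / denom, exp(mus) / denom)
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-12)
})

test_that("interaction LRT separates null from planted interactions", {
  # constant group effect across positions: interaction is null
  d0 <- simulate_composition(600, log_or = c(C = 0, G = 0.7, U = 0),
                             sigma2 = 0.5, seed = 53)
  m0 <- fit_seed_composition(d0)
  it0 <- interaction_test(m0)
  expect_equal(it0$df, 15)
  expect_gt(it0$p.value, 0.001)   # should not be grossly anti-conservative
  # identical groups: far from significance
  dd <- simulate_composition(300, log_or = c(C = 0, G = 0, U = 0),
                             sigma2 = 0, seed = 59)
  expect_gt(interaction_test(fit_seed_composition(dd))$p.value, 0.05)
  # strong position-dependent effect: build by stacking two simulations
  # with different group effects and re-labelling positions
  da <- simulate_composition(500, log_or = c(C = 0, G = 1.5, U = 0),
                             sigma2 = 0, seed = 61)
  db <- simulate_composition(500, log_or = c(C = 0, G = -1.5, U = 0),
                             sigma2 = 0, seed = 62)
  # pair instance i's positions 1-3 (effect +1.5) with positions 4-6
  # (effect -1.5) so every instance still has its 6 rows
  hybrid <- rbind(da[da$position <= 3, ], db[db$position >= 4, ])
  m_int <- fit_seed_composition(hybrid)
  expect_lt(interaction_test(m_int)$p.value, 0.001)
})

test_that("malformed composition data are rejected", {
  d <- simulate_composition(10, seed = 3)
  expect_error(fit_seed_composition(d[-1, ]), "exactly 6")
  d_bad <- d
  d_bad$nucleotide[1] <- "N"
  expect_error(fit_seed_composition(d_bad), "A/C/G/U")
  d_one <- d[d$group == "g1", ]
  expect_error(fit_seed_composition(d_one), "two groups")
})
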