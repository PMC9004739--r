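# Closed-form two-sided binomial oracle: sum of the probabilities of all
# outcomes no more likely than the observed one.
binom_exact_two_sided <- function(x, size, prob) {
  d <- dbinom(0:size, size, prob)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-10)]))
}

make_ct <- function(raw, samples = paste0("s", seq_len(ncol(raw)))) {
  seqs <- random_reads(nrow(raw), 20, seed = nrow(raw) + 1000)
  df <- data.frame(sequence = seqs, raw)
  colnames(df) <- c("sequence", samples)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  normalize_cpm(read_count_table(path))
}

test_that("symmetric counts with equal library sizes give p = 1", {
  raw <- matrix(c(5, 10, 5, 10), ncol = 2)  # identical columns
  ct <- make_ct(raw)
  des <- comparison_design("c", c(s1 = 1, s2 = -1))
  res <- test_differential(ct, des, "poisson")
  expect_equal(res$pvalue, rep(1, 2))
  expect_equal(res$logFC, rep(0, 2))
  expect_equal(res$delta, rep(0, 2))
})

test_that("0-vs-large counts in 1-vs-1 match the binomial tail", {
  N <- 12
  raw <- matrix(c(0, 500, N, 500), ncol = 2)  # equal library sizes
  ct <- make_ct(raw)
  des <- comparison_design("c", c(s1 = 1, s2 = -1))
  res <- test_differential(ct, des, "poisson")
  i <- which(ct$raw[, 1] == 0)
  expect_equal(res$pvalue[i], 2 * 0.5^N, tolerance = 1e-9)
})

test_that("dispersion-zero NB equals the exact binomial on a count grid", {
  des <- comparison_design("c", c(s1 = 1, s2 = -1))
  for (a in c(0L, 1L, 3L, 7L, 20L)) {
    for (b in c(0L, 2L, 5L, 20L)) {
      if (a + b == 0) next
      filler <- 1000L
      ct <- make_ct(matrix(c(a, filler - a, b, filler - b), ncol = 2))
      res <- test_differential(ct, des, "poisson")
      i <- which(ct$raw[, 1] == a & ct$raw[, 2] == b)
      expect_equal(res$pvalue[i],
                   binom_exact_two_sided(a, a + b, 0.5), tolerance = 1e-6,
                   label = sprintf("counts %d vs %d", a, b))
      # below the cutoff the limit is taken exactly
      expect_equal(seedtox:::nb_exact_pvalue(a, a + b, 1, 1, 1e-9),
                   binom_exact_two_sided(a, a + b, 0.5), tolerance = 1e-12)
      # the NB path converges to the binomial as dispersion -> 0; skip
      # probability-tied configurations (a == b or a mirror outcome with
      # an identical binomial probability), where the "no more likely
      # than observed" rule flips discontinuously under perturbation
      d <- dbinom(0:(a + b), a + b, 0.5)
      tied <- sum(abs(d - d[a + 1]) < 1e-12) > 1
      if (!tied) {
        expect_equal(seedtox:::nb_exact_pvalue(a, a + b, 1, 1, 1e-5),
                     binom_exact_two_sided(a, a + b, 0.5), tolerance = 0.02)
      }
    }
  }
})

test_that("BH adjustment is monotone and bounded by 1", {
  set.seed(5)
  raw <- matrix(rnbinom(400, mu = 50, size = 5), ncol = 4)
  ct <- make_ct(raw)
  des <- comparison_design("c", c(s1 = 1, s2 = 1, s3 = -1, s4 = -1))
  res <- test_differential(ct, des, "common")
  ord <- order(res$pvalue)
  expect_true(all(diff(res$padj[ord]) >= -1e-12))
  expect_true(all(res$padj >= res$pvalue - 1e-12))
  expect_true(all(res$padj <= 1))
})

test_that("swapping the groups negates logFC and delta, keeps p", {
  set.seed(6)
  raw <- matrix(rnbinom(300, mu = 40, size = 2), ncol = 6)
  ct <- make_ct(raw)
  des <- comparison_design("c", c(s1 = 1, s2 = 1, s3 = 1,
                                  s4 = -1, s5 = -1, s6 = -1))
  swp <- comparison_design("c", c(s1 = -1, s2 = -1, s3 = -1,
                                  s4 = 1, s5 = 1, s6 = 1))
  r1 <- test_differential(ct, des, "common")
  r2 <- test_differential(ct, swp, "common")
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-9)
  expect_equal(r1$delta, -r2$delta, tolerance = 1e-9)
  expect_equal(r1$logFC, -r2$logFC, tolerance = 1e-9)
})

test_that("significance needs padj < 0.05 AND |logFC| > 0.585", {
  set.seed(8)
  mu1 <- c(rep(100, 5), rep(100, 15))
  mu2 <- c(rep(800, 5), rep(100, 15))
  raw <- cbind(matrix(rpois(20 * 3, mu1), ncol = 3),
               matrix(rpois(20 * 3, mu2), ncol = 3))
  ct <- make_ct(raw, paste0("s", 1:6))
  des <- comparison_design("c", c(s1 = 1, s2 = 1, s3 = 1,
                                  s4 = -1, s5 = -1, s6 = -1))
  res <- test_differential(ct, des, "poisson")
  expect_identical(res$significant,
                   res$padj < 0.05 & abs(res$logFC) > 0.585)
  expect_gte(sum(res$significant), 5)
})

test_that("selection boundaries: padj and fold-change rules are conjunctive", {
  mir <- random_reads(4, 21, seed = 314)
  atab <- build_annotated(list(s1 = rep(mir, 5), s2 = rep(mir, 5)),
                          self_mirna_refs(mir), empty_rnaworld())
  fake <- data.frame(
    sequence = atab$sequence,
    logFC = c(0.60, 0.50, 2.00, -0.70),
    pvalue = c(0.001, 0.001, 0.02, 0.001),
    padj = c(0.040, 0.040, 0.060, 0.040),
    mean_norm_g1 = 100, mean_norm_g2 = 150, delta = c(50, 50, 50, -50),
    significant = NA, stringsAsFactors = FALSE)
  class(fake) <- c("differential_result", "data.frame")
  sel <- select_differential(atab, fake, mode = "padj")
  # padj .04 + logFC .60 -> in; logFC .50 -> out; padj .06 -> out;
  # negative logFC of matching magnitude -> in
  expect_equal(sel$sequence, atab$sequence[c(1, 4)])  # row order preserved
  expect_equal(sel$extra$direction, c("Up", "Down"))
  sel_p <- select_differential(atab, fake, mode = "pvalue")
  expect_setequal(sel_p$sequence, atab$sequence[c(1, 3, 4)])
  fake$padj <- 1
  expect_warning(select_differential(atab, fake, mode = "padj"), "empty")
})

test_that("selection splits Up and Down by the sign of delta", {
  mir <- random_reads(3, 21, seed = 777)
  mirna <- reference_set("mirna", paste0("m", 1:3), mir)
  reads <- list(s1 = c(rep(mir[1], 50), rep(mir[2], 5), rep(mir[3], 45)),
                s2 = c(rep(mir[1], 48), rep(mir[2], 6), rep(mir[3], 46)),
                s3 = c(rep(mir[1], 5), rep(mir[2], 50), rep(mir[3], 45)),
                s4 = c(rep(mir[1], 6), rep(mir[2], 49), rep(mir[3], 45)))
  atab <- build_annotated(reads, mirna, empty_rnaworld())
  des <- comparison_design("c", c(s1 = 1, s2 = 1, s3 = -1, s4 = -1))
  res <- test_differential(atab, des, "poisson")
  sel <- select_differential(atab, res)
  expect_true(all(sel$extra$padj < 0.05 & abs(sel$extra$logFC) > 0.585))
  expect_setequal(sel$extra$direction[match(mir[1:2], sel$sequence)],
                  c("Down", "Up"))
  expect_false(mir[3] %in% sel$sequence)  # unchanged read not selected
  expect_equal(sel$extra$delta,
               res$delta[match(sel$sequence, res$sequence)])
})

test_that("zero-count groups and misaligned designs error", {
  ct <- make_ct(matrix(c(0, 0, 5, 7), ncol = 2))
  des <- comparison_design("c", c(s1 = 1, s2 = -1))
  expect_error(test_differential(ct, des), "zero total")
  expect_error(comparison_design("c", c(s1 = 1, s2 = 2)), "1, -1 or 0")
  expect_error(comparison_design("c", c(s1 = 1, s2 = 0)), "at least one")
})

test_that("type-I error is controlled on null NB data", {
  set.seed(17)
  n_reads <- 1000
  raw <- matrix(rnbinom(n_reads * 6, mu = 100, size = 10), ncol = 6)
  ct <- make_ct(raw, paste0("s", 1:6))
  des <- comparison_design("c", c(s1 = 1, s2 = 1, s3 = 1,
                                  s4 = -1, s5 = -1, s6 = -1))
  res <- test_differential(ct, des, "common")
  rate <- mean(res$pvalue < 0.05)
  # exact conditional tests are valid (possibly conservative): the
  # rejection rate must not exceed the binomial upper bound and should
  # not collapse to zero at these counts
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_reads))
  expect_gt(rate, 0.01)
})

test_that("comparisons CSV parses sample codings", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,s1,s2,s3,s4", "tvc,1,1,-1,-1", "partial,1,0,-1,0"), path)
  designs <- read_comparisons(path)
  expect_length(designs, 2)
  expect_equal(designs[[1]]$name, "tvc")
  expect_equal(unname(designs[[2]]$coding), c(1, 0, -1, 0))
})
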