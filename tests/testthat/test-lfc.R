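test_that("median-of-ratios size factors satisfy the defining identities", {
  k <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40), ncol = 2)
  cm <- toy_counts(k, c("A", "B"))
  expect_equal(unname(size_factors(cm)), c(1, 1))

  # sample 2 = 2x sample 1 -> factors (1/sqrt(2), sqrt(2))
  k2 <- matrix(c(10, 20, 30, 40, 20, 40, 60, 80), ncol = 2)
  cm2 <- toy_counts(k2, c("A", "B"))
  expect_equal(unname(size_factors(cm2)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # planted library sizes recovered proportionally
  d <- rescue_design(n_genes = 500, frac_dependent = 0, dispersion = 0.02,
                     baseline_log_sd = 0.5, replicates = 2,
                     library_sizes = rep(c(1, 2, 4), length.out = 10), seed = 3)
  sim <- simulate_counts(d)
  sf <- size_factors(sim$counts)
  planted <- rep(c(1, 2, 4), length.out = 10)
  rel <- sf / planted
  expect_lt(max(rel) / min(rel) - 1, 0.10)

  expect_error(size_factors(toy_counts(matrix(c(0, 1, 1, 0), 2), c("A", "B"))),
               "no gene expressed")
})

test_that("dispersion estimates recover planted values and degenerate limits", {
  # Poisson truth -> alpha at floor for most genes
  d0 <- rescue_design(n_genes = 300, frac_dependent = 0, dispersion = 0,
                      baseline_log_mean = log(2000), baseline_log_sd = 0.1,
                      replicates = 20, seed = 1)
  s0 <- simulate_counts(d0)
  a0 <- estimate_dispersion(s0$counts)
  expect_lt(median(a0), 0.005)

  # planted alpha = 0.1, 50 replicates, high mean
  d1 <- rescue_design(n_genes = 300, frac_dependent = 0, dispersion = 0.1,
                      baseline_log_mean = log(500), baseline_log_sd = 0.1,
                      replicates = 50, seed = 2)
  s1 <- simulate_counts(d1)
  a1 <- estimate_dispersion(s1$counts)
  expect_lt(abs(median(a1) - 0.1), 0.03)

  # constant replicates -> floor
  k <- matrix(rep(c(100, 200, 300), 4), ncol = 4)   # rows constant across samples
  rownames(k) <- paste0("g", 1:3); colnames(k) <- paste0("s", 1:4)
  cm <- count_matrix(k, setNames(c("A", "A", "B", "B"), colnames(k)))
  expect_true(all(estimate_dispersion(cm) == 1e-8))
})

test_that("lfc_test matches a brute-force oracle on a small matrix", {
  set.seed(10)
  k <- matrix(rpois(20, lambda = c(100, 400, 50, 800, 20)), nrow = 5)
  cm <- toy_counts(k, c("A", "A", "B", "B"))
  res <- lfc_test(cm, c("A", "B"))

  # --- independent reference, spelled out step by step ---
  geo <- apply(k, 1, function(x) exp(mean(log(x))))
  sf <- numeric(4)
  for (j in 1:4) sf[j] <- median(k[, j] / geo)
  y <- k
  for (j in 1:4) y[, j] <- k[, j] / sf[j]
  m1 <- rowMeans(y[, 1:2]); m2 <- rowMeans(y[, 3:4])
  lfc_ref <- log2((m1 + 0.5) / (m2 + 0.5))
  s2 <- (apply(y[, 1:2], 1, var) + apply(y[, 3:4], 1, var)) / 2
  mbar <- rowMeans(y)
  a_ref <- pmax(1e-8, (s2 - mbar) / mbar^2)
  v1 <- (m1 / sf[1] + a_ref * m1^2 + m1 / sf[2] + a_ref * m1^2) / 4
  v2 <- (m2 / sf[3] + a_ref * m2^2 + m2 / sf[4] + a_ref * m2^2) / 4
  se_ref <- sqrt(v1 / pmax(m1, 0.5)^2 + v2 / pmax(m2, 0.5)^2) / log(2)
  p_ref <- 2 * pt(-abs(lfc_ref / se_ref), df = 2)

  expect_equal(unname(res$lfc_mle), unname(lfc_ref), tolerance = 1e-12)
  expect_equal(unname(res$p), unname(p_ref), tolerance = 1e-12)
  expect_equal(unname(res$padj), bh_reference(unname(p_ref)), tolerance = 1e-12)
})

test_that("size factors agree with the DE package's median-of-ratios on nonzero counts", {
  skip_if_not_installed("DESeq2")
  set.seed(4)
  k <- matrix(rpois(600, 200), ncol = 6) + 1L
  cm <- toy_counts(k, rep(c("A", "B"), each = 3))
  expect_equal(unname(size_factors(cm)),
               unname(DESeq2::estimateSizeFactorsForMatrix(k)),
               tolerance = 1e-6)
})

test_that("contrast antisymmetry and normalization invariance hold", {
  d <- rescue_design(n_genes = 200, frac_dependent = 0.5, replicates = 3, seed = 8)
  cm <- simulate_counts(d)$counts
  ab <- lfc_test(cm, c("KO", "EV"))
  ba <- lfc_test(cm, c("EV", "KO"))
  expect_equal(ab$lfc_mle, -ba$lfc_mle, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  # scaling one sample's counts by c scales its size factor by c relative to
  # the others (factors are defined up to a common scale) and leaves LFCs
  # unchanged up to pseudocount effects
  cm2 <- cm
  cm2$counts[, 1] <- cm2$counts[, 1] * 4L
  sf1 <- size_factors(cm); sf2 <- size_factors(cm2)
  expect_equal(unname((sf2[1] / sf2[2]) / (sf1[1] / sf1[2])), 4, tolerance = 1e-9)
  ab2 <- lfc_test(cm2, c("KO", "EV"))
  expect_equal(ab2$lfc_mle, ab$lfc_mle, tolerance = 0.02)
})

test_that("BH adjustment is the step-up transform with its standard properties", {
  k <- matrix(rpois(4 * 6, 100), ncol = 6)
  cm <- toy_counts(k, rep(c("A", "B"), each = 3))
  res <- lfc_test(cm, c("A", "B"))
  expect_true(all(res$padj >= res$p - 1e-15))
  o <- order(res$p)
  expect_true(all(diff(res$padj[o]) >= -1e-15))
  # worked BH example: p = (.01,.02,.03,.04), m = 4 -> all .04
  expect_equal(bh_reference(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("all-zero genes are excluded from testing and the BH count", {
  k <- matrix(c(100, 120, 90, 110,
                0, 0, 0, 0,
                50, 60, 55, 65), ncol = 4, byrow = TRUE)
  cm <- toy_counts(k, c("A", "A", "B", "B"))
  res <- lfc_test(cm, c("A", "B"))
  expect_false(res$tested[2])
  expect_true(is.na(res$p[2]) && is.na(res$padj[2]))
  expect_equal(res$padj[res$tested], bh_reference(res$p[res$tested]), tolerance = 1e-12)
})

test_that("shrinkage obeys the conjugate closed form and its limits", {
  res <- data.frame(gene = "g1", base_mean = 100, lfc_mle = 1.0,
                    lfc_shrunk = NA_real_, se = 0.5, p = 0.01, padj = 0.01,
                    tested = TRUE)
  class(res) <- c("contrast_result", "data.frame")
  expect_equal(shrink_lfc(res, prior_sd = 1.0)$lfc_shrunk, 0.8, tolerance = 1e-12)
  expect_equal(shrink_lfc(res, prior_sd = 1e9)$lfc_shrunk, 1.0, tolerance = 1e-6)
  expect_lt(abs(shrink_lfc(res, prior_sd = 1e-9)$lfc_shrunk), 1e-6)
  expect_error(shrink_lfc(res, prior_sd = -1), "positive")
  # shrinkage never increases magnitude
  expect_lte(abs(shrink_lfc(res, prior_sd = 2)$lfc_shrunk), abs(res$lfc_mle))
})

test_that("DE calls use strict thresholds in both dimensions", {
  res <- data.frame(gene = c("a", "b", "c"),
                    base_mean = 100,
                    lfc_mle = c(0.5, -1.2, 0.8),
                    lfc_shrunk = c(0.5, -1.2, 0.8),
                    se = 0.1,
                    p = c(0.001, 0.0001, 0.2), padj = c(0.01, 0.001, 0.3),
                    tested = TRUE)
  class(res) <- c("contrast_result", "data.frame")
  calls <- call_de(res, de_thresholds(lfc_min = 0.5, padj_max = 0.05))
  expect_false(calls$called[1])   # |lfc| == 0.5 exactly: excluded (strict >)
  expect_true(calls$called[2])
  expect_equal(calls$direction[2], "down")
  expect_false(calls$called[3])   # padj too large
  expect_error(de_thresholds(padj_max = 0), "padj_max")
})
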