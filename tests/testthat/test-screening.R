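test_that("Cohen's d matches its definition and is antisymmetric", {
  a <- c(0, 1, 2); b <- a
  expect_equal(cohens_d(a, b), 0)

  set.seed(51)
  x <- rnorm(50); y <- rnorm(50)
  x <- (x - mean(x)) / sd(x) + 1   # mean 1, sd 1
  y <- (y - mean(y)) / sd(y)       # mean 0, sd 1
  expect_equal(cohens_d(x, y), 1, tolerance = 1e-12)
  expect_equal(cohens_d(y, x), -cohens_d(x, y))

  expect_error(cohens_d(1, 1:3), "n >= 2")
  expect_error(cohens_d(c(2, 2), c(2, 2)), "pooled")

  expect_equal(effect_size_label(0.1), "negligible")
  expect_equal(effect_size_label(-0.3), "small")
  expect_equal(effect_size_label(0.6), "medium")
  expect_equal(effect_size_label(0.8), "large")
})

test_that("2x2 chi-square reproduces the sex-by-group worked example and the direct formula", {
  # printed cohort counts: 18/21 female/male controls, 100/21 pain
  tab <- matrix(c(18, 100, 21, 21), nrow = 2)
  res <- chi_square_2x2(tab)
  expect_equal(res$statistic, 20.3, tolerance = 0.05)
  expect_equal(res$df, 1L)
  expect_lt(res$p, 1e-4)

  # proportional rows give exactly zero
  expect_equal(chi_square_2x2(matrix(c(10, 20, 30, 60), 2))$statistic, 0)

  # matches sum((O-E)^2/E) on random tables
  set.seed(52)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 30) + 1, 2)
    E <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    expect_equal(chi_square_2x2(t2)$statistic, sum((t2 - E)^2 / E),
                 tolerance = 1e-12)
  }

  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("Welch t test behaves at anchors and matches a permutation oracle", {
  x <- c(1.2, 3.4, 2.2, 5)
  expect_equal(welch_t(x, x)$statistic, 0)

  set.seed(53)
  a <- rnorm(20); b <- rnorm(20) + 2
  expect_lt(welch_t(a, b)$statistic, 0)
  expect_gt(welch_t(b, a)$statistic, 0)

  # two-sided p close to an exhaustive-ish permutation p on small samples
  set.seed(54)
  a <- rnorm(8); b <- rnorm(8) + 1
  t_obs <- abs(welch_t(a, b)$statistic)
  pool <- c(a, b)
  perm_p <- mean(replicate(4000, {
    idx <- sample(16, 8)
    abs(welch_t(pool[idx], pool[-idx])$statistic) >= t_obs
  }))
  expect_lt(abs(welch_t(a, b)$p - perm_p), 0.05)

  expect_error(welch_t(c(1, 1), c(1, 1)), "degenerate")
})

test_that("movement screen keeps classes with identical distributions", {
  # synthetic feature table: no group difference at all
  set.seed(55)
  nm <- feature_names()
  n <- 80
  x <- matrix(rnorm(n * length(nm)), n)
  colnames(x) <- nm
  tab <- data.frame(subject = rep(sprintf("s%02d", 1:10), each = 8),
                    group = "healthy", condition = "baseline",
                    mover = rep(c(TRUE, FALSE), each = 40),
                    epoch = rep(1:8, 10), stringsAsFactors = FALSE)
  feats <- cbind(tab, as.data.frame(x))
  scr <- movement_screen(feats)
  expect_s3_class(scr, "screening_result")
  expect_equal(nrow(scr), 7)
  # iid noise: no class effect beyond sampling noise (the smallest class
  # pools 4 features x 40 epochs per group)
  expect_true(all(abs(scr$cohens_d) < 0.35))
  expect_length(attr(scr, "retained"),
                380 - sum(table(feature_info(nm)$class)[scr$class[
                  scr$decision == "drop"]]))
  expect_equal(attr(scr, "threshold"), 0.05 / 7)

  # a planted mover shift in the power class is dropped; others kept
  x2 <- x
  pow_cols <- feature_info(nm)$class == "power"
  x2[tab$mover, pow_cols] <- x2[tab$mover, pow_cols] + 1
  scr2 <- movement_screen(cbind(tab, as.data.frame(x2)))
  expect_equal(scr2$decision[scr2$class == "power"], "drop")
  expect_true(all(scr2$decision[scr2$class %in% c("pe", "dpli")] == "keep"))
  expect_false("power" %in% feature_info(attr(scr2, "retained"))$class)

  expect_error(movement_screen(feats[!feats$mover, ]), "mover")
})

test_that("simulated movement cohorts reproduce the empirical screening pattern", {
  feats <- screen_features()
  scr <- movement_screen(feats)
  dropped <- scr$class[scr$decision == "drop"]
  kept <- scr$class[scr$decision == "keep"]
  expect_true(all(c("power", "wpli", "wgraph") %in% dropped))
  expect_true(all(c("peakfreq", "pe", "dpli", "bgraph") %in% kept))
  # artifact loads spectral power more than permutation entropy
  expect_gt(abs(scr$cohens_d[scr$class == "power"]),
            abs(scr$cohens_d[scr$class == "pe"]))
})
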