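# RSFA, cross-correlation FC, sigma-weighting and binned regression.

test_that("RSFA matches the closed-form sinusoid amplitude", {
  tt <- (0:499) * 2.2
  s <- 10 * (1 + 0.05 * sin(2 * pi * 0.1 * tt))
  st <- rsfa(s)
  expect_equal(st$rsfa, 0.05 / sqrt(2), tolerance = 0.01)
  expect_equal(st$n_used, 500)                  # a pure sinusoid has no outliers
  # constant series
  expect_equal(rsfa(rep(3, 20))$rsfa, 0)
  # invariant to positive rescaling (mean normalization)
  expect_equal(rsfa(7 * s)$rsfa, st$rsfa)
  expect_error(rsfa(rep(0, 20)), "zero-mean")
})

test_that("outlier rejection trims spikes beyond the Tukey fences", {
  set.seed(5)
  s <- 1 + 0.02 * sin(2 * pi * 0.1 * (0:199) * 2.2)
  sp <- s; sp[100] <- 1 + 0.2                   # a 10x amplitude spike
  with_spike <- rsfa(sp)
  expect_lt(with_spike$rsfa, sd(sp / mean(sp)))
  expect_equal(with_spike$n_used, 199)
  expect_equal(with_spike$rsfa, rsfa(s[-100])$rsfa, tolerance = 1e-3)
})

test_that("extremum cross-correlation recovers identity, sign and shift", {
  set.seed(8)
  a <- rnorm(80)
  expect_equal(cross_corr_fc(a, a)$r, 1, tolerance = 1e-12)
  expect_equal(cross_corr_fc(a, a)$lag, 0)
  expect_equal(cross_corr_fc(a, -a)$r, -1, tolerance = 1e-12)
  # delayed sinusoid: recovered at its lag
  tt <- (0:199) * 2.2
  s <- sin(2 * pi * 0.05 * tt)
  s2 <- c(rep(0, 2), s[1:198])
  cc <- cross_corr_fc(s, s2, max_lag = 4)
  expect_equal(cc$lag, 2)
  expect_gt(cc$r, 0.95)
  # zero-variance input is flagged, not crashed
  und <- cross_corr_fc(rep(1, 40), rnorm(40))
  expect_false(und$defined)
  expect_true(is.na(und$r))
})

test_that("cross-correlation agrees with the ccf oracle and is symmetric", {
  set.seed(11)
  a <- as.numeric(arima.sim(list(ar = 0.5), 60))
  b <- as.numeric(arima.sim(list(ar = 0.5), 60))
  ours <- vasobold:::cross_corr_lags(a, b, 5)
  oracle <- ccf(a, b, lag.max = 5, plot = FALSE, demean = TRUE)
  # ccf(a, b) at lag k estimates cor(a[t+k], b[t]): reversed lag sign
  expect_equal(ours$r, rev(as.numeric(oracle$acf)), tolerance = 1e-10)
  f1 <- cross_corr_fc(a, b, 5)
  f2 <- cross_corr_fc(b, a, 5)
  expect_equal(f1$r, f2$r)
  expect_equal(f1$lag, -f2$lag)
})

test_that("sigma weighting scales by the target voxel's sigma", {
  expect_equal(sigma_weight(1, 0.1, 0.03), 0.03)
  expect_equal(sigma_weight(-0.5, 0.1, 0.03), -0.015)
  expect_equal(sigma_weight(0.8, 0.04, 0), 0)
  expect_equal(sigma_weight(0.5, 0.04, 0.09, method = "geometric"),
               0.5 * 0.06)
})

test_that("pairwise FC tables enumerate and class voxel pairs", {
  set.seed(13)
  m <- matrix(rnorm(40 * 9), 40, 9)
  colnames(m) <- as.character(1:9)
  tab <- pairwise_fc_table(m, list(artery = 1:4, vein = 5:9), max_lag = 3)
  expect_equal(sum(tab$class == "AA"), choose(4, 2))
  expect_equal(sum(tab$class == "VV"), choose(5, 2))
  expect_equal(sum(tab$class == "AV"), 4 * 5)
  expect_true(all(abs(tab$r) <= 1))
  expect_equal(tab$weighted, sigma_weight(tab$r, tab$sigma_i, tab$sigma_j))
  # each record matches the single-pair computation
  k <- which(tab$class == "AV")[3]
  single <- cross_corr_fc(m[, as.character(tab$i[k])],
                          m[, as.character(tab$j[k])], max_lag = 3)
  expect_equal(tab$r[k], single$r)
  expect_equal(tab$lag[k], single$lag)
  # overlapping artery/vein voxels resolve to vein
  expect_warning(
    tab2 <- pairwise_fc_table(m, list(artery = 1:5, vein = 5:9),
                              max_lag = 3), "vein")
  expect_equal(sum(tab2$class == "AA"), choose(4, 2))
  # generic mask names keep their labels (vessel-to-shell analyses)
  tab3 <- pairwise_fc_table(m, list(vein = 1:3, shell1 = 4:6),
                            max_lag = 3,
                            between = list(c("vein", "shell1")))
  expect_equal(unique(tab3$class), "shell1-vein")
  expect_equal(nrow(tab3), 9)
})

test_that("binned regression is exact for affine data and floors bins", {
  set.seed(17)
  x <- runif(2050)
  fit <- binned_regression(x, 2 * x + 1, bin_size = 1000)
  expect_equal(fit$n_bins, 2)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  # affine relation survives any bin size
  fit2 <- binned_regression(x, 2 * x + 1, bin_size = 100)
  expect_equal(fit2$slope, 2, tolerance = 1e-10)
  expect_error(binned_regression(x[1:150], x[1:150], bin_size = 100),
               "at least 200")
  # independent noise: no predictive power
  y <- rnorm(10000)
  x2 <- runif(10000)
  expect_lt(binned_regression(x2, y, bin_size = 100)$r_squared, 0.1)
  # methods behave like a model object
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-10)
  expect_equal(unname(predict(fit, newdata = 0.5)), 2, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("recovery R squared falls monotonically with added noise", {
  set.seed(23)
  n <- 4000
  sim <- runif(n, -0.2, 1)
  r2 <- vapply(c(0.05, 0.2, 0.8), function(s) {
    mean(vapply(1:5, function(k) {
      exp_v <- sim + rnorm(n, sd = s)
      binned_regression(sim, exp_v, bin_size = 100)$r_squared
    }, 0))
  }, 0)
  expect_true(all(diff(r2) < 0))
  expect_gt(r2[1], 0.95)
})
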