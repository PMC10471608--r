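test_that("z-scoring normalizes and is affine-invariant", {
  expect_equal(zscore(c(0, 2, 0, 2)), c(-1, 1, -1, 1))
  set.seed(1)
  x <- rnorm(500, 10, 3)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)  # population SD
  expect_equal(zscore(4 * x + 7), z, tolerance = 1e-12)
  expect_error(zscore(rep(3, 10)), "constant")
})

test_that("the 10-sample smoother has the documented impulse response", {
  x <- numeric(100); x[50] <- 1
  y <- moving_average(x, 10)
  expect_equal(sum(y > 0), 10)
  expect_equal(y[y > 0], rep(0.1, 10))
  expect_equal(moving_average(rep(2, 50), 10), rep(2, 50))
  expect_length(moving_average(rnorm(33), 10), 33)
  # white-noise variance reduced about span-fold in the interior
  set.seed(2)
  w <- rnorm(20000)
  sm <- moving_average(w, 10)[100:19900]
  expect_equal(var(sm) * 10, 1, tolerance = 0.1)
})

test_that("preprocessing smooths only fast acquisitions", {
  set.seed(3)
  F <- matrix(rnorm(600, 5, 2), 300, 2)
  slow <- preprocess_roi(roi_matrix(F, sampling_rate = 5))
  expect_equal(slow$Fz[, 1], zscore(F[, 1]), tolerance = 1e-12,
               ignore_attr = TRUE)
  fast <- preprocess_roi(roi_matrix(F, sampling_rate = 29.7))
  expect_equal(fast$Fz[, 1], moving_average(zscore(F[, 1]), 10),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("activity change reports the percent SD difference", {
  set.seed(4)
  x <- c(rnorm(500, sd = 2), rnorm(500, sd = 3))
  ac <- activity_change(x, 1, c(0, 500), c(500, 1000))
  expect_equal(ac$percent_diff,
               100 * (ac$sigma_drug - ac$sigma_baseline) /
                 ac$sigma_baseline)
  expect_equal(ac$percent_diff, 50, tolerance = 12)
  same <- activity_change(c(x[1:500], x[1:500]), 1, c(0, 500),
                          c(500, 1000))
  expect_equal(same$percent_diff, 0, tolerance = 1e-9)
  expect_error(activity_change(x, 1, c(0, 600), c(500, 1000)), "overlap")
  expect_error(activity_change(x, 1, c(0, 500), c(900, 2000)), "window")
})

test_that("drug-gain recordings show the planted activity increase", {
  meds <- sapply(1:4, function(s) {
    sim <- generate_roi_traces(25, 5, 1200, drug_onset = 600,
                               drug_gain = 2, seed = s)
    roi <- preprocess_roi(sim$roi)
    median(vapply(seq_len(25), function(j)
      activity_change(roi$Fz[, j], 5, c(0, 300),
                      c(600, 900))$percent_diff, 0))
  })
  ctrl <- sapply(1:4, function(s) {
    sim <- generate_roi_traces(25, 5, 1200, drug_onset = 600,
                               drug_gain = 1, seed = 50 + s)
    roi <- preprocess_roi(sim$roi)
    median(vapply(seq_len(25), function(j)
      activity_change(roi$Fz[, j], 5, c(0, 300),
                      c(600, 900))$percent_diff, 0))
  })
  expect_true(all(meds > 0))
  expect_gt(min(meds), max(ctrl))
})

test_that("autocorrelation CIs behave like the large-sample theory", {
  set.seed(5)
  ac <- autocorrelation_ci(rnorm(2000), max_lag = 400,
                           simultaneous = FALSE)
  expect_equal(ac$acf[1], 1)
  expect_equal(ac$lower[1], 1)
  # ~5% of white-noise lags fall outside the pointwise CI-of-zero band
  outside <- mean(abs(ac$acf[-1]) > (ac$upper - ac$acf)[-1])
  expect_lt(outside, 0.10)
  expect_gt(outside, 0.01)
  # the simultaneous band contains essentially all null lags
  acs <- autocorrelation_ci(rnorm(2000), max_lag = 400)
  expect_lt(mean(abs(acs$acf[-1]) > (acs$upper - acs$acf)[-1]), 0.005)

  # AR(1): acf(k) ~ phi^k
  phi <- 0.6
  x <- as.numeric(arima.sim(list(ar = phi), 4000))
  ar <- autocorrelation_ci(x, max_lag = 10)
  expect_equal(ar$acf[-1], phi^(1:10), tolerance = 0.12)

  expect_error(autocorrelation_ci(rep(1, 100), max_lag = 10), "constant")
  expect_error(autocorrelation_ci(rnorm(10), max_lag = 50), "shorter")
})

test_that("the CI-crossing rule detects planted rhythms and not drift", {
  # monotone-decaying acf whose upper CI never drops below zero
  ac <- data.frame(lag = 0:50, acf = 0.95^(0:50))
  ac$lower <- ac$acf - 0.05
  ac$upper <- ac$acf + 0.05
  r <- detect_rhythmic(ac)
  expect_false(r$is_rhythmic)

  # sinusoid + noise at SNR 2: rhythmic with the right lag
  hits <- 0; lag_ok <- 0
  for (s in 1:25) {
    set.seed(s)
    t <- seq(0, 300, by = 1)
    x <- sin(2 * pi * t / 10) + rnorm(length(t), sd = 1 / sqrt(2) / 2)
    r <- detect_rhythmic(autocorrelation_ci(x, max_lag = 100),
                         sampling_rate = 1)
    if (r$is_rhythmic) {
      hits <- hits + 1
      if (abs(r$lag_s - 10) <= 1) lag_ok <- lag_ok + 1
    }
  }
  expect_gte(hits, 23)
  expect_gte(lag_ok, 23)

  # white noise: conservative false-positive rate
  fp <- 0
  for (s in 1:200) {
    set.seed(1000 + s)
    r <- detect_rhythmic(autocorrelation_ci(rnorm(300), max_lag = 100))
    fp <- fp + r$is_rhythmic
  }
  expect_lte(fp / 200, 0.08 + 0.03)
})

test_that("per-slice rhythmic fractions aggregate correctly", {
  rf <- rhythmic_fraction(c(TRUE, TRUE, rep(FALSE, 18)), rep("s1", 20))
  expect_equal(rf$per_slice$percent_rhythmic, 10)
  rf2 <- rhythmic_fraction(rep(TRUE, 7), rep(c("a", "b"), c(3, 4)))
  expect_equal(rf2$mean, 100)
  expect_equal(rf2$sd, 0)
})

test_that("roi_rhythmicity recovers the planted rhythmic set", {
  sim <- generate_roi_traces(30, sampling_rate = 5, duration = 600,
                             frac_rhythmic = 0.5, rhythm_period = 10,
                             seed = 12)
  rr <- roi_rhythmicity(preprocess_roi(sim$roi))
  agree <- mean(rr$is_rhythmic == sim$truth$rhythmic)
  expect_gte(agree, 0.9)
  lags <- rr$lag_s[rr$is_rhythmic & sim$truth$rhythmic]
  expect_true(all(abs(lags - 10) <= 2))
})

test_that("sigh-triggered tests flag locked transients and not noise", {
  fs <- 5
  n <- 600 * fs
  sigh_times <- seq(50, 550, by = 25)
  # transients locked to sighs
  set.seed(13)
  x <- numeric(n)
  kern <- exp(-(0:(5 * fs)) / (2 * fs)) - exp(-(0:(5 * fs)) / (0.3 * fs))
  for (t0 in sigh_times) {
    i <- round(t0 * fs)
    x[i:(i + 5 * fs)] <- x[i:(i + 5 * fs)] + kern
  }
  x <- zscore(x + rnorm(n, sd = 0.3))
  res <- sigh_triggered_test(x, fs, sigh_times)
  expect_equal(nrow(res), 4)
  expect_true(any(res$p_corrected < 0.05))
  best <- res[res$window_s == 5, ]
  expect_gt(best$mean_post, best$mean_pre)

  # degenerate: identically zero trace
  res0 <- sigh_triggered_test(rep(0, n) + 0, fs, sigh_times)
  expect_true(all(res0$degenerate))
  expect_true(all(is.na(res0$p_raw)))

  expect_error(sigh_triggered_test(x, fs, c(10, 20)), "at least 3")

  # sighs at the trace edges are dropped with a warning
  expect_warning(
    sigh_triggered_test(x, fs, c(1, sigh_times), windows = 10),
    "dropped")
})

test_that("null sigh-triggered p-values are roughly uniform", {
  set.seed(14)
  fs <- 5
  sigh_times <- seq(50, 550, by = 25)
  p <- replicate(120, {
    x <- zscore(as.numeric(arima.sim(list(ar = 0.5), 600 * fs)))
    sigh_triggered_test(x, fs, sigh_times, windows = 2)$p_raw
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  # batch Bonferroni uses the full family size
  sim <- generate_roi_traces(5, 5, 600, seed = 15)
  roi <- preprocess_roi(sim$roi)
  bt <- sigh_triggered_batch(roi, sigh_times)
  expect_equal(nrow(bt), 5 * 4)
  expect_true(all(bt$p_corrected >= pmin(1, bt$p_raw * 20) - 1e-12,
                  na.rm = TRUE))
})

test_that("the calcium module is affine-invariant end to end", {
  sim <- generate_roi_traces(6, 5, 300, frac_rhythmic = 0.5, seed = 16)
  r1 <- roi_rhythmicity(preprocess_roi(sim$roi))
  F2 <- sim$roi$F * 3.2 + 11
  roi2 <- roi_matrix(F2, 5, sim$roi$roi_ids)
  r2 <- roi_rhythmicity(preprocess_roi(roi2))
  expect_equal(r2$is_rhythmic, r1$is_rhythmic)
  expect_equal(r2$strength, r1$strength, tolerance = 1e-9)
})
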