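test_that("geometric features are exact on analytic bursts", {
  fs <- 1000
  # symmetric triangle, height 2, base 1 s
  tri <- c(seq(0, 2, length.out = fs / 2), seq(2, 0, length.out = fs / 2))
  tr <- sigh_trace(c(numeric(fs), tri, numeric(fs)), fs)
  b <- data.frame(onset_s = 1, peak_s = 1 + 0.5, amplitude = 2,
                  height = 2, prominence = 2, rise_s = 0.5, baseline = 0,
                  onset_clamped = FALSE, artifact = FALSE)
  f <- compute_features(tr, b, onset_frac = 0)
  expect_equal(f$fwhm_s, 0.5, tolerance = 2 / fs)
  expect_equal(f$auc, 1.0, tolerance = 0.01)

  # rectangle height h width w: fwhm = w, auc = h*w
  h <- 3; wsec <- 0.4
  rect <- c(numeric(fs), rep(h, wsec * fs), numeric(fs))
  tr2 <- sigh_trace(rect, fs)
  b2 <- data.frame(onset_s = 1, peak_s = 1 + wsec / 2, amplitude = h,
                   height = h, prominence = h, rise_s = wsec / 2,
                   baseline = 0, onset_clamped = FALSE, artifact = FALSE)
  f2 <- compute_features(tr2, b2)
  expect_equal(f2$fwhm_s, wsec, tolerance = 3 / fs)
  expect_equal(f2$auc, h * wsec, tolerance = h * 3 / fs)
})

test_that("last burst has missing (not zero) interval features", {
  sim <- pop_sim()
  b <- compute_features(sim$trace, detect_bursts(sim$trace))
  n <- nrow(b)
  expect_true(is.na(b$post_burst_interval_s[n]))
  expect_true(is.na(b$inter_event_interval_s[n]))
  expect_true(all(!is.na(b$post_burst_interval_s[-n])))
})

test_that("sighs exceed eupnea in every characterization metric", {
  sim <- generate_population_trace(synth_params(duration = 1200, seed = 13))
  b <- compute_features(sim$trace, detect_bursts(sim$trace))
  m <- match_events(b$peak_s, sim$labels$peak_time, tol = 0.3)
  kind <- sim$labels$kind[m$pairs[, 2]]
  bb <- b[m$pairs[, 1], ]
  med <- function(col, k) median(bb[[col]][kind == k], na.rm = TRUE)
  for (col in c("feat_amplitude", "duration_s", "post_burst_interval_s",
                "inter_event_interval_s")) {
    expect_gt(med(col, "sigh"), med(col, "eupnea"))
  }
})

test_that("features scale linearly in amplitude or not at all", {
  sim <- pop_sim()
  b0 <- compute_features(sim$trace, detect_bursts(sim$trace))
  tr2 <- sigh_trace(sim$trace$samples * 2.5, sim$trace$sampling_rate)
  b1 <- compute_features(tr2, detect_bursts(tr2))
  expect_equal(nrow(b1), nrow(b0))
  expect_equal(b1$feat_amplitude, 2.5 * b0$feat_amplitude,
               tolerance = 1e-6)
  expect_equal(b1$auc, 2.5 * b0$auc, tolerance = 1e-6)
  expect_equal(b1$duration_s, b0$duration_s, tolerance = 1e-6)
  expect_equal(b1$fwhm_s, b0$fwhm_s, tolerance = 1e-6)
})

test_that("shape rule separates single and double-peaked bursts", {
  t <- seq(0, 1.5, by = 0.01)
  mono <- exp(-t / 0.4) - exp(-t / 0.1)
  expect_equal(classify_shape(mono, smooth = 0), "monophasic")

  # two peaks with a deep trough
  bi <- pmax(dnorm(t, 0.3, 0.08), 2 * dnorm(t, 0.9, 0.12) / dnorm(0, 0, 0.12) * dnorm(0, 0, 0.08))
  bi <- dnorm(t, 0.3, 0.08) / dnorm(0, 0, 0.08) + 2.5 * dnorm(t, 0.9, 0.1) / dnorm(0, 0, 0.1)
  expect_equal(classify_shape(bi, smooth = 0), "biphasic")

  # 5% dip between two peaks: below the 20% trough requirement
  shallow <- c(seq(0, 1, length.out = 50), seq(1, 0.95, length.out = 10),
               seq(0.95, 1.02, length.out = 10),
               seq(1.02, 0, length.out = 60))
  expect_equal(classify_shape(shallow, smooth = 0), "monophasic")

  # scale invariance
  expect_equal(classify_shape(bi * 17, smooth = 0), "biphasic")
  expect_equal(classify_shape(shallow * 17, smooth = 0), "monophasic")
})

test_that("generator-built biphasic sighs satisfy the shape rule", {
  p <- synth_params(duration = 1200, noise_sd = 0, seed = 21)
  sim <- generate_population_trace(p)
  b <- detect_bursts(sim$trace, peak_refine = 0)
  shp <- burst_shapes(sim$trace, b)
  m <- match_events(b$peak_s, sim$labels$peak_time, tol = 0.3)
  lab <- sim$labels[m$pairs[, 2], ]
  sel <- which(lab$kind == "sigh")
  expect_gt(length(sel), 3)
  for (i in sel) {
    di <- m$pairs[i, 1]
    expect_equal(classify_shape(shp[di, ], smooth = 0,
                                baseline = b$baseline[di]),
                 lab$shape_class[i])
  }
})

test_that("noisy shape recovery stays accurate across seeds", {
  ok <- 0; n <- 0
  for (s in 1:4) {
    sim <- generate_population_trace(synth_params(duration = 1200,
                                                  seed = s))
    b <- detect_bursts(sim$trace)
    shp <- burst_shapes(sim$trace, b)
    m <- match_events(b$peak_s, sim$labels$peak_time, tol = 0.3)
    lab <- sim$labels[m$pairs[, 2], ]
    sel <- which(lab$kind == "sigh")
    for (i in sel) {
      di <- m$pairs[i, 1]
      pred <- classify_shape(shp[di, ], baseline = b$baseline[di])
      n <- n + 1
      ok <- ok + (pred == lab$shape_class[i])
    }
  }
  expect_gte(ok / n, 0.8)
})

test_that("epoch summaries count and normalize correctly", {
  bursts <- data.frame(
    onset_s = c(seq(10, 2390, by = 40), seq(2410, 4790, by = 20)),
    label = "eupnea", feat_amplitude = 1, duration_s = 0.5)
  # plant sighs: 10 in epoch A (40 min), 10 in epoch B (40 min)
  sighs <- data.frame(onset_s = c(seq(100, 2300, length.out = 10),
                                  seq(2500, 4700, length.out = 10)),
                      label = "sigh", feat_amplitude = 2.5,
                      duration_s = 1)
  all <- rbind(bursts, sighs)
  ep <- data.frame(name = c("A", "B"), start_s = c(0, 2400),
                   end_s = c(2400, 4800))
  s <- summarize_epochs(all, ep, window = 1200)
  expect_equal(s$n_sigh, c(10, 10))
  expect_equal(s$sigh_per_window, c(5, 5))  # 10 per 40 min = 5 per 20
  expect_equal(s$eupnea_per_window[2], 2 * s$eupnea_per_window[1],
               tolerance = 0.02)
  expect_equal(s$sigh_eupnea_amp_ratio, c(2.5, 2.5))

  empty <- summarize_epochs(all[0, ], ep)
  expect_equal(empty$n_sigh, c(0, 0))
  expect_true(all(is.na(empty$mean_amp_eupnea)))

  over <- data.frame(name = c("A", "B"), start_s = c(0, 1000),
                     end_s = c(2400, 3000))
  expect_error(summarize_epochs(all, over), "overlap")
})

test_that("doubled sigh rate in one epoch is recovered in the summary", {
  sim1 <- generate_population_trace(
    synth_params(duration = 2400, sigh_interval_mean = 120, seed = 31))
  sim2 <- generate_population_trace(
    synth_params(duration = 2400, sigh_interval_mean = 60, seed = 32))
  lab2 <- sim2$labels
  lab2$time <- lab2$time + 2400
  lab <- rbind(sim1$labels, lab2)
  tab <- data.frame(onset_s = lab$time, label = ifelse(lab$kind == "sigh",
                                                       "sigh", "eupnea"),
                    feat_amplitude = lab$amplitude, duration_s = 0.7)
  ep <- data.frame(name = c("base", "fast"), start_s = c(0, 2400),
                   end_s = c(2400, 4800))
  s <- summarize_epochs(tab, ep)
  ratio <- s$sigh_per_window[2] / s$sigh_per_window[1]
  # Poisson counts around 20 and 40: ratio within wide stochastic bounds
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})
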