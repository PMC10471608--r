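test_that("robust covariance reduces to the classical estimate at h = n", {
  set.seed(1)
  X <- matrix(rnorm(80), 40, 2)
  rc <- robust_covariance(X, support_fraction = 1)
  expect_equal(rc$location, colMeans(X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rc$scatter, cov(X), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rc$consistency, 1)
})

test_that("robust covariance matches exhaustive search on small data", {
  for (s in 1:20) {
    set.seed(s)
    X <- rbind(matrix(rnorm(16), 8, 2),
               matrix(rnorm(4, mean = 6), 2, 2))
    h <- 8
    rc <- robust_covariance(X, support_fraction = h / nrow(X),
                            n_restarts = 200, seed = s)
    expect_equal(sort(rc$support), brute_mcd(X, h))
  }
})

test_that("robust location resists planted outliers", {
  good <- 0
  for (s in 1:30) {
    set.seed(s)
    X <- rbind(matrix(rnorm(400), 200, 2),
               matrix(rnorm(100, mean = 10), 50, 2))
    rc <- robust_covariance(X, support_fraction = 0.75,
                            n_restarts = 100, seed = s)
    if (sqrt(sum(rc$location^2)) < 0.2 &&
        sqrt(sum(colMeans(X)^2)) > 1)
      good <- good + 1
  }
  expect_gte(good, 28)
})

test_that("robust covariance agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(4)
  X <- rbind(matrix(rnorm(300), 150, 2),
             matrix(rnorm(60, mean = 8), 30, 2))
  rc <- robust_covariance(X, support_fraction = 0.75, n_restarts = 200,
                          seed = 1)
  mm <- MASS::cov.rob(X, method = "mcd",
                      quantile.used = ceiling(0.75 * nrow(X)))
  expect_lt(sqrt(sum((rc$location - mm$center)^2)), 0.3)
})

test_that("robust covariance input validation", {
  expect_error(robust_covariance(matrix(1:4, 2, 2)), "more observations")
  expect_error(robust_covariance(matrix(rnorm(40), 20, 2),
                                 support_fraction = 0.3),
               "support_fraction")
})

test_that("Mahalanobis distance has its closed form", {
  pr <- structure(list(kind = "features", pca_basis = NULL,
                       mean_shape = NULL, robust_location = c(0, 0),
                       robust_scatter = diag(c(2, 0.5))),
                  class = "sigh_prior")
  expect_equal(prior_distance(pr, c(0, 0)), 0)
  expect_equal(prior_distance(pr, c(1, 1)), sqrt(2.5), tolerance = 1e-12)
  pr$robust_scatter <- diag(2)
  expect_equal(prior_distance(pr, c(1, 0)), 1, tolerance = 1e-12)
  expect_error(prior_distance(pr, c(NA, 1)), "non-finite")
})

test_that("the distance threshold follows median + 4 IQR (type 7)", {
  expect_equal(distance_threshold(c(1, 2, 3, 4, 100)), 11)
  expect_equal(distance_threshold(rep(2.5, 20)), 2.5)
})

test_that("PCA truncation keeps the smallest basis reaching 95%", {
  set.seed(2)
  template <- sin(seq(0, pi, length.out = 60))
  shapes <- t(replicate(40, template * rnorm(1, 1, 0.3))) +
    matrix(rnorm(2400, sd = 1e-4), 40)
  pr <- fit_shape_prior(shapes, n_restarts = 50, seed = 1)
  expect_equal(pr$n_components, 1)

  # planted spectrum 80/15/5 in 3 orthogonal directions -> 2 components
  n <- 300
  basis <- qr.Q(qr(matrix(rnorm(9), 3)))
  scores <- cbind(rnorm(n, sd = sqrt(80)), rnorm(n, sd = sqrt(15)),
                  rnorm(n, sd = sqrt(5)))
  X <- scores %*% t(basis)
  # empirical variances wobble; use a generous runway
  pr3 <- fit_shape_prior(X, n_restarts = 50, seed = 1)
  expect_equal(pr3$n_components, 2)

  expect_error(fit_shape_prior(shapes[1:5, ]), "at least 10")
})

test_that("classify_evoked applies the dual gate and amplitude veto", {
  set.seed(3)
  n <- 80
  shapes <- t(replicate(n, sin(seq(0, pi, length.out = 50)) *
                          rnorm(1, 1, 0.1))) +
    matrix(rnorm(n * 50, sd = 0.02), n)
  feats <- cbind(rnorm(n, 1, 0.1), rnorm(n, 0.4, 0.05),
                 rnorm(n, 3, 0.4))
  sp <- fit_shape_prior(shapes, n_restarts = 100, seed = 1)
  fp <- fit_feature_prior(feats, n_restarts = 100, seed = 2)

  # a burst equal to the mean spontaneous shape/features -> eupnea
  res <- classify_evoked(sp, fp, feats[, 1],
                         matrix(colMeans(shapes), 1),
                         matrix(colMeans(feats), 1))
  expect_equal(res$label, "eupnea")
  expect_lt(res$d_shape, sp$d_thresh)

  # pass both outlier gates but with median amplitude -> eupnea
  big_shape <- matrix(colMeans(shapes) * 5 + 1, 1)
  odd_feat <- matrix(c(median(feats[, 1]), 5, 30), 1)
  res2 <- classify_evoked(sp, fp, feats[, 1], big_shape, odd_feat)
  expect_true(res2$shape_outlier && res2$feature_outlier)
  expect_false(res2$amp_pass)
  expect_equal(res2$label, "eupnea")

  # all three satisfied -> sigh attempt
  strong_feat <- matrix(c(3, 5, 30), 1)
  res3 <- classify_evoked(sp, fp, feats[, 1], big_shape, strong_feat)
  expect_equal(res3$label, "sigh_attempt")

  # missing post-burst interval disqualifies, never imputes
  na_feat <- matrix(c(3, 5, NA), 1)
  res4 <- classify_evoked(sp, fp, feats[, 1], big_shape, na_feat)
  expect_false(res4$classifiable)
  expect_equal(res4$label, "eupnea")
})

test_that("priors round-trip through their JSON audit form", {
  set.seed(5)
  shapes <- t(replicate(30, sin(seq(0, pi, length.out = 40)) *
                          rnorm(1, 1, 0.2))) +
    matrix(rnorm(1200, sd = 0.05), 30)
  pr <- fit_shape_prior(shapes, n_restarts = 50, seed = 1)
  f <- tempfile(fileext = ".json")
  write_prior(pr, f)
  back <- read_prior(f)
  expect_equal(back$d_thresh, pr$d_thresh, tolerance = 1e-12)
  expect_equal(back$robust_location, pr$robust_location,
               tolerance = 1e-12, ignore_attr = TRUE)
  x <- shapes[3, ]
  expect_equal(prior_distance(back, x), prior_distance(pr, x),
               tolerance = 1e-9)
})

test_that("evoked classification recovers planted sigh attempts", {
  tp <- 0; fn <- 0; fp <- 0; tn <- 0
  for (s in 1:3) {
    p <- synth_params(duration = 20, sigh_amp_factor = 2.5,
                      sigh_duration_factor = 1.5,
                      post_sigh_apnea_factor = 2, seed = s)
    sw <- generate_evoked_sweeps(p, n_sweeps = 30, stim_time = 10,
                                 p_eupnea = 0.5, p_sigh = 0.3)
    cl <- classify_evoked_sweeps(sw$sweeps, stim_time = 10,
                                 n_restarts = 150, seed = s)
    truth <- sw$outcomes$outcome
    lab <- cl$evoked$label
    tp <- tp + sum(lab == "sigh_attempt" & truth == "sigh")
    fn <- fn + sum(lab != "sigh_attempt" & truth == "sigh")
    fp <- fp + sum(lab == "sigh_attempt" & truth == "eupnea")
    tn <- tn + sum(lab != "sigh_attempt" & truth == "eupnea")
    # failures stay failures
    expect_true(all(lab[truth == "failure"] == "failure"))
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_lte(fp / (fp + tn), 0.1)
})

test_that("the pipeline is invariant to uniform amplitude rescaling", {
  p <- synth_params(duration = 20, seed = 9)
  sw <- generate_evoked_sweeps(p, n_sweeps = 20, stim_time = 10,
                               p_eupnea = 0.5, p_sigh = 0.3)
  cl1 <- classify_evoked_sweeps(sw$sweeps, stim_time = 10,
                                n_restarts = 100, seed = 1)
  scaled <- lapply(sw$sweeps, function(tr)
    sigh_trace(tr$samples * 12.5, tr$sampling_rate, tr$t0, tr$channel))
  cl2 <- classify_evoked_sweeps(scaled, stim_time = 10,
                                n_restarts = 100, seed = 1)
  expect_equal(cl2$evoked$label, cl1$evoked$label)
  expect_equal(cl2$evoked$d_shape, cl1$evoked$d_shape, tolerance = 1e-6)
})

test_that("spontaneous-like evoked bursts are rarely called sighs", {
  # evoked eupnea drawn from the same distribution as spontaneous:
  # the attempt rate is bounded by the amplitude criterion alone
  n_att <- 0; n_ev <- 0
  for (s in 1:3) {
    p <- synth_params(duration = 20, seed = 100 + s)
    sw <- generate_evoked_sweeps(p, n_sweeps = 30, stim_time = 10,
                                 p_eupnea = 1, p_sigh = 0)
    cl <- classify_evoked_sweeps(sw$sweeps, stim_time = 10,
                                 n_restarts = 100, seed = s)
    n_att <- n_att + sum(cl$evoked$label == "sigh_attempt")
    n_ev <- n_ev + sum(cl$evoked$evoked)
  }
  expect_lte(n_att / n_ev, 0.1)
})
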