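#' Robust location and scatter by minimum covariance determinant
#'
#' FastMCD-style estimate: seeded random (d+1)-point starts are refined
#' by concentration steps (keep the h points with smallest Mahalanobis
#' distance, re-estimate, repeat to convergence); the subset whose
#' classical covariance has the smallest determinant wins. The returned
#' scatter is the winning subset's covariance times the usual
#' chi-squared consistency factor, so it is unbiased under normality.
#' With `support_fraction = 1` the classical mean and covariance are
#' returned exactly.
#'
#' @param points numeric matrix, n rows (observations) x d columns.
#' @param support_fraction fraction h/n of points assumed clean, in
#'   `[0.5, 1]`.
#' @param n_restarts number of random starts.
#' @param seed integer seed for the restarts.
#' @param max_csteps concentration-step cap per start.
#' @return A list: `location` (length-d vector), `scatter` (d x d
#'   matrix), `support` (indices of the h-subset), `det` (the raw
#'   subset covariance determinant), `consistency` (the correction
#'   factor applied).
#' @examples
#' x <- matrix(rnorm(60), 30, 2)
#' robust_covariance(x, support_fraction = 1)$location  # = colMeans(x)
#' @export
robust_covariance <- function(points, support_fraction = 0.75,
                              n_restarts = 500, seed = 1L,
                              max_csteps = 30) {
  X <- as.matrix(points)
  n <- nrow(X); d <- ncol(X)
  if (n <= d) stop("need more observations than dimensions")
  if (support_fraction < 0.5 || support_fraction > 1)
    stop("support_fraction must be in [0.5, 1]")
  h <- ceiling(support_fraction * n)
  if (h >= n) {
    mu <- colMeans(X)
    S <- stats::cov(X)
    return(list(location = mu, scatter = S, support = seq_len(n),
                det = det(S), consistency = 1))
  }
  if (h <= d) stop("support subset too small for the dimension")

  cstep <- function(subset) {
    repeat_count <- 0L
    repeat {
      mu <- colMeans(X[subset, , drop = FALSE])
      S <- stats::cov(X[subset, , drop = FALSE])
      S_use <- regularize_spd(S)
      dist2 <- stats::mahalanobis(X, mu, S_use)
      new_subset <- order(dist2)[seq_len(h)]
      repeat_count <- repeat_count + 1L
      if (identical(sort(new_subset), sort(subset)) ||
          repeat_count >= max_csteps)
        return(sort(new_subset))
      subset <- new_subset
    }
  }

  with_seed(seed, {
    best <- NULL; best_det <- Inf
    for (r in seq_len(n_restarts)) {
      start <- sample.int(n, min(n, d + 1L))
      # grow a degenerate start until its covariance has full rank
      while (length(start) < n) {
        S0 <- stats::cov(X[start, , drop = FALSE])
        if (is.finite(det(S0)) && det(S0) > 1e-300) break
        start <- c(start, sample(setdiff(seq_len(n), start), 1L))
      }
      mu0 <- colMeans(X[start, , drop = FALSE])
      S0 <- regularize_spd(stats::cov(X[start, , drop = FALSE]))
      sub0 <- order(stats::mahalanobis(X, mu0, S0))[seq_len(h)]
      sub <- cstep(sub0)
      S_sub <- stats::cov(X[sub, , drop = FALSE])
      dt <- det(S_sub)
      if (dt < best_det) { best_det <- dt; best <- sub }
    }
    mu <- colMeans(X[best, , drop = FALSE])
    S <- stats::cov(X[best, , drop = FALSE])
    # consistency correction for truncation to the h/n quantile
    alpha <- h / n
    cf <- alpha / stats::pchisq(stats::qchisq(alpha, df = d), df = d + 2)
    list(location = mu, scatter = S * cf, support = best, det = best_det,
         consistency = cf)
  })
}

# add a small ridge when a covariance estimate is singular
regularize_spd <- function(S, warn = FALSE) {
  d <- ncol(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-10 * max(abs(ev), 1e-300)) return(S)
  ridge <- max(abs(ev), 1e-12) * 1e-6 + 1e-12
  if (warn) warning(sprintf("singular scatter regularized (ridge %.3g)",
                            ridge))
  S + diag(ridge, d)
}

#' Mahalanobis distance to a fitted eupnea prior
#'
#' `D = sqrt((x - mu)' Sigma^-1 (x - mu))` using the prior's robust
#' location and scatter. For a shape prior, `x` may be a raw shape
#' vector (projected onto the stored PCA basis first) or an
#' already-projected score vector of the prior's dimension.
#'
#' @param prior a `sigh_prior` from [fit_shape_prior()] or
#'   [fit_feature_prior()].
#' @param x numeric vector or matrix (rows = observations).
#' @return Numeric vector of distances `D`.
#' @export
prior_distance <- function(prior, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (any(!is.finite(X))) stop("non-finite values in x")
  if (!is.null(prior$pca_basis) && ncol(X) == length(prior$mean_shape))
    X <- project_shapes(prior, X)
  if (ncol(X) != length(prior$robust_location))
    stop("dimension of x does not match the prior")
  sqrt(stats::mahalanobis(X, prior$robust_location, prior$robust_scatter))
}

# project raw shapes onto the prior's PCA basis
project_shapes <- function(prior, shapes) {
  sweep(as.matrix(shapes), 2, prior$mean_shape) %*% t(prior$pca_basis)
}

#' Outlier threshold over spontaneous distances
#'
#' `D_thresh = median(D) + 4 * IQR(D)`, with quartiles by linear
#' interpolation of order statistics (R's default quantile type 7).
#'
#' @param d_spontaneous distances of the spontaneous bursts to their own
#'   prior.
#' @param iqr_factor multiplier on the IQR.
#' @return The threshold.
#' @examples
#' distance_threshold(c(1, 2, 3, 4, 100))  # 3 + 4 * 2 = 11
#' @export
distance_threshold <- function(d_spontaneous, iqr_factor = 4) {
  stats::median(d_spontaneous) +
    iqr_factor * stats::IQR(d_spontaneous, type = 7)
}

new_sigh_prior <- function(kind, mean_shape, pca_basis, n_components,
                           rc, d_spont, iqr_factor) {
  structure(list(
    kind = kind, mean_shape = mean_shape, pca_basis = pca_basis,
    n_components = n_components, robust_location = rc$location,
    robust_scatter = regularize_spd(rc$scatter, warn = TRUE),
    support = rc$support, d_spontaneous = d_spont,
    d_thresh = distance_threshold(d_spont, iqr_factor)),
    class = "sigh_prior")
}

#' @export
print.sigh_prior <- function(x, ...) {
  cat(sprintf("<sigh_prior:%s> %s%d-dim, D_thresh = %.3f (n_spont = %d)\n",
              x$kind,
              if (!is.null(x$pca_basis)) sprintf("PCA %d comp, ",
                                                 x$n_components) else "",
              length(x$robust_location), x$d_thresh,
              length(x$d_spontaneous)))
  invisible(x)
}

#' Fit the eupneic shape prior from spontaneous bursts
#'
#' Burst shapes are mean-centered and decomposed into principal
#' components; the smallest number of components whose cumulative
#' explained variance reaches `var_explained` (default 95%) is kept.
#' A minimum-covariance-determinant robust location/scatter is fitted
#' on those scores — since spontaneous bursts are never putative sighs,
#' this is the prior distribution of the expected eupneic shape. The
#' Mahalanobis distance of each spontaneous burst to that prior gives
#' `d_spontaneous` and the outlier threshold
#' `d_thresh = median + 4 * IQR`.
#'
#' @param spontaneous_shapes matrix of spontaneous burst shapes (rows =
#'   bursts), e.g. from [burst_shapes()]; must exclude optogenetically
#'   evoked bursts.
#' @param var_explained cumulative explained-variance target for the
#'   PCA truncation.
#' @param support_fraction,n_restarts,seed passed to
#'   [robust_covariance()].
#' @param iqr_factor multiplier in the threshold rule.
#' @return A `sigh_prior` object (kind `"shape"`).
#' @export
fit_shape_prior <- function(spontaneous_shapes, var_explained = 0.95,
                            support_fraction = 0.75, n_restarts = 500,
                            seed = 1L, iqr_factor = 4) {
  X <- as.matrix(spontaneous_shapes)
  if (nrow(X) < 10)
    stop("need at least 10 spontaneous bursts to fit a shape prior")
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- which(cum >= var_explained)[1]
  if (is.na(k)) k <- length(cum)
  if (nrow(X) <= k)
    stop("fewer spontaneous bursts than retained components; ",
         "record more spontaneous bursts")
  scores <- pca$x[, seq_len(k), drop = FALSE]
  rc <- robust_covariance(scores, support_fraction = support_fraction,
                          n_restarts = n_restarts, seed = seed)
  prior <- new_sigh_prior("shape", mean_shape = pca$center,
                          pca_basis = t(pca$rotation[, seq_len(k),
                                                     drop = FALSE]),
                          n_components = k, rc = rc, d_spont = NULL,
                          iqr_factor = iqr_factor)
  # distances of the spontaneous set to its own prior, then Eq-style
  # threshold
  d_spont <- prior_distance(prior, scores)
  prior$d_spontaneous <- d_spont
  prior$d_thresh <- distance_threshold(d_spont, iqr_factor)
  prior
}

#' Fit the intuitive-feature prior from spontaneous bursts
#'
#' Identical construction to [fit_shape_prior()] but on the 3-vector of
#' intuitive features — burst amplitude, FWHM, and time to next burst
#' (post-burst apnea) — with no PCA step.
#'
#' @param spontaneous_features matrix or data frame with columns
#'   amplitude, fwhm, post-burst interval (in that order), spontaneous
#'   bursts only; rows with missing values are dropped.
#' @inheritParams fit_shape_prior
#' @return A `sigh_prior` object (kind `"features"`).
#' @export
fit_feature_prior <- function(spontaneous_features,
                              support_fraction = 0.75, n_restarts = 500,
                              seed = 1L, iqr_factor = 4) {
  X <- as.matrix(spontaneous_features)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 10)
    stop("need at least 10 spontaneous bursts to fit a feature prior")
  rc <- robust_covariance(X, support_fraction = support_fraction,
                          n_restarts = n_restarts, seed = seed)
  prior <- new_sigh_prior("features", mean_shape = NULL, pca_basis = NULL,
                          n_components = ncol(X), rc = rc, d_spont = NULL,
                          iqr_factor = iqr_factor)
  d_spont <- prior_distance(prior, X)
  prior$d_spontaneous <- d_spont
  prior$d_thresh <- distance_threshold(d_spont, iqr_factor)
  prior
}

#' Classify evoked bursts as eupnea or sigh attempts
#'
#' The dual-gate unsupervised rule: an evoked burst is a sigh attempt
#' iff it is a Mahalanobis outlier (`D > d_thresh`) in BOTH the shape
#' prior and the intuitive-feature prior, AND its amplitude exceeds the
#' 90th percentile of the spontaneous burst amplitudes. Bursts with a
#' missing post-burst interval (the last burst of a sweep with nothing
#' after it) cannot be assessed by the feature gate and are labeled
#' eupnea with a flag, rather than imputed.
#'
#' @param shape_prior `sigh_prior` from [fit_shape_prior()].
#' @param feature_prior `sigh_prior` from [fit_feature_prior()].
#' @param spontaneous_amplitudes amplitudes of the spontaneous bursts.
#' @param evoked_shapes matrix of evoked burst shapes (rows = bursts).
#' @param evoked_features matrix/data frame of the 3 intuitive features
#'   for the same bursts (amplitude, fwhm, post-burst interval).
#' @param amp_quantile spontaneous-amplitude percentile an attempt must
#'   exceed (default 0.9).
#' @return Data frame: `d_shape`, `d_features`, `shape_outlier`,
#'   `feature_outlier`, `amp_pass`, `classifiable`, and `label`
#'   (`"eupnea"` / `"sigh_attempt"`).
#' @export
classify_evoked <- function(shape_prior, feature_prior,
                            spontaneous_amplitudes, evoked_shapes,
                            evoked_features, amp_quantile = 0.9) {
  S <- as.matrix(evoked_shapes)
  F <- as.matrix(evoked_features)
  stopifnot(nrow(S) == nrow(F))
  n <- nrow(S)
  d_shape <- prior_distance(shape_prior, S)
  ok <- stats::complete.cases(F)
  d_feat <- rep(NA_real_, n)
  if (any(ok))
    d_feat[ok] <- prior_distance(feature_prior, F[ok, , drop = FALSE])
  amp_thr <- stats::quantile(spontaneous_amplitudes, amp_quantile,
                             names = FALSE, type = 7)
  amp_pass <- F[, 1] > amp_thr
  shape_out <- d_shape > shape_prior$d_thresh
  feat_out <- !is.na(d_feat) & d_feat > feature_prior$d_thresh
  label <- ifelse(ok & shape_out & feat_out & amp_pass,
                  "sigh_attempt", "eupnea")
  data.frame(d_shape = d_shape, d_features = d_feat,
             shape_outlier = shape_out, feature_outlier = feat_out,
             amp_pass = amp_pass, classifiable = ok, label = label,
             stringsAsFactors = FALSE)
}

#' Persist a fitted prior for audit
#'
#' Serializes the PCA basis, robust location/scatter, spontaneous
#' distances and threshold to JSON so a classification run can be
#' audited or reapplied.
#'
#' @param prior a `sigh_prior`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_prior <- function(prior, path) {
  obj <- list(kind = prior$kind, mean_shape = prior$mean_shape,
              pca_basis = prior$pca_basis,
              n_components = prior$n_components,
              robust_location = prior$robust_location,
              robust_scatter = prior$robust_scatter,
              d_spontaneous = prior$d_spontaneous,
              d_thresh = prior$d_thresh)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    kind = obj$kind,
    mean_shape = if (length(obj$mean_shape)) as.numeric(obj$mean_shape),
    pca_basis = if (length(obj$pca_basis)) as.matrix(obj$pca_basis),
    n_components = obj$n_components,
    robust_location = as.numeric(obj$robust_location),
    robust_scatter = as.matrix(obj$robust_scatter),
    d_spontaneous = as.numeric(obj$d_spontaneous),
    d_thresh = obj$d_thresh), class = "sigh_prior")
}
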