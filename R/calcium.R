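#' z-score a fluorescence trace
#'
#' `Fz = (F - mean(F)) / sd(F)` with the population SD; output has mean
#' 0 and (population) SD 1 and is invariant to any positive affine
#' transform of the input.
#'
#' @param x numeric vector of raw (neuropil-corrected) fluorescence.
#' @return z-scored vector.
#' @examples
#' zscore(c(0, 2, 0, 2))
#' @export
zscore <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))  # population SD, as in the z-score formula
  if (!is.finite(s) || s == 0) stop("constant ROI")
  (x - mu) / s
}

#' Centered moving average
#'
#' Moving average over `span` samples with truncated windows at the
#' edges, so length is preserved and a constant input is unchanged. For
#' even spans the window covers `span/2` samples back and
#' `span/2 - 1` forward of each sample's predecessor, i.e. the
#' conventional centered alignment.
#'
#' @param x numeric vector.
#' @param span window length in samples (>= 1).
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, span = 10) {
  span <- as.integer(span)
  if (span <= 1L) return(x)
  n <- length(x)
  back <- span %/% 2L
  fwd <- span - 1L - back
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - back, 1L)
  hi <- pmin(seq_len(n) + fwd, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Preprocess an ROI matrix for analysis
#'
#' z-scores every ROI column; recordings acquired faster than
#' `smooth_above` Hz additionally get a `span`-sample centered moving
#' average (the resonance-galvanometer convention).
#'
#' @param roi an [roi_matrix()].
#' @param span smoothing span, samples.
#' @param smooth_above sampling-rate threshold (Hz) above which
#'   smoothing is applied.
#' @return The [roi_matrix()] with an `Fz` element added.
#' @export
preprocess_roi <- function(roi, span = 10, smooth_above = 20) {
  Fz <- apply(roi$F, 2, zscore)
  if (roi$sampling_rate > smooth_above)
    Fz <- apply(Fz, 2, moving_average, span = span)
  roi$Fz <- Fz
  roi
}

#' Drug-epoch activity change of one ROI
#'
#' Standard deviation of the preprocessed signal in a baseline window
#' and in a drug window (conventionally 5 min each), reported as the
#' percent difference `100 * (sd_drug - sd_baseline) / sd_baseline`.
#'
#' @param x preprocessed (z-scored) ROI trace.
#' @param sampling_rate Hz.
#' @param baseline_window,drug_window two-element numeric `(start, end)`
#'   times in s; must lie within the trace and not overlap.
#' @return A list: `sigma_baseline`, `sigma_drug`, `percent_diff`.
#' @export
activity_change <- function(x, sampling_rate, baseline_window,
                            drug_window) {
  n <- length(x)
  win_idx <- function(w) {
    i0 <- floor(w[1] * sampling_rate) + 1L
    i1 <- min(n, ceiling(w[2] * sampling_rate))
    if (i0 < 1L || i0 >= i1 || w[2] > n / sampling_rate + 1e-9)
      stop("window outside the trace")
    i0:i1
  }
  if (max(baseline_window[1], drug_window[1]) <
      min(baseline_window[2], drug_window[2]))
    stop("baseline and drug windows overlap")
  sb <- stats::sd(x[win_idx(baseline_window)])
  sd_ <- stats::sd(x[win_idx(drug_window)])
  if (sb == 0) stop("baseline window has zero variance")
  list(sigma_baseline = sb, sigma_drug = sd_,
       percent_diff = 100 * (sd_ - sb) / sb)
}

#' Sample autocorrelation with large-sample confidence bands
#'
#' Autocorrelation at lags `0..max_lag` with a Bartlett large-lag
#' standard error per lag, `se_k = sqrt((1 + 2 * sum_{j<k} r_j^2)/n)`,
#' and a `1 - alpha` confidence band centered on each estimate. By
#' default the band is simultaneous over all lags (Bonferroni-corrected
#' critical value), so that downstream zero-crossing rules keep a
#' controlled family-wise error no matter how many lags are scanned; a
#' pointwise per-lag interval is available with
#' `simultaneous = FALSE`.
#'
#' @param x numeric vector (a z-scored ROI trace).
#' @param max_lag maximum lag in samples (default one third of the
#'   trace length).
#' @param alpha band miscoverage (default 0.05 for a 95% band).
#' @param simultaneous if `TRUE` (default), the critical value is
#'   corrected for the number of lags scanned.
#' @return Data frame: `lag` (samples), `acf`, `lower`, `upper`.
#' @export
autocorrelation_ci <- function(x, max_lag = floor(length(x) / 3),
                               alpha = 0.05, simultaneous = TRUE) {
  n <- length(x)
  if (n <= max_lag) stop("trace shorter than max_lag")
  if (stats::sd(x) == 0) stop("constant input")
  r <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  z <- if (simultaneous) stats::qnorm(1 - alpha / 2 / max(max_lag, 1))
    else stats::qnorm(1 - alpha / 2)
  se <- sqrt((1 + 2 * cumsum(c(0, r[-1]^2))) / n)
  se <- c(0, se[seq_len(max_lag)])  # lag 0 is exact
  data.frame(lag = 0:max_lag, acf = r, lower = r - z * se,
             upper = r + z * se)
}

#' Detect rhythmicity from an autocorrelation with CIs
#'
#' Scans lags in ascending order for the event sequence that defines a
#' rhythmic ROI: the upper bound of the autocorrelation CI first drops
#' below zero, and at some later lag the lower bound crosses above
#' zero. When the sequence occurs, the ROI is rhythmic; the reported
#' lag maximizes the autocorrelation within the contiguous
#' lower-bound-positive excursion, and the strength is the
#' autocorrelation there.
#'
#' @param ac data frame from [autocorrelation_ci()].
#' @param sampling_rate Hz, to report the lag in seconds.
#' @return A list: `is_rhythmic`, `lag_s`, `lag_samples`, `strength`.
#' @export
detect_rhythmic <- function(ac, sampling_rate = 1) {
  pos <- ac[ac$lag > 0, , drop = FALSE]
  below <- which(pos$upper < 0)
  if (!length(below))
    return(list(is_rhythmic = FALSE, lag_s = NA_real_,
                lag_samples = NA_integer_, strength = NA_real_))
  first_below <- below[1]
  above <- which(pos$lower > 0)
  above <- above[above > first_below]
  if (!length(above))
    return(list(is_rhythmic = FALSE, lag_s = NA_real_,
                lag_samples = NA_integer_, strength = NA_real_))
  start <- above[1]
  run_end <- start
  while (run_end + 1 <= nrow(pos) && pos$lower[run_end + 1] > 0)
    run_end <- run_end + 1
  seg <- pos[start:run_end, , drop = FALSE]
  best <- which.max(seg$acf)
  list(is_rhythmic = TRUE, lag_s = seg$lag[best] / sampling_rate,
       lag_samples = as.integer(seg$lag[best]), strength = seg$acf[best])
}

#' Rhythmicity verdicts for every ROI of a recording
#'
#' @param roi a preprocessed [roi_matrix()] (see [preprocess_roi()]).
#' @param max_lag_s maximum lag in seconds (default a third of the
#'   recording).
#' @param alpha CI miscoverage.
#' @return Data frame, one row per ROI: `roi_id`, `is_rhythmic`,
#'   `lag_s`, `strength`.
#' @export
roi_rhythmicity <- function(roi, max_lag_s = NULL, alpha = 0.05) {
  if (is.null(roi$Fz)) roi <- preprocess_roi(roi)
  fs <- roi$sampling_rate
  max_lag <- if (is.null(max_lag_s)) floor(nrow(roi$Fz) / 3)
    else round(max_lag_s * fs)
  res <- lapply(seq_len(ncol(roi$Fz)), function(j) {
    ac <- autocorrelation_ci(roi$Fz[, j], max_lag = max_lag,
                             alpha = alpha)
    r <- detect_rhythmic(ac, sampling_rate = fs)
    data.frame(roi_id = roi$roi_ids[j], is_rhythmic = r$is_rhythmic,
               lag_s = r$lag_s, strength = r$strength,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Percent of rhythmic ROIs per slice
#'
#' @param is_rhythmic logical vector of per-ROI verdicts.
#' @param slice factor/vector assigning each ROI to a slice.
#' @return A list: `per_slice` (data frame with `slice`, `n_roi`,
#'   `percent_rhythmic`) and `mean`, `sd` across slices.
#' @export
rhythmic_fraction <- function(is_rhythmic, slice) {
  stopifnot(length(is_rhythmic) == length(slice))
  tab <- tapply(is_rhythmic, slice, function(v) 100 * mean(v))
  per_slice <- data.frame(slice = names(tab),
                          n_roi = as.integer(table(slice)[names(tab)]),
                          percent_rhythmic = as.numeric(tab),
                          stringsAsFactors = FALSE)
  list(per_slice = per_slice, mean = mean(per_slice$percent_rhythmic),
       sd = stats::sd(per_slice$percent_rhythmic))
}

#' Sigh-triggered pre/post test for one ROI
#'
#' For each window size `w`, compares the mean signal in `[t - w, t)`
#' against `[t, t + w)` across sigh onsets `t` with a paired two-sided
#' t-test (the sigh onset belongs to the post window). Sighs whose
#' windows spill past the trace edges are dropped with a warning; fewer
#' than `min_events` usable sighs yields a missing result for that
#' window. Bonferroni correction multiplies each raw p-value by `m`,
#' the total number of tests in the family (by default the number of
#' windows here; batch callers pass `n_roi * n_windows`).
#'
#' @param x preprocessed (z-scored) ROI trace.
#' @param sampling_rate Hz.
#' @param sigh_times sigh onset times, s (need >= `min_events`).
#' @param windows window sizes, s.
#' @param m Bonferroni family size (default `length(windows)`).
#' @param min_events minimum usable sighs per window.
#' @return Data frame, one row per window: `window_s`, `n_events`,
#'   `mean_pre`, `mean_post`, `p_raw`, `p_corrected`, `degenerate`
#'   (TRUE when the paired differences have zero variance and no
#'   p-value exists).
#' @export
sigh_triggered_test <- function(x, sampling_rate, sigh_times,
                                windows = c(1, 2, 5, 10), m = NULL,
                                min_events = 3) {
  if (length(sigh_times) < min_events)
    stop(sprintf("need at least %d sighs", min_events))
  if (is.null(m)) m <- length(windows)
  n <- length(x)
  out <- lapply(windows, function(w) {
    wn <- round(w * sampling_rate)
    idx0 <- round(sigh_times * sampling_rate) + 1L
    ok <- idx0 - wn >= 1L & idx0 + wn - 1L <= n
    if (any(!ok))
      warning(sprintf("window %g s: %d sigh(s) too close to trace edges dropped",
                      w, sum(!ok)))
    use <- idx0[ok]
    if (length(use) < min_events)
      return(data.frame(window_s = w, n_events = length(use),
                        mean_pre = NA_real_, mean_post = NA_real_,
                        p_raw = NA_real_, p_corrected = NA_real_,
                        degenerate = NA))
    pre <- vapply(use, function(i) mean(x[(i - wn):(i - 1L)]), 0)
    post <- vapply(use, function(i) mean(x[i:(i + wn - 1L)]), 0)
    if (stats::sd(post - pre) == 0)
      return(data.frame(window_s = w, n_events = length(use),
                        mean_pre = mean(pre), mean_post = mean(post),
                        p_raw = NA_real_, p_corrected = NA_real_,
                        degenerate = TRUE))
    tt <- stats::t.test(post, pre, paired = TRUE)
    data.frame(window_s = w, n_events = length(use),
               mean_pre = mean(pre), mean_post = mean(post),
               p_raw = tt$p.value,
               p_corrected = min(1, m * tt$p.value), degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Sigh-triggered tests for every ROI, Bonferroni over the whole batch
#'
#' @param roi a preprocessed [roi_matrix()].
#' @param sigh_times sigh onset times, s.
#' @param windows window sizes, s.
#' @param family `"roi_x_window"` (default; m = n_roi * n_windows) or
#'   `"window"` (m = n_windows, per-ROI family).
#' @return Data frame with `roi_id` plus the columns of
#'   [sigh_triggered_test()].
#' @export
sigh_triggered_batch <- function(roi, sigh_times,
                                 windows = c(1, 2, 5, 10),
                                 family = c("roi_x_window", "window")) {
  family <- match.arg(family)
  if (is.null(roi$Fz)) roi <- preprocess_roi(roi)
  m <- if (family == "roi_x_window") ncol(roi$Fz) * length(windows)
    else length(windows)
  res <- lapply(seq_len(ncol(roi$Fz)), function(j) {
    r <- sigh_triggered_test(roi$Fz[, j], roi$sampling_rate, sigh_times,
                             windows = windows, m = m)
    cbind(roi_id = roi$roi_ids[j], r, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
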