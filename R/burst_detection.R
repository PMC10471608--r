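#' Local maxima of a numeric vector
#'
#' A sample is a local maximum when it exceeds its left neighbour and is
#' at least its right neighbour (so the left edge of a plateau counts
#' once). Endpoints are never maxima.
#'
#' @param x numeric vector.
#' @return Integer vector of 1-based indices.
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

#' Topographic prominence of peaks
#'
#' For each peak, walk out on both sides to the nearest strictly higher
#' sample (or the signal edge); the prominence is the peak height minus
#' the higher of the two interval minima. Matches the standard
#' topographic definition used by common peak-finding routines.
#' Implemented with a monotonic stack over the peak sequence plus a
#' sparse-table range-minimum query over inter-peak minima, so whole
#' recordings are handled in about n log n time.
#'
#' @param x numeric vector.
#' @param peaks indices of local maxima (from [local_maxima()]).
#' @return Numeric vector of prominences, one per peak.
#' @keywords internal
peak_prominences <- function(x, peaks) {
  np <- length(peaks)
  if (np == 0L) return(numeric(0))
  h <- x[peaks]
  n <- length(x)
  # minima between consecutive peaks, plus the edges
  gapmin <- if (np > 1L)
    vapply(seq_len(np - 1L),
           function(i) min(x[peaks[i]:peaks[i + 1L]]), 0.0)
  else numeric(0)
  headmin <- min(x[1:peaks[1L]])
  tailmin <- min(x[peaks[np]:n])

  # sparse table over gapmin for O(1) range minima
  K <- if (np > 1L) max(1L, floor(log2(np - 1L)) + 1L) else 1L
  st <- vector("list", K)
  st[[1L]] <- gapmin
  if (np > 1L && K > 1L) for (k in 2:K) {
    prev <- st[[k - 1L]]
    half <- 2^(k - 2L)
    m <- length(prev) - half
    if (m < 1L) { st[[k]] <- prev; next }
    st[[k]] <- pmin(prev[1:m], prev[(1L + half):(m + half)])
  }
  rmq <- function(l, r) {  # min(gapmin[l..r]), l <= r
    len <- r - l + 1L
    k <- floor(log2(len)) + 1L
    span <- 2^(k - 1L)
    min(st[[k]][l], st[[k]][r - span + 1L])
  }

  # nearest strictly higher peak on each side via monotonic stacks
  left_higher <- integer(np); right_higher <- integer(np)
  stack <- integer(0)
  for (i in seq_len(np)) {
    while (length(stack) && h[stack[length(stack)]] <= h[i])
      stack <- stack[-length(stack)]
    left_higher[i] <- if (length(stack)) stack[length(stack)] else 0L
    stack <- c(stack, i)
  }
  stack <- integer(0)
  for (i in rev(seq_len(np))) {
    while (length(stack) && h[stack[length(stack)]] <= h[i])
      stack <- stack[-length(stack)]
    right_higher[i] <- if (length(stack)) stack[length(stack)] else np + 1L
    stack <- c(stack, i)
  }

  vapply(seq_len(np), function(i) {
    lb <- if (left_higher[i] == 0L) {
      if (i > 1L) min(headmin, rmq(1L, i - 1L)) else headmin
    } else rmq(left_higher[i], i - 1L)
    rb <- if (right_higher[i] == np + 1L) {
      if (i < np) min(tailmin, rmq(i, np - 1L)) else tailmin
    } else rmq(i, right_higher[i] - 1L)
    h[i] - max(lb, rb)
  }, 0.0)
}

#' Detect bursts in an integrated trace by peak prominence
#'
#' Finds peaks whose topographic prominence exceeds `prominence_factor`
#' times the standard deviation of the whole trace (default 2.5), merges
#' peaks closer than a refractory gap keeping the larger, and locates
#' each burst's onset at the `onset_frac` crossing of its peak height
#' above a local baseline (see [locate_onset()]). Detection is invariant
#' to adding a constant to the trace and equivariant to positive
#' amplitude scaling, since the prominence and the SD scale together.
#'
#' @param trace a [sigh_trace()].
#' @param prominence_factor prominence threshold in trace-SD units.
#' @param refractory minimum peak separation, s; closer peaks merge,
#'   keeping the larger.
#' @param onset_frac fraction of peak height defining the onset (0.2 =
#'   the 20% rule).
#' @param baseline `"local"` (median of the preceding inter-burst
#'   interval) or `"absolute"` (zero) reference for the onset level.
#' @param peak_refine window, s, of the moving average used to refine
#'   peak locations against noise jitter on the flat burst top; scale it
#'   down for rhythms much faster than the slice default (it should stay
#'   well under the burst period), or set 0 to disable.
#' @param sd_value optional externally supplied trace SD, e.g. pooled
#'   over all sweeps of one recording so a single threshold applies to
#'   every sweep; default is the SD of this trace.
#' @return A data frame with one row per burst, ordered by time:
#'   `onset_s`, `peak_s`, `amplitude` (trace value at the peak),
#'   `height` (peak above the local baseline), `prominence`, `rise_s`
#'   (= peak_s - onset_s), `baseline`, `onset_clamped`, and an
#'   `artifact` flag (all `FALSE`; see [reject_artifacts()]).
#' @examples
#' sim <- generate_population_trace(synth_params(duration = 60, seed = 2))
#' detect_bursts(sim$trace)[1:3, ]
#' @export
detect_bursts <- function(trace, prominence_factor = 2.5, refractory = 0.2,
                          onset_frac = 0.2,
                          baseline = c("local", "absolute"),
                          peak_refine = 0.25, sd_value = NULL) {
  baseline <- match.arg(baseline)
  stopifnot(prominence_factor > 0)
  x <- trace$samples
  sdv <- sd_value %||% stats::sd(x)
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      amplitude = numeric(0), height = numeric(0),
                      prominence = numeric(0), rise_s = numeric(0),
                      baseline = numeric(0), onset_clamped = logical(0),
                      artifact = logical(0))
  if (sdv == 0) {
    warning("constant trace (SD = 0): no bursts detectable")
    return(empty)
  }
  pk <- local_maxima(x)
  if (!length(pk)) return(empty)
  prom <- peak_prominences(x, pk)
  keep <- prom > prominence_factor * sdv
  pk <- pk[keep]; prom <- prom[keep]
  if (!length(pk)) return(empty)

  # refractory merge, keeping the larger peak
  min_gap <- round(refractory * trace$sampling_rate)
  ord <- order(pk)
  pk <- pk[ord]; prom <- prom[ord]
  sel <- 1L
  for (i in seq_along(pk)[-1]) {
    last <- sel[length(sel)]
    if (pk[i] - pk[last] < min_gap) {
      if (x[pk[i]] > x[pk[last]]) sel[length(sel)] <- i
    } else sel <- c(sel, i)
  }
  pk <- pk[sel]; prom <- prom[sel]

  # refine peak locations on a lightly smoothed copy: noise on the flat
  # top of a burst otherwise jitters the peak sample by tens of ms,
  # which corrupts rise-time estimates
  if (peak_refine > 0) {
    w <- max(1L, round(peak_refine * trace$sampling_rate))
    xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    half0 <- max(1L, round(2.5 * peak_refine * trace$sampling_rate))
    np <- length(pk)
    pk <- vapply(seq_len(np), function(i) {
      p <- pk[i]
      # never search past 40% of the gap to a neighbouring peak
      half <- half0
      if (i > 1L) half <- min(half, floor(0.4 * (p - pk[i - 1L])))
      if (i < np) half <- min(half, floor(0.4 * (pk[i + 1L] - p)))
      half <- max(half, 1L)
      lo <- max(1L, p - half); hi <- min(length(x), p + half)
      seg <- xs[lo:hi]
      if (all(is.na(seg))) return(as.integer(p))
      am <- lo + which.max(seg) - 1L
      # quadratic-vertex refinement around the smoothed argmax: lower
      # variance than the raw argmax when the burst top is flat
      qw <- max(2L, round(0.6 * w))
      ql <- max(lo, am - qw); qh <- min(hi, am + qw)
      ts <- (ql:qh) - am
      ys <- xs[ql:qh]
      if (length(ts) >= 5L && !anyNA(ys)) {
        fit <- stats::lm.fit(cbind(1, ts, ts^2), ys)
        a2 <- fit$coefficients[3]; a1 <- fit$coefficients[2]
        if (is.finite(a2) && a2 < 0) {
          vtx <- -a1 / (2 * a2)
          if (abs(vtx) <= qw) am <- am + as.integer(round(vtx))
        }
      }
      am <- as.integer(min(max(am, lo), hi))
      # refinement is for noise on a flat top: if the raw trace at the
      # refined spot is far below the raw peak (a narrow spike, not a
      # flat-topped burst), keep the raw peak
      if (x[am] < 0.5 * x[p]) am <- as.integer(p)
      am
    }, integer(1))
  }

  peak_times <- index_to_time(trace, pk)
  res <- lapply(seq_along(pk), function(i) {
    locate_onset(trace, peak_times[i], onset_frac = onset_frac,
                 baseline = baseline,
                 prev_peak_time = if (i > 1L) peak_times[i - 1L] else NULL)
  })
  data.frame(
    onset_s = vapply(res, `[[`, 0, "onset_s"),
    peak_s = peak_times,
    amplitude = x[pk],
    height = vapply(res, function(r) r$peak_value - r$baseline, 0),
    prominence = prom,
    rise_s = peak_times - vapply(res, `[[`, 0, "onset_s"),
    baseline = vapply(res, `[[`, 0, "baseline"),
    onset_clamped = vapply(res, `[[`, TRUE, "clamped"),
    artifact = FALSE)
}

#' Locate a burst onset at a fraction of peak height
#'
#' Walks backward from the peak and returns the latest time at which the
#' trace crosses `onset_frac` of the peak height (default 20%), with the
#' crossing linearly interpolated between samples. Heights are measured
#' above a local baseline, by default the median of the trace over the
#' inter-burst interval preceding the burst (from the previous peak, or
#' the trace start). If the signal never drops below the level before
#' the previous burst, the onset is clamped there and flagged.
#'
#' @param trace a [sigh_trace()].
#' @param peak_time peak time, s (a detected peak).
#' @param onset_frac fraction of peak height.
#' @param baseline `"local"` or `"absolute"` (zero).
#' @param prev_peak_time previous burst's peak time, s, or `NULL`.
#' @return A list: `onset_s`, `baseline`, `peak_value`, `clamped`.
#' @examples
#' tr <- sigh_trace(seq(0, 1, length.out = 101), 100)  # linear ramp
#' locate_onset(tr, peak_time = 1, baseline = "absolute")$onset_s  # 0.2
#' @export
locate_onset <- function(trace, peak_time, onset_frac = 0.2,
                         baseline = c("local", "absolute"),
                         prev_peak_time = NULL) {
  baseline <- match.arg(baseline)
  x <- trace$samples
  p <- time_to_index(trace, peak_time)
  lim <- if (!is.null(prev_peak_time))
    time_to_index(trace, prev_peak_time) + 1L else 1L
  base <- if (baseline == "absolute") 0 else {
    seg <- x[lim:p]
    stats::median(seg)
  }
  level <- base + onset_frac * (x[p] - base)
  # robust noise scale from first differences, for the hysteresis band
  seg <- x[lim:p]
  sig <- stats::mad(diff(seg), constant = 1.4826) / sqrt(2)
  hyst <- min(0.5 * sig, 0.2 * onset_frac * (x[p] - base))
  # walk back until the trace stays below level - hyst for a persistence
  # window, so noise dips on the rise (or in the inter-peak trough of a
  # biphasic sigh) don't truncate the onset search
  m <- max(1L, round(0.08 * trace$sampling_rate))
  j <- p
  while (j > lim) {
    lo <- max(lim, j - m)
    if (all(x[lo:(j - 1L)] < level - hyst)) break
    j <- j - 1L
  }
  clamped <- FALSE
  if (j == lim && (j == 1L || x[j - 1L] >= level - hyst) &&
      x[j] >= level && !is.null(prev_peak_time)) {
    clamped <- TRUE
    onset <- index_to_time(trace, j)
  } else {
    # from the stop point, take the first upward crossing of the level
    while (j < p && x[j] < level) j <- j + 1L
    if (j > 1L && x[j - 1L] < level && x[j] >= level &&
        x[j] > x[j - 1L]) {
      frac <- (level - x[j - 1L]) / (x[j] - x[j - 1L])
      onset <- index_to_time(trace, j - 1L) + frac / trace$sampling_rate
    } else {
      onset <- index_to_time(trace, j)
    }
  }
  list(onset_s = min(onset, peak_time), baseline = base,
       peak_value = x[p], clamped = clamped)
}

#' Flag aberrant bursts as artifacts
#'
#' Marks bursts whose peak amplitude exceeds `amp_factor` times the mean
#' peak amplitude of all detected bursts, or whose rise (onset to peak)
#' is faster than `min_rise`, as noise. Flagged bursts are retained in
#' the table for audit; downstream stages use rows with
#' `artifact == FALSE`.
#'
#' @param bursts burst table from [detect_bursts()].
#' @param amp_factor amplitude cutoff in units of the mean burst
#'   amplitude.
#' @param min_rise minimum credible rise time, s.
#' @return The burst table with the `artifact` column set.
#' @export
reject_artifacts <- function(bursts, amp_factor = 75, min_rise = 0.150) {
  if (!nrow(bursts)) return(bursts)
  mean_amp <- mean(bursts$amplitude)
  bursts$artifact <- bursts$amplitude > amp_factor * mean_amp |
    bursts$rise_s < min_rise
  bursts
}

#' Extract a fixed-length burst shape
#'
#' Returns the trace over `[onset, onset + window)` as a vector of
#' exactly `round(window * sampling_rate)` samples; values past the end
#' of the trace are zero-padded and the number of padded samples is
#' recorded in the `"padded"` attribute.
#'
#' @param trace a [sigh_trace()].
#' @param onset_time burst onset, s.
#' @param window shape window length, s.
#' @return Numeric vector with attribute `padded`.
#' @export
extract_shape <- function(trace, onset_time, window = 1.5) {
  fs <- trace$sampling_rate
  n <- length(trace$samples)
  end_time <- index_to_time(trace, n)
  if (onset_time >= end_time) stop("onset lies at or past the trace end")
  len <- round(window * fs)
  i0 <- time_to_index(trace, onset_time)
  idx <- i0:(i0 + len - 1L)
  ok <- idx <= n
  out <- numeric(len)
  out[ok] <- trace$samples[idx[ok]]
  attr(out, "padded") <- sum(!ok)
  out
}

#' Shape matrix for a burst table
#'
#' @param trace a [sigh_trace()].
#' @param bursts burst table from [detect_bursts()].
#' @param window shape window length, s.
#' @return Matrix, one row per burst, `round(window * sampling_rate)`
#'   columns; attribute `padded` counts zero-padded samples per row.
#' @export
burst_shapes <- function(trace, bursts, window = 1.5) {
  shp <- lapply(bursts$onset_s, function(o) extract_shape(trace, o, window))
  m <- do.call(rbind, lapply(shp, as.numeric))
  if (is.null(m)) m <- matrix(0, 0, round(window * trace$sampling_rate))
  attr(m, "padded") <- vapply(shp, attr, 0L, "padded")
  m
}

#' Match detected events against ground-truth events
#'
#' Greedy one-to-one matching by temporal proximity within a tolerance;
#' used to score detection and classification against planted labels.
#'
#' @param detected_s detected event times, s.
#' @param truth_s true event times, s.
#' @param tol matching tolerance, s.
#' @return A list: `tp`, `fp`, `fn`, `sensitivity`, `precision`, and
#'   `pairs` (matrix of matched index pairs detected/truth).
#' @export
match_events <- function(detected_s, truth_s, tol = 0.5) {
  nd <- length(detected_s); nt <- length(truth_s)
  used_d <- logical(nd)
  pairs <- NULL
  for (j in seq_len(nt)) {
    d <- abs(detected_s - truth_s[j])
    d[used_d] <- Inf
    if (nd && min(d) <= tol) {
      i <- which.min(d)
      used_d[i] <- TRUE
      pairs <- rbind(pairs, c(detected = i, truth = j))
    }
  }
  tp <- sum(used_d)
  list(tp = tp, fp = nd - tp, fn = nt - tp,
       sensitivity = if (nt) tp / nt else NA_real_,
       precision = if (nd) tp / nd else NA_real_,
       pairs = pairs)
}
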