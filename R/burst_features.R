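#' Characterization features for detected bursts
#'
#' Computes, for each burst, the metrics used to characterize eupnea and
#' sighs and the intuitive features used by the evoked-burst classifier:
#' peak amplitude above the local baseline, burst duration (onset-level
#' crossing to the symmetric return crossing), full width at half
#' maximum, area under the curve above baseline over the burst, the
#' post-burst interval (burst end to next onset) and the inter-event
#' interval (onset to next onset). The last burst of a recording has no
#' following burst, so its interval fields are `NA`, not zero.
#'
#' @param trace a [sigh_trace()].
#' @param bursts burst table from [detect_bursts()] (artifact rows are
#'   carried through; filter on `artifact` as needed).
#' @param onset_frac fraction of peak height defining the onset/end
#'   level (same convention as detection).
#' @param max_duration longest credible burst, s; the duration search
#'   stops there if the trace never returns to the onset level.
#' @return The burst table with columns added: `feat_amplitude`,
#'   `duration_s`, `fwhm_s`, `auc`, `end_s`, `post_burst_interval_s`,
#'   `inter_event_interval_s`.
#' @examples
#' sim <- generate_population_trace(synth_params(duration = 120, seed = 3))
#' b <- compute_features(sim$trace, detect_bursts(sim$trace))
#' summary(b$fwhm_s)
#' @export
compute_features <- function(trace, bursts, onset_frac = 0.2,
                             max_duration = 10) {
  n <- nrow(bursts)
  cols <- c("feat_amplitude", "duration_s", "fwhm_s", "auc", "end_s",
            "post_burst_interval_s", "inter_event_interval_s")
  for (cc in cols) bursts[[cc]] <- rep(NA_real_, n)
  if (!n) return(bursts)
  x <- trace$samples
  fs <- trace$sampling_rate
  for (i in seq_len(n)) {
    base <- bursts$baseline[i]
    p <- time_to_index(trace, bursts$peak_s[i])
    amp <- x[p] - base
    bursts$feat_amplitude[i] <- amp
    lvl_on <- base + onset_frac * amp
    lvl_half <- base + 0.5 * amp
    lim <- min(length(x), p + round(max_duration * fs))
    bursts$end_s[i] <- cross_down(trace, p, lvl_on, lim)
    bursts$duration_s[i] <- bursts$end_s[i] - bursts$onset_s[i]
    # FWHM: last upward and first downward crossing of the half level
    up <- cross_up_back(trace, p, lvl_half,
                        time_to_index(trace, bursts$onset_s[i]))
    dn <- cross_down(trace, p, lvl_half, lim)
    bursts$fwhm_s[i] <- dn - up
    i0 <- time_to_index(trace, bursts$onset_s[i])
    i1 <- time_to_index(trace, bursts$end_s[i])
    if (i1 > i0) {
      seg <- x[i0:i1] - base
      bursts$auc[i] <- sum((seg[-1] + seg[-length(seg)]) / 2) / fs
    } else bursts$auc[i] <- 0
  }
  if (n > 1) {
    nxt_onset <- c(bursts$onset_s[-1], NA_real_)
    bursts$post_burst_interval_s <- nxt_onset - bursts$end_s
    bursts$inter_event_interval_s <- nxt_onset - bursts$onset_s
  }
  bursts
}

# first downward crossing of `level` after index p (interpolated time)
cross_down <- function(trace, p, level, lim) {
  x <- trace$samples
  j <- p
  while (j < lim && x[j + 1L] >= level) j <- j + 1L
  if (j < length(x) && x[j + 1L] < level && x[j] > x[j + 1L]) {
    frac <- (x[j] - level) / (x[j] - x[j + 1L])
    index_to_time(trace, j) + frac / trace$sampling_rate
  } else index_to_time(trace, j)
}

# latest upward crossing of `level` before index p (interpolated time)
cross_up_back <- function(trace, p, level, lim) {
  x <- trace$samples
  j <- p
  while (j > lim && x[j - 1L] >= level) j <- j - 1L
  if (j > 1L && x[j - 1L] < level && x[j] > x[j - 1L]) {
    frac <- (level - x[j - 1L]) / (x[j] - x[j - 1L])
    index_to_time(trace, j - 1L) + frac / trace$sampling_rate
  } else index_to_time(trace, j)
}

#' Classify a sigh shape as monophasic or biphasic
#'
#' A sigh is biphasic when its shape vector contains at least two local
#' maxima, each at least `peak_frac` of the global peak (heights above
#' the burst baseline), separated by a trough at least `trough_frac`
#' below the smaller of the two maxima. The shape window starts at the
#' burst onset, so the window minimum sits near the onset level, NOT at
#' baseline; heights are therefore measured above the caller-supplied
#' baseline (the local baseline from detection). Biphasic sighs appear as a
#' eupneic-scale burst merged into a following large burst; monophasic
#' sighs are a single large burst. The rule is deterministic and
#' invariant to amplitude scaling. Doublets of eupneic activity are
#' never auto-labeled sighs: this classifier is only meaningful for
#' bursts already labeled as sighs.
#'
#' @param shape numeric shape vector (from [extract_shape()]).
#' @param peak_frac minimum secondary peak height as a fraction of the
#'   global peak.
#' @param trough_frac required trough depth as a fraction of the smaller
#'   peak.
#' @param smooth moving-average window (samples) applied before peak
#'   finding, for robustness against sample-level noise; 0 disables.
#' @param baseline burst-local baseline level subtracted before the
#'   height comparisons (see `detect_bursts()$baseline`).
#' @return `"monophasic"` or `"biphasic"`.
#' @examples
#' t <- seq(0, 1.5, by = 0.01)
#' mono <- exp(-t / 0.4) - exp(-t / 0.1)
#' classify_shape(mono)
#' @export
classify_shape <- function(shape, peak_frac = 0.2, trough_frac = 0.2,
                           smooth = 5L, baseline = 0) {
  y <- as.numeric(shape)
  if (smooth > 1)
    y <- moving_average(y, smooth)
  y <- y - baseline
  pks <- local_maxima(y)
  if (length(y) && which.max(y) == length(y)) pks <- c(pks, length(y))
  pks <- pks[y[pks] >= peak_frac * max(y)]
  if (length(pks) < 2L) return("monophasic")
  for (a in seq_len(length(pks) - 1L)) {
    for (b in (a + 1L):length(pks)) {
      smaller <- min(y[pks[a]], y[pks[b]])
      trough <- min(y[pks[a]:pks[b]])
      if (trough <= (1 - trough_frac) * smaller) return("biphasic")
    }
  }
  "monophasic"
}

#' Label spontaneous sighs by their characterization features
#'
#' Simple rule for recordings with a regular, well-synchronized eupneic
#' and sigh rhythm: a burst is labeled a sigh when its amplitude exceeds
#' `amp_factor` times the median burst amplitude and its post-burst
#' interval exceeds `interval_factor` times the median (the post-sigh
#' apnea). Intended for spontaneous activity only; evoked bursts go
#' through [classify_evoked()].
#'
#' @param features burst table from [compute_features()].
#' @param amp_factor amplitude threshold relative to the median.
#' @param interval_factor post-burst-interval threshold relative to the
#'   median.
#' @return The table with a `label` column (`"eupnea"`/`"sigh"`).
#' @export
label_spontaneous_sighs <- function(features, amp_factor = 1.6,
                                    interval_factor = 1.5) {
  med_amp <- stats::median(features$feat_amplitude, na.rm = TRUE)
  med_int <- stats::median(features$post_burst_interval_s, na.rm = TRUE)
  amp_ok <- features$feat_amplitude > amp_factor * med_amp
  int_ok <- features$post_burst_interval_s > interval_factor * med_int
  int_ok[is.na(int_ok)] <- FALSE
  features$label <- ifelse(amp_ok & int_ok, "sigh", "eupnea")
  features
}

#' Summarize burst activity per experimental epoch
#'
#' Counts eupneic bursts and sighs per epoch, normalized to counts per
#' `window` seconds (the conventional bursts-per-20-min reporting),
#' with mean features per class and the sigh:eupnea amplitude ratio.
#'
#' @param bursts labeled burst table (needs `onset_s`, `label`, and
#'   feature columns from [compute_features()]).
#' @param epochs data frame with columns `name`, `start_s`, `end_s`;
#'   epochs must not overlap.
#' @param window normalization window, s (default 1200 = 20 min).
#' @return Data frame, one row per epoch: counts, rates per window,
#'   mean amplitude/duration per class, and `sigh_eupnea_amp_ratio`.
#' @export
summarize_epochs <- function(bursts, epochs, window = 1200) {
  stopifnot(all(c("name", "start_s", "end_s") %in% names(epochs)))
  ep <- epochs[order(epochs$start_s), , drop = FALSE]
  if (nrow(ep) > 1 && any(ep$start_s[-1] < ep$end_s[-nrow(ep)]))
    stop("epochs must not overlap")
  out <- lapply(seq_len(nrow(ep)), function(i) {
    sel <- bursts$onset_s >= ep$start_s[i] & bursts$onset_s < ep$end_s[i]
    b <- bursts[sel, , drop = FALSE]
    len <- ep$end_s[i] - ep$start_s[i]
    n_eup <- sum(b$label == "eupnea")
    n_sigh <- sum(b$label == "sigh")
    mean_of <- function(lab, col) {
      v <- b[[col]][b$label == lab]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }
    amp_e <- mean_of("eupnea", "feat_amplitude")
    amp_s <- mean_of("sigh", "feat_amplitude")
    data.frame(
      name = ep$name[i], start_s = ep$start_s[i], end_s = ep$end_s[i],
      n_eupnea = n_eup, n_sigh = n_sigh,
      eupnea_per_window = n_eup / len * window,
      sigh_per_window = n_sigh / len * window,
      mean_amp_eupnea = amp_e, mean_amp_sigh = amp_s,
      mean_duration_eupnea = mean_of("eupnea", "duration_s"),
      mean_duration_sigh = mean_of("sigh", "duration_s"),
      sigh_eupnea_amp_ratio = if (!is.na(amp_e) && amp_e > 0)
        amp_s / amp_e else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
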