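#' Rectify and integrate a raw EMG trace
#'
#' Absolute value followed by a centered moving average over `window`
#' seconds; output has the same length and sampling rate as the input.
#'
#' @param raw a [sigh_trace()] of raw EMG.
#' @param window integration window, s (must span at least 2 samples).
#' @return A [sigh_trace()], channel suffixed with `"_int"`.
#' @examples
#' raw <- sigh_trace(rnorm(2000), 1000, channel = "dia")
#' rectify_integrate(raw)
#' @export
rectify_integrate <- function(raw, window = 0.05) {
  w <- round(window * raw$sampling_rate)
  if (w < 2) stop("integration window must span at least 2 samples")
  y <- moving_average(abs(raw$samples), w)
  sigh_trace(y, raw$sampling_rate, t0 = raw$t0,
             channel = paste0(raw$channel, "_int"))
}

#' Label sighs in vivo by the rolling 6xMAD rule
#'
#' For each burst, the median and median absolute deviation (MAD,
#' unscaled by default) of amplitude and of area under the curve are
#' computed over the up-to-`n_neighbors` bursts preceding and following
#' it (excluding the burst itself). The burst is labeled a sigh iff its
#' amplitude deviation from the neighborhood median exceeds `k` times
#' the amplitude MAD AND its AUC deviation exceeds `k` times the AUC
#' MAD (both strict). Raw values and MADs live on different scales, so
#' the deviation-vs-MAD comparison is the standard robust-outlier
#' reading; the deviation is signed (`value - median`), since sighs are
#' by definition the unusually LARGE bursts and an absolute deviation
#' would also flag runt bursts such as the small component of a
#' biphasic sigh. `mode = "abs_deviation"` uses |value - median|;
#' `mode = "raw"` preserves the literal value-vs-MAD form.
#' Edge bursts with fewer than `min_neighbors` available neighbors are
#' labeled eupnea. Deterministic, and invariant to uniform amplitude
#' scaling of the recording.
#'
#' @param bursts burst table with `feat_amplitude` and `auc` columns
#'   (from [compute_features()]), ordered by time.
#' @param k threshold in MAD units (default 6).
#' @param n_neighbors neighbors on each side (default 20).
#' @param min_neighbors minimum total neighbors for a verdict.
#' @param mode `"deviation"` (default) compares value - median to
#'   k*MAD; `"abs_deviation"` compares |value - median|; `"raw"`
#'   compares the value itself to k*MAD.
#' @param mad_constant scale factor passed to [stats::mad()]; 1 = the
#'   unscaled MAD (default), 1.4826 = normal-consistent.
#' @return The table with a `label` column (`"eupnea"`/`"sigh"`) and
#'   diagnostic columns `dev_amp`, `dev_auc`, `mad_amp`, `mad_auc`.
#' @export
classify_sighs_invivo <- function(bursts, k = 6, n_neighbors = 20,
                                  min_neighbors = 5,
                                  mode = c("deviation", "abs_deviation",
                                           "raw"),
                                  mad_constant = 1) {
  mode <- match.arg(mode)
  n <- nrow(bursts)
  amp <- bursts$feat_amplitude
  auc <- bursts$auc
  lab <- rep("eupnea", n)
  dev_amp <- dev_auc <- mad_amp <- mad_auc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pre <- if (i > 1L) max(1L, i - n_neighbors):(i - 1L) else integer(0)
    post <- if (i < n) (i + 1L):min(n, i + n_neighbors) else integer(0)
    idx <- c(pre, post)
    if (length(idx) < min_neighbors) next
    ma <- stats::mad(amp[idx], constant = mad_constant)
    mu <- stats::mad(auc[idx], constant = mad_constant)
    mad_amp[i] <- ma; mad_auc[i] <- mu
    if (mode == "deviation") {
      dev_amp[i] <- amp[i] - stats::median(amp[idx])
      dev_auc[i] <- auc[i] - stats::median(auc[idx])
    } else if (mode == "abs_deviation") {
      dev_amp[i] <- abs(amp[i] - stats::median(amp[idx]))
      dev_auc[i] <- abs(auc[i] - stats::median(auc[idx]))
    } else {
      dev_amp[i] <- amp[i]
      dev_auc[i] <- auc[i]
    }
    if (dev_amp[i] > k * ma && dev_auc[i] > k * mu) lab[i] <- "sigh"
  }
  bursts$label <- lab
  bursts$dev_amp <- dev_amp; bursts$dev_auc <- dev_auc
  bursts$mad_amp <- mad_amp; bursts$mad_auc <- mad_auc
  bursts
}
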