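#' Construct a uniformly sampled single-channel trace
#'
#' A `sigh_trace` holds an integrated population-activity or
#' rectified/integrated EMG signal: a numeric sample vector, its sampling
#' rate, the time of the first sample, and a free-text channel label.
#' All downstream times are seconds from `t0`; sample indexing is 0-based
#' when converting to time, and windows are half-open `[start, end)`.
#'
#' @param samples numeric vector of amplitudes (a.u.), all finite,
#'   length >= 2.
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param t0 time of the first sample in seconds.
#' @param channel free-text channel label.
#' @return An object of class `sigh_trace`.
#' @examples
#' tr <- sigh_trace(sin(seq(0, 10, by = 0.01)), sampling_rate = 100)
#' trace_times(tr)[1:3]
#' @export
sigh_trace <- function(samples, sampling_rate, t0 = 0, channel = "pop") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("trace needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("trace samples must all be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         t0 = as.numeric(t0), channel = as.character(channel)),
    class = "sigh_trace")
}

#' @export
print.sigh_trace <- function(x, ...) {
  cat(sprintf("<sigh_trace> channel '%s': %d samples @ %g Hz (%.2f s from t0 = %g s)\n",
              x$channel, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$t0))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace a [sigh_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$sampling_rate
}

# time (s) -> nearest 1-based sample index, clamped to the trace
time_to_index <- function(trace, t) {
  i <- round((t - trace$t0) * trace$sampling_rate) + 1L
  pmin(pmax(as.integer(i), 1L), length(trace$samples))
}

index_to_time <- function(trace, i) {
  trace$t0 + (i - 1L) / trace$sampling_rate
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without clobbering the
#' session RNG. All randomness in the package flows through this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-call stream seed from a base seed and a small stream id.
# Keeps results independent across generator calls that share one seed.
# Stays below 2^31 - 1.
stream_seed <- function(seed, stream) {
  (as.double(seed) * 1009 + stream * 9973) %% 2147483629
}

#' Write a trace as two-column delimited text with a YAML sidecar
#'
#' The data file holds `time_s` and `amplitude` columns (tab-separated);
#' the sidecar `<path>.yaml` records sampling rate, t0, channel and any
#' extra metadata so the trace round-trips exactly.
#'
#' @param trace a [sigh_trace()].
#' @param path output file path.
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, meta = list()) {
  df <- data.frame(time_s = trace_times(trace), amplitude = trace$samples)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(list(sampling_rate = trace$sampling_rate, t0 = trace$t0,
                 channel = trace$channel, units = "a.u."), meta)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path data file path; the sidecar `<path>.yaml` must exist, or
#'   `sampling_rate` must be given (then the sidecar is optional and the
#'   time column is used only for `t0`).
#' @param sampling_rate optional sampling rate override in Hz.
#' @return A [sigh_trace()].
#' @export
read_trace <- function(path, sampling_rate = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  side_path <- paste0(path, ".yaml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else list()
  sr <- sampling_rate %||% side$sampling_rate
  if (is.null(sr)) {
    dt <- diff(df$time_s)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("no sampling rate available and time column is not uniform")
    sr <- 1 / dt[1]
  }
  sigh_trace(df$amplitude, sampling_rate = sr,
             t0 = side$t0 %||% df$time_s[1],
             channel = side$channel %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
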