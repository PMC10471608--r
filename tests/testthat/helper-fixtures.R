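# shared fixtures built in code; nothing is read from disk

# noiseless difference-of-exponentials kernel as a trace
kernel_trace <- function(amp = 1, tau_rise = 0.14, tau_decay = 0.42,
                         fs = 100, pad = 1) {
  t <- seq(0, tau_decay * 9, by = 1 / fs)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k <- amp * k / max(k)
  sigh_trace(c(numeric(round(pad * fs)), k), fs)
}

# small population simulation reused across tests (cheap, fixed seed)
pop_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_population_trace(
        synth_params(duration = 300, seed = 42))
    cache
  }
})

# brute-force minimum-covariance-determinant subset search
brute_mcd <- function(X, h) {
  combos <- utils::combn(nrow(X), h)
  dets <- apply(combos, 2, function(idx)
    det(stats::cov(X[idx, , drop = FALSE])))
  sort(combos[, which.min(dets)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
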