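#' Parameters for the synthetic respiratory-trace generator
#'
#' Bundles the statistical structure of an integrated preBotzinger-complex
#' (or diaphragm-EMG) recording: a fast, regular eupneic burst rhythm with
#' a slower, large-amplitude sigh rhythm superimposed, biphasic or
#' monophasic sigh shapes, post-sigh apnea, band-limited noise and
#' optional fast artifact spikes.  Defaults describe an in vitro slice
#' recording; see [emg_params()] for in vivo-like settings.
#'
#' Bursts use a difference-of-exponentials kernel with
#' `tau_rise = eupnea_duration / 5` and `tau_decay = 3 * eupnea_duration / 5`,
#' so the default 0.7 s burst rises from its 20%-of-peak onset to peak in
#' about 0.22 s, comfortably slower than the 150 ms artifact floor.  Sigh kernels scale both time constants by
#' `sigh_duration_factor`.  Biphasic sighs are a eupnea-amplitude
#' component merged into a following large component with an inter-peak
#' trough, so the downstream shape rule has a well-defined target.
#'
#' @param sampling_rate Hz.
#' @param duration total trace length, s.
#' @param eupnea_period_mean,eupnea_period_cv mean and coefficient of
#'   variation of the eupneic cycle period (s, dimensionless).
#' @param eupnea_amp_mean,eupnea_amp_cv mean and CV of eupneic burst peak
#'   amplitude (a.u.).
#' @param eupnea_duration eupneic burst duration scale, s (sets the
#'   kernel time constants).
#' @param sigh_interval_mean mean interval between sighs, s; `Inf`
#'   disables sighs.
#' @param sigh_amp_factor sigh peak amplitude / eupneic peak amplitude
#'   (> 1).
#' @param sigh_duration_factor sigh kernel time-constant scale factor.
#' @param post_sigh_apnea_factor post-sigh cycle length / eupneic cycle
#'   length (>= 1); models the post-sigh apnea.
#' @param p_biphasic probability a sigh is biphasic (default from the
#'   reported control biphasic fraction; a default, not a constant).
#' @param noise_sd marginal SD of the additive noise, a.u.
#' @param noise_smooth noise correlation window, s; white Gaussian noise
#'   is moving-average filtered over this window then rescaled to
#'   `noise_sd`, emulating the band-limiting of the integration step.
#' @param artifact_rate artifact spikes per second (Poisson).
#' @param artifact_amp_factor artifact peak / `eupnea_amp_mean`.
#' @param biphasic_separation minimum separation, s, between the onsets
#'   of the small and large components of a biphasic sigh; the actual
#'   separation is chosen per event (deterministically in the component
#'   amplitudes) so the noiseless inter-peak trough falls midway between
#'   the 20% onset level and 80% of the small peak, giving the two-peak
#'   shape rule a well-defined target.
#' @param seed integer seed; identical parameters (including seed) give
#'   bit-identical output.
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(sampling_rate = 100, duration = 1200,
                         eupnea_period_mean = 4, eupnea_period_cv = 0.15,
                         eupnea_amp_mean = 1, eupnea_amp_cv = 0.08,
                         eupnea_duration = 0.7,
                         sigh_interval_mean = 120, sigh_amp_factor = 2.5,
                         sigh_duration_factor = 1.5,
                         post_sigh_apnea_factor = 2, p_biphasic = 0.785,
                         noise_sd = 0.1, noise_smooth = 0.05,
                         artifact_rate = 0, artifact_amp_factor = 20,
                         biphasic_separation = 0.45, seed = 1L) {
  p <- list(sampling_rate = sampling_rate, duration = duration,
            eupnea_period_mean = eupnea_period_mean,
            eupnea_period_cv = eupnea_period_cv,
            eupnea_amp_mean = eupnea_amp_mean,
            eupnea_amp_cv = eupnea_amp_cv,
            eupnea_duration = eupnea_duration,
            sigh_interval_mean = sigh_interval_mean,
            sigh_amp_factor = sigh_amp_factor,
            sigh_duration_factor = sigh_duration_factor,
            post_sigh_apnea_factor = post_sigh_apnea_factor,
            p_biphasic = p_biphasic, noise_sd = noise_sd,
            noise_smooth = noise_smooth, artifact_rate = artifact_rate,
            artifact_amp_factor = artifact_amp_factor,
            biphasic_separation = biphasic_separation,
            seed = as.integer(seed))
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  pos <- c("sampling_rate", "duration", "eupnea_period_mean",
           "eupnea_amp_mean", "eupnea_duration", "sigh_interval_mean",
           "sigh_duration_factor", "biphasic_separation")
  for (f in pos)
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("'%s' must be > 0", f))
  nonneg <- c("eupnea_period_cv", "eupnea_amp_cv", "noise_sd",
              "noise_smooth", "artifact_rate")
  for (f in nonneg)
    if (!is.numeric(p[[f]]) || p[[f]] < 0)
      stop(sprintf("'%s' must be >= 0", f))
  if (p$p_biphasic < 0 || p$p_biphasic > 1)
    stop("'p_biphasic' must be in [0, 1]")
  if (p$sigh_amp_factor <= 1)
    stop("'sigh_amp_factor' must be > 1")
  if (p$post_sigh_apnea_factor < 1)
    stop("'post_sigh_apnea_factor' must be >= 1")
  invisible(p)
}

#' In vivo-like generator parameters for diaphragm EMG
#'
#' Convenience wrapper around [synth_params()] with a faster breathing
#' rhythm, shorter bursts, and sighs that stand out chiefly by amplitude
#' and area, as in rectified/integrated diaphragm EMG recordings.
#'
#' @param ... overrides passed to [synth_params()].
#' @return A `synth_params` object.
#' @export
emg_params <- function(...) {
  defaults <- list(eupnea_period_mean = 0.5, eupnea_period_cv = 0.1,
                   eupnea_duration = 0.12, sigh_interval_mean = 60,
                   sigh_amp_factor = 3, sigh_duration_factor = 1.75,
                   post_sigh_apnea_factor = 2, duration = 300,
                   noise_sd = 0.05)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_params, args)
}

# difference-of-exponentials kernel, peak-normalized to `amp`, evaluated
# from its own onset on the sample grid; returns values until decayed
burst_kernel <- function(amp, tau_rise, tau_decay, fs) {
  span <- tau_decay * 9
  t <- seq(0, span, by = 1 / fs)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  amp * k / max(k)
}

eupnea_taus <- function(p) c(p$eupnea_duration / 5, 3 * p$eupnea_duration / 5)

# pick the biphasic component separation so the noiseless inter-peak
# trough lands midway between the 20%-of-peak onset level (below which
# the onset walk-back would start inside the sigh) and 80% of the small
# peak (above which the two-peak rule cannot fire); deterministic in
# the component amplitudes
choose_biphasic_sep <- function(amp_small, amp_big, taus_e, taus_s, fs,
                                sep0) {
  best <- sep0; best_score <- Inf
  for (sep in seq(sep0, sep0 + 0.5, by = 0.02)) {
    t_end <- sep + 4 * taus_s[2]
    x <- numeric(round(t_end * fs) + 1L)
    x <- add_kernel(x, fs, 0, burst_kernel(amp_small, taus_e[1],
                                           taus_e[2], fs))
    x <- add_kernel(x, fs, sep, burst_kernel(amp_big, taus_s[1],
                                             taus_s[2], fs))
    p2 <- which.max(x)
    p1 <- which.max(x[seq_len(round(sep * fs))])
    if (p1 >= p2) next
    trough <- min(x[p1:p2])
    small_pk <- x[p1]
    lo <- 0.2 * x[p2]          # onset level
    hi <- 0.8 * small_pk       # two-peak rule bound
    if (hi <= lo) next
    target <- (lo + hi) / 2
    score <- abs(trough - target)
    if (score < best_score) { best_score <- score; best <- sep }
  }
  best
}

add_kernel <- function(x, fs, t_start, kernel) {
  i0 <- round(t_start * fs) + 1L
  idx <- i0:(i0 + length(kernel) - 1L)
  ok <- idx >= 1L & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + kernel[ok]
  x
}

# band-limited additive noise with marginal SD = noise_sd
make_noise <- function(n, fs, noise_sd, noise_smooth) {
  if (noise_sd == 0) return(numeric(n))
  w <- max(1L, round(noise_smooth * fs))
  e <- stats::rnorm(n + 2L * w)
  if (w > 1L) {
    e <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
    e <- e[!is.na(e)]
  }
  e <- e[seq_len(n)]
  e / stats::sd(e) * noise_sd
}

# locate an event's peak and 20%-of-peak onset on the noiseless signal
noiseless_event_anchor <- function(x, fs, t_plant, search_span,
                                   onset_frac = 0.2) {
  i0 <- max(1L, round(t_plant * fs) + 1L)
  i1 <- min(length(x), i0 + round(search_span * fs))
  pk <- i0 + which.max(x[i0:i1]) - 1L
  level <- onset_frac * x[pk]
  j <- pk
  while (j > 1L && x[j - 1L] >= level && j > i0 - round(fs)) j <- j - 1L
  # interpolate the crossing below the first suprathreshold sample
  t_on <- (j - 1L) / fs
  if (j > 1L && x[j] > x[j - 1L]) {
    frac <- (level - x[j - 1L]) / (x[j] - x[j - 1L])
    t_on <- (j - 2L + frac) / fs
  }
  list(peak_time = (pk - 1L) / fs, peak_amp = x[pk], onset_time = t_on)
}

# internal scheduler shared by population and EMG generators
plan_events <- function(p, margin = NULL) {
  dur <- p$duration
  if (dur < p$eupnea_period_mean) stop("trace too short")
  kinds <- character(0); shapes <- character(0); times <- numeric(0)
  amps <- numeric(0)
  draw_period <- function() {
    max(0.3 * p$eupnea_period_mean,
        stats::rnorm(1, p$eupnea_period_mean,
                     p$eupnea_period_cv * p$eupnea_period_mean))
  }
  draw_amp <- function() {
    max(0.2 * p$eupnea_amp_mean,
        stats::rnorm(1, p$eupnea_amp_mean,
                     p$eupnea_amp_cv * p$eupnea_amp_mean))
  }
  draw_sigh_gap <- function() {
    max(2 * p$eupnea_period_mean, stats::rexp(1, 1 / p$sigh_interval_mean))
  }
  t <- draw_period()
  next_sigh <- if (is.finite(p$sigh_interval_mean)) draw_sigh_gap() else Inf
  if (is.null(margin))
    margin <- 3 * p$eupnea_duration * p$sigh_duration_factor
  while (t < dur - margin) {
    period <- draw_period()
    if (t >= next_sigh) {
      kinds <- c(kinds, "sigh")
      shapes <- c(shapes,
                  if (stats::runif(1) < p$p_biphasic) "biphasic" else "monophasic")
      amps <- c(amps, draw_amp() * p$sigh_amp_factor)
      period <- period * p$post_sigh_apnea_factor
      next_sigh <- t + draw_sigh_gap()
    } else {
      kinds <- c(kinds, "eupnea")
      shapes <- c(shapes, "n/a")
      amps <- c(amps, draw_amp())
    }
    times <- c(times, t)
    t <- t + period
  }
  data.frame(plant_time = times, kind = kinds, shape_class = shapes,
             amp = amps, stringsAsFactors = FALSE)
}

build_trace_from_plan <- function(p, plan, channel) {
  fs <- p$sampling_rate
  n <- round(p$duration * fs)
  x <- numeric(n)
  taus <- eupnea_taus(p)
  k_eup <- function(amp) burst_kernel(amp, taus[1], taus[2], fs)
  k_sigh <- function(amp) burst_kernel(amp, taus[1] * p$sigh_duration_factor,
                                       taus[2] * p$sigh_duration_factor, fs)
  for (i in seq_len(nrow(plan))) {
    tp <- plan$plant_time[i]
    if (plan$kind[i] == "eupnea") {
      x <- add_kernel(x, fs, tp, k_eup(plan$amp[i]))
    } else if (plan$kind[i] == "sigh" && plan$shape_class[i] == "biphasic") {
      small <- max(0.2 * p$eupnea_amp_mean,
                   stats::rnorm(1, p$eupnea_amp_mean,
                                p$eupnea_amp_cv * p$eupnea_amp_mean))
      sep <- choose_biphasic_sep(small, plan$amp[i], taus,
                                 taus * p$sigh_duration_factor, fs,
                                 p$biphasic_separation)
      x <- add_kernel(x, fs, tp, k_eup(small))
      x <- add_kernel(x, fs, tp + sep, k_sigh(plan$amp[i]))
    } else if (plan$kind[i] == "sigh") {
      x <- add_kernel(x, fs, tp, k_sigh(plan$amp[i]))
    } else if (plan$kind[i] == "artifact") {
      x <- add_kernel(x, fs, tp,
                      burst_kernel(plan$amp[i], 0.006, 0.025, fs))
    }
  }
  # label anchors from the noiseless sum, as downstream detection sees it
  span_of <- function(kind, shape) {
    base <- 3 * p$eupnea_duration
    if (kind == "sigh") {
      s <- base * p$sigh_duration_factor
      if (shape == "biphasic") s <- s + p$biphasic_separation + 0.5
      s
    } else if (kind == "artifact") 0.2 else base
  }
  anchors <- lapply(seq_len(nrow(plan)), function(i) {
    noiseless_event_anchor(x, fs, plan$plant_time[i],
                           span_of(plan$kind[i], plan$shape_class[i]))
  })
  labels <- data.frame(
    time = vapply(anchors, `[[`, 0, "onset_time"),
    peak_time = vapply(anchors, `[[`, 0, "peak_time"),
    amplitude = vapply(anchors, `[[`, 0, "peak_amp"),
    kind = plan$kind, shape_class = plan$shape_class,
    provenance = "spontaneous", stringsAsFactors = FALSE)
  labels <- labels[order(labels$time), , drop = FALSE]
  rownames(labels) <- NULL
  y <- x + make_noise(n, fs, p$noise_sd, p$noise_smooth)
  list(trace = sigh_trace(y, fs, t0 = 0, channel = channel),
       labels = labels, noiseless = x)
}

#' Generate a synthetic integrated population-activity trace
#'
#' Produces a uniformly sampled trace in which eupneic bursts recur with
#' the configured period distribution, sighs (biphasic with probability
#' `p_biphasic`) replace a eupneic cycle at roughly `sigh_interval_mean`
#' intervals, the cycle after each sigh is lengthened by
#' `post_sigh_apnea_factor`, and optional fast artifact spikes occur as a
#' Poisson process.  Every planted event is returned with its exact
#' onset (20%-of-peak crossing on the noiseless signal), peak time, peak
#' amplitude and class, so detection and classification can be scored
#' against ground truth.
#'
#' @param params a [synth_params()] object.
#' @return A list with elements `trace` (a [sigh_trace()]), `labels`
#'   (data frame: `time` = onset s, `peak_time`, `amplitude`, `kind` in
#'   eupnea/sigh/artifact, `shape_class`, `provenance`), and `noiseless`
#'   (the kernel sum before noise, for oracle checks).
#' @examples
#' sim <- generate_population_trace(synth_params(duration = 120, seed = 7))
#' table(sim$labels$kind)
#' @export
generate_population_trace <- function(params) {
  validate_synth_params(params)
  with_seed(stream_seed(params$seed, 1L), {
    plan <- plan_events(params)
    if (params$artifact_rate > 0) {
      n_art <- stats::rpois(1, params$artifact_rate * params$duration)
      if (n_art > 0) {
        # artifacts land clear of planted bursts so the ground truth
        # stays unambiguous (an artifact on top of a burst is neither
        # cleanly an artifact nor a clean burst); the forward guard must
        # cover the longest event extent (a biphasic sigh plus its
        # label-anchor search span)
        back_guard <- 1
        fwd_guard <- 3 * params$eupnea_duration *
          params$sigh_duration_factor + params$biphasic_separation + 1.5
        at <- numeric(0); tries <- 0
        while (length(at) < n_art && tries < 200 * n_art) {
          cand <- stats::runif(1, 1, params$duration - 1)
          tries <- tries + 1
          d <- cand - plan$plant_time
          if (all(d > fwd_guard | d < -back_guard) &&
              (!length(at) || all(abs(cand - at) > 0.5)))
            at <- c(at, cand)
        }
        plan <- rbind(plan, data.frame(
          plant_time = at, kind = "artifact", shape_class = "n/a",
          amp = params$artifact_amp_factor * params$eupnea_amp_mean))
        plan <- plan[order(plan$plant_time), , drop = FALSE]
      }
    }
    build_trace_from_plan(params, plan, channel = "pop")
  })
}

#' Generate a synthetic rectified/integrated diaphragm-EMG trace
#'
#' Same construction as [generate_population_trace()] but intended for
#' in vivo-like parameter sets ([emg_params()]): a fast eupneic rhythm in
#' which sighs are distinguished chiefly by amplitude and area under the
#' curve.
#'
#' @param params a [synth_params()] object, typically from [emg_params()].
#' @return As [generate_population_trace()], with channel `"emg"`.
#' @export
generate_emg_trace <- function(params) {
  validate_synth_params(params)
  with_seed(stream_seed(params$seed, 4L), {
    plan <- plan_events(params)
    build_trace_from_plan(params, plan, channel = "emg")
  })
}

#' Generate optogenetically evoked stimulation sweeps
#'
#' Each sweep carries background spontaneous eupnea plus, at `stim_time`,
#' one of three outcomes drawn independently per sweep: an evoked eupneic
#' burst (probability `p_eupnea`), an evoked sigh (`p_sigh`, biphasic with
#' probability `p_biphasic`), or a failure (no burst near the stimulus).
#' Background bursts are suppressed within the evoked detection window
#' around the stimulus, and after an evoked sigh the next background
#' burst is delayed by the post-sigh apnea factor.
#'
#' @param params a [synth_params()] object (its sigh settings shape the
#'   evoked sighs; background bursts are pure eupnea).
#' @param n_sweeps number of sweeps.
#' @param stim_time stimulus onset within each sweep, s.
#' @param p_eupnea,p_sigh outcome probabilities; `p_eupnea + p_sigh <= 1`,
#'   remainder are failures.
#' @param sweep_duration sweep length, s.
#' @param guard half-width of the evoked detection window around
#'   `stim_time` kept free of background bursts, s.
#' @return A list with `sweeps` (list of [sigh_trace()]), `outcomes`
#'   (data frame: `sweep`, `outcome` in eupnea/sigh/failure,
#'   `shape_class`), and `labels` (per-event data frame across sweeps
#'   with `sweep`, onset `time`, `peak_time`, `amplitude`, `kind`,
#'   `shape_class`, `provenance` in spontaneous/evoked/failure).
#' @export
generate_evoked_sweeps <- function(params, n_sweeps = 50, stim_time = 10,
                                   p_eupnea = 0.5, p_sigh = 0.25,
                                   sweep_duration = 20, guard = 1.5) {
  validate_synth_params(params)
  if (p_eupnea < 0 || p_sigh < 0 || p_eupnea + p_sigh > 1)
    stop("need p_eupnea >= 0, p_sigh >= 0 and p_eupnea + p_sigh <= 1")
  if (stim_time <= 0 || stim_time >= sweep_duration)
    stop("stim_time must lie inside the sweep")
  with_seed(stream_seed(params$seed, 2L), {
    outcomes <- sample(c("eupnea", "sigh", "failure"), n_sweeps,
                       replace = TRUE,
                       prob = c(p_eupnea, p_sigh, 1 - p_eupnea - p_sigh))
    sweeps <- vector("list", n_sweeps)
    all_labels <- list()
    out_shape <- character(n_sweeps)
    for (s in seq_len(n_sweeps)) {
      ps <- params
      ps$duration <- sweep_duration
      ps$sigh_interval_mean <- Inf
      plan <- plan_events(ps, margin = 0.5)
      # clear the evoked window of background bursts
      keep <- plan$plant_time < stim_time - guard |
        plan$plant_time > stim_time + guard
      plan <- plan[keep, , drop = FALSE]
      out <- outcomes[s]
      shp <- "n/a"
      if (out == "eupnea") {
        amp <- max(0.2 * ps$eupnea_amp_mean,
                   stats::rnorm(1, ps$eupnea_amp_mean,
                                ps$eupnea_amp_cv * ps$eupnea_amp_mean))
        plan <- rbind(plan, data.frame(plant_time = stim_time,
                                       kind = "eupnea", shape_class = "n/a",
                                       amp = amp))
      } else if (out == "sigh") {
        shp <- if (stats::runif(1) < ps$p_biphasic) "biphasic" else "monophasic"
        amp <- max(0.2, stats::rnorm(1, ps$eupnea_amp_mean,
                                     ps$eupnea_amp_cv * ps$eupnea_amp_mean)) *
          ps$sigh_amp_factor
        plan <- rbind(plan, data.frame(plant_time = stim_time,
                                       kind = "sigh", shape_class = shp,
                                       amp = amp))
        # post-sigh apnea: delay the post-stimulus schedule so the next
        # background burst starts the lengthened cycle
        apnea_end <- stim_time +
          ps$eupnea_period_mean * ps$post_sigh_apnea_factor
        after <- plan$plant_time > stim_time + guard
        if (any(after)) {
          shift <- apnea_end - min(plan$plant_time[after])
          if (shift > 0) {
            plan$plant_time[after] <- plan$plant_time[after] + shift
            plan <- plan[plan$plant_time < sweep_duration - 0.2, ,
                         drop = FALSE]
          }
        }
      }
      out_shape[s] <- shp
      plan <- plan[order(plan$plant_time), , drop = FALSE]
      built <- build_trace_from_plan(ps, plan, channel = "pop")
      built$labels$provenance <-
        ifelse(abs(built$labels$peak_time - stim_time) < guard + 1,
               "evoked", "spontaneous")
      if (out == "failure") {
        fl <- data.frame(time = stim_time, peak_time = stim_time,
                         amplitude = NA_real_, kind = "failure",
                         shape_class = "n/a", provenance = "failure")
        built$labels <- rbind(built$labels, fl)
      }
      built$labels$sweep <- s
      sweeps[[s]] <- built$trace
      all_labels[[s]] <- built$labels
    }
    labels <- do.call(rbind, all_labels)
    rownames(labels) <- NULL
    list(sweeps = sweeps,
         outcomes = data.frame(sweep = seq_len(n_sweeps), outcome = outcomes,
                               shape_class = out_shape,
                               stringsAsFactors = FALSE),
         labels = labels)
  })
}

#' Construct an ROI fluorescence matrix
#'
#' @param F numeric matrix, rows = time points, columns = ROIs.
#' @param sampling_rate Hz.
#' @param roi_ids optional ROI identifiers (default column names or
#'   `roi_1..roi_k`).
#' @param roi_xy optional 2-column matrix of slice coordinates (microns).
#' @return An object of class `roi_matrix` with elements `F`,
#'   `sampling_rate`, `roi_ids`, `roi_xy`.
#' @export
roi_matrix <- function(F, sampling_rate, roi_ids = NULL, roi_xy = NULL) {
  F <- as.matrix(F)
  if (!is.numeric(F) || any(!is.finite(F)))
    stop("F must be a finite numeric matrix")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (is.null(roi_ids))
    roi_ids <- colnames(F) %||% paste0("roi_", seq_len(ncol(F)))
  colnames(F) <- roi_ids
  if (!is.null(roi_xy)) {
    roi_xy <- as.matrix(roi_xy)
    stopifnot(nrow(roi_xy) == ncol(F), ncol(roi_xy) == 2)
  }
  structure(list(F = F, sampling_rate = as.numeric(sampling_rate),
                 roi_ids = roi_ids, roi_xy = roi_xy),
            class = "roi_matrix")
}

#' @export
print.roi_matrix <- function(x, ...) {
  cat(sprintf("<roi_matrix> %d ROIs x %d frames @ %g Hz\n",
              ncol(x$F), nrow(x$F), x$sampling_rate))
  invisible(x)
}

#' Generate synthetic ROI calcium-fluorescence traces
#'
#' Each ROI is a slow baseline drift plus calcium-transient kernels
#' (fast rise, slow decay, GCaMP-like) occurring either as a Poisson
#' process (arrhythmic ROIs) or at `rhythm_period` with jitter (rhythmic
#' ROIs, chosen independently with probability `frac_rhythmic`).  After
#' `drug_onset` the transient rate is scaled by `drug_gain`, emulating a
#' bath-applied agonist that raises astrocytic calcium activity.
#'
#' @param n_roi number of ROIs.
#' @param sampling_rate Hz.
#' @param duration recording length, s.
#' @param frac_rhythmic probability an ROI is rhythmic.
#' @param rhythm_period rhythmic inter-transient period, s.
#' @param drug_onset drug application time, s, or `NULL` for none.
#' @param drug_gain multiplicative change in transient rate after
#'   `drug_onset` (1 = no change).
#' @param base_rate arrhythmic transient rate, events/s.
#' @param amp_mean,amp_cv transient amplitude distribution (lognormal).
#' @param noise_sd additive noise SD, a.u.
#' @param drift_amp slow baseline drift amplitude, a.u.
#' @param jitter_cv rhythmic period jitter CV.
#' @param seed integer seed.
#' @return A list with `roi` (an [roi_matrix()]) and `truth` (data frame:
#'   `roi_id`, `rhythmic` flag, `n_transients`, and `drug_sign`, the sign
#'   of the planted activity change: +1 when `drug_gain > 1`, -1 when
#'   `< 1`, 0 when no drug or `drug_gain = 1`).
#' @export
generate_roi_traces <- function(n_roi, sampling_rate = 5, duration = 1200,
                                frac_rhythmic = 0.13, rhythm_period = 10,
                                drug_onset = NULL, drug_gain = 1,
                                base_rate = 0.05, amp_mean = 1,
                                amp_cv = 0.3, noise_sd = 0.15,
                                drift_amp = 0.1, jitter_cv = 0.1,
                                seed = 1L) {
  if (frac_rhythmic < 0 || frac_rhythmic > 1)
    stop("frac_rhythmic must be in [0, 1]")
  if (!is.null(drug_onset) && drug_onset >= duration)
    stop("drug_onset must fall before the end of the recording")
  with_seed(stream_seed(seed, 3L), {
    fs <- sampling_rate
    n <- round(duration * fs)
    tt <- (seq_len(n) - 1) / fs
    kernel <- burst_kernel(1, 0.3, 2, fs)
    rhythmic <- stats::runif(n_roi) < frac_rhythmic
    F <- matrix(0, n, n_roi)
    n_tr <- integer(n_roi)
    gain_at <- function(t) {
      if (is.null(drug_onset)) 1 else ifelse(t >= drug_onset, drug_gain, 1)
    }
    for (r in seq_len(n_roi)) {
      if (rhythmic[r]) {
        gaps <- abs(stats::rnorm(ceiling(duration / rhythm_period) + 10,
                                 rhythm_period, jitter_cv * rhythm_period))
        ev <- cumsum(gaps)
        ev <- ev[ev < duration]
        # drug scales event rate by thinning/augmenting off-rhythm events
        if (!is.null(drug_onset) && drug_gain != 1) {
          post <- ev[ev >= drug_onset]
          if (drug_gain > 1) {
            extra_n <- stats::rpois(1, (drug_gain - 1) * length(post))
            ev <- c(ev, stats::runif(extra_n, drug_onset, duration))
          } else {
            keep <- stats::runif(length(ev)) < ifelse(ev >= drug_onset,
                                                      drug_gain, 1)
            ev <- ev[keep]
          }
        }
      } else {
        n_cand <- stats::rpois(1, base_rate * duration * max(1, drug_gain))
        cand <- sort(stats::runif(n_cand, 0, duration))
        p_keep <- base_rate * gain_at(cand) /
          (base_rate * max(1, drug_gain))
        ev <- cand[stats::runif(n_cand) < p_keep]
      }
      x <- numeric(n)
      for (te in ev) {
        a <- stats::rlnorm(1, log(amp_mean), amp_cv)
        x <- add_kernel(x, fs, te, kernel * a)
      }
      n_tr[r] <- length(ev)
      drift <- drift_amp * sin(2 * pi * tt / stats::runif(1, 200, 500) +
                                 stats::runif(1, 0, 2 * pi))
      F[, r] <- 1 + x + drift + stats::rnorm(n, 0, noise_sd)
    }
    ids <- paste0("roi_", seq_len(n_roi))
    xy <- cbind(x = stats::runif(n_roi, 0, 580),
                y = stats::runif(n_roi, 0, 580))
    drug_sign <- if (is.null(drug_onset) || drug_gain == 1) 0L
      else if (drug_gain > 1) 1L else -1L
    list(roi = roi_matrix(F, fs, ids, xy),
         truth = data.frame(roi_id = ids, rhythmic = rhythmic,
                            n_transients = n_tr,
                            drug_sign = rep(drug_sign, n_roi),
                            stringsAsFactors = FALSE))
  })
}

#' Write and read ROI matrices as delimited text
#'
#' The data file is tab-separated with a `time_s` column and one column
#' per ROI; a YAML sidecar stores the sampling rate; coordinates, when
#' present, go to `<path>.xy.tsv`.
#'
#' @param roi an [roi_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_matrix <- function(roi, path) {
  df <- data.frame(time_s = (seq_len(nrow(roi$F)) - 1) / roi$sampling_rate)
  df <- cbind(df, as.data.frame(roi$F))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(sampling_rate = roi$sampling_rate), paste0(path, ".yaml"))
  if (!is.null(roi$roi_xy)) {
    xy <- data.frame(roi_id = roi$roi_ids, x = roi$roi_xy[, 1],
                     y = roi$roi_xy[, 2])
    utils::write.table(xy, paste0(path, ".xy.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_roi_matrix
#' @param sampling_rate optional override when no sidecar exists.
#' @export
read_roi_matrix <- function(path, sampling_rate = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  side_path <- paste0(path, ".yaml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else list()
  sr <- sampling_rate %||% side$sampling_rate
  if (is.null(sr)) {
    dt <- diff(df$time_s)
    sr <- 1 / dt[1]
  }
  F <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  xy_path <- paste0(path, ".xy.tsv")
  xy <- NULL
  if (file.exists(xy_path)) {
    xyd <- utils::read.table(xy_path, header = TRUE, sep = "\t")
    xy <- as.matrix(xyd[, c("x", "y")])
  }
  roi_matrix(F, sr, colnames(F), xy)
}

#' Write an event-label table as delimited text
#'
#' @param labels data frame of event labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
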