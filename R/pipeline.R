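#' Detect, featurize and classify evoked sweeps end to end
#'
#' Runs the full evoked-burst pipeline over a collection of stimulation
#' sweeps: burst detection and artifact rejection per sweep, feature
#' and shape extraction, identification of the evoked burst (the burst
#' whose onset falls within `tol` of the stimulus), pooling of all
#' other bursts as the spontaneous set, prior fitting on the
#' spontaneous set only, and dual-gate classification of the evoked
#' bursts (see [classify_evoked()]).
#'
#' @param sweeps list of [sigh_trace()] sweeps.
#' @param stim_time stimulus onset within each sweep, s.
#' @param tol evoked-burst search half-window around the stimulus, s.
#' @param shape_window burst shape length, s.
#' @param var_explained,support_fraction,n_restarts,seed,amp_quantile
#'   classifier settings (see [fit_shape_prior()], [classify_evoked()]).
#' @param detect_args named list of overrides for [detect_bursts()].
#' @param spontaneous extra spontaneous material pooled into the prior:
#'   a list with elements `shapes` and `features` (optional).
#' @return A list: `evoked` (data frame: sweep, onset/peak/features,
#'   classifier outputs, `label` in eupnea/sigh_attempt/failure),
#'   `shape_prior`, `feature_prior`, `n_spontaneous`.
#' @export
classify_evoked_sweeps <- function(sweeps, stim_time, tol = 1,
                                   shape_window = 1.5,
                                   var_explained = 0.95,
                                   support_fraction = 0.75,
                                   n_restarts = 500, seed = 1L,
                                   amp_quantile = 0.9,
                                   detect_args = list(),
                                   spontaneous = NULL) {
  spont_shapes <- list(); spont_feats <- list(); spont_amps <- list()
  evoked_rows <- list()
  # one detection threshold for the whole recording: sweeps are acquired
  # continuously, so the SD is pooled over all of them
  if (is.null(detect_args$sd_value))
    detect_args$sd_value <-
      stats::sd(unlist(lapply(sweeps, `[[`, "samples")))
  for (s in seq_along(sweeps)) {
    tr <- sweeps[[s]]
    b <- do.call(detect_bursts, c(list(trace = tr), detect_args))
    if (!nrow(b)) {
      evoked_rows[[s]] <- data.frame(sweep = s, onset_s = NA_real_,
                                     evoked = FALSE)
      next
    }
    b <- reject_artifacts(b)
    b <- compute_features(tr, b)
    keep <- !b$artifact
    b <- b[keep, , drop = FALSE]
    shp <- burst_shapes(tr, b, window = shape_window)
    is_evoked <- b$onset_s >= stim_time - tol & b$onset_s <= stim_time + tol
    if (any(is_evoked)) {
      # nearest onset to the stimulus wins if several qualify
      cand <- which(is_evoked)
      ev <- cand[which.min(abs(b$onset_s[cand] - stim_time))]
      is_evoked <- seq_len(nrow(b)) == ev
    }
    spont_shapes[[s]] <- shp[!is_evoked, , drop = FALSE]
    spont_feats[[s]] <- b[!is_evoked,
                          c("feat_amplitude", "fwhm_s",
                            "post_burst_interval_s"), drop = FALSE]
    spont_amps[[s]] <- b$feat_amplitude[!is_evoked]
    if (any(is_evoked)) {
      i <- which(is_evoked)
      evoked_rows[[s]] <- cbind(
        data.frame(sweep = s, evoked = TRUE),
        b[i, c("onset_s", "peak_s", "feat_amplitude", "fwhm_s",
               "post_burst_interval_s"), drop = FALSE],
        shape_row = I(list(shp[i, ])))
    } else {
      evoked_rows[[s]] <- data.frame(sweep = s, evoked = FALSE,
                                     onset_s = NA_real_,
                                     peak_s = NA_real_,
                                     feat_amplitude = NA_real_,
                                     fwhm_s = NA_real_,
                                     post_burst_interval_s = NA_real_)
    }
  }
  S <- do.call(rbind, spont_shapes)
  Fm <- as.matrix(do.call(rbind, spont_feats))
  amps <- unlist(spont_amps)
  if (!is.null(spontaneous)) {
    S <- rbind(S, spontaneous$shapes)
    Fm <- rbind(Fm, as.matrix(spontaneous$features))
    amps <- c(amps, spontaneous$features[, 1])
  }
  ok_feat <- stats::complete.cases(Fm)
  shape_prior <- fit_shape_prior(S, var_explained = var_explained,
                                 support_fraction = support_fraction,
                                 n_restarts = n_restarts, seed = seed)
  feature_prior <- fit_feature_prior(Fm[ok_feat, , drop = FALSE],
                                     support_fraction = support_fraction,
                                     n_restarts = n_restarts,
                                     seed = seed + 1L)
  ev <- do.call(rbind, lapply(evoked_rows, function(r) {
    r[, intersect(c("sweep", "evoked", "onset_s", "peak_s",
                    "feat_amplitude", "fwhm_s", "post_burst_interval_s"),
                  names(r)), drop = FALSE]
  }))
  has_burst <- ev$evoked
  lab <- rep("failure", nrow(ev))
  if (any(has_burst)) {
    shp_m <- do.call(rbind, lapply(evoked_rows[has_burst],
                                   function(r) r$shape_row[[1]]))
    fm <- as.matrix(ev[has_burst, c("feat_amplitude", "fwhm_s",
                                    "post_burst_interval_s")])
    cls <- classify_evoked(shape_prior, feature_prior, amps, shp_m, fm,
                           amp_quantile = amp_quantile)
    lab[has_burst] <- cls$label
    for (cc in c("d_shape", "d_features", "shape_outlier",
                 "feature_outlier", "amp_pass"))
      ev[[cc]] <- NA
    ev[has_burst, c("d_shape", "d_features")] <-
      cls[, c("d_shape", "d_features")]
    ev[has_burst, c("shape_outlier", "feature_outlier", "amp_pass")] <-
      cls[, c("shape_outlier", "feature_outlier", "amp_pass")]
  }
  ev$label <- lab
  rownames(ev) <- NULL
  list(evoked = ev, shape_prior = shape_prior,
       feature_prior = feature_prior, n_spontaneous = length(amps))
}

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "sighsort_run",
    simulate = NULL,   # list(kind = "population"|"emg"|"sweeps"|"roi", ...)
    detect = NULL,     # list(prominence_factor = 2.5, ...)
    features = NULL,   # list(onset_frac = 0.2)
    epochs = NULL,     # data frame name/start_s/end_s or list thereof
    classify = NULL,   # list(stim_time = , tol = , ...)
    classify_invivo = NULL, # list(k = 6, n_neighbors = 20)
    calcium = NULL     # list(windows = c(1,2,5,10), baseline_window=, drug_window=, sigh_times=)
  )
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages — simulate, detect (+ artifact
#' rejection + features), epoch summaries, evoked classification, in
#' vivo sigh labeling, calcium analysis — writing each stage's table to
#' `out_dir` as tab-delimited text plus a JSON manifest (package
#' version, seed, full configuration) so a rerun with the same manifest
#' reproduces the outputs bit-identically.
#'
#' @param config nested named list (see Details), or a path to a YAML
#'   file holding one. Unknown keys are an error.
#' @return Invisibly, a list with the stage results and the output
#'   directory.
#' @details Recognized top-level keys: `seed`, `out_dir`, `simulate`,
#'   `detect`, `features`, `epochs`, `classify`, `classify_invivo`,
#'   `calcium`. `simulate$kind` selects the generator; `detect$trace`
#'   may name a file to analyse instead of the simulated trace.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(default_config(), config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list(out_dir = out)
  seed <- as.integer(cfg$seed %||% 1L)

  trace <- NULL; labels <- NULL
  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    kind <- sim_cfg$kind %||% "population"
    pargs <- sim_cfg[setdiff(names(sim_cfg), "kind")]
    pargs$seed <- pargs$seed %||% seed
    if (kind == "population") {
      sim <- generate_population_trace(do.call(synth_params, pargs))
      trace <- sim$trace; labels <- sim$labels
      write_trace(trace, file.path(out, "trace.tsv"),
                  meta = list(seed = seed))
      write_labels(labels, file.path(out, "labels.tsv"))
    } else if (kind == "emg") {
      sim <- generate_emg_trace(do.call(emg_params, pargs))
      trace <- sim$trace; labels <- sim$labels
      write_trace(trace, file.path(out, "trace.tsv"),
                  meta = list(seed = seed))
      write_labels(labels, file.path(out, "labels.tsv"))
    } else if (kind == "sweeps") {
      stim <- pargs$stim_time %||% 10
      sw_args <- pargs[intersect(names(pargs),
                                 c("n_sweeps", "stim_time", "p_eupnea",
                                   "p_sigh", "sweep_duration"))]
      p_args <- pargs[setdiff(names(pargs), names(sw_args))]
      sim <- do.call(generate_evoked_sweeps,
                     c(list(params = do.call(synth_params, p_args)),
                       sw_args))
      res$sweeps <- sim
      write_labels(sim$outcomes, file.path(out, "sweep_outcomes.tsv"))
    } else if (kind == "roi") {
      sim <- do.call(generate_roi_traces, pargs)
      res$roi_sim <- sim
      write_roi_matrix(sim$roi, file.path(out, "roi.tsv"))
      write_labels(sim$truth, file.path(out, "roi_truth.tsv"))
    } else stop("unknown simulate kind: ", kind)
    res$simulate <- sim
  }

  if (!is.null(cfg$detect)) {
    dargs <- cfg$detect
    if (!is.null(dargs$trace)) {
      trace <- read_trace(dargs$trace)
      dargs$trace <- NULL
    }
    if (is.null(trace)) stop("detect stage: no trace available")
    b <- do.call(detect_bursts, c(list(trace = trace), dargs))
    b <- reject_artifacts(b)
    fargs <- cfg$features %||% list()
    b <- do.call(compute_features, c(list(trace = trace, bursts = b),
                                     fargs))
    utils::write.table(b, file.path(out, "bursts.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    res$bursts <- b
  }

  if (!is.null(cfg$epochs) && !is.null(res$bursts)) {
    ep <- as.data.frame(do.call(rbind, lapply(cfg$epochs, as.data.frame)))
    lb <- label_spontaneous_sighs(res$bursts[!res$bursts$artifact, ])
    summ <- summarize_epochs(lb, ep)
    utils::write.table(summ, file.path(out, "epoch_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    res$epochs <- summ
  }

  if (!is.null(cfg$classify)) {
    if (is.null(res$sweeps)) stop("classify stage needs simulated sweeps")
    cargs <- cfg$classify
    cargs$seed <- cargs$seed %||% seed
    cl <- do.call(classify_evoked_sweeps,
                  c(list(sweeps = res$sweeps$sweeps), cargs))
    utils::write.table(cl$evoked, file.path(out, "evoked_labels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_prior(cl$shape_prior, file.path(out, "shape_prior.json"))
    write_prior(cl$feature_prior, file.path(out, "feature_prior.json"))
    res$classify <- cl
  }

  if (!is.null(cfg$classify_invivo) && !is.null(res$bursts)) {
    iargs <- cfg$classify_invivo
    keep <- !res$bursts$artifact
    lab <- do.call(classify_sighs_invivo,
                   c(list(bursts = res$bursts[keep, ]), iargs))
    utils::write.table(lab, file.path(out, "invivo_labels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    res$invivo <- lab
  }

  if (!is.null(cfg$calcium)) {
    if (is.null(res$roi_sim)) stop("calcium stage needs simulated ROIs")
    roi <- preprocess_roi(res$roi_sim$roi)
    ca <- cfg$calcium
    rhythm <- roi_rhythmicity(roi,
                              max_lag_s = ca$max_lag_s %||% NULL)
    tabs <- list(rhythmicity = rhythm)
    if (!is.null(ca$baseline_window) && !is.null(ca$drug_window)) {
      pd <- vapply(seq_len(ncol(roi$Fz)), function(j)
        activity_change(roi$Fz[, j], roi$sampling_rate,
                        unlist(ca$baseline_window),
                        unlist(ca$drug_window))$percent_diff, 0)
      tabs$activity <- data.frame(roi_id = roi$roi_ids,
                                  percent_diff = pd)
    }
    if (!is.null(ca$sigh_times)) {
      tabs$sta <- sigh_triggered_batch(roi, unlist(ca$sigh_times),
                                       windows = unlist(ca$windows %||%
                                                          c(1, 2, 5, 10)))
    }
    for (nm in names(tabs))
      utils::write.table(tabs[[nm]],
                         file.path(out, paste0("calcium_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    res$calcium <- tabs
  }

  manifest <- list(package = "sighsort",
                   version = as.character(utils::packageVersion("sighsort")),
                   seed = seed, config = cfg,
                   created = "run manifest")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(res)
}
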