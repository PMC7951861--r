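# End-to-end orchestration: preprocess -> detect -> sort -> respond ->
# characterize, with declarative configuration and deterministic CSV/JSON
# outputs.

#' Default pipeline configuration
#'
#' A nested list mirroring the stage functions' arguments.  Every
#' experimental parameter (response windows, 3x rate ratio, 10-of-20 trial
#' rule, 25 ms cathodic width, amplitude grid) surfaces as a named key.
#'
#' @return nested list of class `pipeline_config`.
#' @seealso [read_pipeline_config()], [run_pipeline()]
#' @export
pipeline_config <- function() {
  structure(list(
    preprocess = list(k_art = 10, frac = 0.5, guard_s = 0.002),
    detection = list(wavelet = "haar", levels = 2, subband = "approx",
                     hamming_win = 11, combine = "sum", threshold = NULL,
                     refractory_s = 0.001, wf_pre = 8, wf_post = 12,
                     opt_quantile_lo = 0.95, opt_grid_size = 21,
                     opt_max_trials = 20),
    sorting = list(depth = 3, k_max = 5, sc_floor = 0.2, restarts = 10),
    response = list(pre_s = 0.1, post_s = 0.9, mode = "rate",
                    min_pass = NULL, psth_bin_s = 0.01),
    characterize = list(saturation_frac = 0.95)
  ), class = "pipeline_config")
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(base)) {
      stop_measort(paste0("unknown configuration key: ", path, key),
                   "measort_config_error")
    }
    if (is.list(base[[key]]) && !is.null(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(path, key, "."))
    } else {
      base[key] <- user[key]   # [ ] keeps explicit NULLs
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML document with any subset of the keys of [pipeline_config()];
#' unknown keys are rejected, omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  structure(merge_config(unclass(pipeline_config()), user),
            class = "pipeline_config")
}

#' Write a pipeline configuration file
#'
#' @param config a `pipeline_config`.
#' @param path output YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

detection_config_from <- function(dc, threshold = NULL) {
  detection_config(
    wavelet = dc$wavelet, levels = dc$levels, subband = dc$subband,
    hamming_win = dc$hamming_win, combine = dc$combine,
    threshold = if (is.null(threshold)) dc$threshold else threshold,
    refractory_s = dc$refractory_s, wf_pre = dc$wf_pre,
    wf_post = dc$wf_post)
}

## per-channel threshold: optimize over per-trial epochs against the
## manual-marking reference, on a grid of upper quantiles of this
## channel's combined energy
channel_threshold <- function(signal, rec, channel, cfg, dc) {
  e <- energy_trace(signal, dc)
  pos <- e[e > 0]
  if (length(pos) < 100) return(NULL)
  ## log-spaced energies from the noise bulk (95th percentile) up to the
  ## largest excursion: dense where the spike/noise crossover lives
  lo <- stats::quantile(pos, probs = cfg$opt_quantile_lo, names = FALSE)
  hi <- max(pos)
  if (hi <= lo) return(NULL)
  grid <- exp(seq(log(lo), log(hi), length.out = cfg$opt_grid_size))
  grid <- grid[-length(grid)]   # the max itself detects nothing
  if (nrow(rec$stimuli) > 0) {
    eps <- epoch_recording(rec, pre = 0.1,
                           post = min(0.9, rec$stimuli$onset_sample[1] /
                                        rec$rate - 0.1),
                           channels = channel)
    take <- unique(round(seq(1, length(eps),
                             length.out = min(cfg$opt_max_trials,
                                              length(eps)))))
    trials <- lapply(eps[take], `[[`, "samples")
  } else {
    ## no stimuli: chop the trace into 1 s pieces
    n <- length(signal)
    rate <- rec$rate
    n_tr <- min(cfg$opt_max_trials, floor(n / rate))
    trials <- lapply(seq_len(max(n_tr, 1)), function(i) {
      signal[((i - 1) * rate + 1):min(n, i * rate)]
    })
  }
  opt <- optimize_threshold(trials, grid, dc, rate = rec$rate,
                            snr_curve = FALSE)
  opt$threshold
}

#' Run the full analysis pipeline
#'
#' Executes artifact blanking, spike detection (with per-channel threshold
#' optimization unless a fixed threshold is configured), spike sorting,
#' responsiveness classification (per amplitude; a unit is responsive
#' overall if responsive at any amplitude) and characterization, writing
#' all result tables plus a run manifest to `out_dir`.  Identical
#' (input, config, seed) triples produce byte-identical outputs.  On a
#' stage failure, partially written outputs are removed and the error is
#' re-thrown with the stage name.
#'
#' @param rec an `mea_recording`, or a path to a container readable by
#'   [load_recording()].
#' @param config a `pipeline_config`, or a path to a YAML file.
#' @param out_dir output directory (created; pass `NULL` to skip writing).
#' @param seed integer seed driving the stochastic stages (K-means
#'   restarts).
#' @return invisibly, a result bundle: `mask`, `detections`, `units`
#'   (table), `verdicts` (per unit x amplitude), `unit_summary`,
#'   `layers`, `curve`, `fit` (a `voltage_response_curve` or NULL),
#'   `rasters`, `config`, `seed`.
#' @export
run_pipeline <- function(rec, config = pipeline_config(), out_dir = NULL,
                         seed = 1) {
  if (is.character(rec)) rec <- load_recording(rec)
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_recording(rec)

  stage <- "preprocess"
  result <- tryCatch({
    pp <- config$preprocess
    bl <- blank_artifacts(rec, k_art = pp$k_art, frac = pp$frac,
                          guard = pp$guard_s)
    brec <- bl$recording

    stage <- "detect"
    dcfg <- config$detection
    detections <- vector("list", nrow(brec$geometry))
    for (ch in brec$geometry$channel) {
      signal <- brec$samples[ch, ]
      thr <- dcfg$threshold
      if (is.null(thr)) {
        thr <- channel_threshold(signal, brec, ch, dcfg,
                                 detection_config_from(dcfg, threshold = 1))
      }
      detections[[ch]] <- if (is.null(thr)) {
        structure(list(indices = integer(0), times = numeric(0),
                       waveforms = matrix(0, 0, dcfg$wf_pre + dcfg$wf_post),
                       threshold = NA_real_, snr = NA_real_,
                       rate = brec$rate, wf_pre = dcfg$wf_pre,
                       wf_post = dcfg$wf_post),
                  class = "detection_result")
      } else {
        detect_channel(signal, detection_config_from(dcfg, threshold = thr),
                       rate = brec$rate)
      }
    }

    stage <- "sort"
    scfg <- config$sorting
    units <- do.call(rbind, lapply(brec$geometry$channel, function(ch) {
      sort_channel(detections[[ch]], channel = ch,
                   seed = seed + ch, depth = scfg$depth,
                   wavelet = dcfg$wavelet, k_max = scfg$k_max,
                   sc_floor = scfg$sc_floor, restarts = scfg$restarts)
    }))
    units$unit_id <- paste0("ch", units$channel, "u", units$unit)

    stage <- "respond"
    rcfg <- config$response
    unit_ids <- if (nrow(brec$stimuli) > 0) unique(units$unit_id) else
      character(0)
    rasters <- list()
    verdicts <- list()
    unit_summary <- list()
    for (uid in unit_ids) {
      sel <- units[units$unit_id == uid, ]
      r_all <- build_raster(sel$spike_time_s, brec$stimuli,
                            rate = brec$rate, pre = rcfg$pre_s,
                            post = rcfg$post_s)
      rasters[[uid]] <- r_all
      responsive_any <- FALSE
      for (A in sort(unique(brec$stimuli$amplitude_v))) {
        keep <- r_all$amplitude_v == A
        r_amp <- structure(list(trials = r_all$trials[keep],
                                amplitude_v = r_all$amplitude_v[keep],
                                trial = r_all$trial[keep],
                                pre = r_all$pre, post = r_all$post),
                           class = "raster_set")
        v <- classify_unit(r_amp, min_pass = rcfg$min_pass,
                           mode = rcfg$mode)
        verdicts[[length(verdicts) + 1]] <- data.frame(
          unit_id = uid, channel = sel$channel[1], unit = sel$unit[1],
          amplitude_v = A, n_pass = v$n_pass, n_trials = v$n_trials,
          responsive = v$responsive)
        responsive_any <- responsive_any || v$responsive
      }
      unit_summary[[length(unit_summary) + 1]] <- data.frame(
        unit_id = uid, channel = sel$channel[1], unit = sel$unit[1],
        n_spikes = nrow(sel), responsive = responsive_any)
    }
    empty_verdicts <- data.frame(
      unit_id = character(0), channel = integer(0), unit = integer(0),
      amplitude_v = numeric(0), n_pass = integer(0), n_trials = integer(0),
      responsive = logical(0))
    verdicts <- if (length(verdicts)) do.call(rbind, verdicts) else
      empty_verdicts
    unit_summary <- if (length(unit_summary)) do.call(rbind, unit_summary)
      else data.frame(unit_id = character(0), channel = integer(0),
                      unit = integer(0), n_spikes = integer(0),
                      responsive = logical(0))

    stage <- "characterize"
    stim_ch <- unique(brec$stimuli$electrode)
    layers <- if (length(stim_ch) == 1 && nrow(unit_summary) > 0) {
      layer_percentages(unit_summary, stim_ch, brec$geometry)
    } else NULL
    resp_ids <- unit_summary$unit_id[unit_summary$responsive]
    curve <- spikes_per_pulse(rasters[resp_ids])
    fit <- NULL
    if (nrow(curve) >= 4) {
      fit <- tryCatch(
        fit_voltage_curve(curve, config$characterize$saturation_frac),
        measort_error = function(e) NULL)
    }

    list(mask = bl$mask, detections = detections, units = units,
         verdicts = verdicts, unit_summary = unit_summary,
         layers = layers, curve = curve, fit = fit, rasters = rasters,
         config = config, seed = seed)
  }, measort_error = function(e) {
    stop_measort(paste0("pipeline stage '", stage, "' failed: ",
                        conditionMessage(e)), "measort_stage_error")
  })

  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir, rec)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir, rec) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop_measort(paste0("writing outputs failed: ", conditionMessage(e)),
                 "measort_stage_error")
  }
  tryCatch({
    put <- function(name) {
      p <- file.path(out_dir, name)
      written <<- c(written, p)
      p
    }
    write_artifact_mask(result$mask, put("mask.csv"))

    spikes <- do.call(rbind, lapply(seq_along(result$detections),
                                    function(ch) {
      d <- result$detections[[ch]]
      if (length(d$indices) == 0) return(NULL)
      data.frame(channel = ch, spike_sample = d$indices,
                 spike_time_s = d$times)
    }))
    if (is.null(spikes)) {
      spikes <- data.frame(channel = integer(0), spike_sample = numeric(0),
                           spike_time_s = numeric(0))
    }
    write_csv_det(spikes, put("spikes.csv"))

    chan_stats <- do.call(rbind, lapply(seq_along(result$detections),
                                        function(ch) {
      d <- result$detections[[ch]]
      data.frame(channel = ch, n_spikes = length(d$indices),
                 threshold = d$threshold, snr = d$snr)
    }))
    write_csv_det(chan_stats, put("channels.csv"))
    write_csv_det(result$units[, c("channel", "unit", "spike_sample",
                                   "spike_time_s")], put("units.csv"))
    write_csv_det(result$verdicts, put("verdicts.csv"))
    write_csv_det(result$unit_summary, put("unit_summary.csv"))
    if (!is.null(result$layers)) {
      write_csv_det(result$layers, put("layers.csv"))
    }
    write_csv_det(result$curve, put("curve.csv"))

    raster_rows <- do.call(rbind, lapply(names(result$rasters),
                                         function(uid) {
      r <- result$rasters[[uid]]
      do.call(rbind, lapply(seq_along(r$trials), function(i) {
        t <- r$trials[[i]]
        if (length(t) == 0) return(NULL)
        data.frame(unit_id = uid, trial = r$trial[i],
                   amplitude_v = r$amplitude_v[i], t_rel_s = t)
      }))
    }))
    if (is.null(raster_rows)) {
      raster_rows <- data.frame(unit_id = character(0), trial = integer(0),
                                amplitude_v = numeric(0),
                                t_rel_s = numeric(0))
    }
    write_csv_det(raster_rows, put("rasters.csv"))

    fit_json <- if (is.null(result$fit)) {
      list(fitted = FALSE)
    } else {
      list(fitted = TRUE,
           coefficients = as.list(result$fit$coefficients),
           threshold_v = result$fit$threshold_v,
           saturation_v = result$fit$saturation_v,
           rss = result$fit$rss)
    }
    jsonlite::write_json(fit_json, put("fit.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")

    cfg_path <- put("config.yaml")
    write_pipeline_config(result$config, cfg_path)
    manifest <- list(
      package = "measort",
      version = as.character(utils::packageVersion("measort")),
      seed = result$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      n_channels = nrow(rec$samples),
      n_samples = ncol(rec$samples),
      rate = rec$rate,
      n_stimuli = nrow(rec$stimuli),
      files = basename(written)
    )
    jsonlite::write_json(manifest, put("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }, error = on_fail)
  invisible(out_dir)
}
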