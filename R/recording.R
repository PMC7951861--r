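# Core data containers: electrode geometry, stimulus table, recording,
# on-disk container and epoching.
#
# Conventions used throughout the package:
#   * sample indices are 0-based; sample k occurs at time k / rate seconds
#   * voltages are in microvolts, stimulus amplitudes in volts, time in seconds
#   * stimulus onset defines t = 0 for all stimulus-relative windows

#' Rectangular MEA electrode geometry
#'
#' Builds the channel-to-position map for a rectangular electrode grid.
#' Channels are numbered 1..n in row-major order; grid indices are 0-based
#' and physical positions are `col * pitch` / `row * pitch` micrometres.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param pitch inter-electrode spacing in micrometres (default 100, the
#'   pitch of a standard 120-electrode MEA).
#' @return A data frame of class `electrode_geometry` with columns
#'   `channel`, `row`, `col`, `x_um`, `y_um` and attributes `pitch`,
#'   `n_rows`, `n_cols`.
#' @examples
#' geom <- electrode_geometry(3, 3)
#' @export
electrode_geometry <- function(n_rows, n_cols, pitch = 100) {
  stopifnot(is_count(n_rows), is_count(n_cols), n_rows >= 1, n_cols >= 1,
            pitch > 0)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  geom <- data.frame(
    channel = seq_len(n_rows * n_cols),
    row = row, col = col,
    x_um = col * pitch, y_um = row * pitch
  )
  structure(geom, pitch = pitch, n_rows = as.integer(n_rows),
            n_cols = as.integer(n_cols),
            class = c("electrode_geometry", "data.frame"))
}

validate_geometry <- function(geom) {
  if (anyDuplicated(geom$channel)) {
    stop_measort("electrode geometry has duplicate channel ids",
                 "measort_integrity_error")
  }
  pitch <- attr(geom, "pitch")
  if (!is.null(pitch)) {
    ok <- isTRUE(all.equal(geom$x_um, geom$col * pitch)) &&
      isTRUE(all.equal(geom$y_um, geom$row * pitch))
    if (!ok) {
      stop_measort("electrode positions inconsistent with row/col * pitch",
                   "measort_integrity_error")
    }
  }
  invisible(geom)
}

#' Stimulus event table
#'
#' Assembles the stimulation schedule.  Each event is a charge-balanced
#' biphasic pulse: a cathodic phase of amplitude `amplitude_v` (volts) and
#' width `cathode_width_s`, implicitly followed by an anodic phase of half
#' the amplitude and twice the width (never stored separately).
#'
#' @param onset_sample 0-based sample index of pulse onset.
#' @param electrode stimulating channel id.
#' @param amplitude_v cathodic amplitude in volts (> 0).
#' @param cathode_width_s cathodic phase duration in seconds (default 0.025).
#' @param trial 0-based repeat index within an amplitude block.
#' @return data frame with one row per event.
#' @export
stimulus_events <- function(onset_sample, electrode, amplitude_v,
                            cathode_width_s = 0.025, trial = NULL) {
  n <- length(onset_sample)
  if (is.null(trial)) trial <- seq_len(n) - 1L
  stim <- data.frame(
    onset_sample = as.numeric(onset_sample),
    electrode = as.integer(electrode),
    amplitude_v = as.numeric(amplitude_v),
    cathode_width_s = as.numeric(cathode_width_s),
    trial = as.integer(trial)
  )
  if (any(stim$amplitude_v <= 0)) {
    stop_measort("stimulus amplitudes must be positive",
                 "measort_integrity_error")
  }
  stim
}

empty_stimuli <- function() {
  data.frame(onset_sample = numeric(0), electrode = integer(0),
             amplitude_v = numeric(0), cathode_width_s = numeric(0),
             trial = integer(0))
}

#' Multi-channel MEA recording
#'
#' The central container: a channels-by-samples voltage matrix plus the
#' sampling rate, the electrode geometry and the stimulus event table.
#'
#' @param samples numeric matrix, channels x samples, microvolts.  Row `i`
#'   is geometry channel `i`.
#' @param rate sampling frequency in Hz (> 0; the reference acquisition
#'   system runs at 10 kHz per channel).
#' @param geometry an [electrode_geometry()].
#' @param stimuli stimulus event table (see [stimulus_events()]); may be
#'   empty for spontaneous recordings.
#' @return object of class `mea_recording`.
#' @export
mea_recording <- function(samples, rate, geometry, stimuli = empty_stimuli()) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  rec <- structure(
    list(samples = samples, rate = rate, geometry = geometry,
         stimuli = stimuli),
    class = "mea_recording"
  )
  validate_recording(rec)
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat(sprintf("  geometry: %d x %d grid, pitch %g um\n",
              attr(x$geometry, "n_rows"), attr(x$geometry, "n_cols"),
              attr(x$geometry, "pitch")))
  cat(sprintf("  stimuli: %d events", nrow(x$stimuli)))
  if (nrow(x$stimuli) > 0) {
    cat(sprintf(" (amplitudes %s V)",
                paste(format(sort(unique(x$stimuli$amplitude_v))),
                      collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Validate a recording's invariants
#'
#' Checks matrix shape, positive rate, geometry consistency and that every
#' stimulus onset falls inside the recording.
#'
#' @param rec an `mea_recording`.
#' @return the recording, invisibly usable in pipelines.
#' @export
validate_recording <- function(rec) {
  if (!is.matrix(rec$samples) || !is.numeric(rec$samples)) {
    stop_measort("samples must be a numeric channels x samples matrix",
                 "measort_integrity_error")
  }
  if (!is.numeric(rec$rate) || length(rec$rate) != 1 || rec$rate <= 0) {
    stop_measort("sampling rate must be a single positive number",
                 "measort_integrity_error")
  }
  validate_geometry(rec$geometry)
  if (nrow(rec$samples) != nrow(rec$geometry)) {
    stop_measort(sprintf(
      "recording has %d channels but geometry describes %d",
      nrow(rec$samples), nrow(rec$geometry)), "measort_integrity_error")
  }
  n <- ncol(rec$samples)
  st <- rec$stimuli
  if (nrow(st) > 0) {
    if (any(st$onset_sample < 0 | st$onset_sample >= n)) {
      stop_measort("stimulus onsets outside [0, n_samples)",
                   "measort_integrity_error")
    }
    if (!all(st$electrode %in% rec$geometry$channel)) {
      stop_measort("stimulating electrode not present in geometry",
                   "measort_integrity_error")
    }
  }
  rec
}

## ---------------------------------------------------------------------------
## On-disk container: a directory of plain-text files.
##   meta.json                rate, pitch, grid shape, n_samples
##   geometry.csv             channel,row,col,x_um,y_um
##   stimuli.csv              onset_sample,electrode,amplitude_v,cathode_width_s,trial
##   channels/ch_<id>.csv     sample_index,microvolts
## Numbers are written with 17 significant digits, so load(save(x)) is
## bitwise lossless.

#' Write a recording to the plain-text container
#'
#' @param rec an `mea_recording`; refused if any sample is NA/NaN.
#' @param path directory to create (overwritten if it already exists).
#' @return `path`, invisibly.
#' @seealso [load_recording()]
#' @export
save_recording <- function(rec, path) {
  validate_recording(rec)
  if (anyNA(rec$samples) || any(!is.finite(rec$samples))) {
    stop_measort("refusing to write recording with NA/NaN/Inf samples",
                 "measort_integrity_error")
  }
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok) stop_measort(paste("cannot create", path), "measort_io_error")
  dir.create(file.path(path, "channels"), showWarnings = FALSE)

  meta <- list(rate = rec$rate, pitch = attr(rec$geometry, "pitch"),
               n_rows = attr(rec$geometry, "n_rows"),
               n_cols = attr(rec$geometry, "n_cols"),
               n_samples = ncol(rec$samples))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_csv_det(as.data.frame(rec$geometry), file.path(path, "geometry.csv"),
                digits = 17)
  write_csv_det(rec$stimuli, file.path(path, "stimuli.csv"), digits = 17)
  idx <- seq_len(ncol(rec$samples)) - 1L
  for (ch in rec$geometry$channel) {
    write_csv_det(
      data.frame(sample_index = idx, microvolts = rec$samples[ch, ]),
      file.path(path, "channels", sprintf("ch_%03d.csv", ch)), digits = 17)
  }
  invisible(path)
}

#' Read a recording from the plain-text container
#'
#' @param path directory written by [save_recording()] (or assembled by
#'   hand in the same dialect).
#' @return an `mea_recording`.
#' @export
load_recording <- function(path) {
  need <- c("meta.json", "geometry.csv", "stimuli.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop_measort(paste0("container is missing ", f),
                   "measort_format_error")
    }
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  gdf <- utils::read.csv(file.path(path, "geometry.csv"))
  geom <- structure(gdf, pitch = meta$pitch,
                    n_rows = as.integer(meta$n_rows),
                    n_cols = as.integer(meta$n_cols),
                    class = c("electrode_geometry", "data.frame"))
  stim <- utils::read.csv(file.path(path, "stimuli.csv"))
  if (nrow(stim) == 0) {
    stim <- empty_stimuli()
  } else {
    stim$onset_sample <- as.numeric(stim$onset_sample)
    stim$amplitude_v <- as.numeric(stim$amplitude_v)
    stim$cathode_width_s <- as.numeric(stim$cathode_width_s)
    stim$electrode <- as.integer(stim$electrode)
    stim$trial <- as.integer(stim$trial)
  }

  files <- file.path(path, "channels",
                     sprintf("ch_%03d.csv", geom$channel))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop_measort(paste0("container is missing ",
                        paste(basename(files[missing]), collapse = ", ")),
                 "measort_format_error")
  }
  traces <- lapply(files, function(f) utils::read.csv(f)$microvolts)
  lens <- lengths(traces)
  if (length(unique(lens)) != 1) {
    stop_measort("channel traces have inconsistent lengths",
                 "measort_integrity_error")
  }
  samples <- do.call(rbind, traces)
  mea_recording(samples, as.numeric(meta$rate), geom, stim)
}

#' Cut stimulus-aligned epochs from a recording
#'
#' Slices `[-pre, +post]` second windows around every stimulus onset, per
#' channel.  t = 0 is the onset sample; each epoch holds
#' `(pre + post) * rate + 1` samples.
#'
#' @param rec an `mea_recording` with at least one stimulus.
#' @param pre,post window extent in seconds before/after onset.  Defaults
#'   0.1 s pre and 0.9 s post, the windows used for raster displays; the
#'   response criteria only consume `[-0.1, 0)` and `(0, 0.3]`.
#' @param channels channels to epoch (default all).
#' @return list of epochs, each a list with `channel`, `trial`,
#'   `amplitude_v`, `onset_sample`, `window`, `t` (relative times) and
#'   `samples`.
#' @export
epoch_recording <- function(rec, pre = 0.1, post = 0.9, channels = NULL) {
  stopifnot(pre >= 0, post > 0)
  validate_recording(rec)
  if (nrow(rec$stimuli) == 0) {
    stop_measort("recording has no stimuli to epoch around",
                 "measort_epoch_error")
  }
  if (is.null(channels)) channels <- rec$geometry$channel
  n <- ncol(rec$samples)
  npre <- round(pre * rec$rate)
  npost <- round(post * rec$rate)
  onset <- rec$stimuli$onset_sample
  bad <- onset - npre < 0 | onset + npost > n - 1
  if (any(bad)) {
    stop_measort(paste0(
      "stimuli too close to the recording edge for pre=", pre, ", post=",
      post, ": events ", paste(which(bad), collapse = ", ")),
      "measort_epoch_error")
  }
  t_rel <- (seq_len(npre + npost + 1) - 1 - npre) / rec$rate
  out <- vector("list", length(channels) * nrow(rec$stimuli))
  i <- 0L
  for (ch in channels) {
    for (s in seq_len(nrow(rec$stimuli))) {
      o <- onset[s]
      i <- i + 1L
      out[[i]] <- list(
        channel = ch, trial = rec$stimuli$trial[s],
        amplitude_v = rec$stimuli$amplitude_v[s], onset_sample = o,
        window = c(-pre, post), t = t_rel,
        samples = rec$samples[ch, (o - npre + 1):(o + npost + 1)]
      )
    }
  }
  out
}
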