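# Stimulus artifact blanking.
#
# Stimulation artifacts are orders of magnitude larger than spikes and
# appear synchronously across the array.  Two rules remove them before
# detection, both by resetting samples to exactly zero:
#   1. deterministic: the pulse window [onset, onset + 3T + guard] of every
#      stimulus (cathodic phase T plus anodic phase 2T);
#   2. adaptive: any sample where at least `frac` of channels simultaneously
#      exceed `k_art` robust noise SDs, dilated by +/- guard.

#' Robust noise standard deviation (MAD estimator)
#'
#' `sigma = median(|x - median(x)|) / 0.6745`, the median absolute deviation
#' scaled to be consistent for Gaussian noise.  Insensitive to spikes that
#' occupy a small fraction of samples, unlike the raw SD.
#'
#' @param x numeric voltage series of length >= 16.
#' @return nonnegative scalar, in the units of `x`.
#' @export
robust_noise_sigma <- function(x) {
  if (length(x) < 16) {
    stop_measort("need at least 16 samples to estimate noise",
                 "measort_integrity_error")
  }
  stats::median(abs(x - stats::median(x))) / 0.6745
}

#' Blank stimulation artifacts
#'
#' @param rec an `mea_recording`.
#' @param k_art adaptive-rule amplitude multiplier (units of per-channel
#'   robust noise SD).
#' @param frac fraction of channels that must exceed `k_art * sigma`
#'   simultaneously for the adaptive rule to fire.
#' @param guard dilation around blanked intervals, seconds.
#' @return list with elements `recording` (blanked copy) and `mask` (an
#'   `artifact_mask`: logical channels x samples matrix plus an interval
#'   table `channel,start_sample,end_sample`, 0-based inclusive).
#' @export
blank_artifacts <- function(rec, k_art = 10, frac = 0.5, guard = 0.002) {
  validate_recording(rec)
  samples <- rec$samples
  n_ch <- nrow(samples)
  n <- ncol(samples)
  guard_n <- round(guard * rec$rate)
  blank <- rep(FALSE, n)   # samples blanked on all channels

  ## deterministic stimulus windows
  if (nrow(rec$stimuli) > 0) {
    for (s in seq_len(nrow(rec$stimuli))) {
      o <- rec$stimuli$onset_sample[s]
      w <- round(3 * rec$stimuli$cathode_width_s[s] * rec$rate) + guard_n
      lo <- max(0, o)
      hi <- min(n - 1, o + w)
      blank[(lo + 1):(hi + 1)] <- TRUE
    }
  }

  ## adaptive cross-channel coincidence rule
  sig <- apply(samples, 1, robust_noise_sigma)
  exceed <- abs(samples) > (k_art * sig)   # recycles sig down columns
  n_exceed <- colSums(exceed)
  ## coincidence needs at least two channels: a lone large excursion is a
  ## spike, not an artifact
  hot <- n_exceed >= max(2, frac * n_ch)
  if (any(hot)) {
    idx <- which(hot)
    for (i in idx) {
      lo <- max(1, i - guard_n)
      hi <- min(n, i + guard_n)
      blank[lo:hi] <- TRUE
    }
  }

  samples[, blank] <- 0
  mask <- matrix(blank, nrow = n_ch, ncol = n, byrow = TRUE)

  intervals <- if (any(blank)) {
    r <- rle(blank)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start_sample = starts[r$values] - 1,
                       end_sample = ends[r$values] - 1)
    do.call(rbind, lapply(seq_len(n_ch), function(ch) {
      cbind(channel = ch, runs)
    }))
  } else {
    data.frame(channel = integer(0), start_sample = numeric(0),
               end_sample = numeric(0))
  }

  out <- rec
  out$samples <- samples
  list(
    recording = out,
    mask = structure(list(mask = mask, intervals = intervals),
                     class = "artifact_mask")
  )
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d intervals, %.2f%% of samples blanked\n",
              nrow(x$intervals), 100 * mean(x$mask)))
  invisible(x)
}

#' Write an artifact mask's intervals as CSV
#'
#' One row per blanked run: `channel,start_sample,end_sample` (0-based,
#' inclusive).
#'
#' @param mask an `artifact_mask`.
#' @param path output file.
#' @export
write_artifact_mask <- function(mask, path) {
  write_csv_det(mask$intervals, path)
  invisible(path)
}
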