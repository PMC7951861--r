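# Evoked-response identification: rasters, PSTHs and the two-part
# responsiveness criterion.
#
# A unit counts as electrically responsive when
#   (1) its firing rate in the 300 ms after a stimulus exceeds 3x its rate
#       in the 100 ms before (strict inequality), and
#   (2) criterion (1) holds in at least `min_pass` of the repeated trials
#       (10 of 20 by default).
# With the fixed 0.1 s / 0.3 s windows, the rate reading of (1) reduces to
# the integer comparison n_post > 9 * n_pre, which is how it is evaluated
# (no floating-point boundary artifacts).  A count reading
# (n_post > 3 * n_pre) is available because the criterion's wording admits
# both.

#' Build a per-trial raster for one unit
#'
#' Re-references the unit's spike times to each stimulus onset and keeps
#' those in `[-pre, 0) U (0, post]` (the onset sample itself is excluded;
#' it is blanked anyway).
#'
#' @param spike_times unit spike times in seconds, ascending.
#' @param stimuli stimulus event table (see [stimulus_events()]).
#' @param rate sampling rate used to convert onset samples to seconds.
#' @param pre,post raster window, seconds (must cover the response windows:
#'   `pre >= 0.1`, `post >= 0.3`).
#' @return object of class `raster_set`: `trials` (list of numeric vectors,
#'   one per stimulus, in stimulus order), `amplitude_v`, `trial`, `pre`,
#'   `post`.
#' @export
build_raster <- function(spike_times, stimuli, rate = 10000,
                         pre = 0.1, post = 0.9) {
  stopifnot(pre >= 0.1, post >= 0.3)
  onset_t <- stimuli$onset_sample / rate
  trials <- lapply(onset_t, function(o) {
    rel <- spike_times - o
    sort(rel[(rel >= -pre & rel < 0) | (rel > 0 & rel <= post)])
  })
  structure(list(trials = trials, amplitude_v = stimuli$amplitude_v,
                 trial = stimuli$trial, pre = pre, post = post),
            class = "raster_set")
}

#' @export
print.raster_set <- function(x, ...) {
  cat(sprintf("<raster_set> %d trials, %d spikes in [-%g, %g] s\n",
              length(x$trials), sum(lengths(x$trials)), x$pre, x$post))
  invisible(x)
}

#' Raster plot
#'
#' @param x a `raster_set`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.raster_set <- function(x, ...) {
  graphics::plot(NA, xlim = c(-x$pre, x$post),
                 ylim = c(0.5, length(x$trials) + 0.5),
                 xlab = "time from stimulus (s)", ylab = "trial", ...)
  for (i in seq_along(x$trials)) {
    t <- x$trials[[i]]
    if (length(t)) graphics::segments(t, i - 0.4, t, i + 0.4)
  }
  graphics::abline(v = 0, col = "red", lty = 2)
  invisible(x)
}

#' Post-stimulus time histogram
#'
#' Total spike counts per time bin over all trials of a raster.  Bin counts
#' always sum to the raster's in-window spike count.
#'
#' @param raster a `raster_set`.
#' @param bin bin width, seconds (default 0.01).
#' @return data frame `left, right, count` covering `[-pre, post]`.
#' @export
psth <- function(raster, bin = 0.01) {
  stopifnot(bin > 0)
  breaks <- seq(-raster$pre, raster$post, by = bin)
  if (breaks[length(breaks)] < raster$post) {
    breaks <- c(breaks, breaks[length(breaks)] + bin)
  }
  t <- unlist(raster$trials)
  counts <- if (length(t) == 0) {
    integer(length(breaks) - 1)
  } else {
    ## right-closed bins so spikes at exactly `post` are kept
    tabulate(findInterval(t, breaks, left.open = TRUE, all.inside = TRUE),
             nbins = length(breaks) - 1)
  }
  data.frame(left = breaks[-length(breaks)], right = breaks[-1],
             count = counts)
}

#' Single-trial responsiveness criterion
#'
#' @param n_pre spike count in `[-0.1, 0)`.
#' @param n_post spike count in `(0, 0.3]`.
#' @param mode `"rate"` compares firing rates over the fixed windows,
#'   equivalent to `n_post > 9 * n_pre`; `"count"` compares raw counts,
#'   `n_post > 3 * n_pre`.  Both inequalities are strict.
#' @return logical, vectorized over `n_pre`/`n_post`.
#' @export
trial_passes <- function(n_pre, n_post, mode = c("rate", "count")) {
  mode <- match.arg(mode)
  if (mode == "rate") n_post > 9 * n_pre else n_post > 3 * n_pre
}

#' Classify a unit as responsive or not
#'
#' Applies [trial_passes()] to every trial of the raster (spike counts in
#' the fixed windows `[-0.1, 0)` and `(0, 0.3]`) and calls the unit
#' responsive when at least `min_pass` trials pass.
#'
#' @param raster a `raster_set` with at least one trial.
#' @param min_pass trials required; default 10 when there are 20 trials,
#'   otherwise `ceiling(n_trials / 2)`.
#' @param mode criterion mode, see [trial_passes()].
#' @return object of class `response_verdict`: `n_pass`, `n_trials`,
#'   `responsive`, `min_pass`, and per-trial vectors `pass`, `n_pre`,
#'   `n_post`, `pre_rate_hz`, `post_rate_hz`.
#' @export
classify_unit <- function(raster, min_pass = NULL, mode = c("rate", "count")) {
  mode <- match.arg(mode)
  n_trials <- length(raster$trials)
  if (n_trials == 0) {
    stop_measort("cannot classify a unit with zero trials",
                 "measort_integrity_error")
  }
  n_pre <- vapply(raster$trials, function(t) sum(t >= -0.1 & t < 0),
                  numeric(1))
  n_post <- vapply(raster$trials, function(t) sum(t > 0 & t <= 0.3),
                   numeric(1))
  pass <- trial_passes(n_pre, n_post, mode)
  if (is.null(min_pass)) {
    min_pass <- if (n_trials == 20) 10 else ceiling(n_trials / 2)
  }
  structure(
    list(n_pass = sum(pass), n_trials = n_trials,
         responsive = sum(pass) >= min_pass, min_pass = min_pass,
         pass = pass, n_pre = n_pre, n_post = n_post,
         pre_rate_hz = n_pre / 0.1, post_rate_hz = n_post / 0.3),
    class = "response_verdict"
  )
}

#' @export
print.response_verdict <- function(x, ...) {
  cat(sprintf("<response_verdict> %s (%d/%d trials pass, need %d)\n",
              if (x$responsive) "RESPONSIVE" else "not responsive",
              x$n_pass, x$n_trials, x$min_pass))
  invisible(x)
}
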