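# Spatial and voltage characterization of evoked responses: electrode
# "layers" around the stimulation site, responsiveness per layer, mean
# evoked spikes per pulse versus amplitude, and a Boltzmann sigmoid fit
# from which the threshold and saturation voltages are read.

#' Electrode layer index around the stimulation site
#'
#' Layer k is the k-th Chebyshev ring on the grid:
#' `k = max(|row_rec - row_stim|, |col_rec - col_stim|)`.  Ring 1 is
#' exactly the 8 electrodes adjacent to the stimulation site, whose
#' Euclidean distances lie in `[pitch, pitch * sqrt(2)]` (100-141.4 um at
#' 100 um pitch); ring k spans `[k * pitch, k * pitch * sqrt(2)]`.
#' k = 0 is the stimulation electrode itself.
#'
#' @param stim,rec channel ids of the stimulating and recording electrode.
#' @param geom an [electrode_geometry()].
#' @return integer layer index.
#' @export
layer_index <- function(stim, rec, geom) {
  i <- match(stim, geom$channel)
  j <- match(rec, geom$channel)
  if (is.na(i) || is.na(j)) {
    stop_measort("unknown channel id", "measort_integrity_error")
  }
  max(abs(geom$row[j] - geom$row[i]), abs(geom$col[j] - geom$col[i]))
}

#' Responsiveness percentage per electrode layer
#'
#' @param units data frame with one row per unit and columns `channel` and
#'   `responsive` (logical).
#' @param stim stimulating channel id.
#' @param geom an [electrode_geometry()].
#' @return data frame `layer, n_units, n_responsive, percentage`, layers
#'   `>= 1` that contain units, ascending.  The stimulation electrode
#'   (layer 0) is excluded.
#' @export
layer_percentages <- function(units, stim, geom) {
  stopifnot(all(c("channel", "responsive") %in% names(units)))
  layer <- vapply(units$channel, layer_index, numeric(1),
                  stim = stim, geom = geom)
  keep <- layer >= 1
  layer <- layer[keep]
  resp <- units$responsive[keep]
  if (length(layer) == 0) {
    return(data.frame(layer = integer(0), n_units = integer(0),
                      n_responsive = integer(0), percentage = numeric(0)))
  }
  agg <- stats::aggregate(resp, by = list(layer = layer), FUN = function(r) {
    c(n = length(r), resp = sum(r))
  })
  out <- data.frame(layer = agg$layer,
                    n_units = agg$x[, "n"],
                    n_responsive = agg$x[, "resp"])
  out$percentage <- 100 * out$n_responsive / out$n_units
  out[order(out$layer), ]
}

#' Mean evoked spikes per pulse by stimulus amplitude
#'
#' For each amplitude, the mean over (responsive unit x trial) of the spike
#' count in the evoked window `(0, 0.3]` seconds.  Only responsive units
#' enter the average.
#'
#' @param rasters list of `raster_set`s, one per responsive unit.
#' @return data frame `amplitude_v, mean_spikes, n_obs`, amplitudes
#'   ascending; empty when `rasters` is empty.
#' @export
spikes_per_pulse <- function(rasters) {
  if (length(rasters) == 0) {
    return(data.frame(amplitude_v = numeric(0), mean_spikes = numeric(0),
                      n_obs = integer(0)))
  }
  rows <- do.call(rbind, lapply(rasters, function(r) {
    data.frame(
      amplitude_v = r$amplitude_v,
      count = vapply(r$trials, function(t) sum(t > 0 & t <= 0.3), numeric(1))
    )
  }))
  agg <- stats::aggregate(count ~ amplitude_v, data = rows, FUN = function(x) {
    c(mean = mean(x), n = length(x))
  })
  out <- data.frame(amplitude_v = agg$amplitude_v,
                    mean_spikes = agg$count[, "mean"],
                    n_obs = as.integer(agg$count[, "n"]))
  out[order(out$amplitude_v), ]
}

#' Fit a Boltzmann sigmoid to the voltage-response curve
#'
#' Least-squares fit of
#' `y(V) = L + (U - L) / (1 + exp(-(V - V0) / s))`
#' to mean spikes-per-pulse versus cathodic amplitude
#' (Levenberg-Marquardt, initialized from the data: `L = min(y)`,
#' `U = max(y)`, `V0` = mid-range, `s` = range/10).  The threshold voltage
#' is the amplitude where the fitted curve crosses 0.5 spikes per pulse
#' (error if 0.5 lies outside the fitted plateaus); the saturation voltage
#' is the smallest tested amplitude whose fitted value reaches 95% of the
#' upper plateau (NA if none does).
#'
#' @param curve data frame with columns `amplitude_v` and `mean_spikes`
#'   (>= 4 points), e.g. from [spikes_per_pulse()].
#' @param saturation_frac fraction of the upper plateau defining
#'   saturation (default 0.95).
#' @return object of class `voltage_response_curve` with components
#'   `coefficients` (`lower`, `upper`, `v_mid`, `slope`), `threshold_v`,
#'   `saturation_v`, `rss`, `data`.  Methods: `print`, `coef`, `predict`,
#'   `plot`, `residuals`.
#' @export
fit_voltage_curve <- function(curve, saturation_frac = 0.95) {
  stopifnot(all(c("amplitude_v", "mean_spikes") %in% names(curve)))
  V <- curve$amplitude_v
  y <- curve$mean_spikes
  if (length(V) < 4) {
    stop_measort("need at least 4 amplitude points to fit",
                 "measort_fit_error")
  }
  if (is.unsorted(V)) {
    o <- order(V); V <- V[o]; y <- y[o]
  }
  if (stats::sd(y) < 1e-12) {
    stop_measort("flat response curve: sigmoid fit is degenerate",
                 "measort_fit_error")
  }
  start <- list(L = min(y), U = max(y), V0 = mean(range(V)),
                s = diff(range(V)) / 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ L + (U - L) / (1 + exp(-(V - V0) / s)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop_measort(paste0("sigmoid fit failed: ", conditionMessage(e)),
                   "measort_fit_error")
    })
  cf <- stats::coef(fit)
  L <- cf[["L"]]; U <- cf[["U"]]; V0 <- cf[["V0"]]; s <- cf[["s"]]
  rss <- sum(stats::residuals(fit)^2)

  lo <- min(L, U); hi <- max(L, U)
  if (0.5 <= lo || 0.5 >= hi) {
    stop_measort(sprintf(
      "threshold undefined: 0.5 spikes/pulse outside the fitted range [%.3g, %.3g]",
      lo, hi), "measort_threshold_error")
  }
  threshold_v <- V0 - s * log((U - L) / (0.5 - L) - 1)

  predict_v <- function(v) L + (U - L) / (1 + exp(-(v - V0) / s))
  sat_level <- L + saturation_frac * (U - L)
  sat_idx <- which(predict_v(V) >= sat_level)
  saturation_v <- if (length(sat_idx)) V[min(sat_idx)] else NA_real_

  structure(
    list(coefficients = c(lower = L, upper = U, v_mid = V0, slope = s),
         threshold_v = threshold_v, saturation_v = saturation_v,
         rss = rss, saturation_frac = saturation_frac,
         data = data.frame(amplitude_v = V, mean_spikes = y),
         fitted = predict_v(V)),
    class = "voltage_response_curve"
  )
}

#' @export
print.voltage_response_curve <- function(x, ...) {
  cf <- x$coefficients
  cat("<voltage_response_curve> Boltzmann sigmoid fit\n")
  cat(sprintf("  plateaus [%.3g, %.3g] spikes/pulse, midpoint %.3g V, slope %.3g V\n",
              cf["lower"], cf["upper"], cf["v_mid"], cf["slope"]))
  cat(sprintf("  threshold voltage (0.5 spikes/pulse): %.3g V\n",
              x$threshold_v))
  cat(sprintf("  saturation voltage (%.0f%% of upper plateau): %s\n",
              100 * x$saturation_frac,
              if (is.na(x$saturation_v)) "not reached" else
                sprintf("%.3g V", x$saturation_v)))
  cat(sprintf("  residual sum of squares: %.3g\n", x$rss))
  invisible(x)
}

#' @export
coef.voltage_response_curve <- function(object, ...) object$coefficients

#' @rdname fit_voltage_curve
#' @param object,x a fitted `voltage_response_curve`.
#' @param newdata optional numeric vector of amplitudes (volts) at which to
#'   evaluate the fitted sigmoid; default the fitted amplitudes.
#' @param ... unused.
#' @export
predict.voltage_response_curve <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$amplitude_v else as.numeric(newdata)
  cf <- object$coefficients
  cf[["lower"]] + (cf[["upper"]] - cf[["lower"]]) /
    (1 + exp(-(v - cf[["v_mid"]]) / cf[["slope"]]))
}

#' @export
residuals.voltage_response_curve <- function(object, ...) {
  object$data$mean_spikes - object$fitted
}

#' @rdname fit_voltage_curve
#' @export
plot.voltage_response_curve <- function(x, ...) {
  graphics::plot(x$data$amplitude_v, x$data$mean_spikes,
                 xlab = "cathodic amplitude (V)",
                 ylab = "mean spikes per pulse", pch = 19, ...)
  v <- seq(min(x$data$amplitude_v), max(x$data$amplitude_v), length.out = 200)
  graphics::lines(v, predict(x, v), col = "blue")
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$threshold_v, col = "red", lty = 2)
  if (!is.na(x$saturation_v)) {
    graphics::abline(v = x$saturation_v, col = "darkgreen", lty = 2)
  }
  invisible(x)
}
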