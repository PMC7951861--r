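test_that("layer index is the Chebyshev ring around the stimulation site", {
  geom <- electrode_geometry(12, 12, pitch = 100)
  ch <- function(row, col) geom$channel[geom$row == row & geom$col == col]
  expect_equal(layer_index(ch(5, 5), ch(5, 6), geom), 1)  # 100 um
  expect_equal(layer_index(ch(5, 5), ch(6, 6), geom), 1)  # 141.4 um
  expect_equal(layer_index(ch(5, 5), ch(7, 8), geom), 3)
  expect_equal(layer_index(ch(5, 5), ch(5, 5), geom), 0)
  expect_error(layer_index(999, ch(5, 5), geom),
               class = "measort_integrity_error")

  ## ring 1 holds exactly the 8 adjacent electrodes; ring-k Euclidean
  ## distances span [k * pitch, k * pitch * sqrt(2)]
  stim <- ch(5, 5)
  lay <- vapply(geom$channel, layer_index, numeric(1), stim = stim,
                geom = geom)
  expect_equal(sum(lay == 1), 8)
  d <- sqrt((geom$x_um - geom$x_um[stim])^2 + (geom$y_um - geom$y_um[stim])^2)
  for (k in 1:4) {
    expect_true(all(d[lay == k] >= k * 100 - 1e-9))
    expect_true(all(d[lay == k] <= k * 100 * sqrt(2) + 1e-9))
  }
})

test_that("layer percentages aggregate responsiveness by ring", {
  geom <- electrode_geometry(5, 5)
  stim <- geom$channel[geom$row == 2 & geom$col == 2]
  ring1 <- geom$channel[vapply(geom$channel, layer_index, numeric(1),
                               stim = stim, geom = geom) == 1]
  units <- data.frame(channel = c(ring1[1:4], stim),
                      responsive = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  out <- layer_percentages(units, stim, geom)
  expect_equal(out$percentage[out$layer == 1], 50)
  expect_equal(out$n_units[out$layer == 1], 4)
  ## the stimulation electrode itself is not a layer
  expect_false(0 %in% out$layer)

  none <- data.frame(channel = ring1, responsive = FALSE)
  expect_true(all(layer_percentages(none, stim, geom)$percentage == 0))
})

amp_raster <- function(counts_by_amp, n_trials = 20) {
  trials <- list(); amps <- numeric(0)
  for (a in names(counts_by_amp)) {
    for (i in seq_len(n_trials)) {
      trials[[length(trials) + 1]] <- rep(0.1, counts_by_amp[[a]])
      amps <- c(amps, as.numeric(a))
    }
  }
  structure(list(trials = trials, amplitude_v = amps,
                 trial = seq_along(trials) - 1, pre = 0.1, post = 0.9),
            class = "raster_set")
}

test_that("spikes per pulse averages evoked-window counts over units and trials", {
  r1 <- amp_raster(list("0.9" = 2))
  out <- spikes_per_pulse(list(r1))
  expect_equal(out$mean_spikes, 2)
  expect_equal(out$amplitude_v, 0.9)

  r2 <- amp_raster(list("0.9" = 1))
  r3 <- amp_raster(list("0.9" = 3))
  expect_equal(spikes_per_pulse(list(r2, r3))$mean_spikes, 2)

  expect_equal(nrow(spikes_per_pulse(list())), 0)

  ## Poisson counts around a known sigmoid stay within 3 standard errors
  set.seed(61)
  V <- seq(0.15, 1.65, by = 0.15)
  mu <- 3 / (1 + exp(-(V - 0.8) / 0.15))
  rasters <- lapply(1:30, function(u) {
    trials <- list(); amps <- numeric(0)
    for (i in seq_along(V)) {
      for (tr in 1:20) {
        trials[[length(trials) + 1]] <- rep(0.15, rpois(1, mu[i]))
        amps <- c(amps, V[i])
      }
    }
    structure(list(trials = trials, amplitude_v = amps,
                   trial = seq_along(trials) - 1, pre = 0.1, post = 0.9),
              class = "raster_set")
  })
  out <- spikes_per_pulse(rasters)
  se <- sqrt(mu / (30 * 20))
  expect_true(all(abs(out$mean_spikes - mu) <= 3 * se + 1e-12))
})

test_that("sigmoid fitting recovers noiseless parameters and flags degeneracy", {
  V <- seq(0.15, 1.65, by = 0.15)
  y <- 3 / (1 + exp(-(V - 0.8) / 0.15))
  fit <- fit_voltage_curve(data.frame(amplitude_v = V, mean_spikes = y))
  expect_lt(abs(coef(fit)[["v_mid"]] - 0.8), 1e-3)
  true_cross <- 0.8 - 0.15 * log(3 / 0.5 - 1)
  expect_lt(abs(fit$threshold_v - true_cross), 1e-3)
  expect_equal(predict(fit, V), y, tolerance = 1e-6)
  expect_equal(fit$saturation_v, 1.35)

  flat <- data.frame(amplitude_v = V, mean_spikes = rep(0, length(V)))
  expect_error(fit_voltage_curve(flat), class = "measort_fit_error")

  ## 0.5 below both plateaus -> threshold undefined
  high <- data.frame(amplitude_v = V,
                     mean_spikes = 2 + 3 / (1 + exp(-(V - 0.8) / 0.15)))
  expect_error(fit_voltage_curve(high), class = "measort_threshold_error")

  expect_error(fit_voltage_curve(data.frame(amplitude_v = V[1:3],
                                            mean_spikes = y[1:3])),
               class = "measort_fit_error")
})
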