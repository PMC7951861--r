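test_that("simulation is deterministic and respects its degenerate limits", {
  cfg <- synth_config(grid = c(2, 2), n_units = 1, amplitudes_v = c(0.6),
                      n_trials = 3, seed = 71)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$spikes, b$truth$spikes)

  ## no background, no noise, no responsive units -> artifacts only
  cfg0 <- synth_config(grid = c(2, 2), n_units = 1, background_rate_hz = 0,
                       noise_sd_uv = 0, resp_layer1 = 0,
                       amplitudes_v = c(0.6), n_trials = 2, seed = 72)
  sim0 <- simulate_recording(cfg0)
  expect_equal(nrow(sim0$truth$spikes), 0)
  rate <- cfg0$rate
  Tn <- round(cfg0$cathode_width_s * rate)
  art <- rep(FALSE, ncol(sim0$recording$samples))
  for (o in sim0$recording$stimuli$onset_sample) {
    art[(o + 1):(o + 3 * Tn)] <- TRUE
  }
  expect_true(all(sim0$recording$samples[, !art] == 0))
  expect_true(all(sim0$recording$samples[, art] != 0))

  expect_error(synth_config(), class = "measort_integrity_error")
})

test_that("background spike counts concentrate at rate x duration", {
  cfg <- synth_config(grid = c(1, 1), n_units = 1, background_rate_hz = 5,
                      noise_sd_uv = 0, amplitudes_v = numeric(0),
                      duration_s = 100, seed = 73)
  sim <- simulate_recording(cfg)
  n <- nrow(sim$truth$spikes)
  expect_lt(abs(n - 500), 3 * sqrt(500))
  ## spike trains respect the enforced refractory gap
  expect_true(all(diff(sort(sim$truth$spikes$time_s)) >= 0.002 - 1e-9))
})

test_that("detection scoring implements greedy one-to-one matching", {
  perfect <- score_detection(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  empty <- score_detection(c(0.1, 0.2), numeric(0))
  expect_equal(empty$recall, 0)

  half <- score_detection(c(0.1, 0.2), c(0.1, 0.5))
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)

  ## one truth spike cannot absorb two detections
  dbl <- score_detection(0.1, c(0.0999, 0.1001))
  expect_equal(dbl$n_matched, 1)
})

test_that("sorting accuracy maximizes over label permutations", {
  expect_equal(score_sorting(c(1, 1, 2, 2), c(2, 2, 1, 1))$accuracy, 1)

  ## random balanced labels agree at about chance
  set.seed(74)
  acc <- score_sorting(sample(1:2, 2000, TRUE), sample(1:2, 2000, TRUE))
  expect_lt(abs(acc$accuracy - 0.5), 0.06)

  ## a split cluster scores its majority fraction
  split <- score_sorting(rep(1, 10), c(rep(1, 7), rep(2, 3)))
  expect_equal(split$accuracy, 0.7)
})

test_that("response scoring counts the confusion table", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  perfect <- score_response(truth, truth)
  expect_equal(unname(perfect[c("FP", "FN")]), c(0, 0))
  allneg <- score_response(truth, rep(FALSE, 5))
  expect_equal(unname(allneg["FN"]), 3)
  expect_equal(unname(allneg["TN"]), 2)
  expect_equal(unname(allneg[["specificity"]]), 1)
})

test_that("strongly evoked units are reliably flagged through the raster path", {
  ## raster-level check: evoked counts ~ Poisson(3), background 1 Hz
  set.seed(75)
  hits <- 0
  for (rep in 1:20) {
    n_pre <- rpois(20, 1 * 0.1)
    n_post <- rpois(20, 3 + 1 * 0.3)
    trials <- Map(function(a, b) c(rep(-0.05, a), rep(0.1, b)),
                  n_pre, n_post)
    r <- structure(list(trials = trials, amplitude_v = rep(1.05, 20),
                        trial = 0:19, pre = 0.1, post = 0.9),
                   class = "raster_set")
    hits <- hits + classify_unit(r)$responsive
  }
  expect_gte(hits / 20, 0.9)
})
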