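make_stim <- function(n_trials = 20, rate = 10000, gap = 1,
                      amplitude = 1.05) {
  stimulus_events(onset_sample = rate * gap * seq_len(n_trials),
                  electrode = 1, amplitude_v = amplitude,
                  trial = seq_len(n_trials) - 1)
}

test_that("rasters re-reference spikes to the stimulus and clip the window", {
  stim <- make_stim(3)
  ## one spike 50 ms after the second stimulus
  r <- build_raster(2.05, stim)
  expect_length(r$trials, 3)
  expect_equal(r$trials[[2]], 0.05)
  expect_length(r$trials[[1]], 0)

  ## outside the window -> excluded; exactly at onset -> excluded
  r2 <- build_raster(c(2 - 0.2, 2, 2 + 0.95), stim)
  expect_length(r2$trials[[2]], 0)

  ## 20 stimuli -> 20 rows even with no spikes at all
  r3 <- build_raster(numeric(0), make_stim(20))
  expect_length(r3$trials, 20)
})

test_that("PSTH conserves spike counts", {
  stim <- make_stim(20)
  ## one spike 55 ms after each of the 20 stimuli: a single 10 ms bin
  r <- build_raster(rep(1:20, each = 1) + 0.055, stim)
  h <- psth(r, bin = 0.01)
  expect_equal(sum(h$count), 20)
  expect_equal(max(h$count), 20)
  expect_lt(abs(h$left[which.max(h$count)] - 0.05), 1e-9)

  expect_equal(sum(psth(build_raster(numeric(0), stim))$count), 0)

  set.seed(51)
  for (i in 1:5) {
    spikes <- sort(runif(100, 0, 21))
    r <- build_raster(spikes, stim)
    expect_equal(sum(psth(r, bin = 0.013)$count), sum(lengths(r$trials)))
  }
})

test_that("the single-trial criterion is the strict 3x rate rule", {
  expect_true(trial_passes(0, 1))
  expect_false(trial_passes(1, 9))    # 30 Hz vs 30 Hz: not MORE than
  expect_true(trial_passes(1, 10))
  expect_false(trial_passes(0, 0))
  ## count mode
  expect_true(trial_passes(1, 4, mode = "count"))
  expect_false(trial_passes(1, 3, mode = "count"))
})

## raster with given per-trial (n_pre, n_post) counts
counts_raster <- function(n_pre, n_post) {
  trials <- Map(function(a, b) {
    c(rep(-0.05, a), rep(0.1, b))
  }, n_pre, n_post)
  structure(list(trials = trials, amplitude_v = rep(1, length(trials)),
                 trial = seq_along(trials) - 1, pre = 0.1, post = 0.9),
            class = "raster_set")
}

test_that("unit classification applies the 10-of-20 rule at the boundary", {
  pass_trial <- list(0, 2)   # n_pre = 0, n_post = 2 -> pass
  fail_trial <- list(1, 2)   # 2 < 9 -> fail
  mk <- function(n_pass) {
    counts_raster(c(rep(0, n_pass), rep(1, 20 - n_pass)),
                  rep(2, 20))
  }
  expect_true(classify_unit(mk(10))$responsive)
  expect_false(classify_unit(mk(9))$responsive)
  expect_equal(classify_unit(mk(13))$n_pass, 13)

  ## all-empty trials -> not responsive
  empty <- counts_raster(rep(0, 20), rep(0, 20))
  expect_false(classify_unit(empty)$responsive)

  ## non-20-trial default: ceiling(n/2)
  r12 <- counts_raster(rep(0, 12), rep(1, 12))
  expect_equal(classify_unit(r12)$min_pass, 6)

  expect_error(classify_unit(counts_raster(integer(0), integer(0))),
               class = "measort_integrity_error")
})

test_that("classification agrees with direct enumeration on random rasters", {
  set.seed(52)
  for (i in 1:200) {
    n_trials <- sample(c(5, 12, 20), 1)
    n_pre <- rpois(n_trials, 0.5)
    n_post <- rpois(n_trials, 2)
    v <- classify_unit(counts_raster(n_pre, n_post))
    want_pass <- sum(n_post > 9 * n_pre)
    want_min <- if (n_trials == 20) 10 else ceiling(n_trials / 2)
    expect_equal(v$n_pass, want_pass)
    expect_equal(v$responsive, want_pass >= want_min)
  }
})
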