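test_that("peak picking respects threshold and refractory rules", {
  e <- rep(0, 200)
  e[c(50, 100, 150)] <- c(5, 7, 6)
  expect_equal(detect_peaks(e, 1, 10), c(49, 99, 149))
  expect_equal(detect_peaks(e, 100, 10), integer(0) + numeric(0))

  ## two peaks 5 samples apart, refractory 10 -> only the larger survives
  e2 <- rep(0, 100)
  e2[40] <- 3; e2[45] <- 8
  expect_equal(detect_peaks(e2, 1, 10), 44)

  ## negative energies are clipped before picking
  e3 <- rep(-1, 100); e3[50] <- 4
  expect_equal(detect_peaks(e3, 1, 10), 49)
})

test_that("detection count never increases with the threshold", {
  set.seed(31)
  sig <- rnorm(20000, 0, 5)
  tpl <- spike_template(40)
  at <- seq(1000, 19000, by = 450)
  for (a in at) sig[a:(a + 15)] <- sig[a:(a + 15)] + tpl
  e <- energy_trace(sig, detection_config(threshold = 1))
  grid <- quantile(pmax(e, 0), probs = seq(0.5, 0.9999, length.out = 40))
  counts <- vapply(grid, function(th) length(detect_peaks(e, th, 10)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the full channel detector finds planted spikes and drops edge peaks", {
  expect_length(detect_channel(rep(0, 5000),
                               detection_config(threshold = 10))$indices, 0)

  set.seed(32)
  sig <- rnorm(30000, 0, 5)
  tpl <- spike_template(60)
  truth <- seq(500, 29000, by = 700)
  for (a in truth) sig[(a + 1):(a + 16)] <- sig[(a + 1):(a + 16)] + tpl
  det <- detect_channel(sig, detection_config(threshold = 300))
  sc <- score_detection(truth / 10000, det$times)
  expect_gte(sc$precision, 0.95)
  expect_gte(sc$recall, 0.95)
  ## waveforms are peak-aligned: |waveform| maximal at column wf_pre + 1
  peak_col <- apply(abs(det$waveforms), 1, which.max)
  expect_true(all(peak_col == 9))
  expect_equal(ncol(det$waveforms), 20)

  ## a spike hard against the edge is discarded
  sig2 <- rep(0, 1000)
  sig2[3:18] <- tpl
  det2 <- detect_channel(sig2, detection_config(threshold = 300))
  expect_length(det2$indices, 0)
})

test_that("the manual marking rule is 2x the baseline bandwidth", {
  set.seed(33)
  noise <- rnorm(20000)
  hit <- noise; hit[10000] <- 13
  expect_true(9999 %in% reference_manual_rule(hit))
  miss <- noise; miss[10000] <- 10
  expect_false(9999 %in% reference_manual_rule(miss))
  expect_length(reference_manual_rule(rep(0, 1000)), 0)
})

test_that("threshold optimization minimizes the count difference, ties upward", {
  set.seed(34)
  trials <- lapply(1:5, function(i) {
    sig <- rnorm(10000, 0, 5)
    tpl <- spike_template(60)
    at <- seq(500, 9500, by = 1500)
    for (a in at) sig[(a + 1):(a + 16)] <- sig[(a + 1):(a + 16)] + tpl
    sig
  })
  ## single trial, single-point grid
  single <- optimize_threshold(trials[1], grid = 123,
                               ref_counts = 7, snr_curve = FALSE)
  expect_equal(single$threshold, 123)

  ## U-shaped difference curve around the planted optimum
  grid <- exp(seq(log(50), log(5000), length.out = 15))
  opt <- optimize_threshold(trials, grid, ref_counts = rep(7, 5))
  expect_equal(min(opt$difference), 0)
  d <- detect_channel(trials[[1]],
                      detection_config(threshold = opt$threshold))
  expect_lte(abs(length(d$indices) - 7), 2)
  expect_gt(opt$difference[1], min(opt$difference))
  expect_gt(opt$difference[length(grid)], min(opt$difference))

  ## tie -> larger threshold wins
  tie <- optimize_threshold(trials[1], grid = c(1e5, 2e5), ref_counts = 0,
                            snr_curve = FALSE)
  expect_equal(tie$threshold, 2e5)

  expect_error(optimize_threshold(trials, numeric(0)),
               class = "measort_integrity_error")
})

test_that("SNR follows the squared peak-to-peak ratio", {
  ## hand-built detection: spike p2p 10, noise p2p 2
  n <- 4000
  signal <- rep(c(-1, 1), n / 2)           # noise band, p2p 2
  signal[2001:2005] <- c(5, -5, 5, -5, 5)  # one "spike"
  det <- list(indices = 2002, rate = 10000, wf_pre = 8, wf_post = 12,
              waveforms = matrix(c(rep(0, 8), 5, -5, 5, -5, 5, rep(0, 7)),
                                 nrow = 1))
  expect_equal(compute_snr(signal, det), 25)

  ## identical spike and noise p2p -> 1
  det2 <- det
  det2$waveforms <- matrix(rep(c(-1, 1), 10), nrow = 1)
  expect_equal(compute_snr(signal, det2), 1)

  ## doubling the signal at fixed noise quadruples the SNR
  det4 <- det
  det4$waveforms <- 2 * det$waveforms
  expect_equal(compute_snr(signal, det4), 4 * compute_snr(signal, det))

  expect_error(compute_snr(signal, list(indices = integer(0),
                                        waveforms = matrix(0, 0, 20),
                                        rate = 10000, wf_pre = 8,
                                        wf_post = 12)),
               class = "measort_snr_error")
})
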