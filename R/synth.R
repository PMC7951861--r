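# Ground-truthed synthetic MEA recordings.
#
# The generator emulates the structure of an ex vivo retinal stimulation
# experiment: a rectangular electrode grid, background Poisson firing per
# unit, stimulus-locked evoked bursts whose mean count follows a sigmoid of
# the cathodic amplitude, responsiveness probability falling off with
# distance (layer) from the stimulation electrode, biphasic spike
# templates, Gaussian noise, and a large charge-balanced rectangular
# artifact on every channel at each pulse.

#' Synthetic recording configuration
#'
#' Defaults describe the reference experiment at desk scale: a 7 x 7 grid
#' (100 um pitch, 10 kHz), two units per channel, cathodic amplitudes
#' 0.15-1.65 V in 0.15 V steps with 20 repeats each, 25 ms cathodic pulse
#' width, and a 1 s inter-trial gap (the experimental 10 s gap compressed
#' so synthetic recordings stay small; spontaneous statistics are
#' unaffected because rates are per second).
#'
#' @param grid `c(n_rows, n_cols)`.
#' @param pitch electrode spacing, um.
#' @param rate sampling rate, Hz.
#' @param stim_channel stimulating channel id; default the grid centre.
#' @param n_units units per channel.
#' @param template_amps_uv trough amplitude (uV) of each unit's biphasic
#'   template; recycled across `n_units`.
#' @param background_rate_hz spontaneous firing rate per unit.
#' @param noise_sd_uv Gaussian noise SD.
#' @param amplitudes_v cathodic amplitudes, one 20-trial block each, in
#'   order; may be empty for a stimulus-free recording.
#' @param n_trials repeats per amplitude.
#' @param gap_s inter-stimulus interval, seconds.
#' @param cathode_width_s cathodic phase duration T; the implied anodic
#'   phase is A/2 for 2T.
#' @param duration_s recording length when `amplitudes_v` is empty.
#' @param evoked list `u_max`, `v_mid`, `slope_v`: mean evoked spike count
#'   per pulse for a responsive unit is
#'   `mu(A) = u_max / (1 + exp(-(A - v_mid) / slope_v))`.
#' @param latency_range_s evoked-spike latency range (uniform draw).
#' @param resp_layer1 responsiveness probability at layer 1 (and at the
#'   stimulation electrode itself).
#' @param resp_decay multiplicative decay of that probability per layer:
#'   `p(k) = resp_layer1 * resp_decay^(k - 1)`.
#' @param artifact_uv_per_v artifact amplitude in uV per volt of cathodic
#'   amplitude.
#' @param seed RNG seed (mandatory: ground truth must be reproducible).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(grid = c(7, 7), pitch = 100, rate = 10000,
                         stim_channel = NULL, n_units = 2,
                         template_amps_uv = c(100, 70),
                         background_rate_hz = 2, noise_sd_uv = 5,
                         amplitudes_v = seq(0.15, 1.65, by = 0.15),
                         n_trials = 20, gap_s = 1, cathode_width_s = 0.025,
                         duration_s = 10,
                         evoked = list(u_max = 3, v_mid = 0.8,
                                       slope_v = 0.15),
                         latency_range_s = c(0.005, 0.2),
                         resp_layer1 = 0.5, resp_decay = 0.5,
                         artifact_uv_per_v = 1000, seed = NULL) {
  if (is.null(seed)) {
    stop_measort("synth_config requires an explicit seed",
                 "measort_integrity_error")
  }
  stopifnot(background_rate_hz >= 0, noise_sd_uv >= 0, n_units >= 1,
            n_trials >= 1, gap_s > 0, resp_layer1 >= 0, resp_layer1 <= 1,
            resp_decay >= 0, resp_decay <= 1)
  structure(
    list(grid = grid, pitch = pitch, rate = rate,
         stim_channel = stim_channel, n_units = n_units,
         template_amps_uv = template_amps_uv,
         background_rate_hz = background_rate_hz,
         noise_sd_uv = noise_sd_uv, amplitudes_v = amplitudes_v,
         n_trials = n_trials, gap_s = gap_s,
         cathode_width_s = cathode_width_s, duration_s = duration_s,
         evoked = evoked, latency_range_s = latency_range_s,
         resp_layer1 = resp_layer1, resp_decay = resp_decay,
         artifact_uv_per_v = artifact_uv_per_v, seed = seed),
    class = "synth_config"
  )
}

#' Biphasic spike template
#'
#' Difference of two exponentials (fast depolarizing lobe, slower
#' repolarizing overshoot), negated so the trough comes first, trough
#' normalized to `-amp_uv`.  Total width about 1.5-2 ms.
#'
#' @param amp_uv trough amplitude, uV.
#' @param rate sampling rate, Hz.
#' @param tau_r,tau_d rise/decay time constants, seconds.
#' @param n_samples template length.
#' @return numeric vector; the trough sits at the first sample where the
#'   absolute value is maximal.
#' @export
spike_template <- function(amp_uv, rate = 10000, tau_r = 1e-4,
                           tau_d = 4e-4, n_samples = 16) {
  t <- (seq_len(n_samples) - 1) / rate
  w <- exp(-t / tau_r) / tau_r - exp(-t / tau_d) / tau_d
  w <- -w / max(abs(w)) * amp_uv
  w
}

## mean evoked count for a responsive unit at amplitude A
evoked_mu <- function(A, evoked) {
  evoked$u_max / (1 + exp(-(A - evoked$v_mid) / evoked$slope_v))
}

## drop spikes closer than min_gap to their predecessor (keep the earlier)
enforce_gap <- function(times, min_gap) {
  times <- sort(times)
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= min_gap) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Simulate a ground-truthed MEA recording
#'
#' Deterministic given `cfg$seed`.  Background spikes are a Poisson process
#' per unit; responsive units additionally emit `Poisson(mu(A))` evoked
#' spikes per stimulus at uniform latencies; templates superpose linearly;
#' i.i.d. Gaussian noise is added; each stimulus leaves a rectangular
#' charge-balanced artifact (cathodic `-A * gain` for T, anodic
#' `+A * gain / 2` for 2T) on every channel.  Each unit's responsive flag
#' is drawn with probability `resp_layer1 * resp_decay^(layer - 1)`.
#'
#' @param cfg a [synth_config()].
#' @return list with `recording` (an [mea_recording()]) and `truth`
#'   (class `synth_ground_truth`): `spikes` (channel, unit, time_s, sample,
#'   evoked), `units` (channel, unit, layer, responsive, template
#'   amplitude), `stim_channel`, `config`.
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  geom <- electrode_geometry(cfg$grid[1], cfg$grid[2], cfg$pitch)
  n_ch <- nrow(geom)
  stim_ch <- cfg$stim_channel
  if (is.null(stim_ch)) {
    centre_row <- floor((cfg$grid[1] - 1) / 2)
    centre_col <- floor((cfg$grid[2] - 1) / 2)
    stim_ch <- geom$channel[geom$row == centre_row & geom$col == centre_col]
  }

  n_stim <- length(cfg$amplitudes_v) * cfg$n_trials
  duration <- if (n_stim > 0) (n_stim + 1) * cfg$gap_s else cfg$duration_s
  n <- round(duration * cfg$rate)

  stim <- if (n_stim > 0) {
    onset_t <- cfg$gap_s * seq_len(n_stim)
    stimulus_events(
      onset_sample = round(onset_t * cfg$rate),
      electrode = stim_ch,
      amplitude_v = rep(cfg$amplitudes_v, each = cfg$n_trials),
      cathode_width_s = cfg$cathode_width_s,
      trial = rep(seq_len(cfg$n_trials) - 1L, times = length(cfg$amplitudes_v))
    )
  } else empty_stimuli()

  amps <- rep_len(cfg$template_amps_uv, cfg$n_units)
  ## distinct shapes per unit: stagger the time constants
  taus <- lapply(seq_len(cfg$n_units), function(u) {
    c(tau_r = 1e-4 * u, tau_d = 4e-4 * u)
  })
  templates <- lapply(seq_len(cfg$n_units), function(u) {
    spike_template(amps[u], cfg$rate, taus[[u]]["tau_r"], taus[[u]]["tau_d"])
  })

  out <- with_seed(cfg$seed, {
    samples <- matrix(0, nrow = n_ch, ncol = n)

    ## artifacts (before noise, all channels)
    if (n_stim > 0) {
      Tn <- round(cfg$cathode_width_s * cfg$rate)
      for (s in seq_len(nrow(stim))) {
        o <- stim$onset_sample[s]
        A <- stim$amplitude_v[s] * cfg$artifact_uv_per_v
        cat_idx <- (o + 1):min(n, o + Tn)
        ano_idx <- (o + Tn + 1):min(n, o + 3 * Tn)
        samples[, cat_idx] <- samples[, cat_idx] - A
        samples[, ano_idx] <- samples[, ano_idx] + A / 2
      }
    }

    spikes <- list()
    units <- list()
    min_gap <- 0.002   # per-unit refractory period, seconds
    for (ch in seq_len(n_ch)) {
      layer <- layer_index(stim_ch, ch, geom)
      for (u in seq_len(cfg$n_units)) {
        p_resp <- cfg$resp_layer1 * cfg$resp_decay^(max(layer, 1) - 1)
        responsive <- n_stim > 0 && stats::runif(1) < p_resp

        n_bg <- stats::rpois(1, cfg$background_rate_hz * duration)
        t_bg <- sort(stats::runif(n_bg, 0, duration))
        t_ev <- numeric(0)
        if (responsive) {
          for (s in seq_len(nrow(stim))) {
            mu <- evoked_mu(stim$amplitude_v[s], cfg$evoked)
            m <- stats::rpois(1, mu)
            if (m > 0) {
              lat <- stats::runif(m, cfg$latency_range_s[1],
                                  cfg$latency_range_s[2])
              t_ev <- c(t_ev, stim$onset_sample[s] / cfg$rate + lat)
            }
          }
        }
        t_all <- enforce_gap(c(t_bg, t_ev), min_gap)
        is_ev <- t_all %in% t_ev
        smp <- round(t_all * cfg$rate)
        ok <- smp + length(templates[[u]]) - 1 <= n - 1 & smp >= 0
        t_all <- t_all[ok]; is_ev <- is_ev[ok]; smp <- smp[ok]
        for (i in seq_along(smp)) {
          idx <- (smp[i] + 1):(smp[i] + length(templates[[u]]))
          samples[ch, idx] <- samples[ch, idx] + templates[[u]]
        }
        if (length(smp) > 0) {
          spikes[[length(spikes) + 1]] <- data.frame(
            channel = ch, unit = u, time_s = smp / cfg$rate, sample = smp,
            evoked = is_ev)
        }
        units[[length(units) + 1]] <- data.frame(
          channel = ch, unit = u, layer = layer, responsive = responsive,
          template_amp_uv = amps[u])
      }
    }

    if (cfg$noise_sd_uv > 0) {
      samples <- samples + matrix(stats::rnorm(n_ch * n, 0, cfg$noise_sd_uv),
                                  nrow = n_ch)
    }
    list(samples = samples, spikes = spikes, units = units)
  })

  spikes <- if (length(out$spikes)) do.call(rbind, out$spikes) else
    data.frame(channel = integer(0), unit = integer(0), time_s = numeric(0),
               sample = numeric(0), evoked = logical(0))
  truth <- structure(
    list(spikes = spikes, units = do.call(rbind, out$units),
         stim_channel = stim_ch, config = cfg),
    class = "synth_ground_truth"
  )
  rec <- mea_recording(out$samples, cfg$rate, geom, stim)
  list(recording = rec, truth = truth)
}

#' @export
print.synth_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<synth_ground_truth> %d spikes, %d units (%d responsive), stim channel %d\n",
    nrow(x$spikes), nrow(x$units), sum(x$units$responsive), x$stim_channel))
  invisible(x)
}
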