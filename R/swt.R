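# Stationary wavelet transform (undecimated, a trous), Teager energy
# operator and the smoothing/combination primitives of the detector.

## Orthonormal Daubechies scaling (low-pass) filters.  High-pass filters are
## derived by the quadrature mirror relation g[n] = (-1)^n h[L-1-n].
.wavelet_lo <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(0.482962913144690, 0.836516303737469,
          0.224143868041857, -0.129409522550921),
  db4 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
          -0.027983769416984, -0.187034811718881, 0.030841381835987,
          0.032883011666983, -0.010597401784997)
)

#' Wavelet filter bank for the stationary transform
#'
#' Returns the level-1 low- and high-pass taps of an orthonormal wavelet and
#' the family name.  Level-j filters are obtained by dyadic upsampling
#' (inserting `2^(j-1) - 1` zeros between adjacent taps); see
#' [upsample_filter()].
#'
#' @param wavelet one of `"haar"`, `"db2"`, `"db4"`.
#' @return list with elements `lo`, `hi`, `wavelet`.
#' @export
wavelet_filters <- function(wavelet = "haar") {
  wavelet <- match.arg(wavelet, names(.wavelet_lo))
  lo <- .wavelet_lo[[wavelet]]
  L <- length(lo)
  hi <- (-1)^(seq_len(L) - 1) * rev(lo)
  list(lo = lo, hi = hi, wavelet = wavelet)
}

#' Dyadically upsample filter taps
#'
#' Inserts `2^(level-1) - 1` zeros between adjacent taps, producing the
#' level-`level` filter of the a trous algorithm from the level-1 taps.
#'
#' @param f level-1 taps.
#' @param level decomposition level (>= 1; level 1 returns `f` unchanged).
#' @export
upsample_filter <- function(f, level) {
  stopifnot(level >= 1)
  if (level == 1) return(f)
  gap <- 2^(level - 1)
  out <- numeric((length(f) - 1) * gap + 1)
  out[seq(1, length(out), by = gap)] <- f
  out
}

#' Stationary wavelet decomposition
#'
#' Undecimated (a trous) wavelet transform with circular boundary handling.
#' Both coefficient series keep the length of the input at every level, so
#' time information is preserved, and the transform is translation
#' invariant: circularly shifting the input shifts every coefficient series
#' by the same amount.
#'
#' Level j is computed from the level j-1 approximation:
#' `a_j = a_{j-1} (*) lo_j`, `d_j = a_{j-1} (*) hi_j`, where `(*)` is
#' circular convolution and the level-j filters are dyadic upsamplings of
#' the level-1 taps.
#'
#' @param signal numeric series.
#' @param wavelet wavelet family name (see [wavelet_filters()]).
#' @param levels number of levels (>= 1).
#' @return object of class `swt_coefficients`: lists `approx` and `detail`
#'   of per-level series, each `length(signal)` long.
#' @export
swt_decompose <- function(signal, wavelet = "haar", levels = 2) {
  stopifnot(levels >= 1)
  bank <- wavelet_filters(wavelet)
  longest <- (length(bank$lo) - 1) * 2^(levels - 1) + 1
  if (length(signal) < longest) {
    stop_measort(sprintf(
      "signal (%d samples) shorter than the level-%d filter support (%d)",
      length(signal), levels, longest), "measort_decomposition_error")
  }
  approx <- vector("list", levels)
  detail <- vector("list", levels)
  a <- signal
  for (j in seq_len(levels)) {
    lo_j <- upsample_filter(bank$lo, j)
    hi_j <- upsample_filter(bank$hi, j)
    approx[[j]] <- circ_conv(a, lo_j)
    detail[[j]] <- circ_conv(a, hi_j)
    a <- approx[[j]]
  }
  structure(list(approx = approx, detail = detail, wavelet = bank$wavelet,
                 levels = levels),
            class = "swt_coefficients")
}

#' Teager energy operator
#'
#' `psi(n) = x(n)^2 - x(n-1) * x(n+1)` for interior samples; the two
#' endpoints are set to 0.  Amplifies transients (spikes) relative to
#' slowly varying background, because psi tracks instantaneous
#' amplitude-frequency energy.
#'
#' @param x numeric series of length >= 3.
#' @return series of the same length.
#' @export
teo <- function(x) {
  n <- length(x)
  if (n < 3) {
    stop_measort("Teager energy needs at least 3 samples",
                 "measort_integrity_error")
  }
  out <- numeric(n)
  i <- 2:(n - 1)
  out[i] <- x[i]^2 - x[i - 1] * x[i + 1]
  out
}

#' Zero-phase Hamming smoothing
#'
#' Convolves with a unit-area Hamming window centred on each sample
#' (circular boundary), suppressing single-sample noise transients in the
#' energy trace while preserving its scale: a constant series is returned
#' unchanged.
#'
#' @param e numeric series.
#' @param win odd window length in samples, >= 3 (default 11, i.e. 1.1 ms
#'   at 10 kHz).
#' @return smoothed series, same length.
#' @export
smooth_hamming <- function(e, win = 11) {
  if (win %% 2 == 0 || win < 3) {
    stop_measort("Hamming window length must be odd and >= 3",
                 "measort_integrity_error")
  }
  if (length(e) < win) {
    stop_measort("series shorter than the smoothing window",
                 "measort_integrity_error")
  }
  w <- signal::hamming(win)
  w <- w / sum(w)
  h <- (win - 1) / 2
  causal <- circ_conv(e, w)
  n <- length(e)
  ## causal[k] = sum_m w[m] e[k-m]; centring means reading h samples ahead
  causal[((seq_len(n) - 1 + h) %% n) + 1]
}

#' Combine per-sub-band energy traces
#'
#' @param bands list of equal-length numeric series (one per sub-band).
#' @param rule `"sum"` (default) or `"max"`, applied pointwise.
#' @return single combined series.  Teager energy can be negative; negative
#'   values are kept here and clipped to zero by the peak picker.
#' @export
combine_subbands <- function(bands, rule = c("sum", "max")) {
  rule <- match.arg(rule)
  stopifnot(length(bands) >= 1)
  lens <- lengths(bands)
  if (length(unique(lens)) != 1) {
    stop_measort("sub-band lengths differ", "measort_integrity_error")
  }
  if (rule == "sum") {
    Reduce(`+`, bands)
  } else {
    Reduce(pmax, bands)
  }
}
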