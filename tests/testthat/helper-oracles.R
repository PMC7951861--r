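# Independent oracles and small fixture builders used across the suite.

## circular left-ish shift: y[k] = x[k - s mod n]
circ_shift <- function(x, s) {
  n <- length(x)
  x[((seq_len(n) - 1 - s) %% n) + 1]
}

## Brute-force a trous oracle: explicit upsampled filters and a direct
## modular-index convolution sum, no stats::filter, no FFT.
swt_oracle <- function(signal, wavelet, levels) {
  bank <- wavelet_filters(wavelet)
  n <- length(signal)
  conv <- function(x, f) {
    vapply(seq_len(n), function(k) {
      sum(f * x[(((k - 1) - (seq_along(f) - 1)) %% n) + 1])
    }, numeric(1))
  }
  up <- function(f, j) {
    if (j == 1) return(f)
    out <- numeric((length(f) - 1) * 2^(j - 1) + 1)
    out[seq(1, length(out), by = 2^(j - 1))] <- f
    out
  }
  a <- signal
  approx <- detail <- vector("list", levels)
  for (j in seq_len(levels)) {
    approx[[j]] <- conv(a, up(bank$lo, j))
    detail[[j]] <- conv(a, up(bank$hi, j))
    a <- approx[[j]]
  }
  list(approx = approx, detail = detail)
}

## Literal per-sample silhouette: a(i), b(i), s(i) with explicit distance
## recomputation (no stats::dist), singleton a = 0, a = b -> s = 0.
silhouette_oracle <- function(X, labels) {
  n <- nrow(X)
  euclid <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- if (length(own)) mean(vapply(own, euclid, numeric(1), i = i)) else 0
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == cl)
      b <- min(b, mean(vapply(mem, euclid, numeric(1), i = i)))
    }
    s[i] <- if (a == b) 0 else (b - a) / max(a, b)
  }
  s
}

## Gaussian blobs around given centres (matrix rows), sd per coordinate.
make_blobs <- function(n_per, centers, sd) {
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(stats::rnorm(n_per * ncol(centers), 0, sd), ncol = ncol(centers)),
          2, centers[i, ], `+`)
  }))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

## One further Lloyd step on a converged model; used to verify fixed points.
lloyd_step <- function(X, centroids) {
  d2 <- outer(rowSums(X^2), rowSums(centroids^2), `+`) -
    2 * X %*% t(centroids)
  max.col(-d2, ties.method = "first")
}

## tiny two-channel recording with one stimulus, for container tests
tiny_recording <- function(n = 100, seed = 1) {
  set.seed(seed)
  geom <- electrode_geometry(1, 2)
  samples <- matrix(rnorm(2 * n), nrow = 2)
  stim <- stimulus_events(onset_sample = 50, electrode = 1,
                          amplitude_v = 0.45, trial = 0)
  mea_recording(samples, 100, geom, stim)
}
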