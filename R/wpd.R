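# Wavelet-packet feature extraction for spike sorting.
#
# Each detected waveform (L = 20 samples at 10 kHz) is decomposed with a
# stationary (undecimated) wavelet packet transform: unlike the plain
# wavelet transform, BOTH the approximation and the detail branch are split
# at every level, giving the full binary tree.  At depth 3 that is 8
# terminal nodes (AAA, AAD, ..., DDD with A = low-pass, D = high-pass);
# per node and per spike the standard deviation and the first quartile of
# the coefficients summarize the sub-band, yielding 16 raw features.

## Stationary wavelet packet leaves: list of L x n_spikes matrices, natural
## (A-before-D) order.  X is L x n_spikes; circular convolutions are applied
## by a precomputed circulant matrix, one matmul per node.
swpd_leaves <- function(X, wavelet = "haar", depth = 3) {
  bank <- wavelet_filters(wavelet)
  L <- nrow(X)
  nodes <- list(X)
  for (lev in seq_len(depth)) {
    Clo <- circulant_matrix(upsample_filter(bank$lo, lev), L)
    Chi <- circulant_matrix(upsample_filter(bank$hi, lev), L)
    nodes <- unlist(lapply(nodes, function(nd) {
      list(Clo %*% nd, Chi %*% nd)
    }), recursive = FALSE)
  }
  labels <- "S"
  for (lev in seq_len(depth)) {
    labels <- as.vector(t(outer(labels, c("A", "D"), paste0)))
  }
  names(nodes) <- sub("^S", "", labels)
  nodes
}

#' Wavelet-packet features for spike waveforms
#'
#' @param waveforms n_spikes x L numeric matrix of aligned waveforms
#'   (microvolts); `L >= 2^depth`.
#' @param depth packet tree depth (default 3, i.e. 8 terminal nodes).
#' @param wavelet wavelet family (see [wavelet_filters()]).
#' @param standardize centre/scale columns to mean 0, sd 1 and drop
#'   constant columns (default TRUE).
#' @return n_spikes x n_features matrix of class `feature_matrix` with
#'   column names `<node>_sd` / `<node>_q1` and attributes `center`,
#'   `scale`, `dropped` recording the standardization.
#' @export
wpd_features <- function(waveforms, depth = 3, wavelet = "haar",
                         standardize = TRUE) {
  stopifnot(is.matrix(waveforms))
  L <- ncol(waveforms)
  if (L < 2^depth) {
    stop_measort(sprintf("waveform length %d < 2^depth = %d", L, 2^depth),
                 "measort_integrity_error")
  }
  leaves <- swpd_leaves(t(waveforms), wavelet, depth)
  feats <- lapply(names(leaves), function(lab) {
    nd <- leaves[[lab]]
    cbind(
      apply(nd, 2, stats::sd),
      apply(nd, 2, stats::quantile, probs = 0.25, names = FALSE)
    )
  })
  X <- do.call(cbind, feats)
  colnames(X) <- as.vector(vapply(names(leaves), function(lab) {
    c(paste0(lab, "_sd"), paste0(lab, "_q1"))
  }, character(2)))

  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  dropped <- character(0)
  if (standardize && nrow(X) > 1) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    keep <- scale > 1e-12
    dropped <- colnames(X)[!keep]
    X <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2,
               scale[keep], `/`)
    center <- center[keep]; scale <- scale[keep]
  }
  if (anyNA(X)) {
    stop_measort("NaN in feature matrix", "measort_integrity_error")
  }
  structure(X, center = center, scale = scale, dropped = dropped,
            class = c("feature_matrix", class(X)))
}
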