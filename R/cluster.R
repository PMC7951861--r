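# K-means clustering (Lloyd's algorithm) with silhouette-based selection of
# the cluster count.  The clustering itself is implemented here rather than
# delegated, because the iteration (squared-Euclidean assignment, centroid
# averaging, fixed-point stop) and the silhouette definition are the
# method's substance; stats::kmeans and cluster::silhouette serve as
# independent cross-checks in the test suite.

squared_dist_to_centroids <- function(X, C) {
  ## n x k matrix of squared Euclidean distances
  x2 <- rowSums(X^2)
  c2 <- rowSums(C^2)
  d2 <- outer(x2, c2, `+`) - 2 * X %*% t(C)
  pmax(d2, 0)
}

#' K-means by Lloyd's algorithm
#'
#' Assignment by minimum squared Euclidean distance, centroid update by the
#' within-cluster mean, iterated until the assignment is unchanged (a fixed
#' point) or `max_iter` is reached.  `restarts` random initializations
#' (k distinct rows of `X`) are run and the solution with the lowest
#' inertia kept.  An emptied cluster is re-seeded to the point farthest
#' from its current centroid.
#'
#' @param X numeric n x p matrix (typically a [wpd_features()] matrix).
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed RNG seed for the initializations (caller's RNG state is
#'   restored afterwards); `NULL` uses the current RNG stream.
#' @param restarts number of random initializations.
#' @param max_iter iteration cap per restart.
#' @return object of class `cluster_model`: `k`, `centroids` (k x p),
#'   `labels` (1..k, no empty cluster), `inertia`, `inertia_history`
#'   (inertia after each assignment step of the winning restart, a
#'   non-increasing sequence), `iterations`, `seed`.
#' @export
kmeans_fit <- function(X, k, seed = NULL, restarts = 10, max_iter = 300) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) {
    stop_measort(sprintf("k = %d exceeds the number of samples (%d)", k, n),
                 "measort_integrity_error")
  }
  stopifnot(k >= 1, restarts >= 1)

  run_once <- function() {
    C <- X[sample.int(n, k), , drop = FALSE]
    labels <- integer(n)
    history <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- squared_dist_to_centroids(X, C)
      new_labels <- max.col(-d2, ties.method = "first")
      ## re-seed empty clusters to the farthest point from its centroid
      attempts <- 0L
      repeat {
        sizes <- tabulate(new_labels, nbins = k)
        empty <- which(sizes == 0)
        if (length(empty) == 0) break
        attempts <- attempts + 1L
        if (attempts > k) {
          ## degenerate data (e.g. duplicated points): move one point from
          ## the largest cluster into each empty one
          for (j in empty) {
            donor <- which(new_labels == which.max(sizes))[1]
            new_labels[donor] <- j
            sizes <- tabulate(new_labels, nbins = k)
          }
          break
        }
        mind2 <- d2[cbind(seq_len(n), new_labels)]
        far <- which.max(mind2)
        C[empty[1], ] <- X[far, ]
        d2 <- squared_dist_to_centroids(X, C)
        new_labels <- max.col(-d2, ties.method = "first")
      }
      history <- c(history, sum(d2[cbind(seq_len(n), new_labels)]))
      if (it > 1 && all(new_labels == labels)) {
        labels <- new_labels
        break
      }
      labels <- new_labels
      for (j in seq_len(k)) {
        C[j, ] <- colMeans(X[labels == j, , drop = FALSE])
      }
    }
    list(centroids = C, labels = labels, history = history,
         inertia = history[length(history)], iterations = length(history))
  }

  best <- with_seed(seed, {
    fits <- replicate(restarts, run_once(), simplify = FALSE)
    fits[[which.min(vapply(fits, `[[`, numeric(1), "inertia"))]]
  })
  structure(
    list(k = k, centroids = best$centroids, labels = best$labels,
         inertia = best$inertia, inertia_history = best$history,
         iterations = best$iterations, seed = seed, restarts = restarts),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, inertia = %.4g, %d iterations\n",
              x$k, x$inertia, x$iterations))
  cat("  sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette coefficient
#'
#' For each sample i: `a(i)` is the mean distance to the other members of
#' its own cluster (0 for a singleton), `b(i)` the smallest mean distance
#' to any other cluster, and
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, with `s(i) = 0` when
#' `a(i) = b(i)` (including the all-identical-points case where both are
#' 0).  Every `s(i)` lies in `[-1, 1]`.  Distances are Euclidean.
#'
#' @param X numeric n x p matrix.
#' @param labels integer cluster labels, at least 2 distinct values.
#' @return object of class `silhouette_report`: vectors `a`, `b`, `s`,
#'   scalar `mean_sc`.
#' @export
mean_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2) {
    stop_measort("silhouette undefined for a single cluster",
                 "measort_silhouette_error")
  }
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a[i] <- if (any(own)) mean(D[i, own]) else 0
    b[i] <- min(vapply(cl[cl != labels[i]], function(j) {
      mean(D[i, labels == j])
    }, numeric(1)))
    m <- max(a[i], b[i])
    s[i] <- if (a[i] == b[i]) 0 else (b[i] - a[i]) / m
  }
  structure(list(a = a, b = b, s = s, mean_sc = mean(s)),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("<silhouette_report> mean SC = %.3f over %d samples\n",
              x$mean_sc, length(x$s)))
  invisible(x)
}

#' Choose the cluster count by maximizing the mean silhouette
#'
#' Fits K-means for `k = 2 .. min(k_max, n-1)` and keeps the k with the
#' largest mean silhouette coefficient (ties toward smaller k).  Because
#' the silhouette is undefined for k = 1, a single unit is returned instead
#' when the data give no real support for splitting: fewer than 10 spikes,
#' or a best mean SC below `sc_floor`.
#'
#' @param X feature matrix (n >= 2 rows).
#' @param k_max largest candidate cluster count.
#' @param seed RNG seed for the K-means initializations.
#' @param sc_floor minimum mean SC required to accept a split (default
#'   0.20).
#' @param restarts K-means restarts per candidate k.
#' @return list with `model` (the chosen `cluster_model`; `k = 1` uses the
#'   column means as the single centroid) and `selection` (data frame of
#'   candidate `k` and `mean_sc`, plus attributes `chosen_k`, `sil` — the
#'   `silhouette_report` of the chosen model, NULL for k = 1).
#' @export
select_k <- function(X, k_max = 5, seed = NULL, sc_floor = 0.2,
                     restarts = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 1)

  single_unit <- function() {
    C <- matrix(colMeans(X), nrow = 1)
    inertia <- sum(sweep(X, 2, C[1, ])^2)
    structure(list(k = 1L, centroids = C, labels = rep(1L, n),
                   inertia = inertia, inertia_history = inertia,
                   iterations = 1L, seed = seed, restarts = 0L),
              class = "cluster_model")
  }

  k_hi <- min(k_max, n - 1)
  ks <- if (k_hi >= 2) 2:k_hi else integer(0)
  if (n < 10 || length(ks) == 0) {
    sel <- data.frame(k = integer(0), mean_sc = numeric(0))
    attr(sel, "chosen_k") <- 1L
    return(list(model = single_unit(), selection = sel))
  }

  fits <- vector("list", length(ks))
  sils <- vector("list", length(ks))
  with_seed(seed, {
    for (i in seq_along(ks)) {
      fits[[i]] <- kmeans_fit(X, ks[i], seed = NULL, restarts = restarts)
      sils[[i]] <- mean_silhouette(X, fits[[i]]$labels)
    }
  })
  sc <- vapply(sils, `[[`, numeric(1), "mean_sc")
  sel <- data.frame(k = ks, mean_sc = sc)
  best <- which.max(sc)          # first max -> smaller k on ties
  if (sc[best] < sc_floor) {
    attr(sel, "chosen_k") <- 1L
    return(list(model = single_unit(), selection = sel))
  }
  attr(sel, "chosen_k") <- ks[best]
  attr(sel, "sil") <- sils[[best]]
  list(model = fits[[best]], selection = sel)
}

#' Sort one channel's detected spikes into units
#'
#' Wavelet-packet features ([wpd_features()]) followed by
#' silhouette-selected K-means ([select_k()]).  Units are numbered 1..k
#' within the channel.
#'
#' @param det a `detection_result` for the channel.
#' @param channel channel id used in the output table.
#' @param seed RNG seed.
#' @param depth,wavelet feature extraction parameters.
#' @param k_max,sc_floor,restarts model-selection parameters.
#' @return data frame `channel, unit, spike_sample, spike_time_s` (one row
#'   per spike; empty for a spike-less channel) with attributes
#'   `selection` (candidate-k table) and `k`.
#' @export
sort_channel <- function(det, channel = 1L, seed = NULL, depth = 3,
                         wavelet = "haar", k_max = 5, sc_floor = 0.2,
                         restarts = 10) {
  n <- length(det$indices)
  if (n == 0) {
    out <- data.frame(channel = integer(0), unit = integer(0),
                      spike_sample = numeric(0), spike_time_s = numeric(0))
    attr(out, "k") <- 0L
    return(out)
  }
  if (n == 1) {
    out <- data.frame(channel = channel, unit = 1L,
                      spike_sample = det$indices,
                      spike_time_s = det$times)
    attr(out, "k") <- 1L
    return(out)
  }
  X <- wpd_features(det$waveforms, depth = depth, wavelet = wavelet)
  pick <- select_k(X, k_max = k_max, seed = seed, sc_floor = sc_floor,
                   restarts = restarts)
  out <- data.frame(channel = channel, unit = pick$model$labels,
                    spike_sample = det$indices, spike_time_s = det$times)
  attr(out, "selection") <- pick$selection
  attr(out, "k") <- pick$model$k
  out
}
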