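test_that("wavelet-packet features separate distinct templates", {
  set.seed(41)
  t1 <- spike_template(100, tau_r = 1e-4, tau_d = 4e-4, n_samples = 20)
  t2 <- spike_template(50, tau_r = 2e-4, tau_d = 8e-4, n_samples = 20)
  wf <- rbind(
    t(replicate(20, t1 + rnorm(20, 0, 5))),
    t(replicate(20, t2 + rnorm(20, 0, 5)))
  )
  X <- wpd_features(wf)
  expect_equal(nrow(X), 40)
  expect_false(anyNA(X))
  ## standardized columns
  expect_lt(max(abs(colMeans(X))), 1e-10)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-10)
  ## nearest-centroid by true template classifies perfectly
  lab <- rep(1:2, each = 20)
  c1 <- colMeans(X[lab == 1, ]); c2 <- colMeans(X[lab == 2, ])
  pred <- ifelse(rowSums(sweep(X, 2, c1)^2) < rowSums(sweep(X, 2, c2)^2),
                 1, 2)
  expect_equal(pred, lab)
})

test_that("degenerate waveforms give degenerate raw features", {
  wf0 <- matrix(0, nrow = 3, ncol = 20)
  raw <- wpd_features(wf0, standardize = FALSE)
  expect_true(all(raw == 0))
  ## identical spikes -> identical feature rows
  set.seed(42)
  w <- rnorm(20)
  raw2 <- wpd_features(rbind(w, w), standardize = FALSE)
  expect_equal(raw2[1, ], raw2[2, ])
  expect_error(wpd_features(matrix(0, 2, 6), depth = 3),
               class = "measort_integrity_error")
})

test_that("Lloyd iterations satisfy the K-means contract", {
  set.seed(43)
  ## k = 1: centroid is the column mean
  X <- matrix(rnorm(60), ncol = 3)
  m1 <- kmeans_fit(X, 1, seed = 1)
  expect_equal(as.numeric(m1$centroids), colMeans(X))
  expect_equal(m1$inertia, sum(sweep(X, 2, colMeans(X))^2))

  ## two well-separated 1-D groups: the unique optimum is found
  X2 <- matrix(c(0, 0.1, -0.1, 10, 10.1, 9.9), ncol = 1)
  m2 <- kmeans_fit(X2, 2, seed = 2)
  expect_equal(sort(as.numeric(m2$centroids)), c(0, 10))
  expect_equal(m2$labels[1:3], rep(m2$labels[1], 3))
  expect_equal(m2$labels[4:6], rep(m2$labels[4], 3))

  ## inertia never increases; converged model is a Lloyd fixed point
  for (i in 1:10) {
    Xi <- matrix(rnorm(40 * 4), ncol = 4)
    mi <- kmeans_fit(Xi, 3, seed = i)
    expect_true(all(diff(mi$inertia_history) <= 1e-9))
    expect_equal(lloyd_step(Xi, mi$centroids), mi$labels)
    for (j in 1:3) {
      expect_equal(as.numeric(mi$centroids[j, ]),
                   colMeans(Xi[mi$labels == j, , drop = FALSE]))
    }
  }

  expect_error(kmeans_fit(X2, 10), class = "measort_integrity_error")
})

test_that("k-means agrees with an independent implementation on easy data", {
  set.seed(44)
  blobs <- make_blobs(50, rbind(c(0, 0), c(5, 5)), 0.3)
  ours <- kmeans_fit(blobs$X, 2, seed = 9)
  ref <- kmeans(blobs$X, 2, nstart = 10, algorithm = "Lloyd")
  expect_equal(score_sorting(ref$cluster, ours$labels)$accuracy, 1)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
})

test_that("silhouette matches Eq-style oracle and its edge branches", {
  set.seed(45)
  blobs <- make_blobs(30, rbind(c(0, 0), c(10, 10)), 0.2)
  rep1 <- mean_silhouette(blobs$X, blobs$labels)
  expect_gt(rep1$mean_sc, 0.95)
  expect_true(all(rep1$s >= -1 & rep1$s <= 1))

  ## identical points split arbitrarily: a = b = 0 -> s = 0
  Xe <- matrix(1, nrow = 6, ncol = 2)
  repe <- mean_silhouette(Xe, rep(1:2, 3))
  expect_equal(repe$s, rep(0, 6))

  ## oracle equivalence on random instances
  for (i in 1:10) {
    n <- sample(10:60, 1)
    Xi <- matrix(rnorm(n * 3), ncol = 3)
    li <- sample(1:3, n, replace = TRUE)
    if (length(unique(li)) < 2) next
    ri <- mean_silhouette(Xi, li)
    expect_lt(max(abs(ri$s - silhouette_oracle(Xi, li))), 1e-12)
  }

  ## cross-check against the cluster package on a no-singleton instance
  if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(blobs$labels, dist(blobs$X))
    expect_equal(rep1$s, as.numeric(sil[, "sil_width"]), tolerance = 1e-12)
  }

  expect_error(mean_silhouette(blobs$X, rep(1, nrow(blobs$X))),
               class = "measort_silhouette_error")
})

test_that("cluster-count selection follows the mean silhouette with floors", {
  set.seed(46)
  blobs <- make_blobs(100, rbind(c(0, 0), c(1, 0), c(0, 1)), 0.1)
  pick <- select_k(blobs$X, k_max = 5, seed = 1)
  expect_equal(pick$model$k, 3)
  expect_equal(score_sorting(blobs$labels, pick$model$labels)$accuracy, 1)

  ## fewer than 10 spikes -> single unit, no clustering attempted
  tiny <- matrix(rnorm(10), ncol = 2)
  expect_equal(select_k(tiny, seed = 1)$model$k, 1)

  ## one blob: every split scores below the floor
  one <- matrix(rnorm(200 * 8), ncol = 8)
  pick1 <- select_k(one, seed = 2)
  expect_equal(pick1$model$k, 1)
  expect_true(all(pick1$selection$mean_sc < 0.2))
})

test_that("channel sorting returns per-spike unit labels", {
  expect_equal(nrow(sort_channel(list(indices = integer(0),
                                      times = numeric(0),
                                      waveforms = matrix(0, 0, 20)))), 0)

  set.seed(47)
  t1 <- spike_template(100, n_samples = 20)
  t2 <- spike_template(50, tau_r = 2e-4, tau_d = 8e-4, n_samples = 20)
  wf <- rbind(
    t(replicate(30, t1 + rnorm(20, 0, 5))),
    t(replicate(30, t2 + rnorm(20, 0, 5)))
  )
  det <- list(indices = seq(0, by = 100, length.out = 60),
              times = seq(0, by = 0.01, length.out = 60),
              waveforms = wf)
  labs <- sort_channel(det, channel = 3, seed = 5)
  expect_equal(attr(labs, "k"), 2)
  truth <- rep(1:2, each = 30)
  expect_gte(score_sorting(truth, labs$unit)$accuracy, 0.95)
  expect_equal(unique(labs$channel), 3)
})
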