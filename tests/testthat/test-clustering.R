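test_that("fit_kmeans recovers planted blobs and honors its contracts", {
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10)) * 10   # separation 10x sd
  b <- make_blobs(centers, 40, sd = 1, seed = 2)

  # K = 1: single centroid is the coordinate-wise mean
  m1 <- fit_kmeans(b$X, 1, seed = 0)
  expect_equal(as.vector(m1$centroids), colMeans(b$X), tolerance = 1e-10)

  m3 <- fit_kmeans(b$X, 3, seed = 0)
  expect_equal(ari(m3$cluster, b$labels), 1.0)

  # duplicating every point leaves the (well-separated) optimum unchanged
  mdup <- fit_kmeans(rbind(b$X, b$X), 3, seed = 1)
  ord <- order(mdup$centroids[, 1] + 1000 * mdup$centroids[, 2])
  ord0 <- order(m3$centroids[, 1] + 1000 * m3$centroids[, 2])
  expect_equal(unname(mdup$centroids[ord, ]), unname(m3$centroids[ord0, ]),
               tolerance = 1e-8)

  # determinism given seed; final assignment is a fixed point of assign_clusters
  m3b <- fit_kmeans(b$X, 3, seed = 0)
  expect_identical(m3$centroids, m3b$centroids)
  expect_identical(assign_clusters(b$X, m3), m3$cluster)

  expect_error(fit_kmeans(b$X, nrow(b$X) + 1, seed = 0), "K <= n")
})

test_that("silhouette matches the O(n^2) direct oracle to 1e-9", {
  set.seed(9)
  X <- matrix(rnorm(200 * 5), 200)
  for (K in c(2, 4, 7)) {
    lab <- fit_kmeans(X, K, seed = 3)$cluster
    expect_equal(silhouette_mean(X, lab), silhouette_direct(X, lab),
                 tolerance = 1e-9)
    # cross-check against cluster::silhouette on the same partition
    sil <- cluster::silhouette(lab, dist(X))
    expect_equal(silhouette_mean(X, lab), mean(sil[, "sil_width"]),
                 tolerance = 1e-9)
  }

  # two singleton clusters: the singleton convention gives mean silhouette 0
  expect_equal(silhouette_mean(matrix(c(0, 10)), c(1, 2)), 0)
})

test_that("score_k statistics stay in range and find the planted K", {
  centers <- matrix(rnorm(4 * 6), 4) * 0    # 4 orthogonal centers, sep 8
  for (k in 1:4) centers[k, k] <- 8 / sqrt(2)
  b <- make_blobs(centers, 60, sd = 1, seed = 4)
  q <- score_k(b$X, k_range = 2:8, seed = 1, restarts = 5)
  expect_true(all(q$silhouette >= -1 & q$silhouette <= 1))
  expect_true(all(q$calinski_harabasz >= 0))
  expect_equal(q$K[which.max(q$silhouette)], 4)
  expect_equal(suppressWarnings(choose_k(q)), 4L)

  # silhouette column equals the direct oracle for every scanned K
  models <- attr(q, "models")
  for (K in q$K) {
    lab <- models[[as.character(K)]]$cluster
    expect_equal(q$silhouette[q$K == K], silhouette_direct(b$X, lab),
                 tolerance = 1e-9)
  }
  expect_error(score_k(b$X[1:5, ], k_range = 2:10), "n - 1")
})

test_that("choose_k applies the silhouette argmax with CH tie-breaks", {
  q <- data.frame(K = 2:4, silhouette = c(0.2, 0.5, 0.4),
                  calinski_harabasz = c(10, 20, 30))
  expect_warning(k <- choose_k(q), "disagrees")
  expect_equal(k, 3L)

  q2 <- data.frame(K = c(3, 5), silhouette = c(0.5, 0.5),
                   calinski_harabasz = c(10, 20))
  expect_equal(choose_k(q2), 5L)                  # tie -> higher CH

  q3 <- data.frame(K = c(3, 5), silhouette = c(0.5, 0.5),
                   calinski_harabasz = c(20, 20))
  expect_equal(choose_k(q3), 3L)                  # full tie -> smaller K

  q4 <- data.frame(K = 7, silhouette = 0.1, calinski_harabasz = 5)
  expect_equal(choose_k(q4), 7L)
})

test_that("assign_clusters is nearest-centroid with lowest-id ties", {
  model <- structure(list(K = 3L, centroids = rbind(c(0, 0), c(4, 0), c(2, 0))),
                     class = "cluster_model")
  # each centroid maps to its own id
  expect_equal(assign_clusters(model$centroids, model), 1:3)
  # (1, 0) is equidistant to centroids 1 and 3 -> lowest id wins
  expect_equal(assign_clusters(matrix(c(1, 0), 1), model), 1L)
  # brute-force equivalence on random points
  set.seed(11)
  P <- matrix(rnorm(100 * 2, sd = 3), 100)
  brute <- apply(P, 1, function(p)
    which.min(colSums((t(model$centroids) - p)^2)))
  expect_equal(assign_clusters(P, model), as.integer(brute))
  expect_error(assign_clusters(matrix(0, 1, 5), model), "dimension")
})

test_that("calinski_harabasz matches its definition on a worked partition", {
  X <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), ncol = 1)
  lab <- c(1, 1, 1, 1, 2, 2, 2, 2)
  # direct computation: B = sum n_k (mean_k - mean)^2, W = within SS
  mu <- mean(X); mk <- as.vector(tapply(as.vector(X), lab, mean))
  B <- sum(4 * (mk - mu)^2); W <- sum((as.vector(X) - mk[lab])^2)
  expect_equal(calinski_harabasz(X, lab), (B / W) * (8 - 2) / (2 - 1))
})

test_that("cluster model archives round-trip", {
  b <- make_blobs(rbind(c(0, 0), c(8, 8)), 25, seed = 6)
  m <- fit_kmeans(b$X, 2, seed = 1)
  stem <- tempfile()
  write_cluster_model(m, stem)
  m2 <- read_cluster_model(stem)
  expect_equal(m2$K, m$K)
  expect_equal(m2$centroids, unname(m$centroids), tolerance = 1e-12)
  expect_equal(assign_clusters(b$X, m2), m$cluster)
})

test_that("fit_kmeans agrees with stats::kmeans at a well-separated optimum", {
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12), c(12, 12))
  b <- make_blobs(centers, 50, sd = 1, seed = 8)
  ours <- fit_kmeans(b$X, 4, seed = 2)
  ref <- suppressWarnings(stats::kmeans(b$X, 4, nstart = 10, iter.max = 50))
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
  ord_a <- order(ours$centroids[, 1], ours$centroids[, 2])
  ord_b <- order(ref$centers[, 1], ref$centers[, 2])
  expect_equal(unname(ours$centroids[ord_a, ]), unname(ref$centers[ord_b, ]),
               tolerance = 1e-8)
})
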