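#' K-means clustering of patch features
#'
#' Lloyd's algorithm with k-means++ seeding, run `restarts` times from the
#' seeded RNG stream and keeping the run with the lowest inertia (total
#' within-cluster sum of squared Euclidean distances). Fully deterministic
#' given `seed`. If a cluster empties during iteration its centroid is
#' re-seeded from the point farthest from its assigned centroid (logged via
#' `message`).
#'
#' @param X A [feature_matrix()] or numeric `n x D` matrix.
#' @param K Number of clusters, `1 <= K <= n`.
#' @param seed RNG seed (default 0).
#' @param restarts Independent k-means++ initializations (default 10).
#' @param max_iter Iteration cap per restart (default 100).
#' @return Object of class `cluster_model`: `K`, `centroids` (`K x D`),
#'   `cluster` (assignments of the training points), `inertia`, `seed`,
#'   and (once [score_k()] has run) the per-K `quality` table.
#' @export
fit_kmeans <- function(X, K, seed = 0L, restarts = 10L, max_iter = 100L) {
  X <- as_feature_X(X)
  n <- nrow(X)
  if (K < 1 || K > n) stop_invalid("need 1 <= K <= n (n = ", n, ", K = ", K, ")")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- lloyd_once(X, K, max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(K = as.integer(K), centroids = best$centroids,
                 cluster = best$cluster, inertia = best$inertia,
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 iterations = best$iterations, quality = NULL),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> K =", x$K, " D =", ncol(x$centroids),
      " inertia =", signif(x$inertia, 6), " seed =", x$seed, "\n")
  invisible(x)
}

# Squared Euclidean distances between rows of X (n x D) and C (K x D).
dist2_to_centroids <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1)
  if (K > 1) {
    d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[k] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[k], ])^2))
    }
  }
  X[idx, , drop = FALSE]
}

lloyd_once <- function(X, K, max_iter) {
  C <- kmeanspp_init(X, K)
  assign_prev <- rep(-1L, nrow(X))
  it <- 0L
  repeat {
    it <- it + 1L
    d2 <- dist2_to_centroids(X, C)
    a <- max.col(-d2, ties.method = "first")
    for (k in seq_len(K)) {
      if (!any(a == k)) {
        far <- which.max(d2[cbind(seq_len(nrow(X)), a)])
        message("empty cluster ", k, " re-seeded from farthest point ", far)
        C[k, ] <- X[far, ]
        a[far] <- k
      }
    }
    C <- rowsum(X, a) / as.vector(table(factor(a, levels = seq_len(K))))
    if (identical(a, assign_prev) || it >= max_iter) break
    assign_prev <- a
  }
  d2 <- dist2_to_centroids(X, C)
  a <- max.col(-d2, ties.method = "first")
  list(centroids = C, cluster = a,
       inertia = sum(d2[cbind(seq_along(a), a)]), iterations = it)
}

#' Mean silhouette width of a clustering
#'
#' Vectorized O(n^2) computation of the Rousseeuw silhouette
#' `(b - a) / max(a, b)` per point (cohesion `a` = mean within-cluster
#' distance, separation `b` = mean distance to the nearest other cluster),
#' averaged over all points. Points in singleton clusters get silhouette 0.
#'
#' @param X Numeric matrix or [feature_matrix()].
#' @param labels Integer cluster assignments.
#' @param D Optional precomputed `n x n` distance matrix (avoids repeating
#'   the quadratic distance computation when scoring several partitions of
#'   the same points).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_mean <- function(X, labels, D = NULL) {
  X <- as_feature_X(X)
  n <- nrow(X)
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  if (length(sizes) < 2) stop_invalid("silhouette needs >= 2 clusters")
  if (is.null(D)) D <- as.matrix(stats::dist(X))
  S <- rowsum(D, labels)                      # K x n: sum of dists to each cluster
  M <- sweep(S, 1, sizes, "/")                # mean dist to cluster (incl self term)
  own <- cbind(labels, seq_len(n))
  a <- S[own] / pmax(sizes[labels] - 1, 1)
  Mb <- M; Mb[own] <- Inf
  b <- apply(Mb, 2, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1] <- 0
  s[!is.finite(s)] <- 0
  mean(s)
}

#' Calinski-Harabasz index of a clustering
#'
#' Ratio of between-cluster to within-cluster dispersion, scaled by
#' `(n - K) / (K - 1)`.
#'
#' @inheritParams silhouette_mean
#' @return Non-negative index (larger = better separated clusters).
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as_feature_X(X)
  labels <- as.integer(factor(labels))
  n <- nrow(X); K <- max(labels)
  if (K < 2) stop_invalid("Calinski-Harabasz needs >= 2 clusters")
  mu <- colMeans(X)
  sizes <- tabulate(labels)
  C <- rowsum(X, labels) / sizes
  B <- sum(sizes * rowSums(sweep(C, 2, mu)^2))
  W <- sum((X - C[labels, , drop = FALSE])^2)
  if (W == 0) return(Inf)
  (B / W) * (n - K) / (K - 1)
}

#' Score a range of cluster numbers
#'
#' Fits [fit_kmeans()] for each K in `k_range` and computes the mean
#' silhouette width and the Calinski-Harabasz index of each fit. When
#' `n > subsample` the silhouette is computed on a seeded subsample (the
#' distance matrix is quadratic in n); CH is always computed on all points.
#'
#' @inheritParams fit_kmeans
#' @param k_range Candidate cluster numbers (default 2:12).
#' @param subsample Silhouette subsample cap (default 20000).
#' @return Data frame with columns `K`, `silhouette`, `calinski_harabasz`,
#'   carrying the fitted models in `attr(, "models")`.
#' @export
score_k <- function(X, k_range = 2:12, seed = 0L, restarts = 10L,
                    subsample = 20000L) {
  X <- as_feature_X(X)
  n <- nrow(X)
  if (max(k_range) > n - 1) stop_invalid("max(k_range) must be <= n - 1")
  sub <- seq_len(n)
  if (n > subsample) sub <- with_seed(seed, sample.int(n, subsample))
  Dsub <- as.matrix(stats::dist(X[sub, , drop = FALSE]))
  models <- list()
  qual <- data.frame(K = integer(), silhouette = numeric(),
                     calinski_harabasz = numeric())
  for (K in sort(unique(as.integer(k_range)))) {
    m <- fit_kmeans(X, K, seed = seed, restarts = restarts)
    sil <- silhouette_mean(X[sub, , drop = FALSE], m$cluster[sub], D = Dsub)
    ch <- calinski_harabasz(X, m$cluster)
    models[[as.character(K)]] <- m
    qual <- rbind(qual, data.frame(K = K, silhouette = sil,
                                   calinski_harabasz = ch))
  }
  attr(qual, "models") <- models
  qual
}

#' Choose the cluster number from a quality table
#'
#' `K*` is the silhouette argmax; ties are broken by higher
#' Calinski-Harabasz, then smaller K. A warning is raised when the CH argmax
#' disagrees with the silhouette argmax (the two indices peaking together is
#' the expected, well-separated case).
#'
#' @param quality Data frame from [score_k()].
#' @return The chosen integer `K*`.
#' @export
choose_k <- function(quality) {
  if (!nrow(quality)) stop_invalid("empty quality table")
  best_sil <- max(quality$silhouette)
  cand <- quality[quality$silhouette == best_sil, , drop = FALSE]
  cand <- cand[order(-cand$calinski_harabasz, cand$K), , drop = FALSE]
  k_star <- cand$K[1]
  k_ch <- quality$K[which.max(quality$calinski_harabasz)]
  if (k_ch != k_star)
    warning("Calinski-Harabasz argmax (K = ", k_ch,
            ") disagrees with silhouette argmax (K = ", k_star, ")")
  as.integer(k_star)
}

#' Assign patches to the clusters of a fitted model
#'
#' Nearest centroid by Euclidean distance; exact ties go to the lowest
#' cluster id.
#'
#' @param X A [feature_matrix()] or numeric matrix with `D` matching the model.
#' @param model A `cluster_model` from [fit_kmeans()].
#' @return Integer cluster ids, one per row of `X`.
#' @export
assign_clusters <- function(X, model) {
  X <- as_feature_X(X)
  if (ncol(X) != ncol(model$centroids))
    stop_invalid("feature dimension ", ncol(X), " does not match model D = ",
                 ncol(model$centroids))
  d2 <- dist2_to_centroids(X, model$centroids)
  max.col(-d2, ties.method = "first")
}

#' Write / read a cluster model archive (JSON header + centroid CSV)
#'
#' @param model A `cluster_model`.
#' @param path Path stem; writes `<path>.json`, `<path>_centroids.csv` and,
#'   when present, `<path>_quality.csv`.
#' @export
write_cluster_model <- function(model, path) {
  jsonlite::write_json(list(K = model$K, seed = model$seed,
                            inertia = model$inertia, restarts = model$restarts),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(model$centroids),
                   paste0(path, "_centroids.csv"), row.names = FALSE)
  if (!is.null(model$quality))
    utils::write.csv(model$quality, paste0(path, "_quality.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cen <- as.matrix(utils::read.csv(paste0(path, "_centroids.csv")))
  qfile <- paste0(path, "_quality.csv")
  structure(list(K = as.integer(meta$K), centroids = unname(cen),
                 cluster = NULL, inertia = meta$inertia,
                 seed = as.integer(meta$seed), restarts = meta$restarts,
                 iterations = NA_integer_,
                 quality = if (file.exists(qfile)) utils::read.csv(qfile)),
            class = "cluster_model")
}
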