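# Independent brute-force oracles and small fixtures, built in code.

# Exhaustive Otsu: try every split and maximize between-class variance.
otsu_brute <- function(counts) {
  n <- sum(counts)
  bins <- 0:255
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    w0 <- sum(counts[1:(t + 1)]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:(t + 1)] * bins[1:(t + 1)]) / sum(counts[1:(t + 1)])
    mu1 <- sum(counts[(t + 2):256] * bins[(t + 2):256]) / sum(counts[(t + 2):256])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Direct per-point silhouette with explicit loops (singletons -> 0).
silhouette_direct <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# AUC by explicit pair counting, ties counted 1/2.
auc_brute <- function(y, s) {
  pos <- s[as.logical(y)]; neg <- s[!as.logical(y)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Rank-formula AUC (fast enough for bootstrap resampling).
auc_rank_h <- function(y, s) {
  y <- as.logical(y)
  r <- rank(s, ties.method = "average")
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Adjusted Rand index between two partitions.
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  exp_ <- si * sj / ch2(sum(tab))
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Isotropic Gaussian blobs around given centers.
make_blobs <- function(centers, n_per, sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# A constant classifier: always (near-)certain of one class.
make_const_clf <- function(class, classes = glioma_classes(), D = 2) {
  B <- matrix(0, D + 1, length(classes), dimnames = list(NULL, classes))
  B[1, class] <- 50
  structure(list(classes = classes, coef = B, descriptor = "const",
                 metadata = list(classes_present = classes)),
            class = "patch_classifier")
}
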