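#' Feature extractor contract
#'
#' A feature extractor maps a patch raster (resized to 256 x 256) to a
#' fixed-length numeric vector. `transform` must be a pure function of pixel
#' content: the same patch always yields the same vector of length `dim`.
#' The learned 2048-d average-pooling embedding of a 50-layer residual
#' network is one admissible implementation; the package ships a
#' deterministic hand-crafted baseline ([baseline_extractor()]) so that the
#' clustering and selection stages are testable without network training.
#'
#' @param dim Output dimensionality `D`.
#' @param transform Function: `256 x 256 x C` raster in `[0, 255]` -> `D`
#'   numeric values.
#' @param descriptor Provenance string recorded in feature matrices.
#' @return Object of class `feature_extractor`.
#' @export
feature_extractor <- function(dim, transform, descriptor) {
  stopifnot(is.function(transform), dim >= 1)
  structure(list(dim = as.integer(dim), transform = transform,
                 descriptor = descriptor), class = "feature_extractor")
}

#' Deterministic hand-crafted baseline extractor (D = 48)
#'
#' Per-channel mean and dispersion (root variance, so a constant patch
#' scores 0) (6), 8-bin per-channel intensity histograms
#' (24), and gradient-magnitude statistics: mean over a fixed 4 x 4 grid of
#' cells (16) plus overall mean and standard deviation (2). Pixel values are
#' on the 0-255 scale, histogram bins are proportions. On a constant patch
#' all variances and gradient features are 0 and each histogram puts all
#' mass in the bin of the constant value.
#'
#' @return A [feature_extractor()] with `dim = 48`.
#' @export
baseline_extractor <- function() {
  feature_extractor(48L, baseline_transform, "baseline-stats-v1 (D=48)")
}

baseline_transform <- function(patch) {
  if (length(dim(patch)) == 2) patch <- array(patch, c(dim(patch), 3))
  nc <- dim(patch)[3]
  ch <- lapply(seq_len(min(nc, 3)), function(i) patch[, , i])
  if (length(ch) < 3) ch <- rep(ch, length.out = 3)
  means <- vapply(ch, mean, 0)
  # dispersion reported as the root of the per-channel variance so every
  # feature lives on the 0-255 intensity scale (a constant patch gives 0)
  vars <- vapply(ch, function(m) sqrt(mean((m - mean(m))^2)), 0)
  hists <- unlist(lapply(ch, function(m) {
    tabulate(pmin(floor(m / 32) + 1L, 8L), nbins = 8L) / length(m)
  }))
  gray <- (ch[[1]] + ch[[2]] + ch[[3]]) / 3
  gx <- gray[, -1] - gray[, -ncol(gray)]
  gy <- gray[-1, ] - gray[-nrow(gray), ]
  n1 <- min(nrow(gx), nrow(gy)); n2 <- min(ncol(gx), ncol(gy))
  gm <- sqrt(gx[seq_len(n1), seq_len(n2)]^2 + gy[seq_len(n1), seq_len(n2)]^2)
  ri <- ceiling(4 * seq_len(n1) / n1); ci <- ceiling(4 * seq_len(n2) / n2)
  cellsum <- t(rowsum(t(rowsum(gm, ri)), ci))          # 4 x 4, [row cell, col cell]
  cell <- cellsum / outer(tabulate(ri, 4), tabulate(ci, 4))
  c(means, vars, hists, as.vector(cell), mean(gm), stats::sd(gm))
}

#' Resize a square patch to 256 x 256
#'
#' Bilinear resampling (via EBImage); the channel count is preserved and a
#' patch already at 256 x 256 is returned unchanged.
#'
#' @param patch Square raster, `N x N` or `N x N x C`.
#' @return `256 x 256 (x C)` raster of the same scale.
#' @export
resize_patch <- function(patch) {
  d <- dim(patch)
  if (d[1] != d[2]) stop_invalid("resize_patch expects a square patch")
  if (d[1] == 256L) return(patch)
  out <- EBImage::resize(EBImage::Image(patch / 255,
                                        colormode = if (length(d) == 3) "Color" else "Grayscale"),
                         w = 256, h = 256)
  EBImage::imageData(out) * 255
}

#' Feature matrix
#'
#' Rows are patches (aligned with `patch_ids`), columns the `D` extractor
#' dimensions. All entries must be finite.
#'
#' @param X Numeric `n x D` matrix.
#' @param patch_ids Ordered patch identifiers (length `n`).
#' @param descriptor Extractor provenance string.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, patch_ids = rownames(X), descriptor = "unknown") {
  X <- as.matrix(X)
  if (is.null(patch_ids)) patch_ids <- as.character(seq_len(nrow(X)))
  if (length(patch_ids) != nrow(X))
    stop_invalid("patch_ids must align with the rows of X")
  if (any(!is.finite(X))) stop_invalid("feature matrix contains non-finite entries")
  rownames(X) <- patch_ids
  structure(list(patch_ids = as.character(patch_ids), X = X,
                 extractor_descriptor = descriptor), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$X), "patches x", ncol(x$X), "features;",
      x$extractor_descriptor, "\n")
  invisible(x)
}

as_feature_X <- function(X) {
  if (inherits(X, "feature_matrix")) X$X else as.matrix(X)
}

#' Extract features for a set of patches
#'
#' Each patch is resized to 256 x 256 and passed through the extractor; the
#' output has one row per patch in input order. Patches may be given as a
#' named list of rasters, or as a patch manifest data frame together with
#' the slides to crop from. A patch whose pixels cannot be read is skipped
#' with a warning and its row omitted.
#'
#' @param patches Named list of rasters, or a manifest data frame from
#'   [tile_patches()].
#' @param extractor A [feature_extractor()]; default [baseline_extractor()].
#' @param slides When `patches` is a manifest: named list of
#'   [slide_record()]s keyed by `slide_id`.
#' @param standardize Standardize each feature dimension to zero mean / unit
#'   variance across patches (default FALSE; constant dimensions are left
#'   centered).
#' @return A [feature_matrix()].
#' @export
extract_features <- function(patches, extractor = baseline_extractor(),
                             slides = NULL, standardize = FALSE) {
  if (is.data.frame(patches)) {
    if (is.null(slides)) stop_invalid("a manifest needs `slides` for pixel access")
    ids <- paste(patches$slide_id, patches$x, patches$y, sep = "_")
    getter <- function(i) patch_pixels(slides[[patches$slide_id[i]]], patches[i, ])
    n <- nrow(patches)
  } else {
    ids <- names(patches)
    if (is.null(ids)) ids <- as.character(seq_along(patches))
    getter <- function(i) patches[[i]]
    n <- length(patches)
  }
  rows <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    row <- tryCatch(extractor$transform(resize_patch(getter(i))),
                    error = function(e) {
      warning("skipping unreadable patch ", ids[i], ": ", conditionMessage(e))
      NULL
    })
    if (is.null(row)) next
    rows[[i]] <- row
    ok[i] <- TRUE
  }
  X <- do.call(rbind, rows[ok])
  if (standardize) {
    mu <- colMeans(X)
    s <- apply(X, 2, stats::sd)
    X <- sweep(sweep(X, 2, mu), 2, ifelse(s > 0, s, 1), "/")
  }
  feature_matrix(X, ids[ok], extractor$descriptor)
}

#' Write / read a feature store (CSV + JSON header)
#'
#' The matrix goes to `<path>.csv` (first column `patch_id`) and the header
#' (extractor descriptor, D, n) to `<path>.json`.
#'
#' @param fm A [feature_matrix()].
#' @param path Path stem.
#' @export
write_feature_store <- function(fm, path) {
  df <- data.frame(patch_id = fm$patch_ids, fm$X, check.names = FALSE)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(descriptor = fm$extractor_descriptor,
                            dim = ncol(fm$X), n = nrow(fm$X)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(path) {
  df <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feature_matrix(as.matrix(df[, -1, drop = FALSE]), df$patch_id, meta$descriptor)
}
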