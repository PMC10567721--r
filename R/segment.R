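#' Convert an 8-bit RGB raster to CIE L*a*b*
#'
#' Applies the sRGB transfer function and converts to CIE L*a*b* under the
#' D65 white point. H&E tissue is chromatic (large `sqrt(a*^2 + b*^2)`)
#' while slide background is near-achromatic white, which is what tissue
#' segmentation exploits.
#'
#' @param image Numeric array `H x W x 3`, values in `[0, 255]`.
#' @return Numeric array `H x W x 3`: `L*` in `[0, 100]`, `a*`/`b*` signed.
#' @export
rgb_to_lab <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3))
    stop_invalid("rgb_to_lab expects a 3-channel raster")
  d <- dim(image)
  lab <- grDevices::convertColor(matrix(image / 255, ncol = 3), from = "sRGB",
                                 to = "Lab")
  array(lab, d)
}

#' Otsu threshold of a 256-bin histogram
#'
#' Returns the smallest bin index `t` maximizing the between-class variance
#' of the split `[0..t]` vs `[t+1..255]` (ties broken toward the smallest
#' threshold, for determinism).
#'
#' @param counts Non-negative counts over 256 bins (bin indices 0..255).
#' @return Integer threshold `t` in `0..254`.
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256 || any(counts < 0))
    stop_invalid("counts must be 256 non-negative values")
  n <- sum(counts)
  if (n <= 0) stop_invalid("histogram has zero total count")
  if (sum(counts > 0) < 2)
    stop(errorCondition("degenerate histogram: all mass in a single bin",
                        class = c("gliopatch_degenerate_histogram", "error")))
  p <- counts / n
  bins <- 0:255
  w0 <- cumsum(p)[1:255]                 # mass of [0..t], t = 0..254
  mu <- cumsum(p * bins)
  muT <- mu[256]
  mu0 <- mu[1:255]
  w1 <- 1 - w0
  # between-class variance; undefined (0/0) splits get -Inf
  sb <- (muT * w0 - mu0)^2 / (w0 * w1)
  sb[!is.finite(sb)] <- -Inf
  as.integer(which.max(sb) - 1L)
}

#' Segment tissue from background
#'
#' Downsamples the slide (block mean over `downsample x downsample` level-0
#' pixels, approximating a low-power objective), converts to Lab, and
#' thresholds the chroma magnitude `sqrt(a*^2 + b*^2)` with [otsu_threshold()]
#' on a 256-bin chroma histogram over `[0, 128]`. Chromatic (stained) pixels
#' become tissue; near-achromatic white background is excluded. The image is
#' padded with white to a multiple of `downsample`, so the mask always covers
#' the level-0 extent.
#'
#' @param slide A [slide_record()] (or image array / path).
#' @param downsample Integer level-0 pixels per mask pixel (default 4,
#'   i.e. a 5x view of a 20x scan).
#' @return A `tissue_mask`: list with `mask` (logical matrix), `downsample`,
#'   and `threshold_used` (chroma units). A degenerate chroma histogram
#'   (e.g. an entirely white slide) yields an empty mask with a warning.
#' @export
segment_tissue <- function(slide, downsample = 4L) {
  downsample <- as.integer(downsample)
  if (downsample < 1) stop_invalid("downsample must be >= 1")
  img <- slide_image(slide)
  small <- block_mean_rgb(img, downsample, pad_value = 255)
  lab <- rgb_to_lab(small)
  chroma <- sqrt(lab[, , 2]^2 + lab[, , 3]^2)
  breaks <- seq(0, 128, length.out = 257)
  counts <- tabulate(findInterval(pmin(chroma, 128), breaks,
                                  rightmost.closed = TRUE), nbins = 256)
  t_bin <- tryCatch(otsu_threshold(counts), gliopatch_degenerate_histogram =
    function(e) {
      warning("degenerate chroma histogram; returning empty tissue mask")
      NA_integer_
    })
  if (is.na(t_bin)) {
    mask <- matrix(FALSE, nrow(chroma), ncol(chroma))
    thr <- NA_real_
  } else {
    thr <- breaks[t_bin + 2L]  # upper edge of bin t: tissue = chroma > thr
    mask <- chroma > thr
  }
  structure(list(mask = mask, downsample = downsample, threshold_used = thr),
            class = "tissue_mask")
}

# Block-mean downsample of an H x W x 3 array by integer factor, padding the
# bottom/right border with `pad_value` when the factor does not divide H or W.
block_mean_rgb <- function(img, ds, pad_value = 255) {
  if (ds == 1L) return(img)
  d <- dim(img)
  H2 <- ceiling(d[1] / ds); W2 <- ceiling(d[2] / ds)
  out <- array(NA_real_, c(H2, W2, 3))
  padded <- array(pad_value, c(H2 * ds, W2 * ds, 3))
  padded[seq_len(d[1]), seq_len(d[2]), ] <- img
  for (ch in 1:3) {
    m <- padded[, , ch]
    # average within ds x ds blocks via two rowsum passes
    g1 <- rowsum(m, rep(seq_len(H2), each = ds))
    g2 <- rowsum(t(g1), rep(seq_len(W2), each = ds))
    out[, , ch] <- t(g2) / ds^2
  }
  out
}

#' Write / read a tissue mask (PNG + JSON sidecar)
#'
#' The mask raster is stored as a binary PNG; `downsample` and
#' `threshold_used` go to a JSON sidecar `<path>.json`.
#'
#' @param mask A `tissue_mask` from [segment_tissue()].
#' @param path PNG output path.
#' @export
write_tissue_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask$mask), nrow(mask$mask)), path)
  jsonlite::write_json(list(downsample = mask$downsample,
                            threshold_used = mask$threshold_used),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tissue_mask
#' @export
read_tissue_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(mask = m > 0.5, downsample = as.integer(meta$downsample),
                 threshold_used = meta$threshold_used),
            class = "tissue_mask")
}

#' Tile the tissue of a slide into fixed-size patches
#'
#' Lays a non-overlapping `patch_size x patch_size` grid anchored at the
#' level-0 origin (0-based, half-open footprints) over the slide and retains
#' the patches whose tissue fraction under `mask` is at least
#' `min_tissue_fraction`. Only full patches inside the image are considered.
#'
#' @param slide A [slide_record()].
#' @param mask A `tissue_mask` from [segment_tissue()].
#' @param patch_size Patch edge in level-0 pixels (default 1024, i.e.
#'   512 microns at 0.5 microns per pixel).
#' @param min_tissue_fraction Minimum fraction of tissue pixels for a patch
#'   to be retained (default 0.5).
#' @return Data frame of patch references in row-major order with columns
#'   `slide_id`, `patient_id`, `x`, `y`, `size`, `tissue_fraction`, `label`.
#' @export
tile_patches <- function(slide, mask, patch_size = 1024L,
                         min_tissue_fraction = 0.5) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 1) stop_invalid("patch_size must be >= 1")
  img_dim <- dim(slide_image(slide))
  H <- img_dim[1]; W <- img_dim[2]
  ds <- mask$downsample
  if (nrow(mask$mask) * ds < H || ncol(mask$mask) * ds < W)
    stop_invalid("mask does not cover the slide extent")
  ny <- H %/% patch_size; nx <- W %/% patch_size
  rows <- list()
  if (ny > 0 && nx > 0) {
    for (iy in seq_len(ny) - 1L) {
      for (ix in seq_len(nx) - 1L) {
        x <- ix * patch_size; y <- iy * patch_size
        # mask pixels whose centers fall inside [x, x+size) x [y, y+size)
        r0 <- floor(y / ds) + 1L; r1 <- ceiling((y + patch_size) / ds)
        c0 <- floor(x / ds) + 1L; c1 <- ceiling((x + patch_size) / ds)
        tf <- mean(mask$mask[r0:min(r1, nrow(mask$mask)),
                             c0:min(c1, ncol(mask$mask))])
        if (tf >= min_tissue_fraction)
          rows[[length(rows) + 1L]] <- data.frame(
            slide_id = slide$slide_id, patient_id = slide$patient_id,
            x = x, y = y, size = patch_size, tissue_fraction = tf,
            label = slide$label, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(slide_id = character(), patient_id = character(),
                      x = integer(), y = integer(), size = integer(),
                      tissue_fraction = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Crop the pixels of one patch out of its slide
#'
#' @param slide A [slide_record()].
#' @param patch One row of a patch manifest (list or data frame row).
#' @return Numeric `size x size x 3` array in `[0, 255]`.
#' @export
patch_pixels <- function(slide, patch) {
  img <- slide_image(slide)
  x <- patch$x; y <- patch$y; s <- patch$size
  img[(y + 1):(y + s), (x + 1):(x + s), , drop = FALSE]
}
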