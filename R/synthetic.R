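#' Synthetic benchmark configuration
#'
#' Defines the planted-structure benchmark used to exercise every pipeline
#' stage: each slide of a class emits patches from a class-specific mixture
#' over `n_patterns` pattern archetypes. The first `n_informative` patterns
#' are class-informative — their feature-space emission means (and, at the
#' image tier, texture parameters) shift with the slide class — while the
#' remaining patterns are class-independent, carrying no diagnostic signal.
#' By default each class puts 0.4 of its mass on one informative pattern
#' (shared between a "hard pair" of classes with similar histology: A2/A3,
#' O2/O3, A4/GBM) and spreads the rest uniformly over the uninformative
#' patterns.
#'
#' @param n_classes Number of categories (default 6, [glioma_classes()]).
#' @param n_patterns Number of pattern archetypes P (default 9).
#' @param n_informative Leading patterns that carry class signal (default 3).
#' @param mixture Optional `n_classes x n_patterns` mixture matrix, rows
#'   summing to 1; default as described above.
#' @param feature_dim Feature dimensionality D (default 32; must allow
#'   `n_patterns + n_classes` orthogonal directions).
#' @param separation Pairwise distance between pattern centroids in units
#'   of the within-pattern standard deviation (default 8).
#' @param class_shift Distance scale of the class-conditional mean shift
#'   inside informative patterns, same units (default 2).
#' @param slides_per_class Slides (= patients) per class (default 20).
#' @param patches_per_slide Patches per slide (default 64).
#' @param patch_size Edge of generated image patches in pixels (default 256
#'   for desk scale).
#' @param seed Base RNG seed (default 0); the seed fully determines output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 6L, n_patterns = 9L,
                             n_informative = 3L, mixture = NULL,
                             feature_dim = 32L, separation = 8,
                             class_shift = 2, slides_per_class = 20L,
                             patches_per_slide = 64L, patch_size = 256L,
                             seed = 0L) {
  if (n_informative > n_patterns) stop_invalid("n_informative > n_patterns")
  if (feature_dim < n_patterns + n_classes)
    stop_invalid("feature_dim must be >= n_patterns + n_classes")
  if (is.null(mixture)) mixture <- default_mixture(n_classes, n_patterns,
                                                   n_informative)
  mixture <- as.matrix(mixture)
  if (!all(dim(mixture) == c(n_classes, n_patterns)))
    stop_invalid("mixture must be n_classes x n_patterns")
  if (any(mixture < 0) || any(abs(rowSums(mixture) - 1) > 1e-9))
    stop_invalid("mixture rows must be non-negative and sum to 1")
  classes <- if (n_classes == 6) glioma_classes() else
    paste0("C", seq_len(n_classes))
  structure(list(n_classes = as.integer(n_classes),
                 n_patterns = as.integer(n_patterns),
                 n_informative = as.integer(n_informative),
                 mixture = mixture, feature_dim = as.integer(feature_dim),
                 separation = separation, class_shift = class_shift,
                 slides_per_class = as.integer(slides_per_class),
                 patches_per_slide = as.integer(patches_per_slide),
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed), classes = classes),
            class = "synthetic_config")
}

# Each class concentrates on one informative pattern (classes paired onto
# patterns round-robin so histologically "hard pairs" share a pattern) and
# spreads the rest uniformly over the uninformative patterns. With no
# uninformative patterns the informative mass is 1; with 0 informative
# patterns the mixture is uniform over all patterns.
default_mixture <- function(n_classes, n_patterns, n_informative,
                            informative_mass = 0.4) {
  M <- matrix(0, n_classes, n_patterns)
  n_unin <- n_patterns - n_informative
  if (n_informative == 0) return(matrix(1 / n_patterns, n_classes, n_patterns))
  if (n_unin == 0) informative_mass <- 1
  # pair classes onto informative patterns: (1,2)->1, (3,4)->2, ... wrapped;
  # for the 6-class default the pairs are (A2,A3), (A4,O2), (O3,GBM) unless
  # n_informative = 3, where the clinically harder pairing is used.
  pat_of_class <- if (n_classes == 6 && n_informative == 3)
    c(1L, 1L, 3L, 2L, 2L, 3L)   # A2/A3 share 1, O2/O3 share 2, A4/GBM share 3
  else ((seq_len(n_classes) - 1L) %/% 2L) %% n_informative + 1L
  for (c in seq_len(n_classes)) {
    M[c, pat_of_class[c]] <- informative_mass
    if (n_unin > 0)
      M[c, (n_informative + 1):n_patterns] <- (1 - informative_mass) / n_unin
  }
  M
}

# Pattern centroids: separation/sqrt(2) along orthogonal axes gives all
# pairwise centroid distances exactly `separation` (within-sd = 1).
pattern_means <- function(cfg) {
  mu <- matrix(0, cfg$n_patterns, cfg$feature_dim)
  for (p in seq_len(cfg$n_patterns))
    mu[p, p] <- cfg$separation / sqrt(2)
  mu
}

# Class shift directions: orthogonal to the pattern axes.
class_shifts <- function(cfg) {
  sh <- matrix(0, cfg$n_classes, cfg$feature_dim)
  for (c in seq_len(cfg$n_classes))
    sh[c, cfg$n_patterns + c] <- cfg$class_shift / sqrt(2)
  sh
}

#' Generate a feature-space benchmark dataset with planted clusters
#'
#' Slide labels are assigned `slides_per_class` per class; per patch the
#' pattern is drawn from the slide class's mixture row, then features from
#' an isotropic Gaussian (sd 1) around the pattern centroid — shifted by the
#' class-specific offset when the pattern is informative. The same seed
#' reproduces the dataset exactly.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return List: `features` (a [feature_matrix()]), `truth` (list with
#'   `slide_labels` named by slide, `patch_slide`, `patch_class`,
#'   `patch_pattern`).
#' @export
gen_feature_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  mu <- pattern_means(cfg)
  sh <- class_shifts(cfg)
  n_slides <- cfg$n_classes * cfg$slides_per_class
  slide_class <- rep(seq_len(cfg$n_classes), each = cfg$slides_per_class)
  slide_ids <- sprintf("S%03d", seq_len(n_slides))
  n <- n_slides * cfg$patches_per_slide
  with_seed(seed, {
    patch_slide <- rep(seq_len(n_slides), each = cfg$patches_per_slide)
    patch_class <- slide_class[patch_slide]
    patch_pattern <- integer(n)
    for (c in seq_len(cfg$n_classes)) {
      i <- patch_class == c
      patch_pattern[i] <- sample.int(cfg$n_patterns, sum(i), replace = TRUE,
                                     prob = cfg$mixture[c, ])
    }
    X <- matrix(rnorm(n * cfg$feature_dim), n, cfg$feature_dim)
    X <- X + mu[patch_pattern, , drop = FALSE]
    inf <- patch_pattern <= cfg$n_informative
    X[inf, ] <- X[inf, ] + sh[patch_class[inf], , drop = FALSE]
  })
  ids <- sprintf("%s_p%03d", slide_ids[patch_slide],
                 sequence(rep(cfg$patches_per_slide, n_slides)))
  list(features = feature_matrix(X, ids,
         sprintf("synthetic-gaussian (P=%d, sep=%g, seed=%d)",
                 cfg$n_patterns, cfg$separation, seed)),
       truth = list(slide_labels = stats::setNames(cfg$classes[slide_class],
                                                   slide_ids),
                    patch_slide = slide_ids[patch_slide],
                    patch_class = cfg$classes[patch_class],
                    patch_pattern = patch_pattern))
}

# Render one pattern archetype as a patch_size^2 chromatic texture block.
# Odd patterns: oriented sinusoid gratings; even patterns: blob fields.
# Informative patterns code the class into the grating frequency / blob
# density. Returns an s x s x 3 array in [0, 255]; all pixels chromatic.
render_block <- function(cfg, pattern, class_idx, rng_block) {
  s <- cfg$patch_size
  informative <- pattern <= cfg$n_informative
  cshift <- if (informative) class_idx else 0L
  # H&E-like chromatic base colors, one per pattern (pink/purple family);
  # the red channel stays >= 30 above green so chroma never collapses, and
  # base +/- amp stays inside [0, 240] (no clamping, chroma preserved)
  hue <- (pattern * 0.61803) %% 1
  base <- c(175 + 10 * cos(2 * pi * hue),
            85 + 10 * sin(2 * pi * hue),
            150 + 12 * cos(2 * pi * hue + 1))
  amp <- 45
  xs <- matrix(rep(seq_len(s), each = s), s)
  ys <- matrix(rep(seq_len(s), times = s), s)
  if (pattern %% 2 == 1) {
    theta <- pi * pattern / cfg$n_patterns + 0.08 * cshift
    freq <- (0.030 + 0.006 * pattern + 0.012 * cshift)
    wave <- sin(2 * pi * freq * (cos(theta) * xs + sin(theta) * ys))
  } else {
    n_blobs <- 6 + 2 * pattern + 4 * cshift
    cx <- rng_block$runif(n_blobs, 1, s); cy <- rng_block$runif(n_blobs, 1, s)
    r <- s / 14
    wave <- matrix(-1, s, s)
    for (b in seq_len(n_blobs))
      wave <- wave + 2.2 * exp(-((xs - cx[b])^2 + (ys - cy[b])^2) / (2 * r^2))
    wave <- pmin(wave, 1)
  }
  out <- array(0, c(s, s, 3))
  # same-sign channel modulation: the texture rides on lightness, so every
  # tissue pixel keeps the chromatic base color (background stays separable)
  mod <- c(0.9, 1.0, 0.8)
  for (ch in 1:3)
    out[, , ch] <- pmin(pmax(base[ch] + amp * mod[ch] * wave, 0), 240)
  out
}

#' Generate a synthetic composite-texture slide
#'
#' A white canvas carries a contiguous rectangular tissue region tiled by
#' `patches_per_slide` textured blocks of `patch_size` pixels; each block
#' realizes one pattern archetype drawn from the class's mixture row
#' (oriented sinusoid gratings and blob fields, with class-coded parameter
#' shifts for informative patterns). Background pixels are pure white,
#' tissue pixels chromatic, so Otsu chroma segmentation has an exact ground
#' truth. The emitted truth aligns with the level-0 tiling grid.
#'
#' @param cfg A [synthetic_config()].
#' @param class_label Class of the slide (index or label).
#' @param seed RNG seed; same class + seed reproduces the image exactly.
#' @return List: `image` (`H x W x 3`, 0-255), `truth` (list with
#'   `tissue_map` logical block grid, `pattern_grid` integer block grid with
#'   `NA` on background, `patch_size`, `class`).
#' @export
gen_slide <- function(cfg, class_label, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  class_idx <- if (is.character(class_label)) match(class_label, cfg$classes)
               else as.integer(class_label)
  if (is.na(class_idx) || class_idx < 1 || class_idx > cfg$n_classes)
    stop_invalid("unknown class label")
  npatch <- cfg$patches_per_slide
  tr <- floor(sqrt(npatch)); tc <- ceiling(npatch / tr)
  gr <- tr + 2L; gc <- tc + 2L        # one-block white margin all around
  s <- cfg$patch_size
  if (gr * s > 16384 || gc * s > 16384) stop_invalid("patch grid larger than canvas cap")
  img <- array(255, c(gr * s, gc * s, 3))
  tissue_map <- matrix(FALSE, gr, gc)
  pattern_grid <- matrix(NA_integer_, gr, gc)
  with_seed(seed, {
    placed <- 0L
    for (br in seq_len(tr)) for (bc in seq_len(tc)) {
      if (placed >= npatch) break
      placed <- placed + 1L
      pat <- sample.int(cfg$n_patterns, 1, prob = cfg$mixture[class_idx, ])
      rng <- list(runif = function(n, a, b) stats::runif(n, a, b))
      block <- render_block(cfg, pat, class_idx, rng)
      rr <- (br * s + 1):((br + 1) * s); cc <- (bc * s + 1):((bc + 1) * s)
      img[rr, cc, ] <- block
      tissue_map[br + 1L, bc + 1L] <- TRUE
      pattern_grid[br + 1L, bc + 1L] <- pat
    }
  })
  list(image = img,
       truth = list(tissue_map = tissue_map, pattern_grid = pattern_grid,
                    patch_size = s, class = cfg$classes[class_idx]))
}

#' Generate a full synthetic slide set (one slide per patient)
#'
#' `slides_per_class` slides per class; slide `i` of class `c` uses seed
#' `seed + 1000 * c + i` so slides are independent but reproducible.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Base seed (default `cfg$seed`).
#' @return List: `slides` (named list of [slide_record()]s), `truths`
#'   (aligned list of truth objects).
#' @export
gen_slide_set <- function(cfg, seed = cfg$seed) {
  slides <- list(); truths <- list()
  idx <- 0L
  for (c in seq_len(cfg$n_classes)) {
    for (i in seq_len(cfg$slides_per_class)) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      g <- gen_slide(cfg, c, seed = seed + 1000L * c + i)
      slides[[sid]] <- slide_record(sid, sprintf("P%03d", idx), g$image,
                                    label = cfg$classes[c])
      truths[[sid]] <- g$truth
    }
  }
  list(slides = slides, truths = truths)
}
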