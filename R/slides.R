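#' Create a slide record
#'
#' A slide record ties a whole-slide (or plain still) image to its metadata:
#' the patient it came from (one patient has one slide), the resolution in
#' microns per pixel at level 0, and optionally the integrated-diagnosis
#' category used as a weak label for every patch of the slide.
#'
#' @param slide_id Unique slide identifier.
#' @param patient_id Patient identifier (one slide per patient).
#' @param image Either a numeric array `H x W x 3` with values in `[0, 255]`,
#'   or a path to a PNG/TIFF image read lazily by [slide_image()].
#' @param mpp Microns per pixel at level 0. Default 0.5 (20x objective).
#' @param label Optional category, one of [glioma_classes()].
#' @param cohort Optional cohort tag (e.g. "train", "validation", "test").
#' @return An object of class `slide_record`.
#' @export
slide_record <- function(slide_id, patient_id, image, mpp = 0.5,
                         label = NA_character_, cohort = NA_character_) {
  if (!is.numeric(mpp) || length(mpp) != 1 || mpp <= 0)
    stop_invalid("mpp must be a single positive number")
  if (!is.na(label) && !label %in% glioma_classes())
    stop_invalid("label must be one of ", paste(glioma_classes(), collapse = ", "))
  if (is.character(image)) {
    if (!file.exists(image)) stop("slide image not found: ", image)
  } else if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3)) {
    stop_invalid("image must be an H x W x 3 array or a file path")
  }
  structure(list(slide_id = as.character(slide_id),
                 patient_id = as.character(patient_id),
                 image = image, mpp = mpp,
                 label = label, cohort = cohort),
            class = "slide_record")
}

#' @export
print.slide_record <- function(x, ...) {
  d <- tryCatch(dim(slide_image(x)), error = function(e) NULL)
  cat("<slide_record>", x$slide_id, "patient", x$patient_id,
      if (!is.na(x$label)) paste0("[", x$label, "]") else "[unlabeled]",
      if (!is.null(d)) paste0(d[1], "x", d[2]), "\n")
  invisible(x)
}

#' Read a slide image as an RGB array
#'
#' Returns the pixel data of a slide as a numeric `H x W x 3` array with
#' values in `[0, 255]`. Plain PNG and TIFF still images are accepted as
#' single-level slides; in-memory arrays are returned as-is.
#'
#' @param slide A [slide_record()] (or a path / array directly).
#' @return Numeric array `H x W x 3`, values in `[0, 255]`.
#' @export
slide_image <- function(slide) {
  img <- if (inherits(slide, "slide_record")) slide$image else slide
  if (is.character(img)) img <- read_slide_image(img)
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3))
    stop_invalid("slide image must have 3 channels")
  img
}

#' Read a PNG or TIFF image file as a 0-255 RGB array
#'
#' @param path File path; extension decides the reader.
#' @return Numeric array `H x W x 3` in `[0, 255]`.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF slides")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, " (PNG and TIFF are supported)"))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img * 255
}

#' Write an RGB array to PNG
#' @param image Numeric `H x W x 3` array in `[0, 255]`.
#' @param path Output path.
#' @export
write_slide_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Write / read a patch manifest CSV
#'
#' The manifest has one row per retained patch with columns `slide_id`,
#' `patient_id`, `x`, `y`, `size`, `tissue_fraction`, `label` (and
#' `cluster_id` when present). Coordinates are 0-based level-0 pixel origins
#' of half-open `[x, x + size)` footprints.
#'
#' @param patches A patch data frame as returned by [tile_patches()].
#' @param path CSV path.
#' @return `read_patch_manifest` returns the patch data frame.
#' @export
write_patch_manifest <- function(patches, path) {
  utils::write.csv(patches, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_manifest
#' @export
read_patch_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "patient_id", "x", "y", "size", "tissue_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("patch manifest is missing column(s): ", paste(miss, collapse = ", "))
  df
}
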