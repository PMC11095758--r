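#' Single-core fluorescence raster
#'
#' The unit of quantification: one TMA core's grayscale fluorescence image in
#' arbitrary intensity units, with its physical pixel size.
#'
#' @param intensities Numeric matrix, all values >= 0, non-empty.
#' @param pixel_size_um Physical edge length of one pixel in micrometres (> 0).
#' @param core_id TMA position label, e.g. `"A5"`.
#' @return An object of class `core_image`.
#' @export
core_image <- function(intensities, pixel_size_um, core_id = NA_character_) {
  if (!is.matrix(intensities) || length(intensities) == 0L) {
    stop("intensities must be a non-empty matrix")
  }
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(
    list(intensities = intensities, pixel_size_um = pixel_size_um,
         core_id = core_id),
    class = "core_image"
  )
}

#' Binary invasive-cancer mask
#'
#' Pathologist-annotated invasive region of one core, as a logical raster of
#' the same shape as its paired [core_image()].
#'
#' @param mask Logical matrix.
#' @param core_id TMA position label.
#' @return An object of class `invasive_mask`.
#' @export
invasive_mask <- function(mask, core_id = NA_character_) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!is.logical(mask)) {
    storage.mode(mask) <- "logical"
  }
  structure(list(mask = mask, core_id = core_id), class = "invasive_mask")
}

#' @export
print.core_image <- function(x, ...) {
  cat(sprintf("<core_image %s: %d x %d px, %.3g um/px, range [%.4g, %.4g]>\n",
              x$core_id, nrow(x$intensities), ncol(x$intensities),
              x$pixel_size_um, min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.invasive_mask <- function(x, ...) {
  cat(sprintf("<invasive_mask %s: %d x %d px, %d positive>\n",
              x$core_id, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# shape check used at image/mask pairing time
check_pair <- function(image, mask) {
  di <- dim(image$intensities)
  dm <- dim(mask$mask)
  if (!identical(di, dm)) {
    stop(sprintf("image/mask shape mismatch for core %s: %dx%d vs %dx%d",
                 image$core_id, di[1], di[2], dm[1], dm[2]))
  }
  invisible(TRUE)
}
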