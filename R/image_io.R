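#' Read a single-core grayscale TIFF
#'
#' Loads integer inputs losslessly (`tiff::readTIFF(as.is = TRUE)`). Pixel
#' size is attached from the argument; if omitted, embedded TIFF resolution
#' metadata is used when present (argument wins).
#'
#' @param path TIFF file path.
#' @param pixel_size_um Micrometres per pixel edge; optional if the file
#'   carries resolution metadata.
#' @param core_id Label attached to the result (default: file stem).
#' @return A [core_image()].
#' @export
read_core_image <- function(path, pixel_size_um = NULL, core_id = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(x)) != 2L) {
    stop("format error: ", path, " is not a single-channel grayscale raster")
  }
  if (length(x) == 0L) stop("format error: ", path, " is a zero-size image")
  if (is.null(pixel_size_um)) {
    xres <- attr(x, "x.resolution")
    unit <- attr(x, "resolution.unit")
    if (!is.null(xres) && is.numeric(xres) && xres > 0 && !is.null(unit)) {
      pixel_size_um <- switch(as.character(unit),
                              cm = 1e4 / xres, inch = 25400 / xres, NULL)
    }
    if (is.null(pixel_size_um)) {
      stop("pixel_size_um not given and no usable resolution metadata in ",
           path)
    }
  }
  if (is.null(core_id)) core_id <- tools::file_path_sans_ext(basename(path))
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  core_image(m, pixel_size_um, core_id)
}

#' Write a core image as 16-bit grayscale TIFF
#'
#' Intensities are rounded to the nearest integer; values above 65535 saturate
#' at the format maximum with a warning.
#'
#' @param image A [core_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_core_image <- function(image, path) {
  stopifnot(inherits(image, "core_image"))
  v <- round(image$intensities)
  if (any(v > 65535)) {
    warning(sprintf("core %s: %d pixel(s) exceed 65535 and saturate on export",
                    image$core_id, sum(v > 65535)))
    v <- pmin(v, 65535)
  }
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a binary invasive mask (PNG or TIFF)
#'
#' Any strictly positive pixel maps to `TRUE`, zero to `FALSE`.
#'
#' @param path PNG or TIFF file path.
#' @param core_id Label attached to the result (default: file stem).
#' @return An [invasive_mask()].
#' @export
read_mask <- function(path, core_id = NULL) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path, as.is = TRUE),
              stop("unsupported mask format: ", path))
  if (length(dim(x)) == 3L) x <- x[, , 1L] # collapse gray-alpha channels
  if (is.null(core_id)) core_id <- tools::file_path_sans_ext(basename(path))
  invasive_mask(matrix(x > 0, nrow(x), ncol(x)), core_id)
}

#' Write a binary mask as PNG
#'
#' @param mask An [invasive_mask()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "invasive_mask"))
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' Parse a TMA core position label
#'
#' Labels are one letter `A`-`Z` (the row) followed by a positive integer (the
#' column), e.g. `"A5"` is row 1 column 5, `"M16"` row 13 column 16.
#'
#' @param label Character vector of labels.
#' @return Data frame with integer columns `row` and `column`.
#' @export
parse_core_id <- function(label) {
  label <- as.character(label)
  ok <- grepl("^[A-Z][0-9]+$", label)
  if (any(!ok)) {
    stop("malformed core ID: ", paste(label[!ok], collapse = ", "),
         " (expected a letter A-Z followed by a positive integer)")
  }
  row <- match(substr(label, 1L, 1L), LETTERS)
  column <- as.integer(substring(label, 2L))
  if (any(column < 1L)) {
    stop("malformed core ID: ", paste(label[column < 1L], collapse = ", "),
         " (column must be >= 1)")
  }
  data.frame(row = row, column = column)
}
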