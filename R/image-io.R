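# Raster input/output. A grayscale image is represented throughout as a
# plain numeric matrix on the 8-bit 0..255 intensity scale, rows = image rows.

#' Read an AFM raster image as grayscale
#'
#' Decodes a PNG, TIFF or JPEG file and converts it to a single-channel
#' matrix on the 0--255 scale. Lossless inputs (PNG/TIFF) are recommended;
#' JPEG is accepted but its compression artifacts are not corrected.
#'
#' @param path Path to the image file.
#' @return Numeric matrix of intensities in \[0, 255\].
#' @export
read_afm_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    vlp_abort(paste0("Cannot read image: '", path, "' does not exist."),
              class = "io_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE)) {
          vlp_abort("Package 'tiff' is required to read TIFF images.", "io_error")
        }
        tiff::readTIFF(path)
      },
      jpg = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE)) {
          vlp_abort("Package 'jpeg' is required to read JPEG images.", "io_error")
        }
        jpeg::readJPEG(path)
      },
      vlp_abort(paste0("Unsupported image format '", ext, "' for: ", path),
                class = "io_error")
    ),
    error = function(e) {
      vlp_abort(paste0("Failed to decode image '", path, "': ",
                       conditionMessage(e)), class = "io_error")
    }
  )
  g <- to_grayscale(arr)
  # decoders return doubles on [0, 1]; bring gray matrices onto the 8-bit scale
  if (max(g) <= 1 + 1e-12) g <- g * 255
  g
}

#' Convert a raster to single-channel grayscale
#'
#' A 2-D matrix is returned unchanged (idempotent). A 3-D array is reduced
#' with the ITU-R BT.601 luminance weights
#' \eqn{0.299 R + 0.587 G + 0.114 B} (an alpha channel is ignored); arrays
#' on the decoder's \[0, 1\] scale are then expanded to 0--255.
#'
#' @param image Numeric matrix (gray) or 3-D array (RGB/RGBA).
#' @return Numeric matrix of intensities.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) {
    if (any(!is.finite(image))) vlp_abort("Image intensities must be finite.")
    return(image)
  }
  if (!is.array(image) || length(dim(image)) != 3L || !dim(image)[3] %in% c(1L, 3L, 4L)) {
    vlp_abort("`image` must be a matrix or an array with 1, 3 or 4 channels.")
  }
  g <- if (dim(image)[3] == 1L) {
    image[, , 1]
  } else {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  if (any(!is.finite(g))) vlp_abort("Image intensities must be finite.")
  if (max(g) <= 1 + 1e-12) g <- g * 255
  g
}

#' Write a grayscale image as PNG
#'
#' @param image Numeric matrix of intensities in \[0, 255\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_afm_image <- function(image, path) {
  if (!is.matrix(image)) vlp_abort("`image` must be a matrix.")
  png::writePNG(pmin(pmax(image, 0), 255) / 255, target = path)
  invisible(path)
}

# pixels-per-200-nm calibration checks; the published scale bars span 103-125
check_calibration <- function(calibration, warn_range = c(103, 125)) {
  if (length(calibration) != 1L || !is.finite(calibration) || calibration <= 0) {
    vlp_abort("`calibration` (pixels per 200 nm) must be a positive number.")
  }
  if (calibration < warn_range[1] || calibration > warn_range[2]) {
    warn(sprintf(
      "Calibration %.1f px per 200 nm lies outside the typical %g-%g range.",
      calibration, warn_range[1], warn_range[2]))
  }
  invisible(calibration)
}

#' Pixel-to-nanometre conversion factor
#'
#' @param calibration Pixels per 200 nm.
#' @return Nanometres per pixel (`200 / calibration`).
#' @export
nm_per_px <- function(calibration) {
  check_calibration(calibration)
  200 / calibration
}
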