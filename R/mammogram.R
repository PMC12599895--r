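# core image container

#' Construct a mammogram object
#'
#' A mammogram is a 2D grayscale intensity matrix on the internal \[0, 1\]
#' scale plus acquisition metadata. Pixel values must be finite and
#' nonnegative; geometry is row-major with 0-based half-open bounding boxes
#' throughout the package.
#'
#' @param pixels numeric matrix of nonnegative intensities.
#' @param patient_id patient identifier.
#' @param view projection view, `"CC"` or `"MLO"`.
#' @param round screening round, `"prior"` or `"recent"`.
#' @param pixel_spacing optional pixel size in mm/pixel.
#' @param intensity_range representable intensity range, default `c(0, 1)`.
#' @return An object of class `mammogram`.
#' @export
#' @examples
#' m <- mammogram(matrix(runif(64 * 64), 64), patient_id = "P1",
#'                view = "CC", round = "recent")
#' dim(m$pixels)
mammogram <- function(pixels, patient_id = NA_character_,
                      view = c("CC", "MLO"), round = c("recent", "prior"),
                      pixel_spacing = NA_real_, intensity_range = c(0, 1)) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixels must be finite and nonnegative", call. = FALSE)
  view <- match.arg(view)
  round <- match.arg(round)
  structure(list(pixels = pixels, patient_id = patient_id, view = view,
                 round = round, pixel_spacing = pixel_spacing,
                 intensity_range = intensity_range),
            class = "mammogram")
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram %s %s %s: %d x %d px, range [%.3f, %.3f]>\n",
              x$patient_id, x$view, x$round, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# rebuild a mammogram with new pixels, keeping metadata
update_pixels <- function(img, pixels) {
  if (inherits(img, "mammogram")) {
    img$pixels <- pixels
    img
  } else pixels
}

#' Read a mammogram from a PNG or TIFF file
#'
#' @param path image file path (.png, .tif, .tiff).
#' @param ... metadata passed to [mammogram()].
#' @return A `mammogram` with pixels scaled to \[0, 1\].
#' @export
read_mammogram <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(px)) == 3) px <- px[, , 1]
  mammogram(px, ...)
}

#' Write a mammogram to disk as 16-bit TIFF or 8-bit PNG
#'
#' @param img a `mammogram` or numeric matrix in \[0, 1\].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mammogram <- function(img, path) {
  px <- clip01(as_pixels(img))
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16),
    png = png::writePNG(px, path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (identical(ok, FALSE)) stop("failed to write ", path, call. = FALSE)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask logical or 0/1 matrix.
#' @param path output .png path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path .png path.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px > 0.5
}
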