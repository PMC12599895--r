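# contrast enhancement and border cleanup before registration
#
# Stage order: CLAHE -> gamma correction -> border removal. All work is done
# on the internal [0, 1] float scale; conversion back to the source bit depth
# happens only on write.

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit to bound noise
#' amplification. `clip_limit` is the normalized clip fraction (as a
#' fraction of tile pixels per histogram bin multiple); internally mapped to
#' the equalizer's relative limit. A constant image is returned unchanged
#' (no contrast to redistribute).
#'
#' @param img `mammogram` or numeric matrix in \[0, 1\].
#' @param clip_limit normalized clip limit (> 0), default 0.01.
#' @param tiles tile grid `c(nx, ny)`, default 8x8.
#' @return Enhanced image of the same type, in \[0, 1\].
#' @export
apply_clahe <- function(img, clip_limit = 0.01, tiles = c(8, 8)) {
  px <- as_pixels(img)
  if (length(dim(px)) != 2) stop("input must be a 2D image", call. = FALSE)
  if (clip_limit <= 0) stop("clip_limit must be > 0", call. = FALSE)
  if (any(tiles < 1)) stop("tiles must be >= 1x1", call. = FALSE)
  if (diff(range(px)) == 0) return(img)
  out <- EBImage::imageData(EBImage::clahe(EBImage::Image(clip01(px)),
                                           nx = tiles[1], ny = tiles[2],
                                           bins = 256,
                                           limit = clip_limit * 256,
                                           keep.range = TRUE))
  update_pixels(img, clip01(out))
}

#' Gamma correction
#'
#' Power-law remapping `x^gamma` on the normalized \[0, 1\] scale. The rank
#' order of pixel intensities is preserved; composing `gamma` and `1/gamma`
#' recovers the input.
#'
#' @param img `mammogram` or numeric matrix in \[0, 1\].
#' @param gamma positive exponent; `< 1` brightens, `> 1` darkens.
#' @return Corrected image of the same type.
#' @export
#' @examples
#' gamma_correct(matrix(0.25, 2, 2), 0.5)   # -> 0.5
gamma_correct <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a positive number", call. = FALSE)
  px <- clip01(as_pixels(img))
  update_pixels(img, px^gamma)
}

#' Breast border removal
#'
#' Segments the breast as the dominant bright region: Otsu threshold on a
#' Gaussian-blurred copy (blurring suppresses background noise amplified by
#' the preceding contrast enhancement), morphological opening (disc radius
#' `open_radius`), removal of components touching two or more image edges
#' (frame lines, labels), largest remaining connected component, hole
#' filling. Pixels outside the mask are set to 0.
#'
#' @param img `mammogram` or numeric matrix in \[0, 1\].
#' @param open_radius opening disc radius in pixels.
#' @param blur_sigma Gaussian sigma (pixels) for the threshold image.
#' @return list with `image` (masked image, same type as input) and `mask`
#'   (logical breast mask).
#' @export
remove_border <- function(img, open_radius = 5, blur_sigma = 3) {
  px <- clip01(as_pixels(img))
  if (diff(range(px)) == 0)
    stop("border removal failed: empty foreground", call. = FALSE)
  pb <- if (blur_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(px), blur_sigma)) else px
  thr <- EBImage::otsu(EBImage::Image(pb), range = c(0, 1))
  bw <- pb > thr
  bw <- EBImage::imageData(EBImage::opening(EBImage::Image(bw * 1),
                                            disc_kernel(open_radius))) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  n <- max(lab)
  if (n == 0) stop("border removal failed: empty foreground", call. = FALSE)
  nr <- nrow(px); nc <- ncol(px)
  keep <- logical(n)
  sizes <- tabulate(lab[lab > 0], n)
  for (k in seq_len(n)) {
    touches <- sum(any(lab[1, ] == k), any(lab[nr, ] == k),
                   any(lab[, 1] == k), any(lab[, nc] == k))
    keep[k] <- touches < 2
  }
  if (!any(keep)) keep <- sizes == max(sizes)   # frame-only degenerate case
  sizes[!keep] <- 0
  mask <- lab == which.max(sizes)
  # closing smooths boundary notches that would poison downstream erosions
  mask <- EBImage::imageData(EBImage::closing(EBImage::Image(mask * 1),
                                              disc_kernel(open_radius))) > 0
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  if (!any(mask)) stop("border removal failed: empty foreground", call. = FALSE)
  list(image = update_pixels(img, px * mask), mask = mask)
}

#' Full pre-processing pipeline
#'
#' Applies CLAHE, gamma correction and border removal, in that order.
#'
#' @param img `mammogram` or numeric matrix in \[0, 1\].
#' @param params list with optional entries `clip_limit`, `tiles`, `gamma`,
#'   `open_radius`; missing entries use the stage defaults.
#' @return list with `image` (pre-processed) and `mask` (breast mask).
#' @export
preprocess_pipeline <- function(img, params = list()) {
  p <- modifyList(list(clip_limit = 0.01, tiles = c(8, 8), gamma = 1.2,
                       open_radius = 5), params)
  out <- apply_clahe(img, p$clip_limit, p$tiles)
  out <- gamma_correct(out, p$gamma)
  remove_border(out, p$open_radius)
}
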