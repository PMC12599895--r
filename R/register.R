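# deformable (Demons) and affine registration of sequential mammograms
#
# The Demons solver is the classic intensity-driven variant: per-iteration
# displacement updates from the fixed-image gradient, followed by Gaussian
# smoothing of the accumulated field, inside a coarse-to-fine pyramid.

#' Zero deformation field for a given image shape
#' @param shape integer vector `c(rows, cols)`.
#' @return A `rows x cols x 2` array of zero displacements (row, col offsets).
#' @export
zero_field <- function(shape) array(0, c(shape[1], shape[2], 2))

#' Smooth random deformation field from Gaussian bumps
#'
#' Sums a few randomly placed isotropic Gaussian bumps with random 2D
#' amplitudes and rescales so the maximum displacement magnitude equals
#' `magnitude` pixels. Used by the phantom generator to emulate positioning
#' and compression differences between screening rounds.
#'
#' @param shape `c(rows, cols)`.
#' @param magnitude maximum displacement magnitude in pixels.
#' @param n_bumps number of Gaussian bumps.
#' @return Deformation field array (`rows x cols x 2`).
#' @export
random_smooth_field <- function(shape, magnitude, n_bumps = 3) {
  f <- zero_field(shape)
  if (magnitude <= 0) return(f)
  nr <- shape[1]; nc <- shape[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(n_bumps)) {
    r0 <- runif(1, 0.15 * nr, 0.85 * nr)
    c0 <- runif(1, 0.15 * nc, 0.85 * nc)
    sg <- runif(1, nr / 6, nr / 3)
    g <- exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sg^2))
    amp <- rnorm(2)
    f[, , 1] <- f[, , 1] + amp[1] * g
    f[, , 2] <- f[, , 2] + amp[2] * g
  }
  mx <- sqrt(max(f[, , 1]^2 + f[, , 2]^2))
  if (mx > 0) f <- f * (magnitude / mx)
  f
}

#' Warp an image through a deformation field
#'
#' Backward-mapping resampling with bilinear interpolation:
#' `out(x) = img(x + field(x))`. Samples falling outside the image domain
#' are set to 0.
#'
#' @param img `mammogram` or numeric matrix.
#' @param field deformation field array (`rows x cols x 2`, row/col offsets
#'   in pixels).
#' @return Same type as `img`, warped.
#' @export
#' @examples
#' img <- matrix(0, 32, 32); img[16, 16] <- 1
#' f <- zero_field(c(32, 32)); f[, , 1] <- 2   # sample 2 rows down
#' w <- warp_image(img, f)
#' which(w == max(w), arr.ind = TRUE)          # delta moved to row 14
warp_image <- function(img, field) {
  px <- as_pixels(img)
  nr <- nrow(px); nc <- ncol(px)
  if (!identical(dim(field), c(nr, nc, 2L)) &&
      !identical(dim(field), as.integer(c(nr, nc, 2))))
    stop("field shape does not match image", call. = FALSE)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sr <- rr + field[, , 1]
  sc <- cc + field[, , 2]
  out <- bilinear_sample(px, sr, sc)
  update_pixels(img, out)
}

# bilinear interpolation of px at (sr, sc); out-of-domain -> 0
bilinear_sample <- function(px, sr, sc) {
  nr <- nrow(px); nc <- ncol(px)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  valid <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  r0c <- pmin(pmax(r0, 1), nr); r1c <- pmin(r0c + 1, nr)
  c0c <- pmin(pmax(c0, 1), nc); c1c <- pmin(c0c + 1, nc)
  idx <- function(r, c) px[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fr) * (1 - fc) * idx(r0c, c0c) +
       (1 - fr) * fc       * idx(r0c, c1c) +
       fr       * (1 - fc) * idx(r1c, c0c) +
       fr       * fc       * idx(r1c, c1c)
  out <- matrix(v, nr, nc)
  out[!valid] <- 0
  out
}

mse <- function(a, b) mean((as_pixels(a) - as_pixels(b))^2)

resize_matrix <- function(px, nr, nc) {
  EBImage::imageData(EBImage::resize(EBImage::Image(px), w = nr, h = nc))
}

smooth_field <- function(field, sigma) {
  if (sigma <= 0) return(field)
  field[, , 1] <- EBImage::imageData(EBImage::gblur(EBImage::Image(field[, , 1]), sigma))
  field[, , 2] <- EBImage::imageData(EBImage::gblur(EBImage::Image(field[, , 2]), sigma))
  field
}

image_gradient <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  gr <- (px[c(2:nr, nr), ] - px[c(1, 1:(nr - 1)), ]) / 2
  gc <- (px[, c(2:nc, nc)] - px[, c(1, 1:(nc - 1))]) / 2
  list(r = gr, c = gc)
}

#' Demons deformable registration
#'
#' Registers `moving` onto `fixed` with classic Demons forces: at each
#' iteration the displacement update at every pixel is
#' `diff * grad / (|grad|^2 + diff^2)` (Thirion's normalization), the
#' accumulated field is smoothed with a Gaussian of `smoothing_sigma`
#' pixels, and a 3-level coarse-to-fine pyramid provides capture range.
#' If the optimization fails to reduce the mean squared difference the
#' identity field is returned, so registration never makes the pair worse.
#'
#' @param fixed reference (`mammogram` or matrix), typically the recent view.
#' @param moving image to deform, typically the prior view.
#' @param iterations iterations per pyramid level, coarsest first.
#' @param smoothing_sigma Gaussian sigma (pixels) for field regularization.
#' @param levels number of pyramid levels.
#' @return list with `warped` (moving resampled through the field) and
#'   `field` (deformation field; `warp_image(moving, field) == warped`).
#' @export
demons_register <- function(fixed, moving, iterations = c(60, 30, 15),
                            smoothing_sigma = 2, levels = length(iterations)) {
  stopifnot_same_shape(fixed, moving)
  fx <- as_pixels(fixed); mv <- as_pixels(moving)
  nr <- nrow(fx); nc <- ncol(fx)
  iterations <- rep_len(iterations, levels)
  field <- NULL
  for (lev in seq_len(levels)) {
    sc <- 2^(levels - lev)
    lr <- max(16, round(nr / sc)); lc <- max(16, round(nc / sc))
    fxl <- resize_matrix(fx, lr, lc)
    mvl <- resize_matrix(mv, lr, lc)
    if (is.null(field)) {
      field <- zero_field(c(lr, lc))
    } else {
      f1 <- resize_matrix(field[, , 1], lr, lc) * (lr / nrow(field))
      f2 <- resize_matrix(field[, , 2], lr, lc) * (lc / ncol(field))
      field <- array(c(f1, f2), c(lr, lc, 2))
    }
    grad <- image_gradient(fxl)
    g2 <- grad$r^2 + grad$c^2
    for (it in seq_len(iterations[lev])) {
      w <- warp_image(mvl, field)
      d <- fxl - w
      den <- g2 + d^2
      ok <- den > 1e-9
      ur <- matrix(0, lr, lc); uc <- matrix(0, lr, lc)
      ur[ok] <- (d * grad$r)[ok] / den[ok]
      uc[ok] <- (d * grad$c)[ok] / den[ok]
      # cap the per-iteration step at 2 px for stability
      ur <- pmin(pmax(ur, -2), 2); uc <- pmin(pmax(uc, -2), 2)
      field[, , 1] <- field[, , 1] + ur
      field[, , 2] <- field[, , 2] + uc
      field <- smooth_field(field, smoothing_sigma)
    }
  }
  if (nrow(field) != nr || ncol(field) != nc) {
    f1 <- resize_matrix(field[, , 1], nr, nc) * (nr / nrow(field))
    f2 <- resize_matrix(field[, , 2], nr, nc) * (nc / ncol(field))
    field <- array(c(f1, f2), c(nr, nc, 2))
  }
  warped <- warp_image(mv, field)
  if (mse(fx, warped) > mse(fx, mv)) {   # never worse than no registration
    field <- zero_field(c(nr, nc))
    warped <- mv
  }
  attr(field, "provenance") <- list(algorithm = "demons",
                                    iterations = iterations,
                                    smoothing_sigma = smoothing_sigma,
                                    levels = levels)
  list(warped = update_pixels(moving, warped), field = field)
}

# apply 6-parameter affine (a11,a12,a21,a22,tr,tc) about the image center
affine_field <- function(shape, theta) {
  nr <- shape[1]; nc <- shape[2]
  rr <- matrix(seq_len(nr), nr, nc) - (nr + 1) / 2
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - (nc + 1) / 2
  sr <- theta[1] * rr + theta[2] * cc + theta[5]
  sc <- theta[3] * rr + theta[4] * cc + theta[6]
  array(c(sr - rr, sc - cc), c(nr, nc, 2))
}

#' Affine registration baseline
#'
#' Least-squares 6-parameter affine alignment of `moving` to `fixed`,
#' optimized with Nelder-Mead on lightly blurred images. Provided as the
#' rigid/global baseline against which the Demons deformable registration
#' is compared.
#'
#' @inheritParams demons_register
#' @param blur_sigma Gaussian blur (pixels) applied to both images before
#'   computing the cost, for a smoother objective.
#' @return list with `warped`, `transform` (6-parameter vector
#'   `a11,a12,a21,a22,tr,tc` about the image center) and `field` (the
#'   equivalent dense deformation field).
#' @export
affine_register <- function(fixed, moving, blur_sigma = 1.5) {
  stopifnot_same_shape(fixed, moving)
  fx <- as_pixels(fixed); mv <- as_pixels(moving)
  fxb <- if (blur_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(fx), blur_sigma)) else fx
  mvb <- if (blur_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(mv), blur_sigma)) else mv
  shape <- dim(fx)
  cost <- function(theta) mse(fxb, warp_image(mvb, affine_field(shape, theta)))
  theta0 <- c(1, 0, 0, 1, 0, 0)
  fit <- optim(theta0, cost, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-9))
  if (!is.finite(fit$value))
    stop("affine registration failed: non-finite objective", call. = FALSE)
  theta <- fit$par
  if (cost(theta) > cost(theta0)) theta <- theta0   # never worse than identity
  field <- affine_field(shape, theta)
  attr(field, "provenance") <- list(algorithm = "affine", transform = theta)
  list(warped = update_pixels(moving, as_pixels(warp_image(mv, field))),
       transform = theta, field = field)
}

#' Mean endpoint error between two deformation fields
#'
#' Mean Euclidean distance between corresponding displacements, optionally
#' restricted to a region mask (e.g., the breast interior).
#'
#' @param estimated,truth deformation field arrays of identical shape.
#' @param mask optional logical matrix restricting the average.
#' @return Mean endpoint error in pixels.
#' @export
endpoint_error <- function(estimated, truth, mask = NULL) {
  d <- sqrt((estimated[, , 1] - truth[, , 1])^2 +
            (estimated[, , 2] - truth[, , 2])^2)
  if (!is.null(mask)) d <- d[mask]
  mean(d)
}
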