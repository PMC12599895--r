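# warping, Demons and affine registration

test_that("warping follows the backward-mapping contract", {
  img <- matrix(0, 32, 32); img[16, 16] <- 1
  expect_identical(subtracad:::as_pixels(warp_image(img, zero_field(c(32, 32)))),
                   img)
  # constant field (2, 0): out(x) = img(x + 2 rows), delta moves up 2 rows
  f <- zero_field(c(32, 32)); f[, , 1] <- 2
  w <- subtracad:::as_pixels(warp_image(img, f))
  expect_equal(which(w == max(w), arr.ind = TRUE)[1, ], c(row = 14, col = 16))
  expect_equal(max(w), 1)
  expect_error(warp_image(img, zero_field(c(16, 16))), "shape")
})

test_that("warp followed by inverse warp recovers a smooth image", {
  px <- smooth_test_image()
  f <- subtracad:::with_seed(3, random_smooth_field(dim(px), 2))
  back <- subtracad:::as_pixels(warp_image(warp_image(px, f), -f))
  interior <- matrix(FALSE, nrow(px), ncol(px))
  interior[11:(nrow(px) - 10), 11:(ncol(px) - 10)] <- TRUE
  rms_ratio <- sqrt(mean((back[interior] - px[interior])^2)) /
    sqrt(mean(px[interior]^2))
  expect_lt(rms_ratio, 0.02)
})

test_that("random smooth fields hit the requested maximum magnitude", {
  for (seed in 1:3) {
    f <- subtracad:::with_seed(seed, random_smooth_field(c(64, 64), 5))
    expect_equal(max(sqrt(f[, , 1]^2 + f[, , 2]^2)), 5, tolerance = 1e-9)
  }
  expect_true(all(random_smooth_field(c(64, 64), 0) == 0))
})

test_that("Demons on an identical pair returns a near-zero field", {
  px <- fixture_pair(1)$pp_r$image
  reg <- demons_register(px, px)
  expect_lt(max(abs(reg$field)), 1e-3)
  expect_equal(subtracad:::as_pixels(reg$warped),
               subtracad:::as_pixels(px), tolerance = 1e-6)
})

test_that("Demons recovers a pure translation within a pixel", {
  cfg <- cohort_config(n_patients = 1, image_shape = c(128, 104),
                       deformation_magnitude = 0, noise_sigma = 0, seed = 9)
  pat <- generate_patient(cfg, "P1", patient_class = "normal")
  px <- pat$images$CC_prior$pixels
  f <- zero_field(dim(px)); f[, , 1] <- 5; f[, , 2] <- 3
  moved <- subtracad:::as_pixels(warp_image(px, f))
  reg <- demons_register(moved, px)
  mask <- pat$truth$views$CC$breast_mask_prior
  interior <- mask & (subtracad:::as_pixels(warp_image(mask * 1, f)) > 0.5)
  interior <- EBImage::imageData(EBImage::erode(EBImage::Image(interior * 1),
                subtracad:::disc_kernel(6))) > 0
  expect_lt(abs(mean(reg$field[, , 1][interior]) - 5), 1)
  expect_lt(abs(mean(reg$field[, , 2][interior]) - 3), 1)
})

test_that("Demons never increases the pair MSE and reduces it on elastic phantoms", {
  for (seed in 1:3) {
    fx <- fixture_pair(seed)
    m0 <- mean((subtracad:::as_pixels(fx$pp_r$image) -
                subtracad:::as_pixels(fx$pp_p$image))^2)
    m1 <- mean((subtracad:::as_pixels(fx$pp_r$image) -
                subtracad:::as_pixels(fx$reg$warped))^2)
    expect_lte(m1, m0)
    expect_lt(m1, 0.8 * m0)
  }
})

test_that("Demons endpoint error decreases with iterations on average", {
  epe_at <- function(seed, iters) {
    fx <- fixture_pair(seed)
    reg <- demons_register(fx$pp_r$image, fx$pp_p$image, iterations = iters)
    interior <- fx$truth$breast_mask_recent & fx$truth$breast_mask_prior
    endpoint_error(reg$field, fx$truth$deformation, interior)
  }
  seeds <- 1:3
  few <- vapply(seeds, epe_at, numeric(1), iters = c(4, 2, 1))
  many <- vapply(seeds, epe_at, numeric(1), iters = c(60, 30, 15))
  expect_lt(mean(many), mean(few))
})

test_that("affine registration recovers identity and rotation-scale motion", {
  px <- fixture_pair(4, class = "normal")$pp_r$image
  id <- affine_register(px, px)
  expect_lt(max(abs(id$transform - c(1, 0, 0, 1, 0, 0))), 1e-3)
  # rotation 3 degrees + isotropic scale 1.04 about the center
  th <- 3 * pi / 180; s <- 1.04
  theta <- c(s * cos(th), -s * sin(th), s * sin(th), s * cos(th), 0, 0)
  f <- subtracad:::affine_field(dim(subtracad:::as_pixels(px)), theta)
  moving <- subtracad:::as_pixels(warp_image(px, f))
  fit <- affine_register(px, moving)
  mse0 <- mean((subtracad:::as_pixels(px) - moving)^2)
  mse1 <- mean((subtracad:::as_pixels(px) -
                subtracad:::as_pixels(fit$warped))^2)
  expect_lt(mse1, 0.05 * mse0)
})

test_that("Demons beats the affine baseline on elastic deformations", {
  for (seed in 1:2) {
    fx <- fixture_pair(seed)
    aff <- affine_register(fx$pp_r$image, fx$pp_p$image)
    mse_demons <- mean((subtracad:::as_pixels(fx$pp_r$image) -
                        subtracad:::as_pixels(fx$reg$warped))^2)
    mse_affine <- mean((subtracad:::as_pixels(fx$pp_r$image) -
                        subtracad:::as_pixels(aff$warped))^2)
    expect_lte(mse_demons, mse_affine)
  }
})
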