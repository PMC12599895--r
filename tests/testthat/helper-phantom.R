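# shared fixtures: small seeded phantoms, memoized so suites can reuse them

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_cfg <- function(seed = 1, deformation = 4, noise = 0.01) {
  cohort_config(n_patients = 1, image_shape = c(128, 104),
                deformation_magnitude = deformation, noise_sigma = noise,
                seed = seed)
}

# one malignant patient with preprocessing + registration done
fixture_pair <- function(seed = 1, class = "malignant", view = "CC") {
  memo(sprintf("pair_%d_%s_%s", seed, class, view), {
    pat <- generate_patient(small_cfg(seed), sprintf("P%03d", seed),
                            patient_class = class)
    tv <- pat$truth$views[[view]]
    pp_r <- preprocess_pipeline(pat$images[[paste0(view, "_recent")]])
    pp_p <- preprocess_pipeline(pat$images[[paste0(view, "_prior")]])
    reg <- demons_register(pp_r$image, pp_p$image)
    res <- temporal_subtract(pp_r$image, reg$warped, pp_r$mask)
    list(pat = pat, truth = tv, pp_r = pp_r, pp_p = pp_p, reg = reg,
         res = res)
  })
}

# smooth low-frequency test image (no fine texture)
smooth_test_image <- function(nr = 128, nc = 104) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  0.5 + 0.25 * sin(2 * pi * rr / 40) * cos(2 * pi * cc / 35)
}

# random blob ROI for feature property tests
random_roi <- function(seed) {
  subtracad:::with_seed(seed, {
    nr <- 40; nc <- 40
    px <- matrix(runif(nr * nc), nr, nc)
    ctr <- c(20, 20)
    r <- runif(1, 6, 12)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    mask <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2
    list(pixels = px, mask = mask)
  })
}

# rasterized disk mask
disk_mask <- function(radius, pad = 4) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - ctr)^2 + (cc - ctr)^2 <= radius^2
}
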