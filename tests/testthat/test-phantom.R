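# synthetic sequential-mammogram generator

test_that("same config and seed give byte-identical images and masks", {
  cfg <- small_cfg(seed = 42)
  a <- generate_patient(cfg, "P001", patient_class = "malignant")
  b <- generate_patient(cfg, "P001", patient_class = "malignant")
  expect_identical(a$images$CC_recent$pixels, b$images$CC_recent$pixels)
  expect_identical(a$images$MLO_prior$pixels, b$images$MLO_prior$pixels)
  expect_identical(a$truth$views$CC$mass_masks, b$truth$views$CC$mass_masks)
  expect_identical(a$truth$views$CC$deformation, b$truth$views$CC$deformation)
})

test_that("zero deformation and noise give identical prior and recent for normal patients", {
  cfg <- cohort_config(n_patients = 1, image_shape = c(96, 80),
                       deformation_magnitude = 0, noise_sigma = 0, seed = 5)
  pat <- generate_patient(cfg, "P001", patient_class = "normal")
  expect_identical(pat$images$CC_prior$pixels, pat$images$CC_recent$pixels)
  expect_identical(pat$images$MLO_prior$pixels, pat$images$MLO_recent$pixels)
})

test_that("config validation rejects malformed cohorts", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(image_shape = c(32, 80)), "image_shape")
  expect_error(cohort_config(density_weights = c(a = 0.5, b = 0.4,
                                                 c = 0.2, d = 0.1)), "sum")
  expect_error(cohort_config(class_mix = c(normal = 0.9, benign = 0.3,
                                           malignant = 0.1)), "sum")
})

test_that("mass ground truth is well-formed and confined to the breast", {
  for (seed in 1:4) {
    fx <- fixture_pair(seed)
    tv <- fx$truth
    expect_gt(length(tv$mass_masks), 0)
    for (m in tv$mass_masks) {
      expect_gt(sum(m), 0)
      expect_true(all(tv$breast_mask_recent[m]))
    }
    # prior image of a new-mass case has no mass: intensity at the mass
    # footprint matches the surrounding tissue instead of exceeding it
    pri <- fx$pat$images$CC_prior$pixels
    rec <- fx$pat$images$CC_recent$pixels
    um <- Reduce(`|`, tv$mass_masks)
    ring <- EBImage::imageData(EBImage::dilate(EBImage::Image(um * 1),
              subtracad:::disc_kernel(6))) > 0 & !um
    expect_lt(mean(pri[um]) - mean(pri[ring]), 0.05)
    expect_gt(mean(rec[um]) - mean(rec[ring]), 0.08)
  }
})

test_that("inserted masses exceed local background by a contrast margin", {
  fx <- fixture_pair(2)
  cfg <- small_cfg(2)
  rec <- fx$pat$images$CC_recent$pixels
  for (m in fx$truth$mass_masks) {
    ring <- EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1),
              subtracad:::disc_kernel(6))) > 0 & !m
    expect_gt(mean(rec[m]) - mean(rec[ring]), 0.3 * cfg$mass_contrast)
  }
})

test_that("benign masses are rounder than malignant masses", {
  circ <- function(m) unname(shape_features(m)["Shape_Circularity"])
  benign <- c(); malignant <- c()
  for (seed in 1:20) {
    cfg <- cohort_config(n_patients = 1, image_shape = c(128, 104),
                         seed = seed)
    pb <- generate_patient(cfg, "B", patient_class = "benign")
    pm <- generate_patient(cfg, "M", patient_class = "malignant")
    benign <- c(benign, vapply(pb$truth$views$CC$mass_masks, circ, 1))
    malignant <- c(malignant, vapply(pm$truth$views$CC$mass_masks, circ, 1))
  }
  expect_gt(mean(benign), mean(malignant))
  expect_gt(mean(benign) - mean(malignant), 0.3)
})

test_that("cohort generation writes the full manifest and images", {
  out <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 2, views = c("CC", "MLO"),
                       image_shape = c(64, 64), seed = 3)
  manifest <- generate_cohort(cfg, out)
  expect_equal(nrow(manifest), 2 * 2 * 2)   # patients x views x rounds
  expect_true(all(file.exists(manifest$image_path)))
  idx <- read_manifest(file.path(out, "manifest.csv"))
  expect_equal(nrow(idx), 8)
  # single-view, single-patient cohort
  out2 <- withr::local_tempdir()
  m2 <- generate_cohort(cohort_config(n_patients = 1, views = "CC",
                                      image_shape = c(64, 64), seed = 3),
                        out2)
  expect_equal(nrow(m2), 2)
  expect_equal(length(unique(m2$patient_id)), 1)
  # round-trip: written 16-bit image equals in-memory pixels
  img <- read_mammogram(manifest$image_path[1])
  pat <- generate_patient(cfg, "P001")
  expect_equal(img$pixels, pat$images$CC_prior$pixels, tolerance = 1e-4)
})

test_that("density classes follow the cohort weights", {
  dens <- vapply(1:120, function(i) {
    generate_patient(cohort_config(n_patients = 1, views = "CC",
                                   image_shape = c(64, 64), seed = i),
                     sprintf("P%03d", i))$truth$density_class
  }, character(1))
  counts <- table(factor(dens, levels = c("a", "b", "c", "d")))
  gof <- suppressWarnings(
    chisq.test(counts, p = c(0.11, 0.45, 0.39, 0.05)))
  expect_gt(gof$p.value, 0.01)
})
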