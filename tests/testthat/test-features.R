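# the frozen 98-value feature vector

test_that("the feature catalog is frozen at 98 unique names", {
  catalog <- feature_catalog()
  expect_length(catalog, 98)
  expect_false(anyDuplicated(catalog) > 0)
  golden <- readLines(test_path("fixtures", "feature_names.txt"))
  expect_identical(catalog, golden)
  # block sizes: 72 GLCM + 10 FOS + 4 intensity + 12 shape
  expect_length(grep("^GLCM_", catalog), 72)
  expect_length(grep("^FOS_", catalog), 10)
  expect_length(grep("^Intensity_", catalog), 4)
  expect_length(grep("^Shape_", catalog), 12)
})

test_that("a constant ROI follows the degenerate conventions", {
  mask <- disk_mask(6)
  px <- matrix(0.4, nrow(mask), ncol(mask))
  g <- glcm_features(px, mask)
  expect_true(all(g[grep("Correlation_(0|45|90|135)", names(g))] == 0))
  expect_true(all(g[grep("Contrast_(0|45|90|135)", names(g))] == 0))
  expect_true(all(g[grep("Energy_(0|45|90|135)", names(g))] == 1))
  expect_true(all(g[grep("Homogeneity_(0|45|90|135)", names(g))] == 1))
  f <- fos_features(px, mask)
  expect_equal(unname(f[c("FOS_STD", "FOS_Variance", "FOS_Entropy")]),
               c(0, 0, 0))
  expect_equal(unname(f["FOS_Energy"]), 1)
  i <- intensity_features(px, mask)
  expect_equal(unname(i), c(0.4, 0.4, 0.4, 0))
})

test_that("GLCM statistics stay inside their theoretical ranges", {
  for (seed in 1:25) {
    roi <- random_roi(seed)
    g <- glcm_features(roi$pixels, roi$mask)
    corr <- g[grep("Correlation_(0|45|90|135)", names(g))]
    expect_true(all(corr >= -1 - 1e-9 & corr <= 1 + 1e-9))
    expect_true(all(g[grep("Energy_(0|45|90|135)", names(g))] > 0))
    expect_true(all(g[grep("Energy_(0|45|90|135)", names(g))] <= 1 + 1e-9))
    hom <- g[grep("Homogeneity_(0|45|90|135)", names(g))]
    expect_true(all(hom > 0 & hom <= 1 + 1e-9))
    expect_true(all(is.finite(g)))
  }
})

test_that("angle aggregates equal the mean and SD of directional values", {
  roi <- random_roi(3)
  g <- glcm_features(roi$pixels, roi$mask)
  for (d in 1:3) {
    dir_vals <- g[sprintf("GLCM_Correlation_%s_D%d",
                          c("0", "45", "90", "135"), d)]
    expect_equal(unname(g[sprintf("GLCM_Correlation_Mean_D%d", d)]),
                 mean(dir_vals))
    expect_equal(unname(g[sprintf("GLCM_Correlation_STD_D%d", d)]),
                 sd(dir_vals))
  }
})

test_that("first-order statistics satisfy their identities", {
  mask <- matrix(TRUE, 10, 10)
  two <- matrix(rep(c(0, 1), 50), 10, 10)
  f <- fos_features(two, mask)
  expect_equal(unname(f["FOS_Mean"]), 0.5)
  expect_equal(unname(f["FOS_Entropy"]), 1)   # 1 bit
  for (seed in 1:10) {
    roi <- random_roi(seed)
    f <- fos_features(roi$pixels, roi$mask)
    expect_lt(abs(f[["FOS_STD"]]^2 - f[["FOS_Variance"]]), 1e-9)
  }
})

test_that("intensity features order correctly and scale linearly", {
  for (seed in 1:5) {
    roi <- random_roi(seed)
    i <- intensity_features(roi$pixels, roi$mask)
    expect_gte(i[["Intensity_Maximum"]], i[["Intensity_Mean"]])
    expect_gte(i[["Intensity_Mean"]], i[["Intensity_Minimum"]])
    i3 <- intensity_features(roi$pixels * 3, roi$mask)
    expect_equal(unname(i3), unname(i * 3))
  }
})

test_that("shape features match analytic values on squares and disks", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  s <- shape_features(sq)
  expect_equal(unname(s["Shape_Area"]), 100)
  expect_equal(unname(s["Shape_Extent"]), 1)
  expect_equal(unname(s["Shape_FilledArea"]), 100)
  expect_gte(s[["Shape_Solidity"]], 0.99)
  disk <- disk_mask(20)
  sd_ <- shape_features(disk)
  expect_gt(sd_[["Shape_Circularity"]], 0.85)
  expect_lt(sd_[["Shape_Circularity"]], 1.1)
  expect_gte(sd_[["Shape_Solidity"]], 0.95)
  expect_lt(abs(sd_[["Shape_EquivDiameter"]] - 40) / 40, 0.05)
  expect_lt(abs(sd_[["Shape_MajorAxisLength"]] - 40) / 40, 0.06)
  expect_lt(sd_[["Shape_Eccentricity"]], 0.25)
})

test_that("shape features depend on the mask only", {
  roi <- random_roi(4)
  s1 <- shape_features(roi$mask)
  fv1 <- extract_all(list(mask = roi$mask), roi$pixels)
  fv2 <- extract_all(list(mask = roi$mask), roi$pixels * 10)
  shape_cols <- grep("^Shape_", names(fv1))
  expect_equal(fv1[shape_cols], fv2[shape_cols])
  expect_equal(unname(fv1[shape_cols]), unname(s1))
})

test_that("extraction returns exactly 98 named finite values, deterministically", {
  fx <- fixture_pair(1)
  rois <- detect_candidates(fx$res, fx$pp_r$mask)
  expect_gt(length(rois), 0)
  fv <- extract_all(rois[[1]], fx$res)
  expect_length(fv, 98)
  expect_identical(names(fv), feature_catalog())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_all(rois[[1]], fx$res))
})

test_that("report-style names for both classification rounds resolve to the catalog", {
  round1 <- c("Correlation 90 D2", "Correlation Mean D1",
              "Correlation Mean D2", "Correlation 90 D3",
              "Correlation 45 D2", "Correlation 0 D2",
              "Correlation 135 D1", "Correlation Mean D3",
              "Correlation 45 D1", "Correlation 90 D3",
              "Correlation 0 D2", "Correlation 0 D3",
              "Correlation 135 D2", "Correlation 90 D1",
              "Maximum intensity", "Mean intensity",
              "Solidity", "Extent", "STD")
  round2 <- c("Major Axis Length", "Perimeter", "Area",
              "Minor Axis Length", "Equivalent Diameter", "Extent",
              "Convex Area", "Filled Area", "Circularity", "Solidity",
              "Correlation 135 D3", "Correlation 0 D3",
              "Correlation 45 D3", "Correlation Mean D3",
              "Correlation 0 D2", "Correlation 135 D2",
              "Correlation STD D2")
  expect_length(round1, 19)
  expect_length(round2, 17)
  catalog <- feature_catalog()
  for (nm in c(round1, round2))
    expect_true(resolve_feature_name(nm) %in% catalog)
  expect_error(resolve_feature_name("Wavelet L1"), "resolve")
})
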