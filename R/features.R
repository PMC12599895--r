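# fixed 98-value feature vector per candidate ROI
#
# Catalog: 72 GLCM values (4 Haralick statistics x 3 distances x {0, 45, 90,
# 135 degrees, Mean, STD over angles}), 10 first-order statistics, 4
# intensity features, 12 shape features. Order and names are frozen; the
# feature matrix header never changes between runs.

glcm_statistics <- c("Correlation", "Contrast", "Energy", "Homogeneity")
glcm_slots <- c("0", "45", "90", "135", "Mean", "STD")

#' GLCM specification
#'
#' @param distances pixel offsets D1 < D2 < D3.
#' @param levels gray-level quantization count (>= 2).
#' @return list of class `glcm_spec`.
#' @export
glcm_spec <- function(distances = c(1, 2, 4), levels = 16) {
  if (any(diff(distances) <= 0))
    stop("distances must be strictly increasing", call. = FALSE)
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  structure(list(distances = distances, levels = as.integer(levels)),
            class = "glcm_spec")
}

#' Frozen catalog of the 98 feature names
#' @param spec a [glcm_spec()] (distance count fixes the GLCM block).
#' @return Character vector of 98 unique names, in extraction order.
#' @export
feature_catalog <- function(spec = glcm_spec()) {
  glcm <- character(0)
  for (s in glcm_statistics)
    for (d in seq_along(spec$distances))
      for (a in glcm_slots)
        glcm <- c(glcm, sprintf("GLCM_%s_%s_D%d", s, a, d))
  fos <- paste0("FOS_", c("Mean", "STD", "Variance", "Skewness", "Kurtosis",
                          "Entropy", "Energy", "Median", "P01", "P99"))
  intensity <- paste0("Intensity_", c("Maximum", "Mean", "Minimum", "Range"))
  shape <- paste0("Shape_", c("Area", "Perimeter", "MajorAxisLength",
                              "MinorAxisLength", "Eccentricity",
                              "Orientation", "EquivDiameter", "Extent",
                              "ConvexArea", "FilledArea", "Solidity",
                              "Circularity"))
  c(glcm, fos, intensity, shape)
}

# angle -> (row, col) step for one pixel of distance d (image convention:
# 0 deg = east, angles counter-clockwise)
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d))
}

# symmetric normalized co-occurrence matrix of quantized values `qv` (NA
# outside the ROI mask) at one offset
glcm_matrix <- function(qv, offset, levels) {
  nr <- nrow(qv); nc <- ncol(qv)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- qv[r1, c1, drop = FALSE]
  b <- qv[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, levels, levels))
  counts <- tabulate((a[ok] - 1L) * levels + b[ok], levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)                      # symmetric
  P / sum(P)
}

glcm_stats_from_matrix <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  contrast <- sum(P * (i - j)^2)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(i - j)))
  pi_m <- rowSums(P)
  mu <- sum(seq_len(L) * pi_m)
  sg2 <- sum((seq_len(L) - mu)^2 * pi_m)
  correlation <- if (sg2 < 1e-12) 0 else
    (sum(P * i * j) - mu^2) / sg2     # symmetric P: equal marginals
  c(Correlation = correlation, Contrast = contrast, Energy = energy,
    Homogeneity = homogeneity)
}

#' GLCM (Haralick) texture features of an ROI
#'
#' Pixels inside the mask are quantized to `spec$levels` gray levels over the
#' ROI min-max range; for each distance and each of the four directions a
#' symmetric normalized co-occurrence matrix yields correlation, contrast,
#' energy and homogeneity, plus the mean and standard deviation over the four
#' directions. A constant ROI follows the degenerate convention:
#' correlation 0, contrast 0, energy 1, homogeneity 1.
#'
#' @param pixels numeric matrix (full image or ROI crop).
#' @param mask logical ROI mask, same shape as `pixels`.
#' @param spec a [glcm_spec()].
#' @return Named numeric vector of 72 values.
#' @export
glcm_features <- function(pixels, mask, spec = glcm_spec()) {
  vals <- pixels[mask]
  L <- spec$levels
  rng <- range(vals)
  qv <- matrix(NA_integer_, nrow(pixels), ncol(pixels))
  if (diff(rng) < 1e-12) {
    qv[mask] <- 1L
  } else {
    qv[mask] <- pmin(L, 1L + as.integer(floor((pixels[mask] - rng[1]) /
                                                diff(rng) * L)))
  }
  out <- numeric(0)
  angles <- c(0, 45, 90, 135)
  for (s in glcm_statistics) {
    for (d in seq_along(spec$distances)) {
      dist <- spec$distances[d]
      per_angle <- vapply(angles, function(a) {
        P <- glcm_matrix(qv, glcm_offset(a, dist), L)
        st <- if (sum(P) == 0)              # degenerate: no pixel pairs
          c(Correlation = 0, Contrast = 0, Energy = 1, Homogeneity = 1)
        else glcm_stats_from_matrix(P)
        st[[s]]
      }, numeric(1))
      block <- c(per_angle, mean(per_angle), sd(per_angle))
      names(block) <- sprintf("GLCM_%s_%s_D%d", s, glcm_slots, d)
      out <- c(out, block)
    }
  }
  out
}

#' First-order statistics of ROI intensities
#'
#' Histogram features of the intensity distribution: mean, STD, variance,
#' skewness, kurtosis (excess), Shannon entropy in bits (64-bin histogram),
#' histogram energy, median, 1st and 99th percentiles. A constant ROI gives
#' STD = variance = entropy = 0 and energy = 1.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 10 values.
#' @export
fos_features <- function(pixels, mask) {
  x <- pixels[mask]
  n <- length(x)
  if (n == 0) stop("ROI is empty", call. = FALSE)
  m <- mean(x)
  v <- if (n > 1) sum((x - m)^2) / n else 0     # population moments
  s <- sqrt(v)
  skew <- if (s < 1e-12) 0 else mean((x - m)^3) / s^3
  kurt <- if (s < 1e-12) 0 else mean((x - m)^4) / s^4 - 3
  rng <- range(x)
  if (diff(rng) < 1e-12) {
    ent <- 0; ene <- 1
  } else {
    bins <- 64
    h <- tabulate(pmin(bins, 1L + floor((x - rng[1]) / diff(rng) * bins)), bins)
    p <- h / sum(h)
    ent <- -sum(p[p > 0] * log2(p[p > 0]))
    ene <- sum(p^2)
  }
  c(FOS_Mean = m, FOS_STD = s, FOS_Variance = v, FOS_Skewness = skew,
    FOS_Kurtosis = kurt, FOS_Entropy = ent, FOS_Energy = ene,
    FOS_Median = median(x),
    FOS_P01 = quantile(x, 0.01, names = FALSE),
    FOS_P99 = quantile(x, 0.99, names = FALSE))
}

#' Intensity features of an ROI
#' @inheritParams glcm_features
#' @return Named numeric vector: maximum, mean, minimum, range.
#' @export
intensity_features <- function(pixels, mask) {
  x <- pixels[mask]
  if (length(x) == 0) stop("ROI is empty", call. = FALSE)
  c(Intensity_Maximum = max(x), Intensity_Mean = mean(x),
    Intensity_Minimum = min(x), Intensity_Range = diff(range(x)))
}

# chain-code perimeter: length of the oriented boundary contour (unit and
# sqrt(2) steps) with the standard 0.95 digitization-bias correction, so a
# digital disk of radius r measures close to 2*pi*r
perimeter_chain <- function(mask) {
  if (sum(mask) == 1) return(4)
  ct <- EBImage::ocontour(EBImage::Image(mask * 1))
  total <- 0
  for (pts in ct) {
    if (nrow(pts) < 2) { total <- total + 4; next }
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2))
    total <- total + sum(d)
  }
  0.95 * total
}

# exact convex hull area of the union of pixel squares: hull of the 4
# corners of every mask pixel, shoelace formula
convex_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- rbind(cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
  h <- chull(pts)
  p <- pts[h, , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(nrow(idx))
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Shape features of an ROI mask
#'
#' Region descriptors computed from the binary mask alone: area, perimeter,
#' major/minor axis length of the second-moment-matched ellipse,
#' eccentricity, orientation (radians), equivalent diameter, extent
#' (area / bounding-box area), convex area, filled area, solidity
#' (area / convex area) and circularity `4*pi*A / P^2`.
#'
#' @param mask logical single-component mask.
#' @param pixel_spacing optional mm/pixel; when given, lengths are in mm and
#'   areas in mm^2.
#' @return Named numeric vector of 12 values.
#' @export
shape_features <- function(mask, pixel_spacing = NULL) {
  m <- mask > 0
  A <- sum(m)
  if (A == 0) stop("ROI mask is empty", call. = FALSE)
  idx <- which(m, arr.ind = TRUE)
  perim <- perimeter_chain(m)
  ctr <- colMeans(idx)
  dr <- idx[, 1] - ctr[1]; dc <- idx[, 2] - ctr[2]
  mu20 <- mean(dr^2) + 1 / 12    # pixel-extent correction
  mu02 <- mean(dc^2) + 1 / 12
  mu11 <- mean(dr * dc)
  tr <- mu20 + mu02
  det <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det) / 2; l2 <- pmax((tr - det) / 2, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 < 1e-12) 0 else sqrt(pmax(1 - l2 / l1, 0))
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  bbox_area <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  conv <- convex_hull_area(m)
  filled <- sum(EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0)
  sp <- if (is.null(pixel_spacing) || is.na(pixel_spacing)) 1 else pixel_spacing
  c(Shape_Area = A * sp^2,
    Shape_Perimeter = perim * sp,
    Shape_MajorAxisLength = major * sp,
    Shape_MinorAxisLength = minor * sp,
    Shape_Eccentricity = ecc,
    Shape_Orientation = orient,
    Shape_EquivDiameter = sqrt(4 * A / pi) * sp,
    Shape_Extent = A / bbox_area,
    Shape_ConvexArea = conv * sp^2,
    Shape_FilledArea = filled * sp^2,
    Shape_Solidity = A / max(conv, 1e-12),
    Shape_Circularity = 4 * pi * A / max(perim, 1e-12)^2)
}

#' Extract the full 98-value feature vector for one ROI
#'
#' Concatenates GLCM (72), first-order statistics (10), intensity (4) and
#' shape (12) blocks in the frozen catalog order.
#'
#' @param roi a `candidate_roi` (or any list with a `mask`).
#' @param image image the ROI was segmented from (`mammogram`,
#'   `residual_image` or matrix).
#' @param spec a [glcm_spec()].
#' @param pixel_spacing optional mm/pixel for shape features.
#' @return Named numeric vector of exactly 98 finite values, names equal to
#'   [feature_catalog()].
#' @export
extract_all <- function(roi, image, spec = glcm_spec(),
                        pixel_spacing = NULL) {
  px <- as_pixels(image)
  mask <- roi$mask
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  out <- c(glcm_features(px, mask, spec),
           fos_features(px, mask),
           intensity_features(px, mask),
           shape_features(mask, pixel_spacing))
  stopifnot(identical(names(out), feature_catalog(spec)))
  out
}

#' Resolve a report-style feature name to a catalog entry
#'
#' Accepts the naming convention used in radiomics reports — statistic plus
#' angle-or-aggregate plus distance for GLCM features (e.g.
#' `"Correlation 90 D2"`, `"Correlation Mean D1"`), `"Maximum intensity"`,
#' `"Mean intensity"`, `"STD"` (first-order), and plain shape names
#' (`"Major Axis Length"`, `"Solidity"`, ...) — and returns the frozen
#' catalog identifier.
#'
#' @param name character feature name in report style.
#' @return Catalog name (errors if the name does not resolve).
#' @export
#' @examples
#' resolve_feature_name("Correlation 90 D2")
#' resolve_feature_name("Maximum intensity")
resolve_feature_name <- function(name) {
  raw <- gsub("\\$\\^?\\{?\\\\circ\\s*\\}?\\$?|°", "", name)
  raw <- gsub("\\s+", " ", trimws(raw))
  low <- tolower(raw)
  shape_map <- c("major axis length" = "Shape_MajorAxisLength",
                 "minor axis length" = "Shape_MinorAxisLength",
                 "perimeter" = "Shape_Perimeter",
                 "area" = "Shape_Area",
                 "equivalent diameter" = "Shape_EquivDiameter",
                 "extent" = "Shape_Extent",
                 "convex area" = "Shape_ConvexArea",
                 "filled area" = "Shape_FilledArea",
                 "circularity" = "Shape_Circularity",
                 "solidity" = "Shape_Solidity",
                 "eccentricity" = "Shape_Eccentricity",
                 "orientation" = "Shape_Orientation")
  if (low %in% names(shape_map)) return(unname(shape_map[low]))
  if (low == "maximum intensity") return("Intensity_Maximum")
  if (low == "mean intensity") return("Intensity_Mean")
  if (low == "minimum intensity") return("Intensity_Minimum")
  if (low == "std") return("FOS_STD")
  glcm <- regmatches(low,
    regexec("^(correlation|contrast|energy|homogeneity) (0|45|90|135|mean|std) d([0-9])$",
            low))[[1]]
  if (length(glcm) == 4) {
    stat <- paste0(toupper(substring(glcm[2], 1, 1)), substring(glcm[2], 2))
    slot <- switch(glcm[3], mean = "Mean", std = "STD", glcm[3])
    cand <- sprintf("GLCM_%s_%s_D%s", stat, slot, glcm[4])
    if (cand %in% feature_catalog()) return(cand)
  }
  stop("cannot resolve feature name: ", name, call. = FALSE)
}

#' Build a feature matrix from a list of ROIs
#'
#' @param rois list of `candidate_roi`.
#' @param images named list of images keyed however the caller matches ROIs
#'   to images, or a single image used for all ROIs.
#' @param spec a [glcm_spec()].
#' @return data.frame: 98 feature columns (catalog names) plus
#'   `patient_id`, `view`, `roi_id`, `label`.
#' @export
feature_matrix <- function(rois, images, spec = glcm_spec()) {
  rows <- lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    img <- if (is.list(images) && !is.null(roi$image_key))
      images[[roi$image_key]] else images
    fv <- extract_all(roi, img, spec)
    cbind(as.data.frame(t(fv)),
          data.frame(patient_id = roi$patient_id, view = roi$view,
                     roi_id = i, label = roi$matched_truth,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
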