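# synthetic sequential-mammogram generator (digital phantom cohort)
#
# Emulates the structure of a two-round screening cohort: per patient and
# view, a prior image of normal anatomy and a recent image that is the prior
# warped through a smooth random deformation (positioning/compression
# differences) with masses inserted for benign/malignant patients, plus
# global intensity drift and additive noise. Every random quantity derives
# from one seed, so cohorts are bit-reproducible.

#' Cohort configuration for the phantom generator
#'
#' Defaults emulate the study cohort: 100 patients, two views (CC, MLO), two
#' screening rounds, BI-RADS density classes a-d in proportions
#' 11/45/39/5 per 100, and a normal/benign/malignant patient mix of
#' 35/15/50.
#'
#' @param n_patients number of patients (>= 1).
#' @param views character vector of view codes.
#' @param n_rounds number of screening rounds (2: prior and recent).
#' @param density_weights named probabilities for density classes a-d;
#'   must sum to 1.
#' @param class_mix named proportions of normal/benign/malignant patients;
#'   must sum to 1.
#' @param image_shape image size in pixels `c(rows, cols)`, each >= 64.
#' @param deformation_magnitude maximum inter-round displacement in pixels.
#' @param noise_sigma additive Gaussian noise SD on the \[0, 1\] intensity
#'   scale; the low-frequency inter-round intensity drift amplitude is tied
#'   to this value.
#' @param mass_contrast intensity margin of inserted masses over local
#'   background.
#' @param seed integer seed for the whole cohort.
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 2, image_shape = c(96, 80), seed = 7)
cohort_config <- function(n_patients = 100,
                          views = c("CC", "MLO"),
                          n_rounds = 2,
                          density_weights = c(a = 0.11, b = 0.45,
                                              c = 0.39, d = 0.05),
                          class_mix = c(normal = 0.35, benign = 0.15,
                                        malignant = 0.50),
                          image_shape = c(192, 160),
                          deformation_magnitude = 4,
                          noise_sigma = 0.01,
                          mass_contrast = 0.25,
                          seed = 1) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (any(image_shape < 64)) stop("image_shape dims must be >= 64", call. = FALSE)
  if (abs(sum(density_weights) - 1) > 1e-9)
    stop("density_weights must sum to 1", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1", call. = FALSE)
  if (n_rounds != 2) stop("only two screening rounds are supported", call. = FALSE)
  if (deformation_magnitude < 0 || noise_sigma < 0)
    stop("deformation_magnitude and noise_sigma must be >= 0", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), views = views,
                 n_rounds = as.integer(n_rounds),
                 density_weights = density_weights, class_mix = class_mix,
                 image_shape = as.integer(image_shape),
                 deformation_magnitude = deformation_magnitude,
                 noise_sigma = noise_sigma, mass_contrast = mass_contrast,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# half-ellipse breast region anchored on the chest wall (left edge)
breast_region <- function(shape) {
  nr <- shape[1]; nc <- shape[2]
  r0 <- nr / 2 + runif(1, -0.05, 0.05) * nr
  a <- runif(1, 0.38, 0.45) * nr
  b <- runif(1, 0.72, 0.85) * nc
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((rr - r0) / a)^2 + (cc / b)^2 <= 1
}

# density class a-d -> fibroglandular texture amplitude
density_texture_amp <- c(a = 0.03, b = 0.06, c = 0.10, d = 0.14)

# band-pass filtered noise field, unit-normalized
bandpass_noise <- function(shape) {
  n <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  lo <- EBImage::imageData(EBImage::gblur(EBImage::Image(n), 2))
  hi <- EBImage::imageData(EBImage::gblur(EBImage::Image(n), 6))
  bp <- lo - hi
  bp / max(sd(bp), 1e-12)
}

# normal breast anatomy: half-ellipse + radial taper + density texture
breast_anatomy <- function(shape, density_class) {
  mask <- breast_region(shape)
  nr <- shape[1]; nc <- shape[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # normalized distance from chest wall toward skin line
  dn <- clip01(sqrt(((rr - nr / 2) / (0.5 * nr))^2 + (cc / nc)^2))
  base <- 0.45 * (1 - 0.45 * dn^2)
  tex <- bandpass_noise(shape) * density_texture_amp[[density_class]]
  px <- (base + tex) * mask
  clip01(px)
}

# star/blob mass mask from a Fourier-perturbed radial boundary
rasterize_mass <- function(shape, center, radius, ks, amps, phases) {
  nr <- shape[1]; nc <- shape[2]
  pad <- ceiling(radius * 2) + 2
  r_lo <- max(1, floor(center[1] - pad)); r_hi <- min(nr, ceiling(center[1] + pad))
  c_lo <- max(1, floor(center[2] - pad)); c_hi <- min(nc, ceiling(center[2] + pad))
  rr <- matrix(r_lo:r_hi, r_hi - r_lo + 1, c_hi - c_lo + 1)
  cc <- matrix(c_lo:c_hi, r_hi - r_lo + 1, c_hi - c_lo + 1, byrow = TRUE)
  th <- atan2(rr - center[1], cc - center[2])
  rb <- radius * (1 + Reduce(`+`, Map(function(k, a, p) a * cos(k * th + p),
                                      ks, amps, phases)))
  rb <- pmax(rb, 0.2 * radius)
  inside <- sqrt((rr - center[1])^2 + (cc - center[2])^2) <= rb
  m <- matrix(FALSE, nr, nc)
  m[r_lo:r_hi, c_lo:c_hi] <- inside
  m
}

# benign: low-order smooth boundary; malignant: high-frequency spicules
draw_mass_mask <- function(shape, center, radius, label) {
  if (label == "benign") {
    ks <- 2:3
    amps <- runif(2, 0.02, 0.08)
  } else {
    ks <- sample(7:13, 4)
    amps <- runif(4, 0.12, 0.30)
    s <- sum(amps)
    if (s > 0.8) amps <- amps * 0.8 / s
  }
  phases <- runif(length(ks), 0, 2 * pi)
  rasterize_mass(shape, center, radius, as.list(ks), as.list(amps),
                 as.list(phases))
}

# smooth intensity bump confined to the mass mask
mass_bump <- function(mask, center, radius, contrast) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  prof <- 0.5 + 0.5 * exp(-d2 / (2 * (0.6 * radius)^2))
  bump <- contrast * prof * mask
  EBImage::imageData(EBImage::gblur(EBImage::Image(bump), 0.7))
}

place_masses <- function(shape, region, n_masses, labels, contrast) {
  nr <- shape[1]; nc <- shape[2]
  base_radius <- 0.045 * min(shape)
  # keep masses clear of the skin line: peripheral candidates are discarded
  # downstream by design, so cohort masses must sit in the breast interior
  placement_margin <- ceiling(base_radius * 1.6 + min(shape) / 10)
  eroded <- EBImage::imageData(
    EBImage::erode(EBImage::Image(region * 1),
                   disc_kernel(placement_margin))) > 0
  cand <- which(eroded, arr.ind = TRUE)
  if (nrow(cand) < 1)
    stop("degenerate geometry: breast region too small for mass placement",
         call. = FALSE)
  masks <- list(); centers <- list(); radii <- numeric(0)
  for (i in seq_len(n_masses)) {
    placed <- FALSE
    for (try in 1:40) {
      ctr <- cand[sample.int(nrow(cand), 1), ]
      radius <- base_radius * runif(1, 0.8, 1.3)
      if (length(centers) > 0) {
        dmin <- min(vapply(centers, function(p)
          sqrt(sum((p - ctr)^2)), numeric(1)))
        if (dmin < 3.5 * base_radius) next
      }
      m <- draw_mass_mask(shape, ctr, radius, labels[i])
      if (sum(m) > 0 && all(region[m])) {
        masks[[i]] <- m; centers[[i]] <- ctr; radii[i] <- radius
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("degenerate geometry: mass placement failed after bounded retries",
           call. = FALSE)
  }
  list(masks = masks, centers = centers, radii = radii)
}

#' Generate one patient's sequential mammograms with ground truth
#'
#' For each view, a prior image of normal anatomy is generated first; the
#' recent image is the prior warped through a stored smooth random
#' deformation field, with masses inserted for benign/malignant patients,
#' a low-frequency intensity drift, and additive Gaussian noise. The stored
#' field is exactly the backward field that maps recent-frame coordinates
#' onto the prior, enabling registration-recovery tests. Prior images of
#' mass patients contain no mass pixels (newly developed masses).
#'
#' @param config a [cohort_config()].
#' @param patient_id unique identifier string.
#' @param patient_class `"normal"`, `"benign"` or `"malignant"`; drawn from
#'   `config$class_mix` when `NULL`.
#' @return list with `images` (list of `mammogram`, one per round and view)
#'   and `truth` (density class, patient class, and per-view deformation
#'   field, breast masks, mass masks and labels).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 1, image_shape = c(96, 80), seed = 3)
#' pat <- generate_patient(cfg, "P001")
#' names(pat$truth$views)
generate_patient <- function(config, patient_id, patient_class = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "patient", patient_id), {
    density <- sample(names(config$density_weights), 1,
                      prob = config$density_weights)
    if (is.null(patient_class))
      patient_class <- sample(names(config$class_mix), 1,
                              prob = config$class_mix)
    shape <- config$image_shape
    images <- list()
    views <- list()
    for (v in config$views) {
      prior_clean <- breast_anatomy(shape, density)
      prior_mask <- prior_clean > 0
      field <- random_smooth_field(shape, config$deformation_magnitude)
      recent_clean <- as_pixels(warp_image(prior_clean, field))
      recent_mask <- as_pixels(warp_image(prior_mask * 1, field)) > 0.5
      mass_masks <- list(); mass_labels <- character(0)
      if (patient_class != "normal") {
        n_masses <- 1L + rbinom(1, 1, 0.5)
        mass_labels <- rep(patient_class, n_masses)
        pl <- place_masses(shape, recent_mask, n_masses, mass_labels,
                           config$mass_contrast)
        mass_masks <- pl$masks
        for (i in seq_len(n_masses))
          recent_clean <- recent_clean +
            mass_bump(pl$masks[[i]], pl$centers[[i]], pl$radii[i],
                      config$mass_contrast)
      }
      # low-frequency multiplicative drift tied to the noise level
      drift_amp <- config$noise_sigma
      ramp <- matrix(seq(-1, 1, length.out = shape[2]), shape[1], shape[2],
                     byrow = TRUE) * runif(1, -1, 1)
      recent_px <- recent_clean * (1 + drift_amp * ramp)
      if (config$noise_sigma > 0) {
        prior_px <- prior_clean +
          matrix(rnorm(prod(shape), 0, config$noise_sigma), shape[1]) *
          prior_mask
        recent_px <- recent_px +
          matrix(rnorm(prod(shape), 0, config$noise_sigma), shape[1]) *
          recent_mask
      } else prior_px <- prior_clean
      prior_img <- mammogram(quantize16(clip01(prior_px)), patient_id,
                             view = v, round = "prior")
      recent_img <- mammogram(quantize16(clip01(recent_px)), patient_id,
                              view = v, round = "recent")
      images[[paste(v, "prior", sep = "_")]] <- prior_img
      images[[paste(v, "recent", sep = "_")]] <- recent_img
      views[[v]] <- list(deformation = field,
                         breast_mask_prior = prior_mask,
                         breast_mask_recent = recent_mask,
                         mass_masks = mass_masks,
                         mass_labels = mass_labels)
    }
    list(images = images,
         truth = list(patient_id = patient_id, density_class = density,
                      patient_class = patient_class, views = views))
  })
}

#' Generate a full phantom cohort on disk
#'
#' Writes one 16-bit TIFF per patient/view/round, an 8-bit PNG union mass
#' mask for recent views of mass patients, and a CSV manifest with header
#' `patient_id,view,round,image_path,mask_path,label,density`.
#'
#' @param config a [cohort_config()].
#' @param out_dir writable output directory (created if missing).
#' @return The manifest as a data.frame, invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(msk_dir, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", i)
    pat <- generate_patient(config, pid)
    for (v in config$views) {
      tv <- pat$truth$views[[v]]
      for (rnd in c("prior", "recent")) {
        img <- pat$images[[paste(v, rnd, sep = "_")]]
        ipath <- file.path(img_dir, sprintf("%s_%s_%s.tiff", pid, v, rnd))
        write_mammogram(img, ipath)
        mpath <- ""
        label <- if (rnd == "recent") pat$truth$patient_class else "normal"
        if (rnd == "recent" && length(tv$mass_masks) > 0) {
          um <- Reduce(`|`, tv$mass_masks)
          mpath <- file.path(msk_dir, sprintf("%s_%s_mass.png", pid, v))
          write_mask(um, mpath)
        }
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pid, view = v, round = rnd,
          image_path = ipath, mask_path = mpath, label = label,
          density = pat$truth$density_class, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
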