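# candidate-mass segmentation from the subtraction residual
#
# Three steps: percentile thresholding of the nonzero residual, morphological
# cleaning (opening, hole filling, small-component removal), and removal of
# peripheral components near the breast boundary. Surviving components become
# candidate ROIs for feature extraction.

#' Percentile thresholding of a subtraction residual
#'
#' Foreground = pixels at or above the `q`-th percentile of the *nonzero*
#' residual values inside the breast mask. Percentile thresholding is robust
#' to global intensity shifts; an all-zero residual yields an empty mask.
#'
#' @param res a `residual_image` (or matrix plus `mask`).
#' @param q percentile in (0, 100), default 95.
#' @param mask breast mask; taken from `res` when it is a `residual_image`.
#' @return Logical foreground mask.
#' @export
threshold_residual <- function(res, q = 95, mask = NULL) {
  if (q <= 0 || q >= 100) stop("q must be in (0, 100)", call. = FALSE)
  px <- as_pixels(res)
  if (is.null(mask) && inherits(res, "residual_image")) mask <- res$mask
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  vals <- px[mask & px > 0]
  if (length(vals) == 0) return(matrix(FALSE, nrow(px), ncol(px)))
  thr <- quantile(vals, q / 100, names = FALSE, type = 7)
  px >= thr & mask & px > 0
}

#' Morphological cleaning of a candidate mask
#'
#' Closing then opening with a disc of radius `open_radius` (closing first
#' consolidates thresholded regions that fragment across spiculated masses;
#' opening then removes isolated specks), hole filling, and removal of
#' connected components smaller than `min_area` pixels. Idempotent on its
#' own output.
#'
#' @param mask logical matrix.
#' @param open_radius disc radius in pixels (>= 0; 0 skips the morphology).
#' @param min_area minimum component area in pixels.
#' @return Cleaned logical mask.
#' @export
morph_clean <- function(mask, open_radius = 2, min_area = 40) {
  if (open_radius < 0) stop("open_radius must be >= 0", call. = FALSE)
  m <- mask > 0
  if (!any(m)) return(m)
  if (open_radius > 0) {
    kern <- disc_kernel(open_radius)
    m <- EBImage::imageData(EBImage::closing(EBImage::Image(m * 1), kern)) > 0
    m <- EBImage::imageData(EBImage::opening(EBImage::Image(m * 1), kern)) > 0
  }
  if (!any(m)) return(m)
  m <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], max(lab))
    m <- m & matrix(sizes[pmax(lab, 1)] >= min_area & lab > 0,
                    nrow(m), ncol(m))
  }
  m
}

#' Removal of peripheral components
#'
#' Discards connected components whose centroid lies within `margin` pixels
#' of the breast boundary (tested against the breast mask eroded by
#' `margin`). Skin-line artifacts left by imperfect registration concentrate
#' there.
#'
#' @param mask logical candidate mask.
#' @param breast logical breast mask.
#' @param margin distance to the boundary in pixels (0 = identity).
#' @return Filtered logical mask.
#' @export
remove_peripheral <- function(mask, breast, margin = 12) {
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  m <- mask > 0
  if (margin == 0 || !any(m)) return(m)
  interior <- EBImage::imageData(
    EBImage::erode(EBImage::Image((breast > 0) * 1), disc_kernel(margin))) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    ctr <- round(colMeans(idx))
    if (!interior[ctr[1], ctr[2]]) m[lab == k] <- FALSE
  }
  m
}

#' Label candidate ROIs
#'
#' 8-connected labeling of the cleaned mask; one ROI per component, sorted
#' by descending area. Bounding boxes are 0-based and half-open.
#'
#' @param mask cleaned logical mask.
#' @param res residual (or any image) the candidates came from; used for
#'   provenance only.
#' @param patient_id,view optional provenance labels.
#' @return list of `candidate_roi` objects (fields `mask`, `bbox`,
#'   `centroid`, `area_px`, `patient_id`, `view`, `matched_truth`).
#' @export
label_candidates <- function(mask, res = NULL, patient_id = NA_character_,
                             view = NA_character_) {
  m <- mask > 0
  if (!any(m)) return(list())
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  n <- max(lab)
  rois <- vector("list", n)
  for (k in seq_len(n)) {
    comp <- lab == k
    idx <- which(comp, arr.ind = TRUE)
    bbox <- c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
              max(idx[, 1]), max(idx[, 2]))
    rois[[k]] <- structure(list(
      mask = comp, bbox = bbox, centroid = colMeans(idx),
      area_px = nrow(idx), patient_id = patient_id, view = view,
      matched_truth = "none"), class = "candidate_roi")
  }
  rois[order(-vapply(rois, function(r) r$area_px, numeric(1)))]
}

iou <- function(a, b) {
  i <- sum(a & b)
  if (i == 0) return(0)
  i / sum(a | b)
}

#' Match candidate ROIs to ground-truth masses
#'
#' Each ROI is matched to at most one truth mass by maximum intersection
#' over union at or above `iou_threshold` (lenient by default: the tally
#' counts per-mass detection, not segmentation quality).
#'
#' @param rois list of `candidate_roi`.
#' @param truth_masks list of logical ground-truth mass masks.
#' @param truth_labels optional labels (`"benign"`/`"malignant"`) per mass.
#' @param iou_threshold minimum IoU to accept a match.
#' @return list with `rois` (annotated `matched_truth`), `detected` (logical
#'   per truth mass), `n_missed` and `n_fp`.
#' @export
match_to_truth <- function(rois, truth_masks, truth_labels = NULL,
                           iou_threshold = 0.1) {
  nt <- length(truth_masks)
  if (is.null(truth_labels)) truth_labels <- rep("mass", nt)
  detected <- rep(FALSE, nt)
  if (length(rois) > 0 && nt > 0) {
    for (i in seq_along(rois)) {
      ious <- vapply(truth_masks, function(tm) iou(rois[[i]]$mask, tm),
                     numeric(1))
      j <- which.max(ious)
      if (length(j) == 1 && ious[j] >= iou_threshold) {
        rois[[i]]$matched_truth <- truth_labels[j]
        detected[j] <- TRUE
      }
    }
  }
  n_fp <- sum(vapply(rois, function(r) identical(r$matched_truth, "none"),
                     logical(1)))
  list(rois = rois, detected = detected, n_missed = sum(!detected),
       n_fp = n_fp)
}

#' Segment candidate masses from a residual (all three steps)
#'
#' Convenience wrapper: [threshold_residual()], [morph_clean()],
#' [remove_peripheral()], [label_candidates()]. Morphology and margin
#' defaults scale with image size (opening disc radius `min(dim)/80`,
#' minimum area `0.13%` of the frame, peripheral margin `min(dim)/13`), so
#' the same configuration works across phantom resolutions.
#'
#' @param res `residual_image`.
#' @param breast breast mask (defaults to the residual's mask).
#' @param q,open_radius,min_area,margin stage parameters; `NULL` picks the
#'   size-scaled default.
#' @param patient_id,view provenance labels for the ROIs.
#' @return list of `candidate_roi`.
#' @export
detect_candidates <- function(res, breast = NULL, q = 95, open_radius = NULL,
                              min_area = NULL, margin = NULL,
                              patient_id = NA_character_,
                              view = NA_character_) {
  if (is.null(breast)) breast <- res$mask
  s <- min(dim(as_pixels(res)))
  if (is.null(open_radius)) open_radius <- max(1, round(s / 80))
  if (is.null(min_area)) min_area <- max(15, round(0.0013 * prod(dim(as_pixels(res)))))
  if (is.null(margin)) margin <- max(4, round(s / 13))
  m <- threshold_residual(res, q)
  m <- morph_clean(m, open_radius, min_area)
  m <- remove_peripheral(m, breast, margin)
  label_candidates(m, res, patient_id, view)
}
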