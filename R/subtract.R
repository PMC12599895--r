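# temporal subtraction and conspicuity metrics
#
# Unchanged anatomy cancels when the registered prior is subtracted from the
# recent view; newly developed or denser tissue remains bright. Negative
# differences (structure present only in the prior) are clipped to zero.

#' Temporal subtraction of a registered prior from the recent view
#'
#' @param recent pre-processed recent `mammogram` or matrix.
#' @param warped_prior prior image registered onto the recent frame.
#' @param mask logical breast mask (recent frame).
#' @return A `residual_image`: list with `pixels`
#'   (`max(recent - warped_prior, 0)` inside the mask, 0 outside) and `mask`.
#' @export
temporal_subtract <- function(recent, warped_prior, mask) {
  stopifnot_same_shape(recent, warped_prior)
  px <- pmax(as_pixels(recent) - as_pixels(warped_prior), 0) * (mask > 0)
  structure(list(pixels = px, mask = mask > 0,
                 recent_id = if (inherits(recent, "mammogram"))
                   recent$patient_id else NA_character_),
            class = "residual_image")
}

#' Lesion-to-background contrast ratio
#'
#' Mean intensity over the lesion mask divided by mean intensity over the
#' background mask (background mean floored at `eps` so the ratio is always
#' defined).
#'
#' @param img image (`mammogram`, `residual_image` or matrix).
#' @param lesion_mask,background_mask disjoint nonempty logical masks.
#' @param eps floor for the background mean.
#' @return Positive contrast ratio.
#' @export
#' @examples
#' img <- matrix(0.2, 8, 8); img[3:4, 3:4] <- 0.8
#' les <- img > 0.5; bg <- !les
#' contrast_ratio(img, les, bg)   # 4
contrast_ratio <- function(img, lesion_mask, background_mask, eps = 1e-6) {
  if (!any(lesion_mask) || !any(background_mask))
    stop("lesion and background masks must be nonempty", call. = FALSE)
  if (any(lesion_mask & background_mask))
    stop("lesion and background masks must be disjoint", call. = FALSE)
  px <- as_pixels(img)
  if (inherits(img, "residual_image")) px <- img$pixels
  mean(px[lesion_mask]) / max(mean(px[background_mask]), eps)
}

#' Background intensity reduction in percent
#'
#' `100 * (1 - mean_after / mean_before)` over the background mask; the
#' quantity the subtraction stage is designed to drive toward 100%.
#'
#' @param before,after images on the same grid.
#' @param background_mask logical background region mask.
#' @return Percentage reduction (can be negative if background brightened).
#' @export
background_reduction <- function(before, after, background_mask) {
  if (!any(background_mask))
    stop("background mask must be nonempty", call. = FALSE)
  pb <- as_pixels(before); if (inherits(before, "residual_image")) pb <- before$pixels
  pa <- as_pixels(after); if (inherits(after, "residual_image")) pa <- after$pixels
  mb <- mean(pb[background_mask])
  if (mb <= 0)
    stop("undefined metric: zero background mean in 'before'", call. = FALSE)
  100 * (1 - mean(pa[background_mask]) / mb)
}
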