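# shared helpers: seeded evaluation, image conversions, small numerics

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed and a tag
#'
#' Deterministic fan-out rule so each pipeline stage (and each patient) gets
#' its own reproducible substream from one user-facing seed. Result is always
#' a positive integer below 2^31.
#'
#' @param seed integer base seed.
#' @param ... character or integer tags (stage name, patient id, ...).
#' @return A positive integer seed.
#' @export
#' @examples
#' derive_seed(1, "phantom", "P001")
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (k in utf8ToInt(tags)) h <- (h * 31 + k) %% 2147483399
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483399 + 1)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# round to the 16-bit storage grid so in-memory pixels equal written pixels
quantize16 <- function(x) round(x * 65535) / 65535

as_pixels <- function(img) {
  if (is.list(img) && !is.null(img$pixels)) img$pixels else img
}

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(as_pixels(a)), dim(as_pixels(b))))
    stop("image shapes do not match", call. = FALSE)
}

# disc structuring element with odd side 2*r+1
disc_kernel <- function(r) {
  if (r < 1) return(matrix(1L, 1, 1))
  EBImage::makeBrush(2 * as.integer(r) + 1, shape = "disc")
}

# largest connected component of a binary matrix (8-connectivity)
largest_component <- function(bw) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  if (max(lab) == 0) return(matrix(FALSE, nrow(bw), ncol(bw)))
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

# Shannon entropy (bits) of a histogram over `bins` equal-width bins
shannon_entropy <- function(x, bins = 64) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(0)
  r <- range(x)
  if (diff(r) == 0) return(0)
  h <- tabulate(pmin(bins, 1L + floor((x - r[1]) / diff(r) * bins)), bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log2(p))
}
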