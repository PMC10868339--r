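# Step 3 -- voxel binarization against a percentile-derived threshold.

#' Estimate the void (bulk liquid) intensity
#'
#' The representative intensity of the void region is the `p`-th percentile
#' (linear interpolation between order statistics, `stats::quantile` type 7)
#' of all intensities in a horizontal band of planes above the biofilm
#' structure, pooled over the full depth and horizontal extent.
#'
#' @param grid a [voxel_grid()] (normally the trimmed volume).
#' @param top_band inclusive `c(z_low, z_high)` bounds of the band, 1-based.
#'   Default: the first 10% of vertical positions (at least one plane).
#' @param p percentile in `[0, 100]`.
#' @return The void intensity `i_void` (numeric scalar).
#' @export
estimate_void_intensity <- function(grid, top_band = NULL, p = 95) {
  stopifnot(inherits(grid, "voxel_grid"))
  n_z <- dim(grid$intensities)[2]
  if (is.null(top_band)) top_band <- c(1L, max(1L, n_z %/% 10L))
  top_band <- as.integer(top_band)
  if (length(top_band) != 2L || top_band[1] < 1L || top_band[2] > n_z ||
      top_band[1] > top_band[2]) {
    bf_stop("bad_band", sprintf("top_band must satisfy 1 <= low <= high <= %d", n_z))
  }
  if (p < 0 || p > 100) bf_stop("bad_percentile", "p must be in [0, 100]")
  band <- grid$intensities[, top_band[1]:top_band[2], , drop = FALSE]
  unname(stats::quantile(as.numeric(band), probs = p / 100, type = 7))
}

#' Threshold intensity from void intensity and multiplier
#'
#' `i_thresh = i_void * m` with `m > 1`. The value is not rounded; voxel
#' comparisons use the real threshold. A threshold above 255 means no voxel
#' of an 8-bit volume can be classified biomass, which is flagged with a
#' warning.
#'
#' @param i_void void intensity (greyscale value, `>= 0`).
#' @param m multiplier, strictly greater than 1.
#' @return `i_thresh` (numeric scalar).
#' @export
threshold_intensity <- function(i_void, m) {
  if (!is.numeric(m) || length(m) != 1L || m <= 1) {
    bf_stop("bad_multiplier", "'m' must be a scalar > 1")
  }
  if (i_void < 0) bf_stop("bad_void", "'i_void' must be >= 0")
  i_thresh <- i_void * m
  if (i_thresh > 255) {
    warning(sprintf("i_thresh = %.1f exceeds 255: no voxel can be biomass", i_thresh))
  }
  i_thresh
}

#' Binarize a volume into biomass / background
#'
#' Voxels strictly brighter than the threshold are biomass (1); voxels at or
#' below it, background (0). The tie rule (intensity equal to the threshold
#' is background) is fixed so that results are reproducible.
#'
#' @param grid a [voxel_grid()].
#' @param i_thresh intensity threshold (need not be an integer).
#' @return Integer array `(n_y, n_z, n_x)` of 0/1 labels.
#' @export
binarize_volume <- function(grid, i_thresh) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.numeric(i_thresh) || length(i_thresh) != 1L || !is.finite(i_thresh)) {
    bf_stop("bad_threshold", "'i_thresh' must be a finite scalar")
  }
  lab <- array(0L, dim(grid$intensities))
  lab[grid$intensities > i_thresh] <- 1L
  lab
}
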