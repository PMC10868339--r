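# Step 1 -- vertical trimming to the band containing the biofilm.

#' Trim a volume to a vertical band
#'
#' Keeps only vertical positions `z_low <= z <= z_high` (1-based, both
#' inclusive) in every depth slice; `y` and `x` are untouched and retained
#' intensities are copied unchanged. The bounds are typically chosen
#' manually so that the band contains the whole biofilm plus small margins
#' of the top and bottom regions; choosing bounds that exclude biofilm
#' voxels is the caller's responsibility.
#'
#' @param grid a [voxel_grid()].
#' @param z_low,z_high inclusive vertical bounds, `1 <= z_low <= z_high <= n_z`.
#' @return A [voxel_grid()] with `n_z = z_high - z_low + 1`.
#' @examples
#' g <- voxel_grid(array(7L, c(2, 20, 4)), c(1, 1, 1))
#' dim(trim_volume(g, 6, 15))   # 2 x 10 x 4
#' @export
trim_volume <- function(grid, z_low, z_high) {
  stopifnot(inherits(grid, "voxel_grid"))
  n_z <- dim(grid$intensities)[2]
  z_low <- as.integer(z_low); z_high <- as.integer(z_high)
  if (length(z_low) != 1L || length(z_high) != 1L || is.na(z_low) || is.na(z_high) ||
      z_low < 1L || z_high > n_z) {
    bf_stop("bad_bounds", sprintf("trim bounds must satisfy 1 <= z_low <= z_high <= %d", n_z))
  }
  if (z_low > z_high) {
    bf_stop("bad_bounds", "trim bounds select an empty vertical band (z_low > z_high)")
  }
  voxel_grid(grid$intensities[, z_low:z_high, , drop = FALSE], grid$voxel_size)
}

#' Suggest trim bounds from the vertical intensity profile
#'
#' Helper for choosing [trim_volume()] bounds: computes the mean intensity of
#' each constant-`z` plane and returns the smallest band whose profile exceeds
#' the background level of the topmost planes by `factor`, padded by `margin`
#' voxels. The suggestion is never applied automatically.
#'
#' @param grid a [voxel_grid()].
#' @param factor multiple of the top-plane background level a plane must
#'   exceed to be considered part of the biofilm/support band.
#' @param margin number of extra planes kept on each side.
#' @return Named integer vector `c(z_low, z_high)`.
#' @export
suggest_trim_bounds <- function(grid, factor = 2, margin = 10L) {
  stopifnot(inherits(grid, "voxel_grid"))
  n_z <- dim(grid$intensities)[2]
  profile <- apply(grid$intensities, 2, mean)
  top_level <- mean(profile[seq_len(max(1L, n_z %/% 20))])
  hot <- which(profile > max(top_level * factor, 1e-9))
  if (length(hot) == 0L) hot <- c(1L, n_z)
  c(z_low = max(1L, min(hot) - as.integer(margin)),
    z_high = min(n_z, max(hot) + as.integer(margin)))
}
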