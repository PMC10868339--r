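# Step 2 -- bottom (support) interface detection.
#
# The support surface is the strongest reflector in an OCT biofilm scan, so
# within each (z, x) slice the brightest voxel of every vertical column is an
# initial estimate of the interface. Isolated misdetections (speckle, bright
# biomass flocs) are removed by replacing entries that deviate from a running
# median by more than a jump tolerance, iterated to a fixpoint, first along x
# within each slice and finally along the depth axis y at each fixed x.

#' Brightest-voxel interface estimate for one depth slice
#'
#' @param slice_zx numeric matrix `(z, x)` of intensities for one constant-`y`
#'   slice.
#' @return Integer vector, one `z` per column `x`: the row of maximum
#'   intensity; ties are broken toward the smallest `z` (topmost), which
#'   favours the first strong reflector met from the bulk-liquid side.
#' @export
detect_bottom_slice <- function(slice_zx) {
  if (!is.matrix(slice_zx) || ncol(slice_zx) < 1L || nrow(slice_zx) < 1L) {
    bf_stop("empty_slice", "slice must be a non-empty (z, x) matrix")
  }
  apply(slice_zx, 2, which.max)
}

# replace entries deviating from the running median (window w) by more than
# jump_tol with that median; iterate until fixpoint or max_pass passes
.smooth_outliers <- function(z, window, jump_tol, max_pass = 10L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    bf_stop("bad_window", "'window' must be an odd integer >= 3")
  }
  if (jump_tol < 1) bf_stop("bad_window", "'jump_tol' must be >= 1")
  n <- length(z)
  if (n < 3L) return(z)
  k <- min(window, if (n %% 2L == 1L) n else n - 1L)
  for (pass in seq_len(max_pass)) {
    med <- stats::runmed(z, k, endrule = "median")
    bad <- abs(z - med) > jump_tol
    if (!any(bad)) break
    z[bad] <- med[bad]
  }
  as.integer(round(z))
}

#' Smooth a per-slice interface estimate along x
#'
#' Entries deviating from the running median (window `window`) by more than
#' `jump_tol` voxels are replaced by that median, repeatedly until a fixpoint
#' is reached (at most 10 passes). Smooth data -- flat or gently inclined
#' support lines -- pass through unchanged.
#'
#' @param z_est integer vector of interface estimates per `x`.
#' @param window odd running-median window, `>= 3`.
#' @param jump_tol maximum tolerated deviation from the local median, voxels.
#' @return Smoothed integer vector of the same length.
#' @export
smooth_bottom_x <- function(z_est, window = 5L, jump_tol = 5L) {
  .smooth_outliers(as.numeric(z_est), window, jump_tol)
}

#' Smooth a bottom surface along the depth axis
#'
#' The final smoothing step for 3D volumes: the same outlier-versus-running-
#' median replacement as [smooth_bottom_x()], applied along `y` within each
#' constant-`x` slice of the surface. Spurious points that survive per-slice
#' smoothing (visible when the interface is examined at fixed `x`) are
#' flattened here. A single-slice surface (`n_y = 1`) has no depth axis and
#' is returned unchanged.
#'
#' @param surface integer matrix `(y, x)` of interface positions.
#' @inheritParams smooth_bottom_x
#' @return Smoothed integer matrix of the same shape.
#' @export
smooth_bottom_depth <- function(surface, window = 5L, jump_tol = 5L) {
  stopifnot(is.matrix(surface))
  if (nrow(surface) == 1L) return(surface)
  apply(surface, 2, .smooth_outliers, window = window, jump_tol = jump_tol)
}

#' Detect the bottom interface of a volume
#'
#' Runs [detect_bottom_slice()] plus [smooth_bottom_x()] on every depth slice
#' `y = 1, ..., n_y`, then applies [smooth_bottom_depth()] across slices.
#'
#' @param grid a [voxel_grid()].
#' @inheritParams smooth_bottom_x
#' @return Integer matrix `z_bot` of shape `(n_y, n_x)`; every entry lies in
#'   `[1, n_z]`.
#' @export
detect_bottom <- function(grid, window = 5L, jump_tol = 5L) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$intensities)
  z_bot <- matrix(0L, d[1], d[3])
  for (y in seq_len(d[1])) {
    est <- detect_bottom_slice(matrix(grid$intensities[y, , ], d[2], d[3]))
    z_bot[y, ] <- smooth_bottom_x(est, window, jump_tol)
  }
  z_bot <- smooth_bottom_depth(z_bot, window, jump_tol)
  z_bot[z_bot < 1L] <- 1L
  z_bot[z_bot > d[2]] <- d[2]
  matrix(as.integer(z_bot), d[1], d[3])
}
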