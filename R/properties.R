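# Structural parameters of the segmented biofilm.
#
# Thickness at (y, x) counts the voxels strictly between the bottom
# interface and the highest (smallest z) top-interface voxel of that column,
# scaled by the vertical voxel length:
#   L_F(y, x) = (z_bot(y, x) - min z_top(y, x) - 1) * vx_len.
# Roughness is the mean absolute deviation of L_F about its mean, the
# roughness coefficient its mean-normalized form, compaction the fraction of
# the envelope under the top surface occupied by biofilm voxels, and
# porosity the fraction of background voxels within the biofilm region.

#' Thickness map from the interfaces
#'
#' @param bottom bottom surface matrix `(n_y, n_x)` from [detect_bottom()].
#' @param top_interface logical top-interface array from [build_top()].
#' @param vx_len vertical voxel length in micrometres.
#' @param biofilm optional logical biofilm array; when supplied, a column
#'   that contains biofilm voxels but no top-interface voxel raises an
#'   internal-consistency error (after a valid top growth this cannot
#'   happen).
#' @return Numeric matrix `(n_y, n_x)` of thickness in micrometres. Columns
#'   with no top-interface voxel and no biofilm have their top interface
#'   immediately above the bottom interface, i.e. thickness 0.
#' @export
thickness_map <- function(bottom, top_interface, vx_len, biofilm = NULL) {
  d <- dim(top_interface)
  stopifnot(is.matrix(bottom), nrow(bottom) == d[1], ncol(bottom) == d[3],
            vx_len > 0)
  min_top <- bottom - 1L                        # default: empty column
  idx <- which(top_interface)
  if (length(idx) > 0L) {
    a <- arrayInd(idx, d)
    key <- a[, 1] + (a[, 3] - 1L) * d[1]        # linear (y, x) index
    mins <- tapply(a[, 2], key, min)
    min_top[as.integer(names(mins))] <- as.integer(mins)
  }
  if (!is.null(biofilm)) {
    has_bio <- apply(biofilm, c(1, 3), any)
    has_top <- matrix(FALSE, d[1], d[3])
    if (length(idx) > 0L) has_top[unique(key)] <- TRUE
    if (any(has_bio & !has_top)) {
      bf_stop("inconsistent_interfaces",
              "column with biofilm voxels but no top-interface voxel")
    }
  }
  (bottom - min_top - 1L) * vx_len
}

#' Mean biofilm thickness
#'
#' Arithmetic mean of the thickness map over all `(y, x)` positions,
#' including zero-thickness columns.
#'
#' @param map thickness matrix from [thickness_map()], micrometres.
#' @return Mean thickness in micrometres.
#' @export
mean_thickness <- function(map) {
  stopifnot(length(map) > 0L)
  mean(map)
}

#' Biofilm roughness
#'
#' Mean absolute deviation of the thickness map about its mean.
#'
#' @inheritParams mean_thickness
#' @return Roughness in micrometres.
#' @export
roughness <- function(map) {
  stopifnot(length(map) > 0L)
  mean(abs(map - mean(map)))
}

#' Biofilm roughness coefficient
#'
#' Roughness normalized by the mean thickness (dimensionless and invariant
#' under rescaling of the map). Undefined (`NA` with a warning) when the
#' mean thickness is zero.
#'
#' @inheritParams mean_thickness
#' @return Dimensionless roughness coefficient.
#' @export
roughness_coeff <- function(map) {
  m <- mean_thickness(map)
  if (m <= 0) {
    warning("mean thickness is zero: roughness coefficient undefined")
    return(NA_real_)
  }
  roughness(map) / m
}

#' Compaction parameter
#'
#' Number of biofilm voxels divided by the total height (in voxels) of the
#' envelope under the top surface, i.e. the summed thickness map in voxel
#' units. Lies in `(0, 1]` for a non-empty biofilm; 1 means the structure
#' completely fills its envelope.
#'
#' @param biofilm_count number of biofilm voxels (sum of the structure
#'   indicator).
#' @param map thickness matrix in micrometres.
#' @param vx_len vertical voxel length in micrometres.
#' @return Dimensionless compaction, or `NA` with a warning when the
#'   envelope is empty.
#' @export
compaction <- function(biofilm_count, map, vx_len) {
  denom <- sum(map / vx_len)
  if (denom <= 0) {
    warning("empty biofilm envelope: compaction undefined")
    return(NA_real_)
  }
  biofilm_count / denom
}

#' Porosity
#'
#' Fraction of background voxels in the biofilm region:
#' `1 - biofilm_count / region_count`, where the region count is the biofilm
#' voxels plus the enclosed pore voxels from [segregate_regions()].
#'
#' @param biofilm_count number of biofilm voxels.
#' @param region_count total voxel count of the biofilm region
#'   (biofilm + pores), `>= biofilm_count`.
#' @return Dimensionless porosity in `[0, 1)`, or `NA` with a warning when
#'   the region is empty.
#' @export
porosity <- function(biofilm_count, region_count) {
  if (region_count <= 0) {
    warning("empty biofilm region: porosity undefined")
    return(NA_real_)
  }
  1 - biofilm_count / region_count
}

#' All structural parameters from a segmentation
#'
#' Convenience wrapper computing the thickness map and the five scalar
#' parameters from the outputs of the segmentation steps.
#'
#' @inheritParams thickness_map
#' @param labels label array from [segregate_regions()].
#' @param i_thresh optional threshold intensity recorded alongside the
#'   parameters.
#' @return A `structural_params` object: list with `mean_thickness`,
#'   `roughness`, `roughness_coeff`, `compaction`, `porosity` (all scalars),
#'   `mode`, `i_thresh`, and the `thickness` matrix.
#' @export
structural_params <- function(labels, bottom, top_interface, vx_len,
                              i_thresh = NA_real_) {
  lab <- region_labels()
  biofilm_count <- sum(labels == lab[["biofilm"]])
  region_count <- biofilm_count + sum(labels == lab[["biofilm_pore"]])
  map <- thickness_map(bottom, top_interface, vx_len,
                       biofilm = labels == lab[["biofilm"]])
  structure(list(
    mean_thickness  = mean_thickness(map),
    roughness       = roughness(map),
    roughness_coeff = if (mean(map) > 0) roughness_coeff(map) else NA_real_,
    compaction      = if (sum(map) > 0) compaction(biofilm_count, map, vx_len) else NA_real_,
    porosity        = if (region_count > 0) porosity(biofilm_count, region_count) else NA_real_,
    biofilm_count   = biofilm_count,
    region_count    = region_count,
    mode            = attr(labels, "mode"),
    i_thresh        = i_thresh,
    thickness       = map), class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf("<structural_params> mode = %s\n",
              if (is.null(x$mode)) "?" else x$mode))
  cat(sprintf("  mean thickness   %8.2f um\n", x$mean_thickness))
  cat(sprintf("  roughness        %8.2f um\n", x$roughness))
  cat(sprintf("  roughness coeff  %8.3f\n", x$roughness_coeff))
  cat(sprintf("  compaction       %8.3f\n", x$compaction))
  cat(sprintf("  porosity         %8.3f\n", x$porosity))
  invisible(x)
}

#' Structural parameters on a region of interest
#'
#' Restricts the labelling, interfaces and thickness map to a rectangular
#' `(y, x)` window (all `z` retained) and recomputes the five parameters
#' there. The full-volume window reproduces the global parameters.
#'
#' @inheritParams structural_params
#' @param y_range,x_range inclusive index ranges `c(lo, hi)`.
#' @return A `structural_params` object for the window.
#' @export
roi_params <- function(labels, bottom, top_interface, vx_len,
                       y_range, x_range, i_thresh = NA_real_) {
  d <- dim(labels)
  y_range <- as.integer(y_range); x_range <- as.integer(x_range)
  if (y_range[1] < 1L || y_range[2] > d[1] || y_range[1] > y_range[2] ||
      x_range[1] < 1L || x_range[2] > d[3] || x_range[1] > x_range[2]) {
    bf_stop("bad_roi", "region of interest window is empty or out of bounds")
  }
  ys <- y_range[1]:y_range[2]; xs <- x_range[1]:x_range[2]
  sub_labels <- labels[ys, , xs, drop = FALSE]
  attr(sub_labels, "mode") <- attr(labels, "mode")
  structural_params(sub_labels, bottom[ys, xs, drop = FALSE],
                    top_interface[ys, , xs, drop = FALSE], vx_len, i_thresh)
}
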