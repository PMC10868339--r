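# Visual outputs: binary masks, interface overlays, the region-emphasized
# structure volume, the thickness heatmap and the top-surface topography.
# Every renderer is a pure function of its inputs; writing the same inputs
# twice produces byte-identical files.

#' Render the biomass mask
#'
#' @param binary 0/1 biomass array from [binarize_volume()].
#' @param path optional TIFF output path.
#' @return Integer array with biomass voxels white (255) and background
#'   black (0); written as a TIFF stack when `path` is given.
#' @export
render_biomass <- function(binary, path = NULL) {
  img <- array(0L, dim(binary))
  img[binary == 1L] <- 255L
  if (!is.null(path)) write_volume(img, path)
  invisible(img)
}

#' Render the biofilm mask
#'
#' White for biofilm voxels only: floating biomass, excluded from the
#' structure by continuity testing, renders black.
#'
#' @param labels label array from [segregate_regions()] (or a logical
#'   biofilm array from [build_biofilm()]).
#' @param path optional TIFF output path.
#' @return Integer 0/255 array, invisibly.
#' @export
render_biofilm <- function(labels, path = NULL) {
  mask <- if (is.logical(labels)) labels else labels == region_labels()[["biofilm"]]
  img <- array(0L, dim(mask))
  img[mask] <- 255L
  if (!is.null(path)) write_volume(img, path)
  invisible(img)
}

#' Render the interface overlay
#'
#' Greyscale volume with bottom-interface voxels in one high-contrast colour
#' and top-interface voxels in another (defaults follow the green/red
#' convention), highlighting the biofilm contours.
#'
#' @param grid a [voxel_grid()].
#' @param bottom bottom surface matrix from [detect_bottom()].
#' @param top_interface logical top-interface array from [build_top()].
#' @param path optional TIFF output path (RGB pages).
#' @param bottom_rgb,top_rgb length-3 0-255 colours for the two interfaces.
#' @return Integer array `(n_y, n_z, n_x, 3)`, invisibly.
#' @export
render_bounds <- function(grid, bottom, top_interface, path = NULL,
                          bottom_rgb = c(0L, 255L, 0L),
                          top_rgb = c(255L, 0L, 0L)) {
  d <- dim(grid$intensities)
  img <- array(0L, c(d, 3L))
  for (ch in 1:3) img[, , , ch] <- grid$intensities
  bot_idx <- cbind(as.vector(row(bottom)), as.vector(bottom),
                   as.vector(col(bottom)))
  top_idx <- which(top_interface, arr.ind = TRUE)
  for (ch in 1:3) {
    img[cbind(bot_idx, ch)] <- as.integer(bottom_rgb[ch])
    if (nrow(top_idx) > 0L) img[cbind(top_idx, ch)] <- as.integer(top_rgb[ch])
  }
  if (!is.null(path)) write_volume(img, path)
  invisible(img)
}

#' Render the biofilm-region structure volume
#'
#' Keeps the original intensities inside the biofilm region (biofilm voxels
#' and enclosed pores) and paints everything else black, emphasizing the
#' structure. Constant-`y`, `-z` or `-x` slices can be cut from the result
#' with [slice_volume()].
#'
#' @param grid a [voxel_grid()].
#' @param labels label array from [segregate_regions()].
#' @param path optional TIFF output path.
#' @return Integer array of masked intensities, invisibly.
#' @export
render_structure <- function(grid, labels, path = NULL) {
  lab <- region_labels()
  keep <- labels == lab[["biofilm"]] | labels == lab[["biofilm_pore"]]
  img <- array(0L, dim(grid$intensities))
  img[keep] <- grid$intensities[keep]
  if (!is.null(path)) write_volume(img, path)
  invisible(img)
}

#' Cut a 2D slice from a rendered volume
#'
#' @param img 3D array indexed `(y, z, x)`.
#' @param axis `"y"`, `"z"` or `"x"`.
#' @param index 1-based position along `axis`.
#' @return A matrix: `(z, x)` for a `y` slice, `(y, x)` for a `z` slice,
#'   `(y, z)` for an `x` slice.
#' @export
slice_volume <- function(img, axis = c("y", "z", "x"), index) {
  axis <- match.arg(axis)
  d <- dim(img)[1:3]
  index <- as.integer(index)
  ax <- match(axis, c("y", "z", "x"))
  if (index < 1L || index > d[ax]) bf_stop("bad_coord", "slice index out of bounds")
  switch(axis,
         y = matrix(img[index, , ], d[2], d[3]),
         z = matrix(img[, index, ], d[1], d[3]),
         x = matrix(img[, , index], d[1], d[2]))
}

#' Render the thickness heatmap
#'
#' Linear greyscale mapping of the thickness map: the minimum maps to black,
#' the maximum to white; a constant map renders mid-grey by convention.
#'
#' @param map thickness matrix from [thickness_map()].
#' @param path optional PNG output path.
#' @return Integer 0-255 matrix `(n_y, n_x)`, invisibly.
#' @export
render_thickness_heatmap <- function(map, path = NULL) {
  rng <- range(map)
  img <- if (rng[2] > rng[1]) {
    matrix(as.integer(round((map - rng[1]) / (rng[2] - rng[1]) * 255)),
           nrow(map), ncol(map))
  } else {
    matrix(128L, nrow(map), ncol(map))
  }
  if (!is.null(path)) png::writePNG(img / 255, path)
  invisible(img)
}

#' Render the top-interface topography
#'
#' Perspective surface of the elevation of the highest top-interface voxel
#' per `(y, x)`, in physical units, coloured from blue (low) to red (high).
#'
#' @param top_interface logical top-interface array from [build_top()].
#' @param bottom bottom surface matrix (supplies the reference height for
#'   columns without interface voxels).
#' @param voxel_size physical voxel size `(y, z, x)` in micrometres.
#' @param path PNG output path.
#' @return The elevation matrix in micrometres (height of the interface
#'   above the volume's lowest plane), invisibly.
#' @export
render_topography <- function(top_interface, bottom, voxel_size, path) {
  d <- dim(top_interface)
  if (!any(top_interface)) bf_stop("empty_interface", "top interface is empty")
  vx <- voxel_size[2]
  min_top <- bottom - 1L
  idx <- which(top_interface)
  a <- arrayInd(idx, d)
  key <- a[, 1] + (a[, 3] - 1L) * d[1]
  mins <- tapply(a[, 2], key, min)
  min_top[as.integer(names(mins))] <- as.integer(mins)
  elev <- (d[2] - min_top) * vx
  pal <- grDevices::colorRampPalette(c("blue", "cyan", "yellow", "red"))(64)
  # facet colour from mean corner elevation
  fe <- (elev[-1, -1] + elev[-1, -ncol(elev)] +
         elev[-nrow(elev), -1] + elev[-nrow(elev), -ncol(elev)]) / 4
  col_idx <- if (diff(range(fe)) > 0) {
    as.integer(cut(fe, breaks = 64))
  } else {
    matrix(32L, nrow(fe), ncol(fe))
  }
  zlim <- range(elev)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-1, 1)   # flat surface
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::persp(x = seq_len(d[1]) * voxel_size[1],
                  y = seq_len(d[3]) * voxel_size[3],
                  z = elev, zlim = zlim, col = pal[col_idx],
                  theta = 35, phi = 30, expand = 0.5, border = NA,
                  xlab = "depth y (um)", ylab = "horizontal x (um)",
                  zlab = "elevation (um)", ticktype = "detailed")
  invisible(elev)
}
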