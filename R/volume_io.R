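# Volume container and TIFF / parameter-file input-output.
#
# Axis convention used by every module in the package:
#   intensities is a 3D array indexed [y, z, x] (depth, vertical, horizontal),
#   1-based. z = 1 is the bulk-liquid side of the volume; z = n_z is the
#   support side, so z increases downward toward the support and the bottom
#   interface sits at a larger z than the top interface.

#' Construct a voxel grid
#'
#' A `voxel_grid` holds an 8-bit greyscale OCT volume together with the
#' physical size of one voxel. Intensities are stored as an integer array
#' indexed `[y, z, x]` (depth slice, vertical position, horizontal position);
#' `z` increases toward the support surface.
#'
#' @param intensities 3D numeric array of greyscale values in `[0, 255]`,
#'   dimension `(n_y, n_z, n_x)`. A matrix is accepted as the degenerate
#'   single-slice (`n_y = 1`) case and treated as `(z, x)`.
#' @param voxel_size numeric length-3 vector: physical edge lengths of one
#'   voxel along `(y, z, x)` in micrometres. The `z` component is the vertical
#'   voxel length used to convert thickness from voxels to micrometres.
#' @return An object of class `voxel_grid`: a list with elements
#'   `intensities` (integer array) and `voxel_size` (named numeric).
#' @examples
#' g <- voxel_grid(array(0L, c(2, 10, 5)), voxel_size = c(4.89, 2.08, 4.85))
#' dim(g$intensities)
#' @export
voxel_grid <- function(intensities, voxel_size) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, c(1L, nrow(intensities), ncol(intensities)))
  }
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    bf_stop("bad_volume", "'intensities' must be a 3D array indexed (y, z, x)")
  }
  if (anyNA(intensities) || min(intensities) < 0 || max(intensities) > 255) {
    bf_stop("bad_volume", "intensities must be finite values in [0, 255]")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    bf_stop("bad_voxel_size", "'voxel_size' must be 3 strictly positive lengths (y, z, x) in um")
  }
  storage.mode(intensities) <- "integer"
  structure(
    list(intensities = intensities,
         voxel_size = stats::setNames(voxel_size, c("y", "z", "x"))),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (y, z, x), voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%d, %d]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$intensities)

#' Read a multi-page TIFF stack as a voxel grid
#'
#' Page `k` of the TIFF becomes depth slice `y = k`. Within a page, the row
#' index is `z` (row 1 is the image top, away from the support) and the
#' column index is `x`. RGB pages are reduced to greyscale by luminance
#' (0.299 R + 0.587 G + 0.114 B) and 16-bit pages are rescaled linearly to
#' the 8-bit range.
#'
#' @param path path to a readable multi-page TIFF.
#' @param voxel_size physical voxel edge lengths `(y, z, x)` in micrometres
#'   (see [voxel_grid()]). Voxel sizes are deliberately taken from the caller,
#'   not from TIFF tags, because OCT vendors store them inconsistently.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, voxel_size) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    bf_stop("missing_file", sprintf("input TIFF not found: '%s'", path))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) bf_stop("empty_stack", "TIFF contains zero pages")
  pages <- lapply(pages, .page_to_grey8)
  shp <- dim(pages[[1L]])
  same <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
  if (!all(same)) {
    bf_stop("inconsistent_pages", "all TIFF pages must share one 2D shape")
  }
  arr <- array(0L, c(length(pages), shp[1], shp[2]))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  voxel_grid(arr, voxel_size)
}

# one TIFF page -> integer (z, x) matrix of 8-bit grey values
.page_to_grey8 <- function(p) {
  if (length(dim(p)) == 3L) {                       # multi-channel: luminance
    nc <- dim(p)[3]
    p <- if (nc >= 3L) {
      0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
    } else {
      p[, , 1]
    }
  }
  if (is.double(p)) {                               # readTIFF normalized form
    p <- p * 255
  } else if (max(p) > 255L) {                       # 16-bit integers
    p <- p / 257
  }
  m <- as.integer(round(p))
  m[m < 0L] <- 0L
  m[m > 255L] <- 255L
  matrix(m, nrow(p), ncol(p))
}

#' Write a volume as a multi-page TIFF stack
#'
#' Writes depth slice `y = k` as page `k`, 8 bits per sample, so that
#' `read_volume()` on the result reproduces the intensities exactly.
#'
#' @param x a [voxel_grid()], or a 3D numeric array indexed `(y, z, x)` with
#'   values in `[0, 255]` (e.g. a rendered label volume), or such an array
#'   with an extra trailing RGB channel dimension `(y, z, x, 3)`.
#' @param path output file path; the parent directory is created if needed.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "voxel_grid")) x$intensities else x
  nd <- length(dim(arr))
  if (!is.array(arr) || !(nd %in% c(3L, 4L))) {
    bf_stop("bad_volume", "'x' must be a voxel_grid or a 3D/4D (y, z, x[, channel]) array")
  }
  dir <- dirname(path)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    bf_stop("unwritable_path", sprintf("cannot create directory '%s'", dir))
  }
  pages <- if (nd == 3L) {
    lapply(seq_len(dim(arr)[1]), function(k) arr[k, , ] / 255)
  } else {
    lapply(seq_len(dim(arr)[1]),
           function(k) array(arr[k, , , ], dim(arr)[2:4]) / 255)
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 8L),
    error = function(e) bf_stop("unwritable_path", conditionMessage(e)))
  invisible(path)
}

#' Write structural parameters to a key-value file
#'
#' Persists a [structural_params()] result as a flat machine-readable JSON
#' object with one scalar per key (`mean_thickness_um`, `roughness_um`,
#' `roughness_coeff`, `compaction`, `porosity`, `mode`, `i_thresh`).
#' Undefined parameters (e.g. the roughness coefficient of an empty biofilm)
#' are written as `null`.
#'
#' @param params a `structural_params` object.
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @seealso [read_params()] for the round trip.
#' @export
write_params <- function(params, path) {
  if (!inherits(params, "structural_params")) {
    bf_stop("bad_params", "'params' must be a structural_params object")
  }
  dir <- dirname(path)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    bf_stop("unwritable_path", sprintf("cannot create directory '%s'", dir))
  }
  out <- list(
    mean_thickness_um = params$mean_thickness,
    roughness_um      = params$roughness,
    roughness_coeff   = params$roughness_coeff,
    compaction        = params$compaction,
    porosity          = params$porosity,
    mode              = params$mode,
    i_thresh          = params$i_thresh)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read structural parameters written by [write_params()]
#'
#' @param path path to a parameter JSON file.
#' @return A named list of scalars.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) bf_stop("missing_file", sprintf("no such file: '%s'", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# named condition so callers can distinguish failure modes
bf_stop <- function(class, msg) {
  stop(errorCondition(msg, class = c(paste0("biofilm_", class), "biofilm_error")))
}
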