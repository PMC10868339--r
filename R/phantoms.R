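# Synthetic phantom volumes with analytically known ground truth.
#
# Phantoms emulate the essential geometry of an OCT biofilm scan: a dark
# bulk-liquid background, a bright one-voxel support line (the strongest
# reflector, so brightest-voxel detection is exact by construction), and a
# biomass slab of intermediate intensity sitting on the support, optionally
# carrying fully enclosed pores and a narrow vertical channel leading into an
# internal cavity. All voxel counts and the five structural parameters are
# computed by closed-form counting -- never by flood fill -- so the phantoms
# provide an independent oracle for the whole pipeline.

#' Generate a phantom volume with analytic ground truth
#'
#' Builds a slab of biomass resting on a flat (or inclined) support line and
#' returns both the greyscale volume and, for flat geometry, the exact
#' expected segmentation counts and structural parameters for the deep and
#' shallow continuity modes.
#'
#' Geometry, in the package's `(y, z, x)` convention with `z` increasing
#' toward the support: the support line occupies `z = z_support` (one voxel,
#' intensity `levels["support"]`), the slab occupies the `thickness` planes
#' directly above it, and everything else is background. `pores` are single
#' background voxels that must be strictly inside the slab and pairwise
#' non-adjacent, so each is a one-voxel enclosed pore in both modes. A
#' `channel` is a one-voxel-wide vertical shaft at `(y, x)` from the slab top
#' down to an internal cavity box; the top region floods shaft and cavity in
#' deep mode, while in shallow mode the entire shaft and cavity are enclosed
#' pores (under 26-connectivity the voxel above the channel mouth is itself a
#' top-interface voxel, so shallow growth is absorbed before it can enter the
#' shaft).
#'
#' @param shape integer triple `(n_y, n_z, n_x)`.
#' @param z_support vertical index of the support line (scalar for a flat
#'   support, or length-`n_x` vector for an inclined one; inclined phantoms
#'   carry no parameter truth, only the `z_bot` truth).
#' @param thickness slab thickness in voxels (`>= 1`).
#' @param pores optional `n x 3` integer matrix of `(y, z, x)` pore voxels.
#' @param channel optional list with elements `y`, `x` (shaft position) and
#'   `cavity = list(y = c(lo, hi), z = c(lo, hi), x = c(lo, hi))`.
#' @param levels named intensities `c(background, biomass, support)`, with
#'   `support > biomass > background`.
#' @param voxel_size physical voxel size `(y, z, x)` in micrometres.
#' @return List with `grid` (a [voxel_grid()]) and `truth`, a list holding
#'   `z_bot` (matrix), `biomass_count`, `biofilm_count`, and for flat
#'   geometry per-mode lists `deep` and `shallow` with `pore_count`,
#'   `region_count`, `porosity`, plus `mean_thickness`, `roughness`,
#'   `roughness_coeff`, `compaction` and the `thickness_map`.
#' @export
make_phantom <- function(shape, z_support, thickness,
                         pores = NULL, channel = NULL,
                         levels = c(background = 10, biomass = 120, support = 250),
                         voxel_size = c(4.89, 2.08, 4.85)) {
  d <- as.integer(shape)
  stopifnot(length(d) == 3L, all(d >= 1L))
  if (!(levels[["support"]] > levels[["biomass"]] &&
        levels[["biomass"]] > levels[["background"]])) {
    bf_stop("bad_phantom", "intensity levels must satisfy support > biomass > background")
  }
  flat <- length(z_support) == 1L
  zs <- if (flat) rep(as.integer(z_support), d[3]) else as.integer(z_support)
  if (length(zs) != d[3]) bf_stop("bad_phantom", "z_support must be scalar or length n_x")
  thickness <- as.integer(thickness)
  if (thickness < 1L || any(zs - thickness < 2L) || any(zs > d[2])) {
    bf_stop("bad_phantom", "slab does not fit: need 2 <= z_support - thickness + 1 and z_support <= n_z")
  }

  arr <- array(as.integer(levels[["background"]]), d)
  for (x in seq_len(d[3])) {
    arr[, zs[x], x] <- as.integer(levels[["support"]])
    arr[, (zs[x] - thickness):(zs[x] - 1L), x] <- as.integer(levels[["biomass"]])
  }

  carved <- 0L
  channel_len <- 0L
  cavity_vol <- 0L
  if (!is.null(channel)) {
    if (!flat) bf_stop("bad_phantom", "channels require a flat support")
    cy <- as.integer(channel$y); cx <- as.integer(channel$x)
    cav <- channel$cavity
    if (cy <= 1L || cy >= d[1] || cx <= 1L || cx >= d[3]) {
      bf_stop("bad_phantom", "channel must be interior in y and x")
    }
    cav_z <- as.integer(cav$z); cav_y <- as.integer(cav$y); cav_x <- as.integer(cav$x)
    z_top_slab <- zs[1] - thickness
    if (cav_z[1] <= z_top_slab || cav_z[2] >= zs[1] - 1L) {
      bf_stop("bad_phantom", "cavity must be strictly inside the slab in z")
    }
    # shaft from the slab top down to just above the cavity
    shaft_z <- z_top_slab:(cav_z[1] - 1L)
    arr[cy, shaft_z, cx] <- as.integer(levels[["background"]])
    arr[cav_y[1]:cav_y[2], cav_z[1]:cav_z[2], cav_x[1]:cav_x[2]] <-
      as.integer(levels[["background"]])
    channel_len <- length(shaft_z)
    cavity_vol <- prod(cav_y[2] - cav_y[1] + 1L, cav_z[2] - cav_z[1] + 1L,
                       cav_x[2] - cav_x[1] + 1L)
    carved <- channel_len + cavity_vol
  }
  pore_count <- 0L
  if (!is.null(pores)) {
    pores <- matrix(as.integer(pores), ncol = 3L)
    for (i in seq_len(nrow(pores))) {
      p <- pores[i, ]
      if (arr[p[1], p[2], p[3]] != as.integer(levels[["biomass"]])) {
        bf_stop("bad_phantom", "pore voxel is not inside the biomass slab")
      }
      if (p[2] == zs[p[3]] - thickness) {
        # a pore on the slab's top plane touches the exterior and would be
        # flooded by the top growth rather than enclosed
        bf_stop("bad_phantom", "pore voxel must lie strictly below the slab top plane")
      }
      arr[p[1], p[2], p[3]] <- as.integer(levels[["background"]])
    }
    pore_count <- nrow(pores)
    carved <- carved + pore_count
  }

  grid <- voxel_grid(arr, voxel_size)
  z_bot <- matrix(rep(zs, each = d[1]), d[1], d[3])
  slab_total <- as.integer(thickness) * d[1] * d[3]
  biomass_count <- slab_total - carved

  truth <- list(z_bot = z_bot, biomass_count = biomass_count,
                biofilm_count = biomass_count)
  if (flat) {
    vx <- voxel_size[2]
    lf <- matrix(thickness * vx, d[1], d[3])
    envelope <- slab_total                      # sum(L_F / vx_len)
    deep_pores <- pore_count
    shallow_pores <- pore_count + channel_len + cavity_vol
    per_mode <- function(pores_n) {
      region <- biomass_count + pores_n
      list(pore_count = as.integer(pores_n), region_count = as.integer(region),
           porosity = pores_n / region)
    }
    truth <- c(truth, list(
      thickness_map = lf,
      mean_thickness = thickness * vx,
      roughness = 0,
      roughness_coeff = 0,
      compaction = biomass_count / envelope,
      deep = per_mode(deep_pores),
      shallow = per_mode(shallow_pores)))
  }
  list(grid = grid, truth = truth)
}

#' Additive clipped Gaussian noise
#'
#' Adds zero-mean Gaussian noise to every voxel and clips to `[0, 255]`.
#' `sd = 0` is the identity; a fixed seed makes the result deterministic.
#' OCT speckle is not modelled.
#'
#' @param grid a [voxel_grid()].
#' @param sd noise standard deviation in greyscale units, `>= 0`.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A [voxel_grid()] with noisy intensities.
#' @export
add_noise <- function(grid, sd, seed = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), sd >= 0)
  if (sd == 0) return(grid)
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- grid$intensities + stats::rnorm(length(grid$intensities), 0, sd)
  v <- round(pmin(pmax(v, 0), 255))
  voxel_grid(array(as.integer(v), dim(grid$intensities)), grid$voxel_size)
}

#' Serpentine-channel phantom
#'
#' A slab phantom carved with a boustrophedon channel that visits every
#' second row of the `(y, x)` plane at a fixed depth inside the slab,
#' connected to the top by a vertical shaft. The channel crosses every
#' internal chunk boundary of any partition with up to `max(shape)/2` bands,
#' which makes this the adversarial case for chunked/serial equivalence.
#'
#' @inheritParams make_phantom
#' @return List with `grid` and the carved channel coordinate matrix
#'   `path` (no parameter truth; this phantom exists to stress stitching).
#' @export
make_serpentine_phantom <- function(shape, z_support, thickness,
                                    levels = c(background = 10, biomass = 120,
                                               support = 250),
                                    voxel_size = c(4.89, 2.08, 4.85)) {
  d <- as.integer(shape)
  ph <- make_phantom(d, z_support, thickness, levels = levels,
                     voxel_size = voxel_size)
  arr <- ph$grid$intensities
  zc <- as.integer(z_support) - 2L              # depth of the carved path
  stopifnot(zc > as.integer(z_support) - thickness)
  path <- list()
  ys <- seq(2L, d[1] - 1L, by = 2L)
  for (i in seq_along(ys)) {
    xs <- 2L:(d[3] - 1L)
    path[[length(path) + 1L]] <- cbind(ys[i], zc, xs)
    if (i < length(ys)) {                       # connector to the next row
      path[[length(path) + 1L]] <-
        cbind(ys[i]:ys[i + 1L], zc, if (i %% 2L == 1L) d[3] - 1L else 2L)
    }
  }
  path <- do.call(rbind, path)
  arr[path] <- as.integer(levels[["background"]])
  # vertical shaft from the slab top down to the path start
  shaft_z <- (as.integer(z_support) - thickness):zc
  arr[2L, shaft_z, 2L] <- as.integer(levels[["background"]])
  shaft <- cbind(2L, shaft_z, 2L)
  list(grid = voxel_grid(arr, voxel_size),
       path = rbind(path, shaft))
}
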