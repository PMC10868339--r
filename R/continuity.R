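# Steps 4-5 -- continuity testing under 26-connectivity.
#
# The engine works on linear indices of a 1-voxel zero-padded copy of the
# volume, so the 26 neighbour offsets are position-independent and no bounds
# checks are needed inside the growth loop. Each iteration expands the whole
# frontier at once: candidate neighbours are generated in bulk, de-duplicated,
# and filtered against the visit state ("temporary status"), so no voxel is
# counted twice. Growth is a pure breadth-first closure of the seed set under
# the expandable mask; absorbing voxels are marked when first reached but are
# never expanded from.

#' Label codes of the final region volume
#'
#' @return Named integer vector mapping label names to the codes used in the
#'   array returned by [segregate_regions()]: `unclassified` (floating
#'   biomass, never reached by any growth), `biofilm`, `top_region`,
#'   `top_interface`, `biofilm_pore` and `bottom`.
#' @export
region_labels <- function() {
  c(unclassified = 0L, biofilm = 1L, top_region = 2L, top_interface = 3L,
    biofilm_pore = 4L, bottom = 5L)
}

#' 26-connected neighbours of a voxel
#'
#' All in-bounds coordinates differing from `coord` by at most 1 along each
#' of the three axes, excluding `coord` itself: 26 for an interior voxel, 17
#' on a face, 11 on an edge, 7 in a corner.
#'
#' @param coord integer triple `(y, z, x)`, 1-based.
#' @param shape integer triple `(n_y, n_z, n_x)`.
#' @return Integer matrix with one `(y, z, x)` neighbour per row.
#' @export
voxel_neighbours <- function(coord, shape) {
  coord <- as.integer(coord); shape <- as.integer(shape)
  if (length(coord) != 3L || length(shape) != 3L ||
      any(coord < 1L) || any(coord > shape)) {
    bf_stop("bad_coord", "'coord' must be an in-bounds (y, z, x) triple")
  }
  g <- as.matrix(expand.grid(y = coord[1] + (-1:1), z = coord[2] + (-1:1),
                             x = coord[3] + (-1:1)))
  keep <- !(g[, 1] == coord[1] & g[, 2] == coord[2] & g[, 3] == coord[3]) &
    g[, 1] >= 1L & g[, 1] <= shape[1] &
    g[, 2] >= 1L & g[, 2] <= shape[2] &
    g[, 3] >= 1L & g[, 3] <= shape[3]
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# ---- padded-index machinery ------------------------------------------------

.pad_logical <- function(a) {
  d <- dim(a)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
  p
}

# unpadded linear indices -> padded linear indices
.pad_index <- function(idx, d) {
  if (length(idx) == 0L) return(integer(0))
  pd <- d + 2L
  a <- arrayInd(idx, d)
  (a[, 1] + 1L) + a[, 2] * pd[1] + a[, 3] * pd[1] * pd[2]
}

# padded linear indices -> unpadded linear indices
.unpad_index <- function(idx, d) {
  if (length(idx) == 0L) return(integer(0))
  pd <- d + 2L
  a <- arrayInd(idx, pd)
  (a[, 1] - 1L) + (a[, 2] - 2L) * d[1] + (a[, 3] - 2L) * d[1] * d[2]
}

# the 26 linear-index offsets in a padded array
.offsets26 <- function(pd) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(g != 0L) > 0L, , drop = FALSE]
  as.integer(g[, 1] + g[, 2] * pd[1] + g[, 3] * pd[1] * pd[2])
}

# coordinate matrix (n x 3) or linear index vector -> unpadded linear indices
.as_linear <- function(seeds, d) {
  if (is.matrix(seeds)) {
    if (ncol(seeds) != 3L) bf_stop("bad_coord", "seed matrix must have 3 columns (y, z, x)")
    seeds[, 1] + (seeds[, 2] - 1L) * d[1] + (seeds[, 3] - 1L) * d[1] * d[2]
  } else {
    as.integer(seeds)
  }
}

# breadth-first closure on padded indices; state: 0 unvisited, 1 region,
# 2 absorbed. frontier entries are already state == 1. allowed_p restricts
# which voxels may be *entered* (NULL = no restriction).
.grow_bfs <- function(state, frontier, expandable_p, absorbing_p, allowed_p, offs) {
  while (length(frontier) > 0L) {
    cand <- unique(as.vector(outer(offs, frontier, `+`)))
    cand <- cand[state[cand] == 0L]
    if (!is.null(allowed_p)) cand <- cand[allowed_p[cand]]
    nxt <- cand[expandable_p[cand]]
    if (!is.null(absorbing_p)) {
      ab <- cand[!expandable_p[cand] & absorbing_p[cand]]
      if (length(ab) > 0L) state[ab] <- 2L
    }
    if (length(nxt) > 0L) state[nxt] <- 1L
    frontier <- nxt
  }
  state
}

# classify seed voxels into the state (expandable -> region, else absorbing ->
# absorbed; others dropped) and return the padded region-seed frontier
.classify_seeds <- function(state, seeds_p, expandable_p, absorbing_p, allowed_p) {
  if (!is.null(allowed_p)) seeds_p <- seeds_p[allowed_p[seeds_p]]
  seeds_p <- seeds_p[state[seeds_p] == 0L]
  reg <- seeds_p[expandable_p[seeds_p]]
  state[reg] <- 1L
  if (!is.null(absorbing_p)) {
    ab <- seeds_p[!expandable_p[seeds_p] & absorbing_p[seeds_p]]
    if (length(ab) > 0L) state[ab] <- 2L
  }
  list(state = state, frontier = reg)
}

#' Grow a region by iterative frontier expansion
#'
#' Breadth-first closure of a seed set under 26-connectivity. Voxels
#' satisfying `expandable` join the region and keep expanding; voxels
#' satisfying `absorbing` (and not `expandable`) are marked as the absorbed
#' boundary when first reached but are never expanded from. Every voxel is
#' visited at most once and the result is independent of seed ordering.
#'
#' @param expandable logical array `(n_y, n_z, n_x)`: voxels the region may
#'   occupy and expand from.
#' @param absorbing optional logical array of the same shape: voxels that
#'   stop growth (absorbed boundary). `NULL` for none.
#' @param seeds starting voxels, as an `n x 3` integer matrix of `(y, z, x)`
#'   coordinates or a vector of linear indices. Seeds satisfying neither
#'   predicate are ignored; an empty seed set yields an empty region.
#' @return List with logical arrays `region` and `absorbed`.
#' @export
grow_region <- function(expandable, absorbing = NULL, seeds) {
  d <- dim(expandable)
  stopifnot(length(d) == 3L)
  pd <- d + 2L
  expandable_p <- .pad_logical(expandable)
  absorbing_p <- if (is.null(absorbing)) NULL else .pad_logical(absorbing)
  state <- array(0L, pd)
  seeds_p <- .pad_index(.as_linear(seeds, d), d)
  init <- .classify_seeds(state, seeds_p, expandable_p, absorbing_p, NULL)
  state <- .grow_bfs(init$state, init$frontier, expandable_p, absorbing_p,
                     NULL, .offsets26(pd))
  .state_to_masks(state, d)
}

.state_to_masks <- function(state, d) {
  region <- array(FALSE, d)
  absorbed <- array(FALSE, d)
  region[.unpad_index(which(state == 1L), d)] <- TRUE
  absorbed[.unpad_index(which(state == 2L), d)] <- TRUE
  list(region = region, absorbed = absorbed)
}

# TRUE where z < z_bot(y, x): the volume strictly above the bottom interface
.above_bottom <- function(bottom, d) {
  zarr <- array(rep(rep(seq_len(d[2]), each = d[1]), d[3]), d)
  zb <- aperm(array(bottom, c(d[1], d[3], d[2])), c(1, 3, 2))
  zarr < zb
}

# background voxels (26-)adjacent to at least one biofilm voxel, above bottom
.interface_mask <- function(binary, biofilm, above) {
  d <- dim(binary)
  pd <- d + 2L
  bio_p <- .pad_logical(biofilm)
  adj_p <- array(FALSE, pd)
  idx <- which(bio_p)
  if (length(idx) > 0L) {
    for (off in .offsets26(pd)) adj_p[idx + off] <- TRUE
  }
  adj_idx <- which(adj_p)
  a <- arrayInd(adj_idx, pd)                    # drop padded border cells
  interior <- a[, 1] > 1L & a[, 1] < pd[1] & a[, 2] > 1L & a[, 2] < pd[2] &
    a[, 3] > 1L & a[, 3] < pd[3]
  adj <- array(FALSE, d)
  adj[.unpad_index(adj_idx[interior], d)] <- TRUE
  adj & (binary == 0L) & above
}

#' Seed layer for biofilm growth
#'
#' The initial biofilm layer: the voxels immediately above the bottom
#' interface, `(y, z_bot(y, x) - 1, x)`, that are biomass. Biomass with no
#' continuous path to this layer ("floating" biomass) is never reached by the
#' subsequent growth and is excluded from the biofilm by construction.
#'
#' @param binary 0/1 biomass array from [binarize_volume()].
#' @param bottom bottom surface matrix from [detect_bottom()].
#' @return Integer matrix of seed coordinates `(y, z, x)`, possibly empty.
#' @export
seed_biofilm <- function(binary, bottom) {
  d <- dim(binary)
  stopifnot(is.matrix(bottom), nrow(bottom) == d[1], ncol(bottom) == d[3])
  yx <- as.matrix(expand.grid(y = seq_len(d[1]), x = seq_len(d[3])))
  z <- as.vector(bottom) - 1L
  ok <- z >= 1L
  yx <- yx[ok, , drop = FALSE]; z <- z[ok]
  is_bio <- binary[cbind(yx[, 1], z, yx[, 2])] == 1L
  m <- cbind(y = yx[is_bio, 1], z = z[is_bio], x = yx[is_bio, 2])
  storage.mode(m) <- "integer"
  m
}

#' Grow the attached biofilm structure
#'
#' Grows the biofilm region from the seed layer of [seed_biofilm()] through
#' all biomass voxels above the bottom interface, under 26-connectivity. The
#' result is the structure indicator: the subset of biomass forming a
#' continuous structure attached to the bottom interface.
#'
#' @inheritParams seed_biofilm
#' @param plan optional [plan_chunks()] plan for chunked execution; `NULL`
#'   runs serially. Chunked execution is label-identical to serial.
#' @param cores worker processes for chunked execution (forked; ignored on
#'   Windows and when `plan` is `NULL`).
#' @return Logical array `(n_y, n_z, n_x)`: `TRUE` for biofilm voxels.
#' @export
build_biofilm <- function(binary, bottom, plan = NULL, cores = 1L) {
  d <- dim(binary)
  above <- .above_bottom(bottom, d)
  expandable <- (binary == 1L) & above
  seeds <- seed_biofilm(binary, bottom)
  res <- if (is.null(plan)) {
    grow_region(expandable, NULL, seeds)
  } else {
    run_chunked(expandable, NULL, seeds, plan, cores)
  }
  res$region
}

#' Grow the top (bulk liquid) region and locate the top interface
#'
#' Starting from the background voxels of the uppermost plane (`z = 1`),
#' grows the top region through background voxels above the bottom
#' interface. Background voxels adjacent to at least one biofilm voxel are
#' top-interface voxels; the two continuity models differ only in how growth
#' treats them:
#'
#' * `deep`: interface voxels keep expanding, so the top region penetrates
#'   narrow channels into the structure;
#' * `shallow`: interface voxels absorb growth (they are marked but never
#'   expanded from), preserving the external contour of the biofilm.
#'
#' Interface membership is evaluated against the finalized biofilm of
#' [build_biofilm()] in both modes.
#'
#' @inheritParams build_biofilm
#' @param biofilm logical biofilm array from [build_biofilm()].
#' @param mode `"deep"` or `"shallow"`.
#' @return List with logical arrays `top_region` and `top_interface` and the
#'   `mode` string. `top_interface` contains the reached interface voxels;
#'   they belong to the top region for segregation purposes.
#' @export
build_top <- function(binary, biofilm, bottom, mode = c("deep", "shallow"),
                      plan = NULL, cores = 1L) {
  mode <- match.arg(mode)
  d <- dim(binary)
  if (any(binary[, 1, ] == 1L)) {
    bf_stop("top_not_clear",
            "biomass found in the uppermost plane (z = 1); widen the trim band upward")
  }
  above <- .above_bottom(bottom, d)
  background <- binary == 0L
  interface <- .interface_mask(binary, biofilm, above)
  seeds <- cbind(y = rep(seq_len(d[1]), d[3]), z = 1L,
                 x = rep(seq_len(d[3]), each = d[1]))
  if (mode == "deep") {
    expandable <- background & above
    absorbing <- NULL
  } else {
    expandable <- background & above & !interface
    absorbing <- interface
  }
  res <- if (is.null(plan)) {
    grow_region(expandable, absorbing, seeds)
  } else {
    run_chunked(expandable, absorbing, seeds, plan, cores)
  }
  if (mode == "deep") {
    list(top_region = res$region & !interface,
         top_interface = res$region & interface, mode = mode)
  } else {
    list(top_region = res$region, top_interface = res$absorbed, mode = mode)
  }
}

#' Segregate the volume into its final regions
#'
#' Produces the total labelling: voxels at or below the bottom interface are
#' `bottom`; biofilm voxels keep their label; reached top-region and
#' top-interface voxels theirs; every background voxel above the bottom
#' interface left unexplored by the top growth becomes `biofilm_pore`.
#' Floating biomass (biomass never connected to the bottom interface) remains
#' `unclassified`. The biofilm region of the porosity calculation is
#' `biofilm + biofilm_pore`; top-interface voxels belong to the top region.
#'
#' @inheritParams build_top
#' @param top result of [build_top()].
#' @return Integer array of [region_labels()] codes with attribute `mode`.
#' @export
segregate_regions <- function(binary, biofilm, top, bottom) {
  d <- dim(binary)
  lab <- region_labels()
  above <- .above_bottom(bottom, d)
  labels <- array(lab[["bottom"]], d)
  labels[above] <- lab[["unclassified"]]
  pore <- above & (binary == 0L) & !top$top_region & !top$top_interface
  labels[pore] <- lab[["biofilm_pore"]]
  labels[top$top_region] <- lab[["top_region"]]
  labels[top$top_interface] <- lab[["top_interface"]]
  labels[biofilm] <- lab[["biofilm"]]
  attr(labels, "mode") <- top$mode
  labels
}

#' Voxel counts per region label
#'
#' @param labels label array from [segregate_regions()].
#' @return Named integer vector of counts, one entry per label of
#'   [region_labels()].
#' @export
region_counts <- function(labels) {
  lab <- region_labels()
  vapply(lab, function(code) sum(labels == code), integer(1))
}
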