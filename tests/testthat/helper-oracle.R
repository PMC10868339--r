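# Independent brute-force oracles for the continuity and parameter code.
# The growth oracle builds a full voxel-voxel adjacency matrix from Chebyshev
# distance and iterates the closure until a fixpoint, sharing no code with
# the package's frontier engine. Only usable on small volumes.

oracle_grow <- function(expandable, absorbing = NULL, seeds) {
  d <- dim(expandable)
  n <- prod(d)
  co <- arrayInd(seq_len(n), d)
  adj <- (abs(outer(co[, 1], co[, 1], "-")) <= 1) &
    (abs(outer(co[, 2], co[, 2], "-")) <= 1) &
    (abs(outer(co[, 3], co[, 3], "-")) <= 1)
  diag(adj) <- FALSE
  exp_v <- as.vector(expandable)
  abs_v <- if (is.null(absorbing)) rep(FALSE, n) else as.vector(absorbing)
  seed_idx <- if (is.matrix(seeds) && ncol(seeds) == 3L) {
    seeds[, 1] + (seeds[, 2] - 1L) * d[1] + (seeds[, 3] - 1L) * d[1] * d[2]
  } else {
    as.integer(seeds)
  }
  region <- rep(FALSE, n)
  absorbed <- rep(FALSE, n)
  if (length(seed_idx) > 0L) {
    region[seed_idx[exp_v[seed_idx]]] <- TRUE
    absorbed[seed_idx[!exp_v[seed_idx] & abs_v[seed_idx]]] <- TRUE
  }
  repeat {
    reach <- as.vector(adj %*% region) > 0
    newr <- reach & exp_v & !region & !absorbed
    newa <- reach & abs_v & !exp_v & !region & !absorbed
    if (!any(newr) && !any(newa)) break
    region <- region | newr
    absorbed <- absorbed | newa
  }
  list(region = array(region, d), absorbed = array(absorbed, d))
}

# standard small test phantom: slab + two pores + narrow channel into cavity
channel_phantom <- function() {
  make_phantom(c(12, 30, 14), z_support = 25, thickness = 6,
               pores = rbind(c(3, 22, 12), c(10, 21, 3)),
               channel = list(y = 6, x = 7,
                              cavity = list(y = c(4, 8), z = c(21, 23), x = c(5, 9))),
               voxel_size = c(4.89, 2.08, 4.85))
}

# run the pipeline on a phantom grid with phantom-friendly settings
run_phantom_pipeline <- function(grid, ...) {
  run_pipeline(grid, p = 95, m = 1.5, parallel = FALSE, ...)
}

expect_params_equal_truth <- function(params, truth, mode) {
  expect_equal(params$mean_thickness, truth$mean_thickness)
  expect_equal(params$roughness, truth$roughness)
  expect_equal(params$roughness_coeff, truth$roughness_coeff)
  expect_equal(params$compaction, truth$compaction)
  expect_equal(params$biofilm_count, truth$biofilm_count)
  expect_equal(params$region_count, truth[[mode]]$region_count)
  expect_equal(params$porosity, truth[[mode]]$porosity)
}
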