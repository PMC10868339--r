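# Chunked region growing: partition the (y, x) plane into bands, grow inside
# each chunk independently, then stitch in two merge stages. Growth is a pure
# monotone closure, so expanding chunk-locally and then re-expanding from
# region voxels next to the previously internal edges reaches exactly the
# serial fixpoint -- chunked output is bit-identical to the serial run.

#' Plan a chunk partition of the (y, x) plane
#'
#' Splits the depth axis into `y_bands` and the horizontal axis into
#' `x_bands` contiguous ranges of near-equal size (sizes differ by at most
#' one); the vertical axis is never partitioned.
#'
#' @param shape integer triple `(n_y, n_z, n_x)`.
#' @param y_bands,x_bands positive band counts, at most the axis sizes.
#' @return A `chunk_plan`: list with `y_bands`, `x_bands` and the index
#'   range lists `y_ranges`, `x_ranges` (each range an inclusive `c(lo, hi)`).
#' @export
plan_chunks <- function(shape, y_bands, x_bands) {
  shape <- as.integer(shape)
  y_bands <- as.integer(y_bands); x_bands <- as.integer(x_bands)
  if (y_bands < 1L || x_bands < 1L || y_bands > shape[1] || x_bands > shape[3]) {
    bf_stop("bad_plan", "band counts must be >= 1 and no larger than the axis sizes")
  }
  split_axis <- function(n, bands) {
    b <- as.integer(floor(seq(0, n, length.out = bands + 1L)))
    lapply(seq_len(bands), function(i) c(b[i] + 1L, b[i + 1L]))
  }
  structure(list(y_bands = y_bands, x_bands = x_bands,
                 y_ranges = split_axis(shape[1], y_bands),
                 x_ranges = split_axis(shape[3], x_bands)),
            class = "chunk_plan")
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("<chunk_plan> %d y-bands x %d x-bands = %d chunks\n",
              x$y_bands, x$x_bands, x$y_bands * x$x_bands))
  invisible(x)
}

# padded logical mask that is TRUE inside a (y-range, all z, x-range) box
.box_mask <- function(d, y_range, x_range) {
  m <- array(FALSE, d + 2L)
  m[(y_range[1] + 1L):(y_range[2] + 1L), 2L:(d[2] + 1L),
    (x_range[1] + 1L):(x_range[2] + 1L)] <- TRUE
  m
}

# padded indices of region voxels whose y (axis = 1) or x (axis = 3)
# coordinate lies within distance 1 of an internal band boundary
.edge_frontier <- function(state, d, ranges, axis) {
  if (length(ranges) < 2L) return(integer(0))
  bounds <- vapply(ranges[-length(ranges)], `[`, integer(1), 2L)
  near <- sort(unique(c(bounds, bounds + 1L)))
  idx <- which(state == 1L)
  if (length(idx) == 0L) return(integer(0))
  a <- arrayInd(idx, d + 2L)
  idx[(a[, axis] - 1L) %in% near]
}

.apply_worker <- function(items, fn, cores) {
  cores <- max(1L, as.integer(cores))
  if (cores > 1L && .Platform$OS.type == "unix" && length(items) > 1L) {
    parallel::mclapply(items, fn, mc.cores = cores)
  } else {
    lapply(items, fn)
  }
}

#' Grow a region by chunked three-stage execution
#'
#' Equivalent to [grow_region()], scheduled in three stages: (i) each of the
#' `y_bands * x_bands` chunks grows independently from the seeds it contains,
#' confined to its own box; (ii) chunks are merged along `x` into `y_bands`
#' large bands and growth continues from region voxels adjacent to the
#' previously internal `x` edges; (iii) bands are merged along `y` and growth
#' finishes from region voxels adjacent to the internal `y` edges. The final
#' labelling is identical to the serial run for every plan. A `(1, 1)` plan
#' bypasses chunking (and worker creation) entirely.
#'
#' @inheritParams grow_region
#' @param plan a [plan_chunks()] plan.
#' @param cores worker processes for the per-chunk and per-band stages
#'   (forked via \pkg{parallel}; values above 1 are ignored on Windows).
#' @return List with logical arrays `region` and `absorbed`, identical to
#'   `grow_region(expandable, absorbing, seeds)`.
#' @export
run_chunked <- function(expandable, absorbing = NULL, seeds, plan, cores = 1L) {
  stopifnot(inherits(plan, "chunk_plan"))
  d <- dim(expandable)
  if (plan$y_bands == 1L && plan$x_bands == 1L) {
    return(grow_region(expandable, absorbing, seeds))
  }
  pd <- d + 2L
  offs <- .offsets26(pd)
  expandable_p <- .pad_logical(expandable)
  absorbing_p <- if (is.null(absorbing)) NULL else .pad_logical(absorbing)
  seeds_p <- .pad_index(.as_linear(seeds, d), d)
  state <- array(0L, pd)

  chunk_grid <- expand.grid(iy = seq_len(plan$y_bands), ix = seq_len(plan$x_bands))
  run_stage <- function(items, stage_fn) {
    out <- .apply_worker(items, function(it) {
      tryCatch(stage_fn(it), error = function(e) e)
    }, cores)
    for (i in seq_along(out)) {
      if (inherits(out[[i]], "error")) {
        bf_stop("chunk_failure", sprintf("worker for chunk %d failed: %s",
                                         i, conditionMessage(out[[i]])))
      }
      state[out[[i]]$region] <<- 1L
      state[out[[i]]$absorbed] <<- 2L
    }
  }

  # stage (i): independent growth inside each small chunk
  run_stage(seq_len(nrow(chunk_grid)), function(ci) {
    yr <- plan$y_ranges[[chunk_grid$iy[ci]]]
    xr <- plan$x_ranges[[chunk_grid$ix[ci]]]
    allowed <- .box_mask(d, yr, xr)
    s <- array(0L, pd)
    init <- .classify_seeds(s, seeds_p, expandable_p, absorbing_p, allowed)
    s <- .grow_bfs(init$state, init$frontier, expandable_p, absorbing_p,
                   allowed, offs)
    list(region = which(s == 1L), absorbed = which(s == 2L))
  })

  # stage (ii): merge along x into y-bands; continue from internal x edges
  if (plan$x_bands > 1L) {
    base_state <- state
    run_stage(seq_len(plan$y_bands), function(bi) {
      yr <- plan$y_ranges[[bi]]
      allowed <- .box_mask(d, yr, c(1L, d[3]))
      frontier <- .edge_frontier(base_state, d, plan$x_ranges, axis = 3L)
      frontier <- frontier[allowed[frontier]]
      s <- .grow_bfs(base_state, frontier, expandable_p, absorbing_p,
                     allowed, offs)
      list(region = which(s == 1L & base_state != 1L),
           absorbed = which(s == 2L & base_state != 2L))
    })
  }

  # stage (iii): merge along y; finish from internal y edges
  if (plan$y_bands > 1L) {
    frontier <- .edge_frontier(state, d, plan$y_ranges, axis = 1L)
    state <- .grow_bfs(state, frontier, expandable_p, absorbing_p, NULL, offs)
  }
  .state_to_masks(state, d)
}
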