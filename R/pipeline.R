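# End-to-end pipeline: trim -> bottom interface -> binarize -> biofilm
# growth -> top growth (deep and/or shallow) -> segregation -> structural
# parameters -> renders. Deterministic for a given configuration; chunked
# execution never changes any output byte.

#' Run the full characterization pipeline
#'
#' @param input path to a multi-page TIFF, or a [voxel_grid()].
#' @param voxel_size physical voxel size `(y, z, x)` in micrometres
#'   (required when `input` is a path; a grid carries its own).
#' @param z_low,z_high optional inclusive trim bounds (see [trim_volume()]);
#'   `NULL` skips trimming.
#' @param mode `"both"` (default), `"deep"` or `"shallow"` top continuity.
#' @param p,m binarization percentile and multiplier (see
#'   [estimate_void_intensity()] and [threshold_intensity()]). Results are
#'   sensitive to image acquisition settings; tune per dataset.
#' @param i_void optional manual void intensity overriding the percentile
#'   estimate.
#' @param top_band optional `c(z_low, z_high)` band (after trimming) for the
#'   void estimate; default the first 10% of planes.
#' @param bottom_window,bottom_jump_tol bottom-interface smoothing controls
#'   (see [smooth_bottom_x()]).
#' @param y_bands,x_bands chunk counts for the chunked growth stages.
#'   Volumes smaller than 64 voxels along `y` or `x` fall back to a single
#'   chunk, where chunking overhead outweighs any gain.
#' @param parallel logical; `FALSE` forces the single-chunk plan.
#' @param cores worker processes for chunked execution.
#' @param roi optional list `list(y = c(lo, hi), x = c(lo, hi))`: also report
#'   parameters on this region of interest.
#' @param out_dir optional directory; when given, persists the pre-processed
#'   volume, interfaces, masks, renders and parameter files.
#' @param verbose log step durations and voxel counts via `message()`.
#' @return List with `grid` (pre-processed volume), `i_void`, `i_thresh`,
#'   `z_bot`, `binary`, `biofilm`, and one entry per mode holding `top`,
#'   `labels`, `params` (and `roi` when requested).
#' @export
run_pipeline <- function(input, voxel_size = NULL, z_low = NULL, z_high = NULL,
                         mode = c("both", "deep", "shallow"),
                         p = 95, m = 2, i_void = NULL, top_band = NULL,
                         bottom_window = 5L, bottom_jump_tol = 5L,
                         y_bands = 5L, x_bands = 5L, parallel = TRUE,
                         cores = 1L, roi = NULL, out_dir = NULL,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("deep", "shallow") else mode
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  step <- function(name, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    say("[%s] %.2f s", name, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    val
  }

  grid <- if (inherits(input, "voxel_grid")) input else {
    step("read", read_volume(input, voxel_size))
  }
  if (!is.null(z_low) || !is.null(z_high)) {
    n_z <- dim(grid$intensities)[2]
    grid <- step("trim", trim_volume(grid,
                                     if (is.null(z_low)) 1L else z_low,
                                     if (is.null(z_high)) n_z else z_high))
  }
  d <- dim(grid$intensities)
  say("volume %d x %d x %d (y, z, x)", d[1], d[2], d[3])

  z_bot <- step("bottom", detect_bottom(grid, bottom_window, bottom_jump_tol))
  iv <- if (is.null(i_void)) {
    step("void", estimate_void_intensity(grid, top_band, p))
  } else i_void
  it <- threshold_intensity(iv, m)
  say("i_void = %.2f, i_thresh = %.2f", iv, it)
  binary <- step("binarize", binarize_volume(grid, it))
  say("biomass voxels: %d", sum(binary))

  plan <- NULL
  if (isTRUE(parallel) && (y_bands > 1L || x_bands > 1L) &&
      d[1] >= 64L && d[3] >= 64L) {
    plan <- plan_chunks(d, min(y_bands, d[1]), min(x_bands, d[3]))
  }
  biofilm <- step("biofilm", build_biofilm(binary, z_bot, plan, cores))
  say("biofilm voxels: %d (floating biomass: %d)", sum(biofilm),
      sum(binary == 1L & .above_bottom(z_bot, d)) - sum(biofilm))

  out <- list(grid = grid, i_void = iv, i_thresh = it, z_bot = z_bot,
              binary = binary, biofilm = biofilm)
  vx <- grid$voxel_size[["z"]]
  for (md in modes) {
    top <- step(paste0("top_", md),
                build_top(binary, biofilm, z_bot, md, plan, cores))
    labels <- segregate_regions(binary, biofilm, top, z_bot)
    params <- structural_params(labels, z_bot, top$top_interface, vx, it)
    say("[%s] region %d voxels, porosity %.4f", md, params$region_count,
        params$porosity)
    entry <- list(top = top, labels = labels, params = params)
    if (!is.null(roi)) {
      entry$roi <- roi_params(labels, z_bot, top$top_interface, vx,
                              roi$y, roi$x, it)
    }
    out[[md]] <- entry
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(out_dir, ...)
    write_volume(grid, fp("pre_processed.tif"))
    render_biomass(binary, fp("biomass.tif"))
    utils::write.csv(data.frame(y = as.vector(row(z_bot)),
                                x = as.vector(col(z_bot)),
                                z_bot = as.vector(z_bot)),
                     fp("z_bot.csv"), row.names = FALSE)
    for (md in modes) {
      e <- out[[md]]
      render_biofilm(e$labels, fp(sprintf("biofilm_%s.tif", md)))
      render_bounds(grid, z_bot, e$top$top_interface,
                    fp(sprintf("bounds_%s.tif", md)))
      render_structure(grid, e$labels, fp(sprintf("structure_%s.tif", md)))
      render_thickness_heatmap(e$params$thickness,
                               fp(sprintf("thickness_%s.png", md)))
      if (any(e$top$top_interface)) {
        render_topography(e$top$top_interface, z_bot, grid$voxel_size,
                          fp(sprintf("topography_%s.png", md)))
        ti <- which(e$top$top_interface, arr.ind = TRUE)
        colnames(ti) <- c("y", "z", "x")
        utils::write.csv(ti, fp(sprintf("z_top_%s.csv", md)), row.names = FALSE)
      }
      write_params(e$params, fp(sprintf("params_%s.json", md)))
      if (!is.null(e$roi)) write_params(e$roi, fp(sprintf("params_roi_%s.json", md)))
    }
    say("outputs written to %s", out_dir)
  }
  out
}
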