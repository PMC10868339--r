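test_that("the 26-neighbourhood shrinks correctly at faces, edges and corners", {
  expect_equal(nrow(voxel_neighbours(c(2, 2, 2), c(3, 3, 3))), 26L)
  expect_equal(nrow(voxel_neighbours(c(1, 2, 2), c(3, 3, 3))), 17L)
  expect_equal(nrow(voxel_neighbours(c(1, 1, 2), c(3, 3, 3))), 11L)
  expect_equal(nrow(voxel_neighbours(c(1, 1, 1), c(2, 2, 2))), 7L)
  # degenerate single-slice volume: 2D 8-neighbourhood
  expect_equal(nrow(voxel_neighbours(c(1, 2, 2), c(1, 3, 3))), 8L)
  expect_error(voxel_neighbours(c(0, 1, 1), c(2, 2, 2)), class = "biofilm_bad_coord")
})

test_that("the biofilm seed layer sits immediately above the bottom interface", {
  ph <- make_phantom(c(4, 15, 5), z_support = 12, thickness = 4)
  b <- binarize_volume(ph$grid, 50)
  seeds <- seed_biofilm(b, ph$truth$z_bot)
  expect_equal(nrow(seeds), 4L * 5L)
  expect_true(all(seeds[, 2] == 11L))

  empty <- array(0L, c(4, 15, 5))
  expect_equal(nrow(seed_biofilm(empty, ph$truth$z_bot)), 0L)

  floating <- array(0L, c(4, 15, 5))
  floating[2, 3, 3] <- 1L                   # biomass far above the interface
  expect_equal(nrow(seed_biofilm(floating, ph$truth$z_bot)), 0L)
})

test_that("grow_region equals the brute-force closure on crafted cases", {
  d <- c(5, 5, 5)
  # seeds walled into a cavity
  expandable <- array(TRUE, d)
  expandable[, 3, ] <- FALSE                # impassable floor
  seeds <- cbind(3, 1, 3)
  got <- grow_region(expandable, NULL, seeds)
  want <- oracle_grow(expandable, NULL, seeds)
  expect_identical(got, want)
  expect_true(all(!got$region[, 4:5, ]))

  # absorbing shell one voxel thick around the seed
  expandable2 <- array(FALSE, d)
  expandable2[3, 3, 3] <- TRUE
  absorbing <- array(FALSE, d)
  absorbing[2:4, 2:4, 2:4] <- TRUE
  absorbing[3, 3, 3] <- FALSE
  got2 <- grow_region(expandable2, absorbing, seeds = cbind(3, 3, 3))
  want2 <- oracle_grow(expandable2, absorbing, cbind(3, 3, 3))
  expect_identical(got2, want2)
  expect_equal(sum(got2$absorbed), 26)

  # everything expandable: closure is the whole volume
  all_exp <- array(TRUE, d)
  expect_true(all(grow_region(all_exp, NULL, cbind(1, 1, 1))$region))
})

test_that("grow_region matches the oracle on random volumes and is seed-order invariant", {
  set.seed(42)
  for (i in 1:25) {
    d <- sample(2:8, 3, replace = TRUE)
    expandable <- array(stats::runif(prod(d)) < 0.6, d)
    absorbing <- array(stats::runif(prod(d)) < 0.2, d) & !expandable
    n_seed <- sample(1:4, 1)
    seeds <- cbind(sample(d[1], n_seed, TRUE), sample(d[2], n_seed, TRUE),
                   sample(d[3], n_seed, TRUE))
    got <- grow_region(expandable, absorbing, seeds)
    want <- oracle_grow(expandable, absorbing, seeds)
    expect_identical(got, want)
    perm <- grow_region(expandable, absorbing,
                        seeds[sample(nrow(seeds)), , drop = FALSE])
    expect_identical(perm, got)
  }
})

test_that("biofilm growth keeps attached structure and drops floating biomass", {
  ph <- make_phantom(c(6, 20, 8), z_support = 16, thickness = 5)
  b <- binarize_volume(ph$grid, 50)
  bio <- build_biofilm(b, ph$truth$z_bot)
  expect_equal(sum(bio), ph$truth$biofilm_count)

  b2 <- b
  b2[3, 3, 4] <- 1L                         # floating blob above the slab
  bio2 <- build_biofilm(b2, ph$truth$z_bot)
  expect_false(bio2[3, 3, 4])
  expect_equal(sum(bio2), ph$truth$biofilm_count)
})

test_that("a blob disconnected per slice joins the biofilm through a neighbour slice", {
  ph <- make_phantom(c(5, 22, 9), z_support = 18, thickness = 4)
  b <- binarize_volume(ph$grid, 50)
  # blob in slices y = 2..3 at z = 8..9, not touching the slab within any
  # constant-y slice; a bridge voxel in slice y = 4 connects blob to slab top
  b[2:3, 8:9, 4:5] <- 1L
  b[4, 10:13, 5] <- 1L                      # vertical bridge down to slab (z = 14)
  bio <- build_biofilm(b, ph$truth$z_bot)
  expect_true(all(bio[2:3, 8:9, 4:5]))
  # removing the bridging slice column leaves the blob floating
  b_cut <- b
  b_cut[4, 10:13, 5] <- 0L
  bio_cut <- build_biofilm(b_cut, ph$truth$z_bot)
  expect_false(any(bio_cut[2:3, 8:9, 4:5]))
})

test_that("top growth distinguishes deep and shallow continuity on a channel", {
  ph <- channel_phantom()
  b <- binarize_volume(ph$grid, 50)
  bio <- build_biofilm(b, ph$truth$z_bot)
  deep <- build_top(b, bio, ph$truth$z_bot, "deep")
  shallow <- build_top(b, bio, ph$truth$z_bot, "shallow")
  # deep penetrates shaft + cavity; shallow leaves them unexplored
  expect_true(deep$top_region[6, 22, 7] | deep$top_interface[6, 22, 7])
  expect_false(shallow$top_region[6, 22, 7] | shallow$top_interface[6, 22, 7])
  # deep top region contains the shallow one
  shallow_all <- shallow$top_region | shallow$top_interface
  deep_all <- deep$top_region | deep$top_interface
  expect_true(all(deep_all[shallow_all]))

  # flat slab: both modes identical
  flat <- make_phantom(c(5, 18, 6), z_support = 14, thickness = 4)
  fb <- binarize_volume(flat$grid, 50)
  fbio <- build_biofilm(fb, flat$truth$z_bot)
  fd <- build_top(fb, fbio, flat$truth$z_bot, "deep")
  fs <- build_top(fb, fbio, flat$truth$z_bot, "shallow")
  expect_identical(fd$top_region, fs$top_region)
  expect_identical(fd$top_interface, fs$top_interface)
  expect_true(all(fd$top_interface[, 9, ]))  # layer above the slab top (z = 10)

  # biomass in the top plane is a trim problem, reported as such
  bad <- fb; bad[1, 1, 1] <- 1L
  expect_error(build_top(bad, fbio, flat$truth$z_bot, "deep"),
               class = "biofilm_top_not_clear")
})

test_that("segregation yields a total labelling that partitions the volume", {
  ph <- channel_phantom()
  b <- binarize_volume(ph$grid, 50)
  bio <- build_biofilm(b, ph$truth$z_bot)
  b[2, 3, 2] <- 1L                          # floating voxel -> unclassified
  for (md in c("deep", "shallow")) {
    top <- build_top(b, bio, ph$truth$z_bot, md)
    labels <- segregate_regions(b, bio, top, ph$truth$z_bot)
    counts <- region_counts(labels)
    expect_equal(sum(counts), prod(dim(b)))
    expect_equal(counts[["unclassified"]], 1L)
    expect_equal(counts[["biofilm"]], ph$truth$biofilm_count)
    expect_equal(counts[["biofilm_pore"]], ph$truth[[md]]$pore_count)
    expect_equal(counts[["bottom"]], 12L * 14L * (30L - 25L + 1L))
  }

  solid <- make_phantom(c(4, 16, 5), z_support = 12, thickness = 4)
  sb <- binarize_volume(solid$grid, 50)
  sbio <- build_biofilm(sb, solid$truth$z_bot)
  stop_ <- build_top(sb, sbio, solid$truth$z_bot, "deep")
  slab_labels <- segregate_regions(sb, sbio, stop_, solid$truth$z_bot)
  expect_equal(region_counts(slab_labels)[["biofilm_pore"]], 0L)
})
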