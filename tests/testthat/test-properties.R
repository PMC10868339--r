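test_that("thickness counts voxels strictly between the interfaces", {
  # one column: bottom at index 21, highest top-interface voxel at index 10
  bottom <- matrix(21L, 1, 1)
  ti <- array(FALSE, c(1, 30, 1)); ti[1, 10, 1] <- TRUE
  expect_equal(thickness_map(bottom, ti, 2.08)[1, 1], (21 - 10 - 1) * 2.08)

  # empty column: forced zero
  expect_equal(thickness_map(bottom, array(FALSE, c(1, 30, 1)), 2.08)[1, 1], 0)

  # uniform slab phantom: thickness T * vx_len everywhere
  ph <- make_phantom(c(4, 20, 6), z_support = 16, thickness = 5,
                     voxel_size = c(1, 2, 1))
  res <- run_phantom_pipeline(ph$grid, mode = "deep")
  expect_equal(res$deep$params$thickness, matrix(10, 4, 6))

  # biofilm without a top interface is an internal inconsistency
  bio <- array(FALSE, c(1, 30, 1)); bio[1, 15, 1] <- TRUE
  expect_error(thickness_map(bottom, array(FALSE, c(1, 30, 1)), 2.08, biofilm = bio),
               class = "biofilm_inconsistent_interfaces")
})

test_that("mean, roughness and coefficient match brute-force sums", {
  expect_equal(mean_thickness(matrix(50, 3, 4)), 50)
  expect_equal(mean_thickness(matrix(c(10, 30), 2, 4)), 20)
  expect_equal(roughness(matrix(50, 3, 4)), 0)
  expect_equal(roughness(matrix(c(10, 30), 2, 4)), 10)
  expect_equal(roughness_coeff(matrix(50, 3, 4)), 0)

  set.seed(31)
  m <- matrix(stats::rexp(35, 1 / 40), 5, 7)
  brute_mean <- sum(m) / length(m)
  brute_r <- sum(abs(m - brute_mean)) / length(m)
  expect_equal(mean_thickness(m), brute_mean)
  expect_equal(roughness(m), brute_r)
  expect_equal(roughness_coeff(m), brute_r / brute_mean)
  # scale invariance of the coefficient
  expect_equal(roughness_coeff(3.7 * m), roughness_coeff(m))
  # identity R_a* x mean = R_a
  expect_equal(roughness_coeff(m) * mean_thickness(m), roughness(m))
  expect_warning(rc <- roughness_coeff(matrix(0, 2, 2)), "undefined")
  expect_true(is.na(rc))
})

test_that("the reported roughness statistics are mutually consistent", {
  # a two-level map realizing mean 71.1 um and roughness 44.8 um
  m <- matrix(c(71.1 - 44.8, 71.1 + 44.8), 2, 10)
  expect_equal(mean_thickness(m), 71.1)
  expect_equal(roughness(m), 44.8)
  expect_equal(round(roughness_coeff(m), 3), 0.630)
})

test_that("compaction and porosity follow their count definitions", {
  map <- matrix(8, 3, 4)                     # envelope 8 voxels high, vx 1
  expect_equal(compaction(8 * 12, map, 1), 1)
  expect_equal(compaction(4 * 12, map, 1), 0.5)
  expect_warning(cp <- compaction(5, matrix(0, 2, 2), 1), "undefined")
  expect_true(is.na(cp))
  expect_equal(porosity(380, 400), 0.05)
  expect_equal(porosity(100, 100), 0)
  expect_warning(ph <- porosity(0, 0), "undefined")
  expect_true(is.na(ph))
})

test_that("region-of-interest windows reproduce their slab's parameters", {
  ph <- channel_phantom()
  res <- run_phantom_pipeline(ph$grid, mode = "shallow")
  e <- res$shallow
  full <- roi_params(e$labels, res$z_bot, e$top$top_interface,
                     ph$grid$voxel_size[["z"]], c(1, 12), c(1, 14))
  expect_equal(full$mean_thickness, e$params$mean_thickness)
  expect_equal(full$porosity, e$params$porosity)
  expect_equal(full$compaction, e$params$compaction)

  # a window avoiding channel, cavity and pores is a solid sub-slab
  sub <- roi_params(e$labels, res$z_bot, e$top$top_interface,
                    ph$grid$voxel_size[["z"]], c(1, 2), c(1, 2))
  expect_equal(sub$porosity, 0)
  expect_equal(sub$compaction, 1)
  expect_equal(sub$mean_thickness, 6 * 2.08)
  expect_error(roi_params(e$labels, res$z_bot, e$top$top_interface, 2.08,
                          c(5, 4), c(1, 2)), class = "biofilm_bad_roi")
})

test_that("parameters are invariant under lateral translation of the structure", {
  base <- make_phantom(c(10, 24, 12), z_support = 20, thickness = 5,
                       pores = rbind(c(3, 17, 4)))
  shifted <- make_phantom(c(10, 24, 12), z_support = 20, thickness = 5,
                          pores = rbind(c(6, 17, 9)))
  r1 <- run_phantom_pipeline(base$grid, mode = "deep")$deep$params
  r2 <- run_phantom_pipeline(shifted$grid, mode = "deep")$deep$params
  for (k in c("mean_thickness", "roughness", "roughness_coeff",
              "compaction", "porosity")) {
    expect_equal(r1[[k]], r2[[k]])
  }
})

test_that("deep and shallow agree on everything except porosity", {
  ph <- channel_phantom()
  res <- run_phantom_pipeline(ph$grid)
  d <- res$deep$params; s <- res$shallow$params
  expect_equal(d$mean_thickness, s$mean_thickness)
  expect_equal(d$roughness, s$roughness)
  expect_equal(d$roughness_coeff, s$roughness_coeff)
  expect_equal(d$compaction, s$compaction)
  expect_lt(d$porosity, s$porosity)
})
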