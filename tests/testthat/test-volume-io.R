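test_that("TIFF pages map to depth slices with the (y, z, x) convention", {
  pages <- lapply(1:3, function(k) matrix(as.integer(k * 10 + 0:19), 4, 5))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(pages, function(p) p / 255), path, bits.per.sample = 8L)
  g <- read_volume(path, c(4.89, 2.08, 4.85))
  expect_equal(dim(g$intensities), c(3L, 4L, 5L))
  for (k in 1:3) expect_equal(matrix(g$intensities[k, , ], 4, 5), pages[[k]])

  tiff::writeTIFF(pages[[1]] / 255, path, bits.per.sample = 8L)
  expect_equal(dim(read_volume(path, c(1, 1, 1))$intensities)[1], 1L)
})

test_that("write/read round trip is lossless for 8-bit volumes", {
  set.seed(11)
  arr <- array(sample(0:255, 2 * 6 * 5, replace = TRUE), c(2, 6, 5))
  g <- voxel_grid(arr, c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(g, path)
  g2 <- read_volume(path, c(1, 2, 3))
  expect_identical(g2$intensities, g$intensities)

  zero <- voxel_grid(array(0L, c(2, 2, 2)), c(1, 1, 1))
  write_volume(zero, path)
  expect_true(all(read_volume(path, c(1, 1, 1))$intensities == 0L))
})

test_that("RGB and 16-bit inputs are reduced to 8-bit greyscale", {
  path <- withr::local_tempfile(fileext = ".tif")
  rgb <- array(0, c(4, 5, 3))
  rgb[, , 1] <- 1                      # pure red: luminance 0.299
  tiff::writeTIFF(rgb, path, bits.per.sample = 8L)
  g <- read_volume(path, c(1, 1, 1))
  expect_true(all(g$intensities == round(0.299 * 255)))

  tiff::writeTIFF(matrix(c(0, 0.5, 1), 3, 4), path, bits.per.sample = 16L)
  g16 <- read_volume(path, c(1, 1, 1))
  # stored 16-bit values are 0, 32767, 65535; linear rescale by 1/257
  expect_equal(sort(unique(as.vector(g16$intensities))),
               as.integer(round(c(0, 32767, 65535) / 257)))
})

test_that("reader failures raise distinct named conditions", {
  expect_error(read_volume("no/such/file.tif", c(1, 1, 1)),
               class = "biofilm_missing_file")
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0, 2, 2), matrix(0, 3, 2)), path,
                  bits.per.sample = 8L)
  expect_error(read_volume(path, c(1, 1, 1)),
               class = "biofilm_inconsistent_pages")
  tiff::writeTIFF(matrix(0, 2, 2), path, bits.per.sample = 8L)
  expect_error(read_volume(path, c(1, 0, 1)), class = "biofilm_bad_voxel_size")
  expect_error(voxel_grid(array(300, c(1, 2, 2)), c(1, 1, 1)),
               class = "biofilm_bad_volume")
})

test_that("parameter files round-trip and differ between modes only as expected", {
  ph <- channel_phantom()
  res <- run_phantom_pipeline(ph$grid)
  dir <- withr::local_tempdir()
  pd <- file.path(dir, "deep.json")
  ps <- file.path(dir, "shallow.json")
  write_params(res$deep$params, pd)
  write_params(res$shallow$params, ps)
  back <- read_params(pd)
  expect_equal(back$porosity, res$deep$params$porosity)
  expect_equal(back$mean_thickness_um, res$deep$params$mean_thickness)
  expect_equal(back$mode, "deep")

  a <- read_params(pd); b <- read_params(ps)
  same <- c("mean_thickness_um", "roughness_um", "roughness_coeff",
            "compaction", "i_thresh")
  for (k in same) expect_equal(a[[k]], b[[k]])
  expect_false(isTRUE(all.equal(a$porosity, b$porosity)))
  expect_false(identical(a$mode, b$mode))
})
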