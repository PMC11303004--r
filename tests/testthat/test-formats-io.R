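test_that("MRC stack roundtrip preserves pixels and pixel size", {
  set.seed(1)
  data <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  st <- image_stack(data, 1.44,
                    data.frame(segment_id = 1:3, psi_deg = c(10.123456, 0, 90)))
  path <- tempfile(fileext = ".mrc")
  write_stack(st, path)
  back <- read_stack(path)
  ## 32-bit storage: exact for float32-representable values
  expect_equal(back$data, data, tolerance = 1e-6)
  expect_equal(back$pixel_size, 1.44, tolerance = 1e-6)
  expect_equal(nrow(back$metadata), 3)
  ## metadata numeric roundtrip keeps >= 6 significant digits
  expect_equal(back$metadata$psi_deg[1], 10.123456, tolerance = 1e-6)
})

test_that("truncated MRC stack is rejected", {
  set.seed(2)
  st <- image_stack(array(rnorm(16 * 16 * 4), c(16, 16, 4)), 1)
  path <- tempfile(fileext = ".mrc")
  write_stack(st, path)
  ## claim 5 images in the header while the file holds 4
  con <- file(path, "r+b")
  seek(con, 8, rw = "write")
  writeBin(5L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_stack(path), "truncated|promises")
})

test_that("simulator stacks survive write/read with metadata intact", {
  sim <- simulate_tube_dataset(n_tubes = 3, image_size = 96,
                               pixel_size = 2,
                               profile = tube_profile(55, 20, 5),
                               particle = NULL, snr = 2, seed = 4)
  path <- tempfile(fileext = ".mrc")
  write_stack(sim$stack, path)
  back <- read_stack(path)
  expect_equal(n_images(back), 3)
  expect_equal(back$pixel_size, 2, tolerance = 1e-6)
  expect_equal(back$metadata$origin_x, sim$stack$metadata$origin_x,
               tolerance = 1e-6)
})

test_that("empty stacks cannot be written", {
  st <- image_stack(array(0, c(8, 8, 1)), 1)
  st$data <- st$data[, , 0, drop = FALSE]
  st$metadata <- st$metadata[0, , drop = FALSE]
  expect_error(write_stack(st, tempfile()), "empty")
})

test_that("volume roundtrip works and non-cubic volumes are rejected", {
  set.seed(3)
  v <- volume3d(array(rnorm(32^3), c(32, 32, 32)), 2.5)
  path <- tempfile(fileext = ".mrc")
  write_volume(v, path)
  back <- read_volume(path)
  expect_equal(back$voxels, v$voxels, tolerance = 1e-6)
  expect_equal(back$voxel_size, 2.5, tolerance = 1e-6)
  ## rectangular file: forge header dims 64 x 64 x 32 is awkward; instead
  ## write a stack (non-cubic data) and read it as a volume
  st <- image_stack(array(rnorm(16 * 16 * 4), c(16, 16, 4)), 1)
  p2 <- tempfile(fileext = ".mrc")
  write_stack(st, p2)
  expect_error(read_volume(p2), "cubic")
  expect_error(volume3d(array(0, c(4, 4, 5)), 1), "cubic")
})

test_that("all-zero volume records zeroed header statistics", {
  v <- volume3d(array(0, c(32, 32, 32)), 1)
  path <- tempfile(fileext = ".mrc")
  write_volume(v, path)
  con <- file(path, "rb")
  seek(con, 76)
  stats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  close(con)
  expect_equal(stats, c(0, 0, 0))
})

test_that("STAR tables roundtrip with RELION-style labels", {
  df <- data.frame(segment_id = 1:4, psi_deg = c(0.5, 90.25, 179.999, 45),
                   shift_x_px = c(-3.25, 0, 7.5, 1.125),
                   align_ok = c(1L, 1L, 0L, 1L))
  path <- tempfile(fileext = ".star")
  write_star(df, path)
  txt <- readLines(path)
  expect_true(any(grepl("_rlnAnglePsi", txt)))
  expect_true(any(grepl("_rlnOriginX", txt)))
  back <- read_star(path)
  expect_equal(back$psi_deg, df$psi_deg, tolerance = 1e-7)
  expect_equal(back$shift_x_px, df$shift_x_px, tolerance = 1e-7)
})

test_that("pick coordinate files roundtrip", {
  picks <- data.frame(segment_id = c(1L, 2L), micrograph_id = c(1L, 1L),
                      local_x = c(10.25, 40), local_y = c(20.5, 11),
                      global_x = c(110.25, 170), global_y = c(220.5, 241),
                      score = c(0.9, 0.5))
  path <- tempfile(fileext = ".txt")
  write_picks(picks, path)
  back <- read_picks(path)
  expect_equal(back$global_x, picks$global_x, tolerance = 1e-6)
  expect_equal(back$score, picks$score, tolerance = 1e-6)
})

test_that("stack constructor enforces the metadata join invariant", {
  expect_error(image_stack(array(0, c(8, 8, 3)), 1,
                           data.frame(segment_id = 1:2)),
               "metadata rows")
  expect_error(image2d(matrix(c(1, NA, 3, 4), 2, 2), 1), "finite")
})
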