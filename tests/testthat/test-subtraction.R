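test_that("per-segment scaling recovers alpha and self-subtraction is exact", {
  prof <- tube_profile(); ps <- 6.875; n <- 64
  proj <- render_tube_projection(prof, n, ps)
  ## img == proj: alpha = 1, residual ~ 0
  r <- subtract_segment(proj, proj)
  expect_equal(r$scale_alpha, 1, tolerance = 1e-9)
  expect_lt(r$residual_rms_in_mask, 1e-9)
  ## img = 2.5 proj + noise: least-squares closed form
  set.seed(6)
  img <- image2d(2.5 * proj$pixels +
                   matrix(stats::rnorm(n * n, 0, 0.1 * max(proj$pixels)),
                          n, n), ps)
  r2 <- subtract_segment(img, proj)
  expect_equal(r2$scale_alpha, 2.5, tolerance = 0.05 / 2.5)
  ## an empty projection cannot be subtracted
  expect_error(subtract_segment(img, image2d(matrix(0, n, n) + 0 * 1e-30 +
                                               matrix(0, n, n), ps)),
               "empty|nothing")
})

test_that("pixels outside the projection support are untouched", {
  n <- 64
  img <- matrix(stats::rnorm(n * n), n, n)
  proj <- matrix(0, n, n)
  proj[20:40, ] <- 5
  r <- subtract_segment(image2d(img, 1), image2d(proj, 1))
  outside <- img - r$subtracted$pixels
  expect_equal(outside[proj == 0], rep(0, sum(proj == 0)))
})

test_that("stack subtraction erases the tube and preserves particles", {
  prof <- tube_profile(); ps <- 6.875; n <- 96
  sim <- simulate_tube_dataset(n_tubes = 15, image_size = n, pixel_size = ps,
                               particle = gaussian_particle(pixel_size = ps),
                               particles_per_segment = 1, snr = Inf,
                               max_offset_px = 4, seed = 13)
  st <- align_stack(sim$stack, seed = 3)
  rl <- refine_loop(st, max_iter = 2, oversample = 1)
  sub <- subtract_stack(rl$stack)
  tr <- sim$truth
  nccs <- c(); ratios <- c()
  for (i in which(sub$metadata$align_ok == 1)) {
    sgt <- tr$segments[i, ]
    bare <- render_tube_projection(prof, n, ps, sgt$psi_true_deg,
                                   sgt$center_offset_px)$pixels
    ponly <- sim$stack$data[, , i] - bare
    m <- bare > 0.1 * max(bare)
    tres <- sub$data[, , i] - ponly
    ratios <- c(ratios, sqrt(mean((tres[m] - mean(tres[m]))^2)) /
                  sqrt(mean((bare[m] - mean(bare[m]))^2)))
    if (stats::sd(ponly) > 0) nccs <- c(nccs, ncc(sub$data[, , i], ponly))
  }
  ## with a bright particle overlapping the tube band, a small residual
  ## (alignment bias from the decoration) remains on the shells
  expect_lt(stats::median(ratios), 0.2)
  expect_gt(stats::median(nccs), 0.9)
  ## metadata gained the subtraction columns
  expect_true(all(c("scale_alpha", "residual_rms") %in%
                  names(sub$metadata)))
  expect_equal(stats::median(sub$metadata$scale_alpha, na.rm = TRUE), 1,
               tolerance = 0.1)
  ## empty stack errors
  bad <- sub; bad$metadata$align_ok <- 0L
  expect_error(subtract_stack(bad), "no aligned")
})

test_that("residual tube power shrinks with more segments in the average", {
  prof <- tube_profile(); ps <- 6.875; n <- 96
  resid_for <- function(N) {
    sim <- simulate_tube_dataset(n_tubes = N, image_size = n,
                                 pixel_size = ps, particle = NULL,
                                 snr = Inf, max_offset_px = 3, seed = 17)
    st <- sim$stack
    tr <- sim$truth$segments
    md <- st$metadata
    md$psi_deg <- tr$psi_true_deg
    md$shift_x_px <- -tr$center_offset_px
    md$shift_y_px <- 0; md$align_ok <- 1L
    set.seed(2)
    md$phi_deg <- stats::runif(N, 0, 360)
    md$theta_deg <- sample(c(90, 270), N, replace = TRUE)
    st$metadata <- md
    avg <- smooth_z(reconstruct_average(st, oversample = 1))
    sub <- subtract_stack(st, avg, projection = "volume")
    mean(vapply(seq_len(N), function(i) {
      bare <- render_tube_projection(prof, n, ps, tr$psi_true_deg[i],
                                     tr$center_offset_px[i])$pixels
      m <- bare > 0.1 * max(bare)
      sum((sub$data[, , i][m] - mean(sub$data[, , i][m]))^2)
    }, numeric(1)))
  }
  expect_lte(resid_for(40), resid_for(10))
})
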