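test_that("reconstruction of uniformly spun projections matches the analytic
           body of revolution", {
  st <- phi_series_stack(n = 64, n_views = 60)
  avg <- reconstruct_average(st)
  ana <- analytic_tube_volume(64)
  n <- 64; g <- (0:(n - 1)) - (n - 1) / 2
  r_px <- sqrt(outer(g^2, g^2, "+"))
  mask <- array(as.logical(outer(r_px <= 0.4 * n, abs(g) <= 0.4 * n)),
                c(n, n, n))
  expect_gt(stats::cor(avg$voxels[mask], ana$voxels[mask]), 0.98)
  expect_gt(cylindricity(avg), 0.99)
  ## all-zero input gives an (effectively) all-zero volume
  z <- st; z$data[] <- 0
  avg0 <- reconstruct_average(z)
  expect_lt(max(abs(avg0$voxels)), 1e-10)
  ## missing angles error
  bad <- st; bad$metadata$phi_deg[2] <- NA
  expect_error(reconstruct_average(bad), "missing")
  ## linearity
  sc <- st; sc$data <- sc$data * 2.5
  avg2 <- reconstruct_average(sc)
  expect_equal(avg2$voxels, 2.5 * avg$voxels, tolerance = 1e-8)
})

test_that("Fourier-slice consistency: projecting the reconstruction returns
           the input view", {
  st <- phi_series_stack(n = 64, n_views = 60)
  avg <- smooth_z(reconstruct_average(st))
  proj <- project_average(avg, phi_deg = 123, theta_deg = 90, psi_deg = 0)
  expect_gt(ncc(proj$pixels, st$data[, , 1]), 0.995)
})

test_that("z smoothing averages slices and is a fixed point", {
  n <- 32
  v <- array(0, c(n, n, n))
  ## single nonzero slice of constant value v among the averaged slices
  v[, , 16] <- 3
  vol <- volume3d(v, 1)
  sm <- smooth_z(vol, z_fraction = 0.5)
  nuse <- round(0.5 * n)
  expect_equal(sm$voxels[1, 1, 1], 3 / nuse, tolerance = 1e-12)
  ## every slice now identical
  expect_equal(sm$voxels[, , 1], sm$voxels[, , n])
  ## fixed point on z-invariant input
  expect_equal(smooth_z(sm, 0.5)$voxels, sm$voxels)
  ## linear ramp along z averages to the ramp mean over the central window
  vr <- volume3d(array(rep(1:n, each = n * n), c(n, n, n)), 1)
  smr <- smooth_z(vr, z_fraction = 0.5)
  z0 <- floor((n - nuse) / 2) + 1
  expect_equal(smr$voxels[5, 5, 1], mean(z0:(z0 + nuse - 1)))
})

test_that("cylindricity separates bodies of revolution from decorated ones", {
  ana <- analytic_tube_volume(48)
  expect_gt(cylindricity(ana), 0.999)
  blob <- ana
  blob$voxels[34:38, 24, 20:28] <- blob$voxels[34:38, 24, 20:28] +
    max(ana$voxels) * 2
  expect_lt(cylindricity(blob), cylindricity(ana))
  expect_error(cylindricity(volume3d(array(0, c(8, 8, 8)), 1)), "zero")
})

test_that("projection respects spin symmetry and zero input", {
  zero <- volume3d(array(0, c(32, 32, 32)), 1)
  expect_equal(max(abs(project_average(zero)$pixels)), 0)
  ana <- smooth_z(analytic_tube_volume(48), 0.8)
  p1 <- project_average(ana, phi_deg = 10)
  p2 <- project_average(ana, phi_deg = 185)
  rms <- sqrt(mean((p1$pixels - p2$pixels)^2)) /
    sqrt(mean((p1$pixels - mean(p1$pixels))^2))
  expect_lt(rms, 0.001)
  ## theta = 90 projection of the analytic cylinder matches the renderer
  bare <- render_tube_projection(tube_profile(), 48, 6.875)
  expect_gt(ncc(project_average(ana)$pixels, bare$pixels), 0.999)
})

test_that("refinement against a reference is a fixed point at the optimum
           and recovers perturbed segments", {
  prof <- tube_profile(); ps <- 6.875; n <- 64
  vol <- analytic_tube_volume(n)
  set.seed(8)
  psi_t <- stats::runif(6, 0, 180); off_t <- stats::runif(6, -4, 4)
  imgs <- lapply(seq_len(6), function(i)
    render_tube_projection(prof, n, ps, psi_t[i], off_t[i])$pixels)
  md <- data.frame(segment_id = 1:6, psi_deg = psi_t, theta_deg = 90,
                   phi_deg = stats::runif(6, 0, 360),
                   shift_x_px = -off_t, shift_y_px = 0, align_ok = 1)
  st <- image_stack(simplify2array(imgs), ps, md)
  ## at the optimum nothing moves beyond the fine step
  st1 <- refine_against_average(st, vol)
  expect_lt(attr(st1, "mean_dpsi"), align_config()$fine_step_deg)
  expect_lt(attr(st1, "mean_dshift"), 0.25)
  ## perturbed by +/- 2 degrees: recovered within 0.3 degrees in one pass
  stp <- st
  stp$metadata$psi_deg <- (psi_t + c(2, -2, 2, -2, 2, -2)) %% 180
  st2 <- refine_against_average(stp, vol)
  expect_lt(max(abs(angle_err(st2$metadata$psi_deg, psi_t))), 0.3)
  ## idempotence: a second pass changes nothing material
  st3 <- refine_against_average(st2, vol)
  expect_lt(attr(st3, "mean_dpsi"), align_config()$fine_step_deg)
  expect_lt(attr(st3, "mean_dshift"), 0.25)
})

test_that("the leave-one-out refinement loop converges on simulated tubes", {
  sim <- simulate_tube_dataset(n_tubes = 8, image_size = 96,
                               pixel_size = 6.875, particle = NULL,
                               snr = 0.5, max_offset_px = 4, seed = 31)
  st <- align_stack(sim$stack, seed = 5)
  rl <- refine_loop(st, max_iter = 3, oversample = 1)
  tr <- sim$truth$segments
  err <- angle_err(rl$stack$metadata$psi_deg, tr$psi_true_deg)
  sh <- rl$stack$metadata$shift_x_px + tr$center_offset_px
  expect_lt(max(abs(err)), 0.8)
  expect_lt(max(abs(sh)), 1)
  expect_true(all(diff(rl$history$mean_dpsi) <= 0.5))
})
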