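test_that("psi estimation finds the tube angle and rejects pure noise", {
  prof <- tube_profile(); ps <- 6.875; n <- 96
  ## an already-vertical tube needs (almost) no rotation
  v <- render_tube_projection(prof, n, ps)
  e0 <- estimate_psi(v)
  expect_lt(abs(angle_err(e0$psi_deg, 0)), 0.3)
  ## a tilted noisy tube is recovered; exhaustive fine-grid oracle agrees
  img <- render_tube_projection(prof, n, ps, psi_deg = 37,
                                center_offset_px = 3)
  noisy <- add_noise(img, noise_sigma_for_snr(img, 0.2), seed = 3)
  e <- estimate_psi(noisy)
  expect_lt(abs(angle_err(e$psi_deg, 37)), 1.5)
  expect_gt(e$score, align_config()$score_floor)
  ## pure Gaussian noise: no tube detected
  set.seed(9)
  noise <- image2d(matrix(rnorm(n * n), n, n), ps)
  expect_error(estimate_psi(noise), "no tube")
})

test_that("psi estimation is equivariant under rotation of the input", {
  prof <- tube_profile(); ps <- 6.875; n <- 96
  img <- render_tube_projection(prof, n, ps, psi_deg = 20)
  base <- estimate_psi(img)$psi_deg
  for (delta in c(15, 50)) {
    ## rotating the content by -delta increases the required correction
    rot <- rotate_image(img$pixels, -delta, fill = mean(img$pixels))
    e <- estimate_psi(image2d(rot, ps))
    expect_lt(abs(angle_err(e$psi_deg, base + delta)), 1)
  }
})

test_that("edge finding centers the tube and flags degenerate inputs", {
  prof <- tube_profile(); ps <- 137.5 / 40; n <- 128  # outer radius 40 px
  img <- render_tube_projection(prof, n, ps)
  ed <- find_tube_edges(img)
  ## the detected edges are the outermost maxima of the profile; the
  ## analytic oracle is the outer-tangent peak of the Abel transform
  xs <- seq(33, 45, by = 0.01)
  P <- abel_transform(prof, xs * ps)
  peak <- xs[which.max(P)]
  c0 <- (n - 1) / 2
  expect_lt(abs(ed$right_px - c0 - peak), 1)
  expect_equal(ed$shift_x_px, 0, tolerance = 0.2)
  ## offset tube: symmetric-template matched filter midpoint oracle
  img7 <- render_tube_projection(prof, n, ps, center_offset_px = 7)
  ed7 <- find_tube_edges(img7)
  expect_equal(ed7$shift_x_px, -7, tolerance = 0.5)
  ## flat image fails
  expect_error(find_tube_edges(matrix(1, n, n)), "edge detection failed|flat")
})

test_that("random angle assignment has the documented distributions", {
  expect_equal(nrow(assign_random_angles(0, 1)), 0)
  a4 <- assign_random_angles(4, 2)
  expect_true(all(a4$phi_deg >= 0 & a4$phi_deg < 360))
  expect_true(all(a4$theta_deg %in% c(90, 270)))
  big <- assign_random_angles(10000, 3)
  chi <- stats::chisq.test(table(cut(big$phi_deg, seq(0, 360, by = 10))))
  expect_gt(chi$p.value, 0.01)
  expect_equal(mean(big$theta_deg == 90), 0.5, tolerance = 0.04)
  ## reproducible
  expect_identical(assign_random_angles(10, 5), assign_random_angles(10, 5))
})

test_that("align_stack recovers simulated geometry and is idempotent", {
  sim <- simulate_tube_dataset(n_tubes = 8, image_size = 96,
                               pixel_size = 6.875, particle = NULL,
                               snr = 1, max_offset_px = 4, seed = 21)
  st <- align_stack(sim$stack, seed = 4)
  tr <- sim$truth$segments
  expect_gte(sum(st$metadata$align_ok), 7)
  ok <- st$metadata$align_ok == 1
  expect_lt(max(abs(angle_err(st$metadata$psi_deg[ok],
                              tr$psi_true_deg[ok]))), 1.5)
  expect_lt(max(abs(st$metadata$shift_x_px[ok] +
                    tr$center_offset_px[ok])), 1.5)
  ## only phi/theta depend on the seed
  st2 <- align_stack(sim$stack, seed = 99)
  expect_identical(st$metadata$psi_deg, st2$metadata$psi_deg)
  expect_false(identical(st$metadata$phi_deg, st2$metadata$phi_deg))
  ## idempotence: aligning an already aligned (rotated + shifted) image
  ## returns psi ~ 0, shift ~ 0
  i <- which(ok)[1]
  al <- rastr:::aligned_segment(st, i)
  e <- estimate_psi(image2d(al, 6.875))
  ed <- find_tube_edges(al)
  expect_lt(abs(angle_err(e$psi_deg, 0)), 1)
  expect_lt(abs(ed$shift_x_px), 1)
  ## a stack of pure noise fails as a whole
  set.seed(1)
  noise_stack <- image_stack(array(rnorm(64 * 64 * 3), c(64, 64, 3)), 1)
  expect_error(align_stack(noise_stack, seed = 1), "no segment")
})

test_that("shift estimate is equivariant under perpendicular translation", {
  prof <- tube_profile(); ps <- 6.875; n <- 96
  base <- find_tube_edges(render_tube_projection(prof, n, ps))$shift_x_px
  for (t_px in c(3, -6)) {
    img <- render_tube_projection(prof, n, ps, center_offset_px = t_px)
    ed <- find_tube_edges(img)
    expect_equal(ed$shift_x_px - base, -t_px, tolerance = 0.5)
  }
})
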