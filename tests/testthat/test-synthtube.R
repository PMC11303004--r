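test_that("radial profile has the closed-form shell structure", {
  p <- tube_profile(outer_radius = 120, bilayer_separation = 40,
                    shell_sigma = 9, amplitude = 2)
  ## at the outer shell: A * (1 + exp(-sep^2 / 2 sigma^2))
  expect_equal(radial_profile(p, 120), 2 * (1 + exp(-40^2 / (2 * 81))))
  ## far away the density vanishes
  expect_lt(radial_profile(p, 400), 1e-12)
  ## integral of 2 pi r g(r) against a fine quadrature oracle
  r <- seq(0, 300, by = 0.01)
  byhand <- sum(2 * pi * r * radial_profile(p, r)) * 0.01
  f <- function(r) 2 * pi * r * radial_profile(p, r)
  quad <- stats::integrate(f, 0, 300, rel.tol = 1e-9)$value
  expect_equal(byhand, quad, tolerance = 1e-3)
})

test_that("tube projection matches a voxel ray-sum oracle and symmetries", {
  prof <- tube_profile()
  n <- 64; ps <- 6.875
  img <- render_tube_projection(prof, n, ps)
  ## vertical tube: every column of constant x is constant along y
  expect_lt(max(apply(img$pixels, 1, stats::sd)), 1e-10)
  ## symmetric about the center
  p <- rowMeans(img$pixels)
  expect_equal(p, rev(p), tolerance = 1e-6)
  ## psi = 90 is the transpose of psi = 0
  img90 <- render_tube_projection(prof, n, ps, psi_deg = 90)
  expect_equal(img90$pixels, t(img$pixels), tolerance = 1e-9)
  ## brute-force voxelized cylinder ray-sum oracle
  oracle <- raysum_tube_oracle(prof, n, ps, sub = 4)
  expect_gt(ncc(matrix(p), matrix(oracle)), 0.999)
  ## a tube wider than the field is rejected
  expect_error(render_tube_projection(prof, 32, 6.875), "fit")
})

test_that("abel transform and inversion are mutually consistent", {
  prof <- tube_profile()
  x <- seq(0, 200, by = 0.5)
  P <- abel_transform(prof, x)
  g <- abel_invert(P, x, seq(60, 160, by = 2))
  expect_equal(g, radial_profile(prof, seq(60, 160, by = 2)),
               tolerance = 0.01)
})

test_that("decorated segments place particles by the azimuth convention", {
  prof <- tube_profile()
  ps <- 6.875; n <- 96
  part <- gaussian_particle(pixel_size = ps)
  ## no particles reduces to the bare projection
  r0 <- render_decorated_segment(prof, part, NULL, n, ps)
  bare <- render_tube_projection(prof, n, ps)
  expect_equal(r0$image$pixels, bare$pixels)
  ## azimuth 0: particle projects onto the tube midline
  pl <- data.frame(axial_px = 0, azimuth_deg = 0, rot_deg = 0)
  r1 <- render_decorated_segment(prof, part, pl, n, ps)
  c0 <- (n - 1) / 2
  expect_equal(r1$truth$particles$local_x, c0, tolerance = 1e-9)
  ## azimuth 90: perpendicular offset (outer_radius + offset) / pixel_size
  pl2 <- data.frame(axial_px = 0, azimuth_deg = 90, rot_deg = 0)
  r2 <- render_decorated_segment(prof, part, pl2, n, ps)
  expect_equal(r2$truth$particles$perp_px,
               (prof$outer_radius + part$attachment_offset) / ps,
               tolerance = 1e-9)
  ## a particle beyond the field errors
  pl3 <- data.frame(axial_px = n, azimuth_deg = 90, rot_deg = 0)
  expect_error(render_decorated_segment(prof, part, pl3, n, ps), "outside")
  ## placements violating the axial spacing are rejected
  pl4 <- data.frame(axial_px = c(0, 3), azimuth_deg = c(0, 180),
                    rot_deg = c(0, 0))
  expect_error(render_decorated_segment(prof, part, pl4, n, ps), "spacing")
})

test_that("noise is seeded, additive and at the requested level", {
  img <- render_tube_projection(tube_profile(), 256, 6.875)
  expect_equal(add_noise(img, 0, seed = 1)$pixels, img$pixels)
  n1 <- add_noise(img, 3, seed = 7)
  n2 <- add_noise(img, 3, seed = 7)
  expect_identical(n1$pixels, n2$pixels)
  n3 <- add_noise(img, 3, seed = 8)
  expect_false(identical(n1$pixels, n3$pixels))
  expect_equal(stats::sd(n1$pixels - img$pixels), 3, tolerance = 0.02)
})

test_that("CTF keeps power bounded and has the expected first zero", {
  set.seed(5)
  img <- image2d(matrix(rnorm(128 * 128), 128, 128), 2)
  out <- apply_ctf(img, defocus_A = 15000, amplitude_contrast = 0)
  p_in <- sum((img$pixels - mean(img$pixels))^2)
  p_out <- sum((out$pixels - mean(out$pixels))^2)
  expect_lte(p_out, p_in * (1 + 1e-9))
  ## first zero at k = sqrt(1 / (lambda * dz)) (Cs term off)
  lambda <- electron_wavelength(300)
  k0 <- sqrt(1 / (lambda * 15000))
  ctf1d <- function(k) sin(pi * lambda * 15000 * k^2)
  root <- stats::uniroot(ctf1d, c(0.8 * k0, 1.2 * k0))$root
  expect_equal(root, k0, tolerance = 0.02)
})

test_that("the simulated dataset is reproducible and fully book-kept", {
  args <- list(n_tubes = 3, segments_per_tube = 2, segment_step_px = 40,
               image_size = 96, pixel_size = 6.875,
               particles_per_segment = 2, snr = 1, seed = 11)
  s1 <- do.call(simulate_tube_dataset, args)
  s2 <- do.call(simulate_tube_dataset, args)
  expect_identical(s1$stack$data, s2$stack$data)
  expect_identical(s1$truth$particles, s2$truth$particles)
  ## every visible particle references an existing particle and segment
  expect_true(all(s1$truth$visible$particle_id %in%
                  s1$truth$particles$particle_id))
  expect_true(all(s1$truth$visible$segment_id %in%
                  s1$truth$segments$segment_id))
  ## visible local coordinates are consistent with origins
  v <- merge(s1$truth$visible, s1$truth$particles, by = "particle_id")
  sg <- s1$truth$segments
  ori <- sg[match(v$segment_id, sg$segment_id), c("origin_x", "origin_y")]
  c0 <- (96 - 1) / 2
  expect_equal(v$local_x, v$global_x - ori$origin_x + c0, tolerance = 1e-9)
  ## overlapping windows of one tube share their pixels exactly
  md <- s1$stack$metadata
  a <- which(md$micrograph_id == 1)[1:2]
  d1 <- s1$stack$data[, , a[1]]; d2 <- s1$stack$data[, , a[2]]
  sh <- round(md$origin_x[a[2]] - md$origin_x[a[1]])
  shy <- round(md$origin_y[a[2]] - md$origin_y[a[1]])
  ov1 <- d1[max(1, 1 + sh):min(96, 96 + sh),
            max(1, 1 + shy):min(96, 96 + shy)]
  ov2 <- d2[max(1, 1 - sh):min(96, 96 - sh),
            max(1, 1 - shy):min(96, 96 - shy)]
  expect_identical(ov1, ov2)
})
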