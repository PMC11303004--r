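## Shared fixtures and small oracles for the test suite. Everything is
## generated in code; no binary fixtures.

## angular difference modulo 180 (tube axes are unsigned)
angle_err <- function(est, truth) (est - truth + 90) %% 180 - 90

## a small tube model whose 40-pixel outer radius fits a 96-128 box at the
## default pixel size of the simulator geometry used in tests
test_profile <- function() tube_profile()

## noiseless aligned stack of identical vertical tube views with uniformly
## spaced phi, for reconstruction tests
phi_series_stack <- function(n = 64, pixel_size = 6.875, n_views = 36,
                             profile = tube_profile()) {
  img <- render_tube_projection(profile, n, pixel_size)
  md <- data.frame(segment_id = seq_len(n_views), psi_deg = 0,
                   theta_deg = 90,
                   phi_deg = seq(0, 360, length.out = n_views + 1)[1:n_views],
                   shift_x_px = 0, shift_y_px = 0, align_ok = 1)
  image_stack(array(rep(img$pixels, n_views), c(n, n, n_views)),
              pixel_size, md)
}

## analytic body of revolution of a tube profile on a cubic grid
analytic_tube_volume <- function(n = 64, pixel_size = 6.875,
                                 profile = tube_profile()) {
  g <- (0:(n - 1)) - (n - 1) / 2
  r_xy <- sqrt(outer(g^2, g^2, "+")) * pixel_size
  volume3d(array(radial_profile(profile, r_xy), c(n, n, n)), pixel_size)
}

## brute-force voxel ray-sum projection of a radial density (oracle for the
## analytic Abel renderer): voxelize g on a fine 3D grid and sum along one
## axis
raysum_tube_oracle <- function(profile, n, pixel_size, sub = 2) {
  nf <- n * sub
  g <- ((0:(nf - 1)) + 0.5) / sub - 0.5 - (n - 1) / 2   # fine pixel centers
  r <- sqrt(outer(g^2, g^2, "+")) * pixel_size
  dens <- radial_profile(profile, r)
  ## integrate along the second fine axis (depth), in Angstrom
  P_fine <- rowSums(dens) * pixel_size / sub
  ## average fine samples back to pixel resolution
  colMeans(matrix(P_fine, sub, n))
}
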