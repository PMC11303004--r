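## Synthetic decorated-tube simulator: analytic bilayer-tube model, Abel
## projection, particle decoration, noise and CTF. Provides ground truth for
## every downstream stage.

#' Bilayer tube density model
#'
#' The tube is modelled as a body of revolution whose radial density is the
#' sum of two Gaussian shells (the two leaflets of the lipid bilayer).
#'
#' @param outer_radius outer shell radius in Angstrom. Default 137.5 A
#'   (27.5 nm tube width, the middle of the 25-30 nm range typical of
#'   galactosylceramide nanotubes).
#' @param bilayer_separation distance between the two shells in Angstrom
#'   (default 37 A, a typical headgroup-to-headgroup distance).
#' @param shell_sigma Gaussian sigma of each shell in Angstrom (default 8 A).
#' @param amplitude shell peak density (arbitrary units, default 1).
#' @return object of class `tube_profile`.
#' @export
tube_profile <- function(outer_radius = 137.5, bilayer_separation = 37,
                         shell_sigma = 8, amplitude = 1) {
  stopifnot(outer_radius > bilayer_separation, bilayer_separation > 0,
            shell_sigma > 0)
  structure(list(outer_radius = outer_radius,
                 bilayer_separation = bilayer_separation,
                 shell_sigma = shell_sigma, amplitude = amplitude),
            class = "tube_profile")
}

#' Radial density of a bilayer tube
#'
#' `g(r) = A (exp(-(r - r_out)^2 / 2 s^2) + exp(-(r - r_in)^2 / 2 s^2))`
#' with `r_in = r_out - bilayer_separation`.
#'
#' @param profile a [tube_profile()].
#' @param r radii in Angstrom (>= 0).
#' @return densities at `r`.
#' @export
radial_profile <- function(profile, r) {
  stopifnot(all(r >= 0))
  r_out <- profile$outer_radius
  r_in <- r_out - profile$bilayer_separation
  s2 <- 2 * profile$shell_sigma^2
  profile$amplitude * (exp(-(r - r_out)^2 / s2) + exp(-(r - r_in)^2 / s2))
}

#' Abel transform of a radial density
#'
#' Line-integral projection of a radially symmetric density:
#' `P(x) = 2 * integral_0^Inf g(sqrt(x^2 + s^2)) ds`. This is the intensity
#' profile perpendicular to the axis of a projected tube.
#'
#' @param g function of radius (Angstrom) returning density, or a
#'   [tube_profile()].
#' @param x perpendicular distances in Angstrom.
#' @param r_max integration limit (Angstrom); beyond it `g` is assumed 0.
#' @param ds integration step (Angstrom).
#' @return `P(x)`.
#' @export
abel_transform <- function(g, x, r_max, ds = NULL) {
  if (inherits(g, "tube_profile")) {
    prof <- g
    if (missing(r_max)) r_max <- prof$outer_radius + 6 * prof$shell_sigma
    if (is.null(ds)) ds <- prof$shell_sigma / 5
    g <- function(r) radial_profile(prof, r)
  }
  if (is.null(ds)) ds <- r_max / 2000
  s <- seq(0, r_max, by = ds)
  ## trapezoid in s, vectorized over x
  vapply(x, function(xi) {
    vals <- g(sqrt(xi^2 + s^2))
    2 * (sum(vals) - 0.5 * (vals[1] + vals[length(vals)])) * ds
  }, numeric(1))
}

#' Inverse Abel transform of a sampled projection profile
#'
#' Recovers the radial density `g(r)` from a projection profile `P(x)`
#' sampled on an increasing grid `x >= 0`, using the classical inversion
#' `g(r) = -(1/pi) integral_r^Inf P'(x) dx / sqrt(x^2 - r^2)` with `P`
#' treated as piecewise linear (the integral over each linear piece has a
#' closed form, which keeps the endpoint singularity exact).
#'
#' @param P projection values at `x`.
#' @param x sample positions (Angstrom or pixels, increasing, `x[1] >= 0`).
#' @param r radii at which to evaluate `g` (same units).
#' @return `g(r)`.
#' @export
abel_invert <- function(P, x, r) {
  stopifnot(length(P) == length(x), !is.unsorted(x), x[1] >= 0)
  slopes <- diff(P) / diff(x)
  xj <- x[-length(x)]; xj1 <- x[-1]
  vapply(r, function(ri) {
    use <- xj1 > ri
    if (!any(use)) return(0)
    a <- pmax(xj[use], ri); b <- xj1[use]
    f <- function(t) log(t + sqrt(pmax(t^2 - ri^2, 0)))
    -(1 / pi) * sum(slopes[use] * (f(b) - f(a)))
  }, numeric(1))
}

## Fine 1D lookup of the tube projection profile, in pixels.
tube_projection_lut <- function(profile, pixel_size, half_width_px,
                                oversample = 4) {
  xs <- seq(0, half_width_px, by = 1 / oversample) * pixel_size
  P <- abel_transform(profile, xs)
  list(x_px = xs / pixel_size, P = P)
}

#' Render a noiseless projected tube image
#'
#' Analytic projection of the tube model: the intensity at perpendicular
#' distance `d` from the tube axis is the Abel transform of the radial
#' density. The tube axis passes at `center_offset_px` pixels from the image
#' center (along the axis normal) and makes angle `psi_deg` with the image y
#' axis (rotating the image by `+psi_deg` would make it vertical).
#'
#' @param profile a [tube_profile()].
#' @param image_size image side in pixels (square).
#' @param pixel_size Angstrom/pixel.
#' @param psi_deg in-plane tube angle in degrees.
#' @param center_offset_px perpendicular offset of the axis from the image
#'   center, in pixels.
#' @return an [image2d()].
#' @export
render_tube_projection <- function(profile, image_size, pixel_size,
                                   psi_deg = 0, center_offset_px = 0) {
  n <- image_size
  stopifnot(abs(center_offset_px) < n / 2)
  half_A <- profile$outer_radius + 3 * profile$shell_sigma
  if (2 * half_A / pixel_size > n)
    stop("tube (", round(2 * half_A), " A wide) does not fit in a ", n,
         "-pixel field at ", pixel_size, " A/px")
  lut <- tube_projection_lut(profile, pixel_size, half_width_px = n)
  cx <- grid_center(n); cy <- grid_center(n)
  a <- psi_deg * pi / 180
  nxv <- cos(a); nyv <- -sin(a)     # axis normal for axis direction (sin a, cos a)
  gx <- rep(0:(n - 1), times = n) - cx
  gy <- rep(0:(n - 1), each = n) - cy
  d <- abs(nxv * gx + nyv * gy - center_offset_px)
  vals <- stats::approx(lut$x_px, lut$P, xout = d, rule = 2)$y
  image2d(matrix(vals, n, n), pixel_size)
}

#' Globular particle model
#'
#' A 3D Gaussian blob standing in for a globular protein (e.g. a ~520 kDa
#' tetramer of ~170 A diameter), held off the tube surface by a short linker.
#'
#' @param radius_A particle radius in Angstrom (blob sigma = radius / 2).
#' @param pixel_size grid spacing (must match the segment images).
#' @param amplitude peak density; the default 1.35 reflects the typical
#'   protein:lipid density ratio relative to the unit-amplitude bilayer
#'   shells.
#' @param attachment_offset_A gap between tube outer radius and particle
#'   center... the particle center sits at tube radius + this offset.
#' @return object of class `particle_model`: list with `density`
#'   ([volume3d()]) and `attachment_offset`.
#' @export
gaussian_particle <- function(radius_A = 85, pixel_size = 6.875,
                              amplitude = 1.35, attachment_offset_A = 20) {
  sigma_px <- radius_A / 2 / pixel_size
  n <- 2 * ceiling(radius_A / pixel_size) + 5    # >= 2-voxel margin
  c0 <- grid_center(n)
  g <- (0:(n - 1)) - c0
  r2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  vox <- amplitude * exp(-r2 / (2 * sigma_px^2))
  structure(list(density = volume3d(vox, pixel_size),
                 attachment_offset = attachment_offset_A,
                 radius_A = radius_A),
            class = "particle_model")
}

#' Two-lobe asymmetric test particle
#'
#' Two unequal Gaussian lobes; its distinct projected views are used to
#' exercise 2D classification.
#'
#' @inheritParams gaussian_particle
#' @param lobe_sep_A center-to-center lobe separation.
#' @export
two_lobe_particle <- function(radius_A = 70, pixel_size = 6.875,
                              amplitude = 1, attachment_offset_A = 20,
                              lobe_sep_A = 60) {
  sigma_px <- radius_A / 3 / pixel_size
  n <- 2 * ceiling((radius_A + lobe_sep_A / 2) / pixel_size) + 5
  c0 <- grid_center(n)
  g <- (0:(n - 1)) - c0
  d <- lobe_sep_A / 2 / pixel_size
  blob <- function(cx, cy, cz, amp, s) {
    r2 <- outer(outer((g - cx)^2, (g - cy)^2, "+"), (g - cz)^2, "+")
    amp * exp(-r2 / (2 * s^2))
  }
  vox <- blob(-d, 0, 0, amplitude, sigma_px) +
         blob(d, 0, 0, 0.6 * amplitude, 0.7 * sigma_px)
  structure(list(density = volume3d(vox, pixel_size),
                 attachment_offset = attachment_offset_A,
                 radius_A = radius_A),
            class = "particle_model")
}

## z-projection of a particle model (integrated in Angstrom, like the
## analytic tube projection), rotated in-plane by rot_deg.
particle_projection <- function(particle, rot_deg = 0) {
  p2 <- apply(particle$density$voxels, c(1, 2), sum) *
    particle$density$voxel_size
  if (rot_deg %% 360 != 0) p2 <- rotate_image(p2, rot_deg)
  p2
}

## Add `patch` into `img` centered at fractional 0-based position (cx, cy).
## Errors if the patch footprint leaves the field.
add_patch <- function(img, patch, cx, cy) {
  np <- nrow(patch); n1 <- nrow(img); n2 <- ncol(img)
  pc <- grid_center(np)
  x0 <- cx - pc; y0 <- cy - pc            # 0-based position of patch[1,1]
  ix0 <- floor(x0); iy0 <- floor(y0)
  fx <- x0 - ix0; fy <- y0 - iy0
  if (ix0 < 0 || iy0 < 0 || ix0 + np + 1 > n1 || iy0 + np + 1 > n2)
    stop("particle projects outside the field (center ", round(cx, 1), ",",
         round(cy, 1), ")")
  ## bilinear splat of the patch at the fractional offset
  pp <- matrix(0, np + 1, np + 1)
  pp[1:np, 1:np] <- pp[1:np, 1:np] + patch * (1 - fx) * (1 - fy)
  pp[2:(np + 1), 1:np] <- pp[2:(np + 1), 1:np] + patch * fx * (1 - fy)
  pp[1:np, 2:(np + 1)] <- pp[1:np, 2:(np + 1)] + patch * (1 - fx) * fy
  pp[2:(np + 1), 2:(np + 1)] <- pp[2:(np + 1), 2:(np + 1)] + patch * fx * fy
  xs <- (ix0 + 1):(ix0 + np + 1); ys <- (iy0 + 1):(iy0 + np + 1)
  img[xs, ys] <- img[xs, ys] + pp
  img
}

#' Render a decorated tube segment with ground truth
#'
#' Draws the analytic tube projection and adds the projected particle
#' densities. Azimuth convention: 0 degrees faces the viewer (the particle
#' projects onto the tube midline), 90 degrees points toward +x after the
#' psi rotation, so the projected perpendicular offset is
#' `(outer_radius + attachment_offset) * sin(azimuth) / pixel_size` pixels.
#'
#' @param profile a [tube_profile()].
#' @param particle a `particle_model` (or NULL for a bare tube).
#' @param placements data frame with columns `axial_px` (position along the
#'   axis relative to the segment center, pixels), `azimuth_deg`, `rot_deg`
#'   (in-plane particle rotation). May have zero rows.
#' @param image_size,pixel_size image geometry.
#' @param psi_deg,center_offset_px tube pose (see
#'   [render_tube_projection()]).
#' @param min_axial_spacing_px placements closer than this along the axis are
#'   rejected (default: particle diameter in pixels).
#' @return list with `image` ([image2d()]) and `truth` (a `tube_ground_truth`
#'   list: psi, offset, per-particle placements incl. projected local
#'   positions).
#' @export
render_decorated_segment <- function(profile, particle, placements,
                                     image_size, pixel_size,
                                     psi_deg = 0, center_offset_px = 0,
                                     min_axial_spacing_px = NULL) {
  img <- render_tube_projection(profile, image_size, pixel_size,
                                psi_deg, center_offset_px)
  px <- img$pixels
  np <- if (is.null(placements)) 0 else nrow(placements)
  truth <- list(psi_true_deg = psi_deg, center_offset_px = center_offset_px,
                particles = placements, noise_sigma = 0, seed = NA)
  if (np > 0) {
    if (is.null(min_axial_spacing_px))
      min_axial_spacing_px <- 2 * particle$radius_A / pixel_size
    ax <- sort(placements$axial_px)
    if (np > 1 && min(diff(ax)) < min_axial_spacing_px)
      stop("particle placements violate the minimum axial spacing (",
           round(min_axial_spacing_px, 1), " px)")
    stopifnot(abs(particle$density$voxel_size - pixel_size) < 1e-9)
    r_dec <- (profile$outer_radius + particle$attachment_offset) / pixel_size
    a <- psi_deg * pi / 180
    u <- c(sin(a), cos(a))      # axis direction
    nv <- c(cos(a), -sin(a))    # axis normal
    c0 <- grid_center(image_size)
    lx <- ly <- perp <- numeric(np)
    for (i in seq_len(np)) {
      perp[i] <- r_dec * sin(placements$azimuth_deg[i] * pi / 180)
      pos <- c(c0, c0) + u * placements$axial_px[i] +
        nv * (perp[i] + center_offset_px)
      lx[i] <- pos[1]; ly[i] <- pos[2]
      proj <- particle_projection(particle, placements$rot_deg[i])
      px <- add_patch(px, proj, pos[1], pos[2])
    }
    truth$particles <- cbind(placements, perp_px = perp,
                             local_x = lx, local_y = ly)
  }
  list(image = image2d(px, pixel_size), truth = structure(truth,
       class = "tube_ground_truth"))
}

#' Additive white Gaussian noise
#'
#' @param img an [image2d()] (or matrix).
#' @param sigma noise standard deviation (same units as the image).
#' @param seed RNG seed; the result is bit-identical for identical inputs
#'   and seed.
#' @return noisy [image2d()].
#' @export
add_noise <- function(img, sigma, seed) {
  stopifnot(sigma >= 0)
  img <- as_image2d(img)
  if (sigma == 0) return(img)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- dim(img$pixels)
  image2d(img$pixels + matrix(stats::rnorm(prod(d), 0, sigma), d[1], d[2]),
          img$pixel_size)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Noise sigma giving a target signal-to-noise ratio
#'
#' SNR is defined as signal variance over noise variance.
#'
#' @param pixels noiseless image (matrix or [image2d()]).
#' @param snr target SNR (> 0; `Inf` gives 0).
#' @export
noise_sigma_for_snr <- function(pixels, snr) {
  if (inherits(pixels, "image2d")) pixels <- pixels$pixels
  if (is.infinite(snr)) return(0)
  stats::sd(pixels) / sqrt(snr)
}

#' Electron wavelength in Angstrom
#' @param voltage_kV accelerating voltage in kV.
#' @export
electron_wavelength <- function(voltage_kV) {
  v <- voltage_kV * 1000
  12.2643 / sqrt(v * (1 + 0.978466e-6 * v))
}

#' Apply a contrast transfer function to an image
#'
#' Multiplies the image Fourier transform by the standard weak-phase CTF
#' `C(k) = sqrt(1 - A^2) sin(chi) + A cos(chi)` with
#' `chi(k) = pi lambda dz k^2 - (pi/2) Cs lambda^3 k^4`. The zero-frequency
#' term is scaled by the amplitude contrast `A`, and `|C| <= 1` everywhere.
#'
#' @param img an [image2d()].
#' @param defocus_A defocus in Angstrom (> 0 = underfocus).
#' @param voltage_kV accelerating voltage (default 300).
#' @param amplitude_contrast fraction `A` in `[0, 1)` (default 0.07).
#' @param cs_mm spherical aberration in mm (default 2.7).
#' @return CTF-modulated [image2d()].
#' @export
apply_ctf <- function(img, defocus_A, voltage_kV = 300,
                      amplitude_contrast = 0.07, cs_mm = 2.7) {
  stopifnot(defocus_A > 0)
  img <- as_image2d(img)
  n <- nrow(img$pixels)
  lambda <- electron_wavelength(voltage_kV)
  cs <- cs_mm * 1e7
  k <- fft_freqs(n) / (n * img$pixel_size)      # cycles / Angstrom
  k2 <- outer(k^2, k^2, "+")
  chi <- pi * lambda * defocus_A * k2 - (pi / 2) * cs * lambda^3 * k2^2
  A <- amplitude_contrast
  ctf <- sqrt(1 - A^2) * sin(chi) + A * cos(chi)
  out <- Re(stats::fft(stats::fft(img$pixels) * ctf, inverse = TRUE)) / n^2
  image2d(out, img$pixel_size)
}

#' Simulate a full decorated-tube dataset with ground truth
#'
#' Generates `n_tubes` straight tubes, each windowed into
#' `segments_per_tube` (possibly overlapping) square segments, decorated
#' sparsely with copies of one particle model at random axial/azimuthal
#' positions, with additive Gaussian noise at a target SNR. Every stage
#' downstream of the simulator can be validated against the returned ground
#' truth.
#'
#' @param n_tubes number of tubes (one micrograph each).
#' @param segments_per_tube overlapping segments windowed along each tube.
#' @param segment_step_px axial distance between consecutive segment centers
#'   (default half the box, i.e. 50% overlap).
#' @param image_size segment box side in pixels.
#' @param pixel_size Angstrom/pixel.
#' @param profile tube model ([tube_profile()]).
#' @param particle particle model or NULL for bare tubes.
#' @param particles_per_segment mean number of particles per box length.
#' @param snr signal-to-noise ratio (variance ratio); `Inf` for noiseless.
#' @param max_offset_px tube axis offset from box center drawn uniformly in
#'   `[-max_offset_px, max_offset_px]`.
#' @param with_ctf if TRUE each segment gets a random defocus in
#'   `defocus_range_A` and CTF modulation.
#' @param defocus_range_A defocus range for `with_ctf`.
#' @param seed RNG seed (dataset is reproducible bit-for-bit).
#' @return list with `stack` (an [image_stack()] whose metadata has
#'   segment_id, micrograph_id, origin_x/origin_y) and `truth` (segments,
#'   particles with global coordinates, per-segment visible placements).
#' @export
simulate_tube_dataset <- function(n_tubes = 50, segments_per_tube = 1,
                                  segment_step_px = NULL,
                                  image_size = 96, pixel_size = 6.875,
                                  profile = tube_profile(),
                                  particle = gaussian_particle(pixel_size = pixel_size),
                                  particles_per_segment = 4,
                                  snr = 0.3, max_offset_px = 5,
                                  with_ctf = FALSE,
                                  defocus_range_A = c(10000, 25000),
                                  seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(segment_step_px)) segment_step_px <- image_size / 2
  n <- image_size
  part_half <- if (is.null(particle)) 0 else
    (nrow(particle$density$voxels) + 2) / 2
  imgs <- vector("list", n_tubes * segments_per_tube)
  meta <- list(); seg_truth <- list(); part_truth <- list(); vis <- list()
  sigma <- NA
  seg_i <- 0; part_id <- 0
  c0 <- grid_center(n)
  for (t in seq_len(n_tubes)) {
    psi_t <- stats::runif(1, 0, 180)
    off_t <- stats::runif(1, -max_offset_px, max_offset_px)
    a <- psi_t * pi / 180
    u <- c(sin(a), cos(a)); nv <- c(cos(a), -sin(a))
    span <- (segments_per_tube - 1) * segment_step_px
    centers <- seq(-span / 2, span / 2, length.out = segments_per_tube)
    ## one micrograph per tube: overlapping segments are integer-pixel
    ## crops of the same rendered field, so they share their noise exactly
    ## as overlapping windows of a real micrograph do
    nm <- 2 * ceiling((n + span + 2 * max_offset_px + 4) / 2)
    mc0 <- grid_center(nm)
    ## particles on a jittered axial grid along the covered tube length
    L <- span + n
    min_sp <- if (is.null(particle)) n else 2 * particle$radius_A / pixel_size
    n_slots <- max(0, floor(particles_per_segment * L / n))
    parts <- NULL
    if (!is.null(particle) && n_slots > 0) {
      ## place slots inside the axial range whose particles fit in a window
      L_eff <- L - 2 * part_half
      slot_w <- L_eff / n_slots
      ax <- -L_eff / 2 + (seq_len(n_slots) - 0.5) * slot_w +
        stats::runif(n_slots, -1, 1) * pmax(0, (slot_w - min_sp) / 2) * 0.9
      parts <- data.frame(
        particle_id = part_id + seq_len(n_slots),
        axial_px = ax,
        azimuth_deg = stats::runif(n_slots, 0, 360),
        rot_deg = stats::runif(n_slots, 0, 360))
      part_id <- part_id + n_slots
      r_dec <- (profile$outer_radius + particle$attachment_offset) / pixel_size
      parts$perp_px <- r_dec * sin(parts$azimuth_deg * pi / 180)
      ## global coordinates = 0-based micrograph pixels; the tube axis runs
      ## through the micrograph center
      parts$global_x <- mc0 + u[1] * parts$axial_px + nv[1] * parts$perp_px
      parts$global_y <- mc0 + u[2] * parts$axial_px + nv[2] * parts$perp_px
      parts$micrograph_id <- t
      part_truth[[t]] <- parts
    }
    pl_mic <- if (!is.null(parts))
      data.frame(axial_px = parts$axial_px,
                 azimuth_deg = parts$azimuth_deg,
                 rot_deg = parts$rot_deg) else NULL
    rend <- render_decorated_segment(profile, particle, pl_mic, nm,
                                     pixel_size, psi_deg = psi_t,
                                     center_offset_px = 0,
                                     min_axial_spacing_px = 0)
    mic <- rend$image
    defocus <- if (with_ctf)
      stats::runif(1, defocus_range_A[1], defocus_range_A[2])
    else NA_real_
    if (with_ctf) mic <- apply_ctf(mic, defocus)
    if (is.na(sigma)) {
      ## calibrate the noise level once, on a bare segment-sized field
      refimg <- render_tube_projection(profile, n, pixel_size, psi_t, off_t)
      sigma <- noise_sigma_for_snr(refimg, snr)
    }
    mic <- add_noise(mic, sigma, seed = seed + 7919 * t)
    for (s in seq_len(segments_per_tube)) {
      seg_i <- seg_i + 1
      cs_ax <- centers[s]
      ## integer crop start so the window is an exact pixel subset
      ctr_f <- c(mc0, mc0) + u * cs_ax - nv * off_t
      start <- round(ctr_f - c0)                 # 0-based crop start
      start <- pmin(pmax(start, 0), nm - n)
      ctr_real <- start + c0                     # realized window center
      ## realized perpendicular tube offset of this window
      off_s <- sum(nv * (c(mc0, mc0) - ctr_real))
      imgs[[seg_i]] <- mic$pixels[start[1] + 1:n, start[2] + 1:n]
      origin <- ctr_real
      pl <- NULL
      if (!is.null(parts) && nrow(parts) > 0) {
        loc_x <- parts$global_x - origin[1] + c0
        loc_y <- parts$global_y - origin[2] + c0
        lim <- n / 2 - part_half
        keep <- abs(loc_x - c0) < lim & abs(loc_y - c0) < lim
        if (any(keep))
          pl <- data.frame(particle_id = parts$particle_id[keep],
                           local_x = loc_x[keep], local_y = loc_y[keep])
      }
      meta[[seg_i]] <- data.frame(
        segment_id = seg_i, micrograph_id = t,
        origin_x = origin[1], origin_y = origin[2],
        defocus_A = defocus)
      seg_truth[[seg_i]] <- data.frame(
        segment_id = seg_i, micrograph_id = t, psi_true_deg = psi_t,
        center_offset_px = off_s, axial_center_px = cs_ax,
        origin_x = origin[1], origin_y = origin[2], noise_sigma = sigma)
      if (!is.null(pl) && nrow(pl) > 0) {
        vis[[seg_i]] <- data.frame(segment_id = seg_i,
                                   particle_id = pl$particle_id,
                                   local_x = pl$local_x, local_y = pl$local_y)
      }
    }
  }
  stack <- image_stack(simplify2array(imgs), pixel_size,
                       metadata = do.call(rbind, meta))
  truth <- list(segments = do.call(rbind, seg_truth),
                particles = if (length(part_truth))
                  do.call(rbind, part_truth) else NULL,
                visible = if (length(vis)) do.call(rbind, vis) else NULL,
                noise_sigma = sigma, seed = seed,
                profile = profile, particle = particle,
                image_size = n, pixel_size = pixel_size)
  list(stack = stack, truth = truth)
}

#' Score picks against simulator ground truth
#'
#' Greedy matching (picks in descending score order) of pick global
#' coordinates to true particle positions within `tol_px`; each true
#' particle can be matched once.
#'
#' @param picks data frame with micrograph_id, global_x, global_y, score.
#' @param truth the `truth` element of [simulate_tube_dataset()].
#' @param tol_px match radius in pixels.
#' @return list with `recall`, `precision`, `n_true`, `n_picks`,
#'   `n_matched`, `match_dist_px` (distances of matched picks).
#' @export
match_picks_to_truth <- function(picks, truth, tol_px = 2) {
  tp <- truth$particles
  ## only particles that actually appear in at least one segment count
  if (!is.null(tp) && !is.null(truth$visible))
    tp <- tp[tp$particle_id %in% truth$visible$particle_id, , drop = FALSE]
  if (is.null(tp) || nrow(tp) == 0)
    return(list(recall = NA, precision = if (nrow(picks)) 0 else NA,
                n_true = 0, n_picks = nrow(picks), n_matched = 0,
                match_dist_px = numeric(0)))
  matched_true <- rep(FALSE, nrow(tp))
  matched_pick <- rep(FALSE, nrow(picks))
  dists <- numeric(0)
  if (nrow(picks) > 0) {
    ord <- order(-picks$score)
    for (i in ord) {
      cand <- which(tp$micrograph_id == picks$micrograph_id[i] & !matched_true)
      if (!length(cand)) next
      d <- sqrt((tp$global_x[cand] - picks$global_x[i])^2 +
                (tp$global_y[cand] - picks$global_y[i])^2)
      j <- which.min(d)
      if (d[j] <= tol_px) {
        matched_true[cand[j]] <- TRUE
        matched_pick[i] <- TRUE
        dists <- c(dists, d[j])
      }
    }
  }
  list(recall = mean(matched_true),
       precision = if (nrow(picks)) mean(matched_pick) else NA,
       n_true = nrow(tp), n_picks = nrow(picks),
       n_matched = sum(matched_true), match_dist_px = dists)
}
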