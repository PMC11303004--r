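## Azimuthal average: direct Fourier (central-slice) reconstruction from
## aligned segments, z smoothing, cylindricity QC, re-projection and
## reference-based refinement.

#' Reconstruct the azimuthal average volume
#'
#' Direct Fourier inversion: every segment image is shift-corrected (phase
#' ramp), its 2D Fourier transform is inserted as the central slice at the
#' segment's Euler orientation (trilinear spreading with per-voxel weight
#' accumulation), and the accumulated transform is normalized by the weights
#' (Wiener constant `eps * max(weight)`) before inverse transformation.
#' With randomized phi the result is the azimuthal average of the tube.
#'
#' @param stack aligned [image_stack()] (`psi_deg`, `theta_deg`, `phi_deg`,
#'   `shift_x_px`, `shift_y_px` present; rows with `align_ok == 0` are
#'   skipped).
#' @param size volume side in voxels (default: the segment box size).
#' @param eps Wiener constant as a fraction of the maximum weight
#'   (default 0.001).
#' @param oversample Fourier oversampling factor (2 = insert into a grid of
#'   twice-finer frequency spacing, which suppresses gridding interpolation
#'   artifacts; 1 is faster and coarser).
#' @return object of class `az_average` (a [volume3d()] with a `provenance`
#'   element: `n_segments`, `iteration`).
#' @export
reconstruct_average <- function(stack, size = NULL, eps = 0.001,
                                oversample = 2) {
  md <- stack$metadata
  need <- c("psi_deg", "theta_deg", "phi_deg", "shift_x_px", "shift_y_px")
  if (!all(need %in% names(md)))
    stop("reconstruct_average: stack is missing alignment columns")
  use <- if ("align_ok" %in% names(md)) which(md$align_ok == 1)
         else seq_len(n_images(stack))
  if (length(use) == 0) stop("reconstruct_average: no aligned segments")
  if (anyNA(md[use, need])) stop("reconstruct_average: missing angles")
  n <- dim(stack$data)[1]
  if (is.null(size)) size <- n
  if (size != n)
    stop("reconstruct_average: volume size must equal the box size (", n, ")")
  if (!is.null(attr(stack, "tube_width_px")) &&
      size < attr(stack, "tube_width_px"))
    stop("reconstruct_average: volume smaller than the tube diameter")
  stopifnot(oversample >= 1)
  no <- 2 * ceiling(oversample * n / 2)   # oversampled (even) grid side
  kx <- fft_freqs(no); c0 <- grid_center(n)
  k2x <- rep(kx, times = no); k2y <- rep(kx, each = no)
  F3 <- array(0 + 0i, c(no, no, no)); W <- array(0, c(no, no, no))
  half <- no / 2
  pad <- matrix(0, no, no)
  for (i in use) {
    pad[1:n, 1:n] <- stack$data[, , i]
    f <- stats::fft(pad)
    ## center the object: undo the recorded shift (converted to the image
    ## frame), move center to origin
    t2 <- shift_to_image_frame(md$psi_deg[i], md$shift_x_px[i],
                               md$shift_y_px[i])
    phase <- exp(-2i * pi * (k2x * (t2[1] - c0) +
                             k2y * (t2[2] - c0)) / no)
    v <- as.vector(f) * phase
    A <- euler_matrix(md$phi_deg[i], md$theta_deg[i], md$psi_deg[i])
    K <- t(A) %*% rbind(k2x, k2y, 0)
    inside <- abs(K[1, ]) <= half - 1 & abs(K[2, ]) <= half - 1 &
              abs(K[3, ]) <= half - 1
    Ki <- K[, inside, drop = FALSE]; vi <- v[inside]
    x0 <- floor(Ki[1, ]); y0 <- floor(Ki[2, ]); z0 <- floor(Ki[3, ])
    fx <- Ki[1, ] - x0; fy <- Ki[2, ] - y0; fz <- Ki[3, ] - z0
    vre <- Re(vi); vim <- Im(vi)
    for (corner in 0:7) {
      dx <- corner %% 2; dy <- (corner %/% 2) %% 2; dz <- corner %/% 4
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
           (if (dz) fz else 1 - fz)
      ix <- (x0 + dx) %% no; iy <- (y0 + dy) %% no; iz <- (z0 + dz) %% no
      lin <- 1 + ix + iy * no + iz * no * no
      ## order + run-length aggregation (duplicate-safe, no name coercion)
      o <- order(lin); ls <- lin[o]
      ends <- which(c(ls[-1] != ls[-length(ls)], TRUE))
      at <- ls[ends]
      agg <- function(v) diff(c(0, cumsum(v[o])[ends]))
      F3[at] <- F3[at] + complex(real = agg(w * vre),
                                 imaginary = agg(w * vim))
      W[at] <- W[at] + agg(w)
    }
  }
  F3 <- F3 / pmax(W, eps * max(W))
  ## move the object center to 0-based c0, then crop the original box
  pc <- exp(-2i * pi * kx * c0 / no)
  F3 <- F3 * as.vector(outer(outer(pc, pc), pc))
  vol_os <- Re(stats::fft(F3, inverse = TRUE)) / no^3
  vol <- vol_os[1:n, 1:n, 1:n]
  ## roll-off correction: undo the real-space apodization of the trilinear
  ## gridding kernel (FT of a unit triangle = sinc^2)
  sinc2 <- function(x) ifelse(x == 0, 1, (sin(pi * x) / (pi * x))^2)
  ro <- 1 / sinc2(((0:(n - 1)) - c0) / no)
  vol <- vol * as.vector(outer(outer(ro, ro), ro))
  structure(c(volume3d(vol, stack$pixel_size),
              list(provenance = list(n_segments = length(use),
                                     iteration = 1L))),
            class = c("az_average", "volume3d"))
}

#' Smooth the azimuthal average along the tube axis
#'
#' The mean z slice over the central `z_fraction` of slices replaces every
#' slice, making the volume exactly z-invariant (a straight tube is
#' translationally invariant along its axis; the edge slices, affected by
#' wrap-around, are excluded from the mean).
#'
#' @param avg an `az_average` (or [volume3d()]).
#' @param z_fraction fraction of central slices averaged (default 0.8).
#' @return z-invariant volume of the same class.
#' @export
smooth_z <- function(avg, z_fraction = 0.8) {
  stopifnot(z_fraction > 0, z_fraction <= 1)
  v <- avg$voxels
  nz <- dim(v)[3]
  nuse <- max(1, round(z_fraction * nz))
  z0 <- floor((nz - nuse) / 2) + 1
  mean_slice <- apply(v[, , z0:(z0 + nuse - 1), drop = FALSE], c(1, 2), mean)
  avg$voxels <- array(mean_slice, dim = dim(v))
  avg
}

#' Rotationally symmetrize a volume about its z axis
#'
#' Replaces every z slice by its rotational (azimuthal) average, making the
#' volume an exact body of revolution. Applied after [smooth_z()] this
#' yields the azimuthal average in its literal sense; it suppresses the
#' angular ripple left by inserting a finite number of segment slices.
#'
#' @param avg `az_average` / [volume3d()].
#' @param bin_px radial bin width in voxels for the profile (default 0.25).
#' @return symmetrized volume of the same class.
#' @export
symmetrize_average <- function(avg, bin_px = 0.25) {
  v <- avg$voxels
  n <- dim(v)[1]; nz <- dim(v)[3]
  c0 <- grid_center(n)
  g <- (0:(n - 1)) - c0
  r <- sqrt(outer(g^2, g^2, "+")) / bin_px
  i0 <- floor(r); fr <- r - i0
  nb <- max(i0) + 2
  idx_lo <- as.vector(i0) + 1; w_hi <- as.vector(fr)
  z_invariant <- max(abs(v[, , 1] - v[, , nz])) <=
    1e-9 * max(abs(v[, , 1]), 1e-300)
  fit_slice <- function(sl) {
    sl <- as.vector(sl)
    num <- rowsum(c(sl * (1 - w_hi), sl * w_hi), c(idx_lo, idx_lo + 1))
    den <- rowsum(c(1 - w_hi, w_hi), c(idx_lo, idx_lo + 1))
    prof <- as.vector(num / pmax(den, 1e-12))
    lut <- rep(0, nb); lut[as.integer(rownames(num))] <- prof
    matrix(lut[idx_lo] * (1 - w_hi) + lut[idx_lo + 1] * w_hi, n, n)
  }
  if (z_invariant) {
    sym <- fit_slice(v[, , 1])
    avg$voxels <- array(sym, dim(v))
  } else {
    for (z in seq_len(nz)) avg$voxels[, , z] <- fit_slice(v[, , z])
  }
  avg
}

#' Cylindricity of a volume about its z axis
#'
#' `1 - (power of the residual after subtracting the rotational average
#' about z) / (total power)`. 1 means a perfect body of revolution.
#'
#' @param avg `az_average` / [volume3d()] with non-zero content.
#' @param bin_px radial bin width in voxels (default 0.25, linearly
#'   interpolated).
#' @return value in `[0, 1]`.
#' @export
cylindricity <- function(avg, bin_px = 0.25) {
  v <- avg$voxels
  total <- sum(v^2)
  if (total == 0) stop("cylindricity: zero volume")
  n <- dim(v)[1]; nz <- dim(v)[3]
  c0 <- grid_center(n)
  g <- (0:(n - 1)) - c0
  r <- sqrt(outer(g^2, g^2, "+")) / bin_px
  i0 <- floor(r); fr <- r - i0
  nb <- max(i0) + 2
  resid <- 0
  idx_lo <- as.vector(i0) + 1; w_hi <- as.vector(fr)
  for (z in seq_len(nz)) {
    sl <- as.vector(v[, , z])
    num <- rowsum(c(sl * (1 - w_hi), sl * w_hi), c(idx_lo, idx_lo + 1))
    den <- rowsum(c(1 - w_hi, w_hi), c(idx_lo, idx_lo + 1))
    prof <- as.vector(num / pmax(den, 1e-12))
    bins <- as.integer(rownames(num))
    lut <- rep(0, nb); lut[bins] <- prof
    fit <- lut[idx_lo] * (1 - w_hi) + lut[idx_lo + 1] * w_hi
    resid <- resid + sum((sl - fit)^2)
  }
  1 - resid / total
}

#' Rotationally averaged radial profile of a volume
#'
#' Mean density as a function of cylinder radius about z, averaged over the
#' central `z_fraction` of slices. Used to compare reconstructions against
#' analytic tube models.
#'
#' @param avg a [volume3d()].
#' @param r_px radii (in voxels) at which to sample (default 0 .. n/2 - 1
#'   step 0.5).
#' @param z_fraction central fraction of slices to include.
#' @return data frame with `r_px`, `r_A`, `density`.
#' @export
radial_average <- function(avg, r_px = NULL, z_fraction = 0.8) {
  v <- avg$voxels
  n <- dim(v)[1]; nz <- dim(v)[3]
  if (is.null(r_px)) r_px <- seq(0, n / 2 - 1, by = 0.5)
  nuse <- max(1, round(z_fraction * nz))
  z0 <- floor((nz - nuse) / 2) + 1
  sl <- apply(v[, , z0:(z0 + nuse - 1), drop = FALSE], c(1, 2), mean)
  ## band-limited 4x upsampling of the slice so ring sampling does not blur
  up <- 4L
  fs <- stats::fft(sl)
  h <- n / 2
  big <- matrix(0 + 0i, up * n, up * n)
  lo <- 1:h; hi_src <- (h + 2):n; hi_dst <- (up * n - h + 2):(up * n)
  big[lo, lo] <- fs[lo, lo];      big[lo, hi_dst] <- fs[lo, hi_src]
  big[hi_dst, lo] <- fs[hi_src, lo]; big[hi_dst, hi_dst] <- fs[hi_src, hi_src]
  slf <- Re(stats::fft(big, inverse = TRUE)) / (n * n)
  c0 <- up * grid_center(n) + 1
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  dens <- vapply(r_px, function(ri) {
    mean(bilinear_sample(slf, c0 + up * ri * cos(th), c0 + up * ri * sin(th)))
  }, numeric(1))
  data.frame(r_px = r_px, r_A = r_px * avg$voxel_size, density = dens)
}

#' Project the azimuthal average at a segment's orientation
#'
#' Real-space ray sum of the rotated volume, with the segment's in-plane
#' rotation and shifts applied inversely so the projection overlays the
#' original (unaligned) segment image.
#'
#' @param avg `az_average` / [volume3d()].
#' @param phi_deg,theta_deg,psi_deg Euler angles (package convention).
#' @param shift_x_px,shift_y_px recorded centering shifts of the segment
#'   (rotated-frame convention, as stored by the aligner).
#' @param extend `"auto"` (default) renders a z-invariant volume as an
#'   axially unbounded tube from its vertical projection profile, so tilted
#'   projections have no cube-end artifacts; `"none"` always ray-sums the
#'   cube.
#' @return an [image2d()] with the same side as the volume.
#' @export
project_average <- function(avg, phi_deg = 0, theta_deg = 90, psi_deg = 0,
                            shift_x_px = 0, shift_y_px = 0,
                            extend = c("auto", "none")) {
  extend <- match.arg(extend)
  v <- avg$voxels
  n <- dim(v)[1]
  c0 <- grid_center(n)
  nz <- dim(v)[3]
  z_invariant <- max(abs(v[, , 1] - v[, , nz])) <=
    1e-9 * max(abs(v[, , 1]), 1e-300)
  if (extend == "auto" && z_invariant && abs(theta_deg %% 180 - 90) < 1e-9) {
    ## z-invariant (axially smoothed) volume: render the tube as infinitely
    ## long, so a tilted projection has no finite-cube end artifacts and
    ## overlays the whole segment
    cylindrical <- tryCatch(cylindricity(avg) > 0.98,
                            error = function(e) FALSE)
    if (cylindrical) {
      ## body of revolution: its projection profile is the Abel transform
      ## of the radial profile, which is exactly phi-independent
      rr <- seq(0, 0.75 * n, by = 0.25)
      ra <- radial_average(avg, r_px = rr)
      gfun <- function(r) stats::approx(rr, ra$density, xout = r,
                                        yleft = ra$density[1],
                                        yright = 0)$y
      sgrid <- seq(0, max(rr), by = 0.25)
      xsf <- seq(0, n, by = 1 / 8)
      pf <- vapply(xsf, function(xi) {
        vals <- gfun(sqrt(xi^2 + sgrid^2))
        2 * (sum(vals) - 0.5 * (vals[1] + vals[length(vals)])) * 0.25
      }, numeric(1))
      xsf <- c(rev(-xsf[-1]), xsf)
      pf <- c(rev(pf[-1]), pf)
    } else {
      base <- project_average(avg, phi_deg, theta_deg, 0, 0, 0,
                              extend = "none")$pixels
      prof <- rowMeans(base)
      up <- 8
      pf <- sinc_upsample(prof - mean(prof), up) + mean(prof)
      xsf <- (0:(up * n - 1)) / up - c0
    }
    a <- psi_deg * pi / 180
    gx <- rep(0:(n - 1), times = n) - c0
    gy <- rep(0:(n - 1), each = n) - c0
    d <- cos(a) * gx - sin(a) * gy + shift_x_px
    vals <- stats::approx(xsf, pf, xout = d, rule = 2)$y
    return(image2d(matrix(vals, n, n), avg$voxel_size))
  }
  A <- euler_matrix(phi_deg, theta_deg, psi_deg)
  ## image pixel (x, y): ray over z_img; sample volume at A^T (p + t - c) + c
  t2 <- shift_to_image_frame(psi_deg, shift_x_px, shift_y_px)
  g <- (0:(n - 1))
  px <- rep(g, times = n) - c0 + t2[1]
  py <- rep(g, each = n) - c0 + t2[2]
  out <- numeric(n * n)
  At <- t(A)
  for (zi in g) {
    z <- zi - c0
    sx <- At[1, 1] * px + At[1, 2] * py + At[1, 3] * z + c0 + 1
    sy <- At[2, 1] * px + At[2, 2] * py + At[2, 3] * z + c0 + 1
    sz <- At[3, 1] * px + At[3, 2] * py + At[3, 3] * z + c0 + 1
    out <- out + trilinear_sample(v, sx, sy, sz)
  }
  image2d(matrix(out, n, n), avg$voxel_size)
}

#' Refine psi and centering shifts against a reference
#'
#' One pass of reference-based alignment. The reference is a 1D tube
#' profile: either the projection of the (z-smoothed) azimuthal average
#' volume, or -- when `avg` is NULL -- the mean of the aligned per-segment
#' profiles with the segment under refinement left out (so its own noise
#' cannot bias the search). For every aligned segment, psi and the
#' perpendicular centering shift are re-optimized by nested golden-section
#' search of the matched-filter score between the raw segment pixels and an
#' analytically evaluated reference image; phi and theta are untouched.
#'
#' The matched filter is evaluated over a central disk (a disk is
#' reflection-symmetric about any candidate axis, which keeps the psi
#' objective even in the angle error even for an imperfect reference), the
#' reference profile is continued by band-limited (sinc) interpolation, and
#' the noisy segment pixels are never interpolated.
#'
#' @param stack aligned [image_stack()].
#' @param avg `az_average` reference volume, or NULL to use the
#'   leave-one-out mean aligned profile of the stack itself.
#' @param psi_window half-width of the psi search around the current value,
#'   degrees (default 3).
#' @param config an [align_config()] (fine step reused).
#' @return the updated stack; attributes `mean_dpsi` and `mean_dshift`
#'   report the mean absolute parameter changes for convergence monitoring.
#' @export
refine_against_average <- function(stack, avg = NULL, psi_window = 3,
                                   config = align_config()) {
  n <- dim(stack$data)[1]
  c0 <- grid_center(n)
  md <- stack$metadata
  use <- which(md$align_ok == 1)
  x1 <- 0:(n - 1)
  if (!is.null(avg)) {
    ref <- project_average(avg)$pixels
    refsum <- rowMeans(ref)
    profs <- NULL
  } else {
    ## aligned (rotated, shift-corrected) 1D profile of every segment
    ys <- round(n / 4):round(3 * n / 4)
    profs <- matrix(0, n, length(use))
    for (j in seq_along(use)) {
      i <- use[j]
      m <- stack$data[, , i]
      r <- rotate_image(m, md$psi_deg[i], fill = mean(m))
      p <- rowMeans(r[, ys])
      ## apply the current centering shift (content moves by +shift)
      profs[, j] <- stats::approx(x1, p, xout = x1 - md$shift_x_px[i],
                                  rule = 2)$y
    }
    refsum <- rowMeans(profs) * length(use)
  }
  ## band-limited (sinc) upsampling; spline continuation would overshoot at
  ## the shell peaks and bias the angle search
  up <- 8
  sinc_up <- function(p) {
    rf <- stats::fft(p - mean(p))
    rf_fine <- complex(up * n)
    rf_fine[1:(n / 2)] <- rf[1:(n / 2)]
    rf_fine[up * n - n / 2 + 2:(n / 2)] <- rf[n / 2 + 2:(n / 2)]
    Re(stats::fft(rf_fine, inverse = TRUE)) / n
  }
  xs_fine <- (0:(up * n - 1)) / up - c0
  gx <- rep(0:(n - 1), times = n) - c0
  gy <- rep(0:(n - 1), each = n) - c0
  ## circular support: a disk is reflection-symmetric about any tube axis,
  ## so the matched-filter objective stays even in the angle error even
  ## when the reference profile is imperfect (a square box would bias psi)
  disk <- gx^2 + gy^2 <= c0^2
  gx <- gx[disk]; gy <- gy[disk]
  dpsi <- dsh <- numeric(0)
  for (j in seq_along(use)) {
    i <- use[j]
    refprof <- if (is.null(profs)) refsum / length(use) else {
      if (length(use) > 1) (refsum - profs[, j]) / (length(use) - 1)
      else refsum
    }
    prof_fine <- sinc_up(refprof)
    pref_safe <- function(d) {
      out <- numeric(length(d))
      inr <- abs(d) <= max(xs_fine)
      out[inr] <- stats::approx(xs_fine, prof_fine, xout = d[inr],
                                rule = 2)$y
      out
    }
    img <- as.vector(stack$data[, , i])[disk]
    img <- img - mean(img)
    ## matched filter <segment, reference(psi, s)>; s is the perpendicular
    ## offset of the tube from center in the unrotated frame (= -shift_x)
    score_xs <- function(psi, s) {
      a <- psi * pi / 180
      d <- cos(a) * gx - sin(a) * gy
      sum(img * pref_safe(d - s))
    }
    psi0 <- md$psi_deg[i]
    ## coarse re-scan of the offset first: a failed edge detection can
    ## leave the stored shift several pixels off
    s_grid <- seq(-md$shift_x_px[i] - 8, -md$shift_x_px[i] + 8, by = 1)
    s0 <- s_grid[which.max(vapply(s_grid,
                                  function(s) score_xs(psi0, s),
                                  numeric(1)))]
    best_s_at <- function(psi) {
      golden_max(function(s) score_xs(psi, s), s0 - 2, s0 + 2, tol = 0.03)
    }
    score_at <- function(psi) score_xs(psi, best_s_at(psi))
    psi_new <- golden_max(score_at, psi0 - psi_window, psi0 + psi_window,
                          tol = config$fine_step_deg / 2)
    shift_new <- -best_s_at(psi_new)
    dpsi <- c(dpsi, abs(psi_new - md$psi_deg[i]))
    dsh <- c(dsh, abs(shift_new - md$shift_x_px[i]))
    md$psi_deg[i] <- psi_new %% 180
    md$shift_x_px[i] <- shift_new
  }
  stack$metadata <- md
  attr(stack, "mean_dpsi") <- mean(dpsi)
  attr(stack, "mean_dshift") <- mean(dsh)
  stack
}

#' Iterate alignment refinement to convergence
#'
#' Repeats [refine_against_average()] with the leave-one-out mean-profile
#' reference until the mean parameter changes fall below `tol_psi` /
#' `tol_shift` or `max_iter` passes, then reconstructs and z-smooths the
#' final azimuthal average.
#'
#' @param stack aligned stack.
#' @param z_fraction passed to [smooth_z()].
#' @param tol_psi,tol_shift convergence thresholds (degrees, pixels).
#' @param max_iter maximum refinement passes (default 5).
#' @param oversample passed to [reconstruct_average()].
#' @return list with `stack`, `average` (final smoothed `az_average`),
#'   `iterations`, `history` (data frame of mean changes).
#' @export
refine_loop <- function(stack, z_fraction = 0.8, tol_psi = 0.2,
                        tol_shift = 0.25, max_iter = 5, oversample = 2) {
  hist <- NULL
  it <- 0
  repeat {
    it <- it + 1
    stack <- refine_against_average(stack, avg = NULL)
    hist <- rbind(hist, data.frame(iteration = it,
                                   mean_dpsi = attr(stack, "mean_dpsi"),
                                   mean_dshift = attr(stack, "mean_dshift")))
    if ((attr(stack, "mean_dpsi") < tol_psi &&
         attr(stack, "mean_dshift") < tol_shift) || it >= max_iter) break
  }
  avg <- smooth_z(reconstruct_average(stack, oversample = oversample),
                  z_fraction)
  avg$provenance$iteration <- it
  list(stack = stack, average = avg, iterations = it, history = hist)
}
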