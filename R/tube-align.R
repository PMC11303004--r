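## In-plane tube alignment: autocorrelation-based psi search, profile-peak
## edge finding / centering, and randomized azimuth (phi) and polarity
## (theta) assignment.

#' Alignment configuration
#'
#' @param coarse_step_deg coarse psi grid step (default 1).
#' @param fine_step_deg refinement tolerance for psi (default 0.1).
#' @param smooth_sigma_px Gaussian sigma for profile smoothing (default 2).
#' @param peak_frac local maxima below this fraction of the profile maximum
#'   (above baseline) are ignored (default 0.3).
#' @param min_width_px,max_width_px plausibility window for the tube width
#'   (edge-to-edge); defaults are 15% and 90% of the box side.
#' @param score_floor minimum autocorrelation anisotropy score; below it the
#'   segment is declared tube-free (default 3; pure-noise fields score
#'   around 1-2, clear tubes above 6).
#' @return list of class `align_config`.
#' @export
align_config <- function(coarse_step_deg = 1, fine_step_deg = 0.1,
                         smooth_sigma_px = 2, peak_frac = 0.3,
                         min_width_px = NULL, max_width_px = NULL,
                         score_floor = 3) {
  structure(list(coarse_step_deg = coarse_step_deg,
                 fine_step_deg = fine_step_deg,
                 smooth_sigma_px = smooth_sigma_px, peak_frac = peak_frac,
                 min_width_px = min_width_px, max_width_px = max_width_px,
                 score_floor = score_floor),
            class = "align_config")
}

## Variance of the line sums along y (per-x totals) of the central half of
## `m` after rotating it by `angle`. Maximal when the tube axis is vertical.
psi_objective <- function(ac, angle, mask_idx) {
  r <- rotate_image(ac, angle)
  stats::var(rowSums(r[mask_idx$x, mask_idx$y]))
}

#' Estimate the in-plane tube angle (psi) of a segment
#'
#' Autocorrelation-based search: the 2D autocorrelation of a tube image is
#' elongated along the tube axis; for candidate angles the autocorrelation
#' is rotated and scored by the variance of its per-column line sums over
#' the central half of the field. A coarse grid (default 1 degree) is
#' followed by golden-section refinement. The returned score is the
#' anisotropy of the objective over the coarse grid
#' (`max / median - 1`); values near 0 indicate no directional structure.
#'
#' @param img square [image2d()] (or matrix) containing one dominant tube.
#' @param config an [align_config()].
#' @return list with `psi_deg` in `[0, 180)` (the rotation that makes the
#'   tube vertical) and `score`.
#' @export
estimate_psi <- function(img, config = align_config()) {
  if (inherits(img, "image2d")) img <- img$pixels
  n <- nrow(img)
  stopifnot(n == ncol(img))
  ac <- autocorrelation(img)          # 2n x 2n, zero lag at center
  na <- nrow(ac)
  ctr <- floor(na / 2) + 1
  ## normalize by the zero-padding overlap envelope (pyramid), which would
  ## otherwise bias the angle search, then apply an isotropic circular
  ## window so the scored support is rotation-invariant
  lag <- (1:na) - ctr
  env <- outer(pmax(n - abs(lag), n / 4), pmax(n - abs(lag), n / 4))
  ac <- ac / env
  q <- round(n / 2)
  r <- sqrt(outer(lag^2, lag^2, "+"))
  w <- 0.5 * (1 + cos(pi * pmin(pmax(r / q, 0.8), 1) / 0.2 - 4 * pi))
  ac <- ac * w
  ## suppress the isotropic zero-lag noise spike
  sp <- max(1, round(n / 64))
  ac[(ctr - sp):(ctr + sp), (ctr - sp):(ctr + sp)] <-
    mean(ac[(ctr - sp):(ctr + sp), (ctr - sp):(ctr + sp)])
  ## the window zeroes everything beyond radius q, so rotation only needs
  ## the central square
  keep <- (ctr - q - 1):(ctr + q)
  ac <- ac[keep, keep]
  ctr <- q + 2
  mask_idx <- list(x = (ctr - q):(ctr + q - 1), y = (ctr - q):(ctr + q - 1))
  angles <- seq(0, 180 - config$coarse_step_deg, by = config$coarse_step_deg)
  scores <- vapply(angles, function(a) psi_objective(ac, a, mask_idx),
                   numeric(1))
  best <- which.max(scores)
  score <- scores[best] / stats::median(scores) - 1
  if (score < config$score_floor)
    stop("no tube detected (anisotropy score ", signif(score, 3),
         " below floor ", config$score_floor, ")")
  lo <- angles[best] - config$coarse_step_deg
  hi <- angles[best] + config$coarse_step_deg
  psi <- golden_max(function(a) psi_objective(ac, a, mask_idx), lo, hi,
                    tol = config$fine_step_deg / 2)
  list(psi_deg = psi %% 180, score = score)
}

## Parabolic sub-pixel refinement of a discrete peak position.
parabolic_peak <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(i)
  d <- (v[i - 1] - v[i + 1]) / 2
  den <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (den == 0) return(i)
  i + d / den * -1
}

#' Locate the tube edges and centering shift in a rotated segment
#'
#' For an image whose tube is already vertical: the per-x profile (mean over
#' y) is Gaussian-smoothed, local maxima above a prominence fraction of the
#' profile maximum are found, and the outermost pair is taken as the tube
#' edges. The centering shift is the distance from the edge midpoint to the
#' image center.
#'
#' @param img_rotated square [image2d()]/matrix with a vertical tube.
#' @param config an [align_config()].
#' @return list with `left_px`, `right_px` (0-based, sub-pixel),
#'   `shift_x_px` (translation that centers the tube) and `width_px`.
#' @export
find_tube_edges <- function(img_rotated, config = align_config()) {
  if (inherits(img_rotated, "image2d")) img_rotated <- img_rotated$pixels
  n <- nrow(img_rotated)
  ## mean over the central half of y only: avoids corner fill after rotation
  ys <- max(1, round(n / 4)):min(n, round(3 * n / 4))
  prof <- rowMeans(img_rotated[, ys])
  sm <- smooth_profile(prof, config$smooth_sigma_px)
  base <- stats::median(sm)
  height <- max(sm) - base
  if (height <= 0 || !is.finite(height) ||
      height < 2 * stats::sd(sm - prof) + 1e-12 * max(abs(sm)))
    stop("edge detection failed: flat profile")
  ## symmetry center of the profile (matched filter against its own mirror):
  ## the self-convolution of the baseline-subtracted profile peaks at twice
  ## the symmetry center. This anchors the edge pairing under noise.
  sb <- sm - base
  pad <- c(sb, numeric(n))
  cv <- Re(stats::fft(stats::fft(pad)^2, inverse = TRUE)) / (2 * n)
  u <- which.max(cv[1:(2 * n - 1)])
  u_ref <- parabolic_peak(cv, u)
  c_sym <- (u_ref - 1) / 2            # 0-based symmetry center
  thr <- base + config$peak_frac * height
  idx <- which(diff(sign(diff(sm))) == -2) + 1
  idx <- idx[sm[idx] > thr]
  if (length(idx) < 2)
    stop("edge detection failed: fewer than 2 profile peaks")
  pk <- vapply(idx, function(i) parabolic_peak(sm, i), numeric(1)) - 1
  ## outermost pair of peaks lying symmetrically about the symmetry center
  lefts <- pk[pk < c_sym - 1]; rights <- pk[pk > c_sym + 1]
  min_w <- if (is.null(config$min_width_px)) 0.15 * n else config$min_width_px
  max_w <- if (is.null(config$max_width_px)) 0.90 * n else config$max_width_px
  best <- NULL
  for (L in lefts) for (R in rights) {
    w <- R - L
    if (w < min_w || w > max_w) next
    if (abs((L + R) / 2 - c_sym) > 2.5) next
    if (is.null(best) || w > best[2] - best[1]) best <- c(L, R)
  }
  if (is.null(best))
    stop("edge detection failed: no symmetric edge pair in width window [",
         round(min_w, 1), ", ", round(max_w, 1), "]")
  left <- best[1]; right <- best[2]
  ctr <- grid_center(n)
  list(left_px = left, right_px = right,
       shift_x_px = ctr - (left + right) / 2, width_px = right - left)
}

#' Assign randomized azimuth and polarity angles
#'
#' Each segment receives `phi ~ Uniform[0, 360)` (spin about the tube axis)
#' and `theta` drawn from `{90, 270}` with equal probability (tube
#' polarity). Reproducible under `seed`.
#'
#' @param n number of segments.
#' @param seed RNG seed.
#' @return data frame with columns `phi_deg`, `theta_deg` (`n` rows).
#' @export
assign_random_angles <- function(n, seed) {
  stopifnot(n >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  data.frame(phi_deg = stats::runif(n, 0, 360),
             theta_deg = sample(c(90, 270), n, replace = TRUE))
}

#' Align a stack of tube segments
#'
#' Runs [estimate_psi()] and [find_tube_edges()] on every segment, assigns
#' random phi/theta, and writes the resulting columns (`psi_deg`,
#' `theta_deg`, `phi_deg`, `shift_x_px`, `shift_y_px`, `edge_left_px`,
#' `edge_right_px`, `alignment_score`, `align_ok`) into the stack metadata.
#' Segments that fail psi or edge detection are flagged `align_ok = 0` and
#' are excluded by downstream stages. The axial shift (`shift_y_px`) is
#' fixed at 0: a straight tube is translationally invariant along its axis,
#' so the minimum centering shift has no axial component.
#'
#' @param stack an [image_stack()].
#' @param config an [align_config()].
#' @param seed seed for the phi/theta randomization (alignment itself is
#'   deterministic).
#' @param verbose print a per-stack summary line.
#' @return the stack with updated metadata.
#' @export
align_stack <- function(stack, config = align_config(), seed = 1,
                        verbose = FALSE) {
  n <- n_images(stack)
  if (n == 0) stop("align_stack: empty stack")
  ang <- assign_random_angles(n, seed)
  md <- stack$metadata
  md$psi_deg <- NA_real_; md$theta_deg <- ang$theta_deg
  md$phi_deg <- ang$phi_deg
  md$shift_x_px <- NA_real_; md$shift_y_px <- 0
  md$edge_left_px <- NA_real_; md$edge_right_px <- NA_real_
  md$alignment_score <- NA_real_; md$align_ok <- 0L
  for (i in seq_len(n)) {
    ok <- tryCatch({
      ps <- estimate_psi(stack$data[, , i], config)
      rot <- rotate_image(stack$data[, , i], ps$psi_deg,
                          fill = mean(stack$data[, , i]))
      ed <- find_tube_edges(rot, config)
      md$psi_deg[i] <- ps$psi_deg
      md$alignment_score[i] <- ps$score
      md$edge_left_px[i] <- ed$left_px
      md$edge_right_px[i] <- ed$right_px
      md$shift_x_px[i] <- ed$shift_x_px
      TRUE
    }, error = function(e) FALSE)
    md$align_ok[i] <- as.integer(ok)
  }
  if (all(md$align_ok == 0))
    stop("align_stack: no segment passed tube alignment")
  if (verbose)
    message(sprintf("align_stack: %d/%d segments aligned", sum(md$align_ok), n))
  stack$metadata <- md
  stack
}

#' Keep only segments that passed alignment
#' @param stack aligned [image_stack()].
#' @export
filter_aligned <- function(stack) {
  keep <- which(stack$metadata$align_ok == 1)
  image_stack(stack$data[, , keep, drop = FALSE], stack$pixel_size,
              stack$metadata[keep, , drop = FALSE])
}

## Apply a segment's alignment (rotate by psi about the center, then
## translate by the recorded centering shift along x in the rotated frame).
aligned_segment <- function(stack, i, fill_mean = TRUE) {
  m <- stack$data[, , i]
  md <- stack$metadata[i, ]
  fill <- if (fill_mean) mean(m) else 0
  r <- rotate_image(m, md$psi_deg, fill = fill)
  shift_image(r, md$shift_x_px, md$shift_y_px, method = "bilinear") +
    0  # keep matrix
}
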