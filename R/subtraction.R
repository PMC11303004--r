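## Tube-signal subtraction: scale the projected azimuthal average to each
## segment (least squares over the tube mask) and subtract it.

#' Subtract a tube projection from a segment image
#'
#' The scale `alpha` minimizing `||img - alpha * proj||^2` is fitted over
#' the tube mask (pixels where the projection exceeds `mask_frac` of its
#' maximum); the scaled projection is subtracted from the whole frame.
#' Fitting only where the tube has signal avoids bias from particles off
#' the tube.
#'
#' @param img segment [image2d()] (or matrix).
#' @param proj matching tube projection (same shape).
#' @param mask_frac mask threshold as a fraction of `max(proj)`
#'   (default 0.1).
#' @param match_bandlimit also fit a small Gaussian blur/sharpen factor to
#'   the projection before subtracting (default FALSE).
#' @return list of class `subtraction_result`: `subtracted` ([image2d()]),
#'   `scale_alpha`, `residual_rms_in_mask`.
#' @export
subtract_segment <- function(img, proj, mask_frac = 0.1,
                             match_bandlimit = FALSE) {
  ps <- if (inherits(img, "image2d")) img$pixel_size else 1
  if (inherits(img, "image2d")) img <- img$pixels
  if (inherits(proj, "image2d")) proj <- proj$pixels
  stopifnot(all(dim(img) == dim(proj)))
  pmax_ <- max(abs(proj))
  if (pmax_ == 0 || stats::sd(proj) == 0)
    stop("subtract_segment: projection is empty, nothing to subtract")
  mask <- proj > mask_frac * max(proj)
  if (!any(mask)) stop("subtract_segment: empty tube mask")
  fit_alpha <- function(p) {
    pm <- p[mask]; im <- img[mask]
    ## least squares with intercept: ice background varies per segment;
    ## a constant projection inside the mask degenerates to the no-intercept
    ## fit
    pm_c <- pm - mean(pm); im_c <- im - mean(im)
    if (sum(pm_c^2) > 0) {
      alpha <- sum(pm_c * im_c) / sum(pm_c^2)
      ## one trimmed refit: particles overlapping the tube band are gross
      ## outliers of the fit and would otherwise bias the scale
      res <- im_c - alpha * pm_c
      cut <- 3.5 * stats::mad(res)
      keep <- abs(res) <= cut
      if (cut > 0 && any(keep) && !all(keep)) {
        pk <- pm[keep] - mean(pm[keep]); ik <- im[keep] - mean(im[keep])
        if (sum(pk^2) > 0) alpha <- sum(pk * ik) / sum(pk^2)
      }
      list(alpha = alpha, ss = sum((im_c - alpha * pm_c)^2))
    } else {
      alpha <- sum(pm * im) / sum(pm^2)
      list(alpha = alpha, ss = sum((im - alpha * pm)^2))
    }
  }
  blim <- 0
  if (match_bandlimit) {
    ## Gaussian band-limit matching: the projected average can be slightly
    ## sharper or blurrier than the segment; fit a small blur/sharpen
    ## factor exp(-2 pi^2 B k^2) (B in px^2, clamped gain) jointly with
    ## alpha
    n1 <- nrow(proj); n2 <- ncol(proj)
    k2 <- outer((fft_freqs(n1) / n1)^2, (fft_freqs(n2) / n2)^2, "+")
    Fp <- stats::fft(proj)
    proj_at <- function(B) {
      gain <- pmin(pmax(exp(-2 * pi^2 * B * k2 * n1^2 / n1^2), 0), 10)
      gain <- exp(-2 * pi^2 * B * k2)
      gain <- pmin(gain, 10)
      Re(stats::fft(Fp * gain, inverse = TRUE)) / (n1 * n2)
    }
    blim <- golden_max(function(B) -fit_alpha(proj_at(B))$ss, -3, 3,
                       tol = 0.01)
    proj <- proj_at(blim)
  }
  fit <- fit_alpha(proj)
  alpha <- fit$alpha
  out <- img - alpha * proj
  res <- out[mask] - mean(out[mask])
  structure(list(subtracted = image2d(out, ps), scale_alpha = alpha,
                 bandlimit_B = blim,
                 residual_rms_in_mask = sqrt(mean(res^2))),
            class = "subtraction_result")
}

#' Subtract the azimuthal average from every segment of a stack
#'
#' For each aligned segment the average is projected at the segment's
#' angles/shifts ([project_average()]) and subtracted via
#' [subtract_segment()]. The metadata gains `scale_alpha` and
#' `residual_rms` columns; segments that fail are flagged
#' (`align_ok = 0`) and their pixels left untouched. The subtracted stack
#' is subsequently treated as a set of micrographs by the picking stage.
#'
#' @param stack aligned [image_stack()].
#' @param avg `az_average` (normally z-smoothed); may be NULL when
#'   `projection = "profile"`.
#' @param mask_frac,match_bandlimit see [subtract_segment()].
#' @param destripe after subtracting, remove the per-distance median of
#'   each segment along its axis: a robust cleanup of coherent shell
#'   residual streaks that leaves localized particles intact (default
#'   FALSE).
#' @param projection `"profile"` (default) derives the tube projection from
#'   the mean aligned 1D profile of the stack itself -- the projection of
#'   the azimuthal average estimated directly in projection space, which
#'   avoids the gridding loss of the volume round-trip; `"volume"` projects
#'   `avg` by ray summation.
#' @return the subtracted [image_stack()].
#' @export
subtract_stack <- function(stack, avg = NULL, mask_frac = 0.1,
                           match_bandlimit = FALSE,
                           projection = c("profile", "volume"),
                           destripe = FALSE) {
  projection <- match.arg(projection)
  n <- n_images(stack)
  if (n == 0) stop("subtract_stack: empty stack")
  md <- stack$metadata
  if (!"align_ok" %in% names(md))
    stop("subtract_stack: stack has not been aligned")
  if (projection == "volume" && is.null(avg))
    stop("subtract_stack: projection = 'volume' needs the average volume")
  md$scale_alpha <- NA_real_; md$residual_rms <- NA_real_
  use <- which(md$align_ok == 1)
  if (length(use) == 0) stop("subtract_stack: no aligned segments")
  nb <- dim(stack$data)[1]
  c0 <- grid_center(nb)
  gx <- rep(0:(nb - 1), times = nb) - c0
  gy <- rep(0:(nb - 1), each = nb) - c0
  if (projection == "profile") {
    ## pool every aligned pixel into fine perpendicular-distance bins
    ## (linear interpolation weights); this estimates the tube profile
    ## without ever interpolating image values, so the estimate is not
    ## blurred by rotation
    bw <- 0.25
    allb <- integer(0); allv <- numeric(0)
    for (i in use) {
      a <- md$psi_deg[i] * pi / 180
      d <- cos(a) * gx - sin(a) * gy + md$shift_x_px[i]
      allb <- c(allb, as.integer(round((d + nb) / bw)))
      allv <- c(allv, as.vector(stack$data[, , i]))
    }
    ## per-bin median: robust to the minority of pixels that belong to
    ## particles, which would otherwise leave a faint ring in the profile
    med <- tapply(allv, allb, stats::median)
    xsf <- (as.numeric(names(med)) * bw) - nb
    pfine <- as.numeric(med)
  }
  destripe_one <- function(seg, psi_deg, shift_x) {
    ## residual de-striping: remove the per-distance MEDIAN of the
    ## subtracted segment along the tube axis. The median tracks the
    ## coherent shell residual streak but is insensitive to a localized
    ## particle, which only occupies a small fraction of the rows.
    a <- psi_deg * pi / 180
    d <- cos(a) * gx - sin(a) * gy + shift_x
    b <- round(d)
    med <- stats::ave(as.vector(seg), b, FUN = stats::median)
    seg - matrix(med, nrow(seg), ncol(seg))
  }
  n_fail <- 0
  for (i in use) {
    ok <- tryCatch({
      proj <- if (projection == "volume") {
        project_average(avg, md$phi_deg[i], md$theta_deg[i],
                        md$psi_deg[i], md$shift_x_px[i],
                        md$shift_y_px[i])
      } else {
        a <- md$psi_deg[i] * pi / 180
        d <- cos(a) * gx - sin(a) * gy + md$shift_x_px[i]
        image2d(matrix(stats::approx(xsf, pfine, xout = d, rule = 2)$y,
                       nb, nb), stack$pixel_size)
      }
      r <- subtract_segment(image2d(stack$data[, , i], stack$pixel_size),
                            proj, mask_frac, match_bandlimit)
      out_px <- r$subtracted$pixels
      if (destripe)
        out_px <- destripe_one(out_px, md$psi_deg[i], md$shift_x_px[i])
      stack$data[, , i] <- out_px
      md$scale_alpha[i] <- r$scale_alpha
      md$residual_rms[i] <- r$residual_rms_in_mask
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      md$align_ok[i] <- 0L
      n_fail <- n_fail + 1
    }
  }
  if (n_fail == length(use))
    stop("subtract_stack: subtraction failed for every segment")
  stack$metadata <- md
  stack
}
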