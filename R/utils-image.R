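## Low-level grid utilities shared by all pipeline stages.
##
## Conventions (used everywhere in the package):
##  * a 2D image is a matrix indexed [x + 1, y + 1] for 0-based pixel
##    coordinates (x, y); x runs horizontally (columns of the displayed
##    image), y vertically.
##  * the image/volume center sits at the 0-based coordinate (n - 1) / 2,
##    i.e. between the two middle pixels of an even-sized grid.
##  * rotations are counter-clockwise in the (x, y) plane, in degrees.

#' Signed FFT frequency indices
#'
#' Integer frequencies in cycles per grid for an n-point DFT, in the order
#' returned by [stats::fft()]: 0, 1, ..., then negative frequencies.
#'
#' @param n grid size.
#' @return integer vector of length `n`.
#' @keywords internal
#' @noRd
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

## 0-based center of an n-pixel axis
grid_center <- function(n) (n - 1) / 2

#' Bilinear sampling of a matrix at fractional 1-based coordinates.
#' Points outside the grid return `fill`.
#' @noRd
bilinear_sample <- function(mat, x, y, fill = 0) {
  nx <- nrow(mat); ny <- ncol(mat)
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny
  out <- rep(fill, length(x))
  if (any(ok)) {
    x0 <- x0[ok]; y0 <- y0[ok]; fx <- fx[ok]; fy <- fy[ok]
    i00 <- x0 + (y0 - 1) * nx
    v <- mat[i00]       * (1 - fx) * (1 - fy) +
         mat[i00 + 1]   * fx       * (1 - fy) +
         mat[i00 + nx]  * (1 - fx) * fy +
         mat[i00 + nx + 1] * fx    * fy
    out[ok] <- v
  }
  out
}

#' Trilinear sampling of a 3D array at fractional 1-based coordinates.
#' @noRd
trilinear_sample <- function(arr, x, y, z, fill = 0) {
  d <- dim(arr)
  x0 <- pmin(floor(x), d[1] - 1)
  y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, length(x))
  if (any(ok)) {
    x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
    fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
    nx <- d[1]; nxy <- d[1] * d[2]
    i000 <- x0 + (y0 - 1) * nx + (z0 - 1) * nxy
    v <- arr[i000]            * (1 - fx) * (1 - fy) * (1 - fz) +
         arr[i000 + 1]        * fx       * (1 - fy) * (1 - fz) +
         arr[i000 + nx]       * (1 - fx) * fy       * (1 - fz) +
         arr[i000 + nx + 1]   * fx       * fy       * (1 - fz) +
         arr[i000 + nxy]      * (1 - fx) * (1 - fy) * fz +
         arr[i000 + nxy + 1]  * fx       * (1 - fy) * fz +
         arr[i000 + nxy + nx] * (1 - fx) * fy       * fz +
         arr[i000 + nxy + nx + 1] * fx   * fy       * fz
    out[ok] <- v
  }
  out
}

#' Rotate an image about its center
#'
#' Rotates image content counter-clockwise by `angle_deg` about the pixel
#' center `((n-1)/2, (n-1)/2)` (0-based) using bilinear interpolation.
#' Pixels sampled from outside the input are set to `fill`.
#'
#' @param pixels numeric matrix (`[x, y]` indexing).
#' @param angle_deg rotation angle in degrees, counter-clockwise.
#' @param fill value for out-of-field samples (default 0).
#' @return matrix of the same dimensions.
#' @export
rotate_image <- function(pixels, angle_deg, fill = 0) {
  if (angle_deg %% 360 == 0) return(pixels)
  nx <- nrow(pixels); ny <- ncol(pixels)
  cx <- grid_center(nx) + 1; cy <- grid_center(ny) + 1
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  gx <- rep(seq_len(nx), times = ny) - cx
  gy <- rep(seq_len(ny), each = nx) - cy
  ## output(p) = input(R(-angle) (p - c) + c)
  sx <- ca * gx + sa * gy + cx
  sy <- -sa * gx + ca * gy + cy
  matrix(bilinear_sample(pixels, sx, sy, fill = fill), nx, ny)
}

#' Translate an image by a (possibly fractional) pixel shift
#'
#' Moves image content by `(dx, dy)` pixels: `out(x, y) = in(x - dx, y - dy)`.
#' Fourier (phase-ramp) shifting is exact for band-limited data and is the
#' default; bilinear shifting is available for non-periodic content.
#'
#' @param pixels numeric matrix.
#' @param dx,dy shift in pixels along x and y.
#' @param method `"fourier"` (default, circular) or `"bilinear"` (zero fill).
#' @return shifted matrix.
#' @export
shift_image <- function(pixels, dx, dy, method = c("fourier", "bilinear")) {
  method <- match.arg(method)
  if (dx == 0 && dy == 0) return(pixels)
  nx <- nrow(pixels); ny <- ncol(pixels)
  if (method == "fourier") {
    kx <- fft_freqs(nx); ky <- fft_freqs(ny)
    px <- exp(-2i * pi * kx * dx / nx)
    py <- exp(-2i * pi * ky * dy / ny)
    Re(stats::fft(stats::fft(pixels) * outer(px, py), inverse = TRUE)) / (nx * ny)
  } else {
    gx <- rep(seq_len(nx), times = ny) - dx
    gy <- rep(seq_len(ny), each = nx) - dy
    matrix(bilinear_sample(pixels, gx, gy), nx, ny)
  }
}

## Centered linear 2D autocorrelation (Wiener-Khinchin on the zero-padded,
## mean-subtracted image so tilted features do not wrap), zero lag at the
## center after fftshift.
autocorrelation <- function(pixels) {
  nx <- nrow(pixels); ny <- ncol(pixels)
  p <- matrix(0, 2 * nx, 2 * ny)
  p[1:nx, 1:ny] <- pixels - mean(pixels)
  f <- stats::fft(p)
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / (4 * nx * ny)
  fftshift2(ac)
}

## Swap quadrants so the zero-frequency / zero-lag element moves to the
## center-ish position (floor(n/2) + 1).
fftshift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- c((floor(nx / 2) + 1):nx, 1:floor(nx / 2))
  iy <- c((floor(ny / 2) + 1):ny, 1:floor(ny / 2))
  m[ix, iy]
}

#' Normalized cross-correlation of two equal-sized images
#'
#' Pearson correlation between the pixel vectors of `a` and `b`.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @return correlation in `[-1, 1]`.
#' @export
ncc <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  av <- as.vector(a) - mean(a)
  bv <- as.vector(b) - mean(b)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(0)
  sum(av * bv) / den
}

## Gaussian smoothing of a 1D profile (reflective edges).
smooth_profile <- function(v, sigma) {
  if (sigma <= 0) return(v)
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-hw:hw)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(v)
  vp <- c(rev(v[seq_len(hw)]), v, rev(v[n - seq_len(hw) + 1]))
  as.numeric(stats::filter(vp, k, sides = 2))[(hw + 1):(hw + n)]
}

## Unnormalized 1D cross-correlation cc[k] = sum_x a[x + k] b[x] for
## k = -max_lag .. max_lag (zero-padded ends).
xcorr1d <- function(a, b, max_lag) {
  n <- length(a)
  lag <- -max_lag:max_lag
  cc <- vapply(lag, function(k) {
    ia <- max(1, 1 + k):min(n, n + k)
    sum(a[ia] * b[ia - k])
  }, numeric(1))
  list(lag = lag, cc = cc)
}

## Golden-section maximization of f on [lo, hi] to tolerance tol.
golden_max <- function(f, lo, hi, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}

## Rotation matrix mapping volume coordinates to image coordinates:
## A = Rz(-psi) %*% Rx(theta) %*% Rz(phi). With theta = 90 the tube (volume
## z) axis lies in the image plane; psi matches the in-plane convention of
## the aligner (the tube axis runs along (sin psi, cos psi), i.e. rotating
## the image content by +psi makes the tube vertical); theta = 270 flips
## the polarity; phi spins the tube about its own axis.
euler_matrix <- function(phi_deg, theta_deg, psi_deg) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  rx <- function(a) {
    a <- a * pi / 180
    matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  }
  rz(-psi_deg) %*% rx(theta_deg) %*% rz(phi_deg)
}

## Convert the stored rotated-frame centering shift (perpendicular to the
## tube, i.e. along x after rotating the image by +psi) into the equivalent
## image-frame content translation.
shift_to_image_frame <- function(psi_deg, shift_x, shift_y) {
  a <- psi_deg * pi / 180
  c(cos(a) * shift_x + sin(a) * shift_y,
    -sin(a) * shift_x + cos(a) * shift_y)
}

## Band-limited (sinc) upsampling of a 1D profile by integer factor `up`
## (zero-padding of the spectrum; the Nyquist bin is dropped).
sinc_upsample <- function(p, up = 8) {
  n <- length(p)
  rf <- stats::fft(p)
  rf_fine <- complex(up * n)
  rf_fine[1:(n / 2)] <- rf[1:(n / 2)]
  rf_fine[up * n - n / 2 + 2:(n / 2)] <- rf[n / 2 + 2:(n / 2)]
  Re(stats::fft(rf_fine, inverse = TRUE)) / n
}
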