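## Particle recovery from subtracted segments: template NCC picking,
## sub-box tiling, multi-reference 2D classification, picking by
## classification, and cross-correlation duplicate elimination.

## FFT-based normalized cross-correlation of a template against an image.
## Returns the full NCC map (circular); positions closer than half the
## template to the border are set to -Inf by the caller via `valid_margin`.
ncc_map <- function(img, tpl) {
  n1 <- nrow(img); n2 <- ncol(img)
  nt <- nrow(tpl)
  tp <- tpl - mean(tpl)
  tnorm <- sqrt(sum(tp^2))
  if (tnorm == 0) stop("ncc_map: flat template")
  big_t <- matrix(0, n1, n2)
  big_t[1:nt, 1:nt] <- tp
  ## center the template footprint on the map position
  c_off <- floor(grid_center(nt))
  Fi <- stats::fft(img)
  Ft <- stats::fft(big_t)
  cross <- Re(stats::fft(Fi * Conj(Ft), inverse = TRUE)) / (n1 * n2)
  ## local mean/variance of the image under the template window (box sums)
  box <- matrix(0, n1, n2); box[1:nt, 1:nt] <- 1
  Fb <- stats::fft(box)
  s1 <- Re(stats::fft(Fi * Conj(Fb), inverse = TRUE)) / (n1 * n2)
  s2 <- Re(stats::fft(stats::fft(img^2) * Conj(Fb), inverse = TRUE)) / (n1 * n2)
  npx <- nt * nt
  varloc <- pmax(s2 - s1^2 / npx, 0)
  den <- sqrt(varloc) * tnorm
  m <- cross / pmax(den, 1e-12 * max(den))
  m[den <= 0] <- 0
  ## shift so m[x, y] scores the template centered at 0-based (x-1, y-1)
  m <- m[c((n1 - c_off + 1):n1, 1:(n1 - c_off)),
         c((n2 - c_off + 1):n2, 1:(n2 - c_off))]
  m
}

## Intensity-weighted centroid of a score map around (x, y) (1-based),
## window half-width hw, squared weights above the local floor.
centroid_refine <- function(map, x, y, hw) {
  n1 <- nrow(map); n2 <- ncol(map)
  xs <- max(1, x - hw):min(n1, x + hw)
  ys <- max(1, y - hw):min(n2, y + hw)
  w <- map[xs, ys, drop = FALSE]
  w[!is.finite(w)] <- 0
  w <- pmax(w - max(min(w), 0), 0)^2
  if (sum(w) == 0) return(c(x, y))
  c(sum(outer(xs, rep(1, length(ys))) * w) / sum(w),
    sum(outer(rep(1, length(xs)), ys) * w) / sum(w))
}

#' Template-based particle picking on one segment
#'
#' Normalized cross-correlation of the (optionally rotated) template at
#' every position of the segment; local maxima above `threshold` are
#' accepted greedily in descending score with a minimum separation. The
#' pick is mapped to the parent-micrograph frame through the segment origin
#' when supplied.
#'
#' @param segment [image2d()]/matrix (a tube-subtracted segment treated as a
#'   micrograph).
#' @param template square [image2d()]/matrix smaller than the segment.
#' @param threshold NCC acceptance threshold (default 0.15, calibrated so that pure-noise frames pick nothing).
#' @param min_separation_px minimum distance between picks (default: half
#'   the template side).
#' @param n_rot number of in-plane template rotations searched (default 24).
#' @param segment_id,micrograph_id,origin_x,origin_y metadata used to fill
#'   the global coordinates (`global = origin + local - segment_center`).
#' @param stripe_axis_deg when the segment's tube angle (psi) is known, the
#'   per-distance median of the score map along that axis is removed before
#'   peak extraction, suppressing axis-aligned residual ridges.
#' @return data frame of picks: segment_id, micrograph_id, local_x, local_y
#'   (0-based pixels), global_x, global_y, score. Zero rows if nothing
#'   exceeds the threshold.
#' @export
pick_by_template <- function(segment, template, threshold = 0.15,
                             min_separation_px = NULL, n_rot = 24,
                             segment_id = NA, micrograph_id = NA,
                             origin_x = NA, origin_y = NA,
                             stripe_axis_deg = NULL) {
  if (inherits(segment, "image2d")) segment <- segment$pixels
  if (inherits(template, "image2d")) template <- template$pixels
  nt <- nrow(template)
  stopifnot(nt <= nrow(segment), nt <= ncol(segment))
  if (is.null(min_separation_px)) min_separation_px <- round(nt / 2)
  best <- matrix(-Inf, nrow(segment), ncol(segment))
  angles <- seq(0, 360, length.out = n_rot + 1)[seq_len(max(n_rot, 1))]
  for (a in angles) {
    tpl <- if (a == 0) template else rotate_image(template, a)
    best <- pmax(best, ncc_map(segment, tpl))
  }
  if (!is.null(stripe_axis_deg)) {
    ## remove the per-distance median of the score map along the tube
    ## axis: coherent shell-residual ridges are axis-aligned and bias the
    ## peak localization, while a localized particle leaves the median
    ## untouched
    aa <- stripe_axis_deg * pi / 180
    gxs <- rep(seq_len(nrow(best)), times = ncol(best))
    gys <- rep(seq_len(ncol(best)), each = nrow(best))
    b <- round(cos(aa) * gxs - sin(aa) * gys)
    v <- as.vector(best)
    fin <- is.finite(v)
    med <- stats::ave(v[fin], b[fin], FUN = stats::median)
    v[fin] <- v[fin] - med
    best <- matrix(v, nrow(best), ncol(best))
  }
  ## exclude positions whose box leaves the segment
  marg <- ceiling(nt / 2)
  n1 <- nrow(segment); n2 <- ncol(segment)
  best[c(seq_len(marg), (n1 - marg + 1):n1), ] <- -Inf
  best[, c(seq_len(marg), (n2 - marg + 1):n2)] <- -Inf
  cand <- which(best >= threshold, arr.ind = TRUE)
  out <- data.frame(segment_id = integer(0), micrograph_id = integer(0),
                    local_x = numeric(0), local_y = numeric(0),
                    global_x = numeric(0), global_y = numeric(0),
                    score = numeric(0))
  if (nrow(cand) == 0) return(out)
  sc <- best[cand]
  ord <- order(-sc, cand[, 1], cand[, 2])
  acc_x <- acc_y <- acc_s <- numeric(0)
  for (j in ord) {
    x <- cand[j, 1]; y <- cand[j, 2]
    if (length(acc_x) &&
        any((acc_x - x)^2 + (acc_y - y)^2 < min_separation_px^2)) next
    acc_x <- c(acc_x, x); acc_y <- c(acc_y, y); acc_s <- c(acc_s, sc[j])
  }
  c0 <- grid_center(n1)
  ## sub-pixel localization: intensity-weighted centroid of the correlation
  ## peak over a local window (averages out noise jitter of the argmax,
  ## which matters because a smooth template gives a broad peak)
  hw <- max(2L, round(0.3 * nt))
  ref <- vapply(seq_along(acc_x),
                function(j) centroid_refine(best, acc_x[j], acc_y[j], hw),
                numeric(2))
  lx <- ref[1, ] - 1; ly <- ref[2, ] - 1
  data.frame(segment_id = segment_id, micrograph_id = micrograph_id,
             local_x = lx, local_y = ly,
             global_x = origin_x + (lx - c0),
             global_y = origin_y + (ly - grid_center(n2)),
             score = acc_s)
}

#' Template picking across a whole stack
#'
#' Applies [pick_by_template()] to every usable segment (rows with
#' `align_ok == 1` when the column exists), filling the metadata-derived
#' identifiers and origins.
#'
#' @inheritParams pick_by_template
#' @param stack an [image_stack()].
#' @return combined pick data frame.
#' @export
pick_stack_by_template <- function(stack, template, threshold = 0.15,
                                   min_separation_px = NULL, n_rot = 24) {
  md <- stack$metadata
  use <- if ("align_ok" %in% names(md)) which(md$align_ok == 1)
         else seq_len(n_images(stack))
  res <- lapply(use, function(i) {
    pick_by_template(stack$data[, , i], template, threshold,
                     min_separation_px, n_rot,
                     segment_id = md$segment_id[i],
                     micrograph_id = md$micrograph_id[i],
                     origin_x = md$origin_x[i], origin_y = md$origin_y[i],
                     stripe_axis_deg = NULL)
  })
  do.call(rbind, res)
}

#' Tile a segment into an even grid of overlapping sub-boxes
#'
#' Centers are evenly spaced over the segment interior (margin = half the
#' sub-box side) on an `nx x ny` grid; neighboring boxes overlap whenever
#' the sub-box side exceeds the grid spacing.
#'
#' @param segment [image2d()]/matrix.
#' @param divisions integer vector `c(nx, ny)` (or one number used for
#'   both).
#' @param subbox_size sub-box side in pixels (<= segment side).
#' @return list with `boxes` (array `subbox_size^2 x nx*ny`), `grid` (data
#'   frame of 0-based center_x, center_y per box), `subbox_size`.
#' @export
tile_subboxes <- function(segment, divisions, subbox_size) {
  if (inherits(segment, "image2d")) segment <- segment$pixels
  if (length(divisions) == 1) divisions <- c(divisions, divisions)
  nx <- divisions[1]; ny <- divisions[2]
  stopifnot(nx >= 1, ny >= 1)
  n1 <- nrow(segment); n2 <- ncol(segment)
  if (subbox_size > min(n1, n2))
    stop("tile_subboxes: sub-box larger than the segment")
  half <- subbox_size / 2
  cx <- if (nx == 1) (n1 - 1) / 2 else
    seq(half - 0.5, n1 - 1 - (half - 0.5), length.out = nx)
  cy <- if (ny == 1) (n2 - 1) / 2 else
    seq(half - 0.5, n2 - 1 - (half - 0.5), length.out = ny)
  grid <- expand.grid(center_x = cx, center_y = cy)
  boxes <- array(0, c(subbox_size, subbox_size, nrow(grid)))
  for (b in seq_len(nrow(grid))) {
    x0 <- round(grid$center_x[b] - (subbox_size - 1) / 2) + 1
    y0 <- round(grid$center_y[b] - (subbox_size - 1) / 2) + 1
    x0 <- min(max(x0, 1), n1 - subbox_size + 1)
    y0 <- min(max(y0, 1), n2 - subbox_size + 1)
    boxes[, , b] <- segment[x0:(x0 + subbox_size - 1),
                            y0:(y0 + subbox_size - 1)]
    grid$center_x[b] <- x0 - 1 + (subbox_size - 1) / 2
    grid$center_y[b] <- y0 - 1 + (subbox_size - 1) / 2
  }
  list(boxes = boxes, grid = grid, subbox_size = subbox_size,
       divisions = c(nx, ny))
}

## Precompute rotated copies of every image (normalized) and their FFTs.
prep_rotations <- function(data, angles) {
  n <- dim(data)[3]
  lapply(seq_len(n), function(i) {
    img <- data[, , i]
    img <- img - mean(img)
    s <- sqrt(sum(img^2)); if (s > 0) img <- img / s
    lapply(angles, function(a) {
      r <- if (a == 0) img else {
        rr <- rotate_image(img, a)
        rr <- rr - mean(rr)
        ss <- sqrt(sum(rr^2)); if (ss > 0) rr / ss else rr
      }
      stats::fft(r)
    })
  })
}

#' Multi-reference 2D classification with in-plane alignment
#'
#' Reference-based k-class alignment clustering: starting from a random
#' partition (under `seed`), each iteration aligns every image to every
#' class reference over a grid of in-plane rotations and integer shifts
#' (cross-correlation via FFT), assigns it to the best-correlating class,
#' and rebuilds each reference as the average of its aligned members
#' (normalized to zero mean / unit variance). Stops after `n_iter`
#' iterations or when fewer than 1% of assignments change.
#'
#' @param stack [image_stack()] or 3D array of (sub-box) images.
#' @param k number of classes (`1 <= k <= n`).
#' @param n_iter maximum iterations (default 15).
#' @param seed RNG seed for the initial partition.
#' @param rot_step_deg in-plane rotation step (default 30).
#' @param max_shift_px maximum |shift| searched per axis (default 1/4 box).
#' @return list of class `class_set`: `references` (array), `assignment`,
#'   `rot_deg`, `shift_x`, `shift_y`, `score` (per image), `population`,
#'   `objective` (per-iteration mean correlation), `n_iter_run`.
#' @export
classify_2d <- function(stack, k, n_iter = 15, seed = 1, rot_step_deg = 30,
                        max_shift_px = NULL) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  n <- dim(data)[3]; nb <- dim(data)[1]
  stopifnot(k >= 1)
  if (k > n) stop("classify_2d: k (", k, ") exceeds number of images (", n, ")")
  if (is.null(max_shift_px)) max_shift_px <- floor(nb / 4)
  angles <- seq(0, 360 - rot_step_deg, by = rot_step_deg)
  pre <- prep_rotations(data, angles)
  ## allowed circular shift indices
  sh <- if (max_shift_px >= 1)
    unique(c(0:max_shift_px, (nb - max_shift_px):(nb - 1))) else 0L
  sh <- sh[sh >= 0 & sh <= nb - 1]
  signed <- ifelse(sh > nb / 2, sh - nb, sh)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assignment <- sample(rep_len(seq_len(k), n))
  refs <- array(0, c(nb, nb, k))
  norm_img <- function(m) {
    m <- m - mean(m); s <- sqrt(sum(m^2)); if (s > 0) m / s else m
  }
  ## center a reference on its own energy centroid: the in-class shifts
  ## are reported relative to the reference frame, so picks are only
  ## meaningful if every reference keeps its feature centered
  c0r <- grid_center(nb) + 1
  center_ref <- function(m) {
    w <- (m - mean(m))^2
    cx <- sum(rep(seq_len(nb), times = nb) * w) / sum(w)
    cy <- sum(rep(seq_len(nb), each = nb) * w) / sum(w)
    if (max(abs(c(cx - c0r, cy - c0r))) < nb / 3)
      shift_image(m, c0r - cx, c0r - cy, method = "bilinear")
    else m
  }
  ## seed each reference with a single member of its random class: an
  ## unaligned class mean would smear features beyond the alignment
  ## capture range and stall the iteration
  for (cl in seq_len(k))
    refs[, , cl] <- norm_img(center_ref(data[, , which(assignment == cl)[1]]))
  rot_best <- shift_x <- shift_y <- score <- numeric(n)
  objective <- numeric(0)
  it_run <- 0
  for (it in seq_len(n_iter)) {
    it_run <- it
    refF <- lapply(seq_len(k), function(cl) Conj(stats::fft(refs[, , cl])))
    new_assign <- assignment
    for (i in seq_len(n)) {
      best <- -Inf; b_cl <- 1L; b_rot <- 0; b_sx <- 0; b_sy <- 0
      for (cl in seq_len(k)) {
        for (ai in seq_along(angles)) {
          cc <- Re(stats::fft(pre[[i]][[ai]] * refF[[cl]],
                              inverse = TRUE)) / (nb * nb)
          sub <- cc[sh + 1, sh + 1]
          m <- which.max(sub)
          if (sub[m] > best) {
            best <- sub[m]
            b_cl <- cl; b_rot <- angles[ai]
            b_sx <- signed[(m - 1) %% length(sh) + 1]
            b_sy <- signed[(m - 1) %/% length(sh) + 1]
          }
        }
      }
      new_assign[i] <- b_cl; rot_best[i] <- b_rot
      shift_x[i] <- b_sx; shift_y[i] <- b_sy; score[i] <- best
    }
    objective <- c(objective, mean(score))
    changed <- mean(new_assign != assignment)
    assignment <- new_assign
    for (cl in seq_len(k)) {
      members <- which(assignment == cl)
      if (!length(members)) next   # keep the previous reference
      acc <- matrix(0, nb, nb)
      for (i in members) {
        al <- rotate_image(data[, , i], rot_best[i])
        al <- shift_image(al, -shift_x[i], -shift_y[i], method = "bilinear")
        acc <- acc + al
      }
      refs[, , cl] <- norm_img(center_ref(acc / length(members)))
    }
    if (changed < 0.01 && it > 1) break
  }
  structure(list(references = refs, assignment = assignment,
                 rot_deg = rot_best, shift_x = shift_x, shift_y = shift_y,
                 score = score,
                 population = tabulate(assignment, nbins = k),
                 objective = objective, n_iter_run = it_run,
                 rot_step_deg = rot_step_deg),
            class = "class_set")
}

#' Rank classes by coherence (mean in-class alignment score)
#'
#' Ground-truth-free ranking used to select "good" (particle-containing)
#' classes: members of a real particle class correlate strongly with their
#' common reference, while noise-only and incoherent residue classes align
#' poorly. Classes whose mean member correlation exceeds 1.4x the median
#' over classes are kept (so a stack with no coherent class selects
#' nothing).
#'
#' @param classset a `class_set`.
#' @param n_good how many top classes to return (overrides the automatic
#'   threshold).
#' @return integer vector of class indices, best first (possibly empty).
#' @export
rank_classes <- function(classset, n_good = NULL) {
  k <- dim(classset$references)[3]
  v <- vapply(seq_len(k), function(cl) {
    m <- classset$assignment == cl
    if (!any(m)) return(-Inf)
    mean(classset$score[m])
  }, numeric(1))
  ## ignore tiny classes, whose mean score is inflated by overfitting
  v[classset$population < max(2, 0.02 * length(classset$assignment))] <- -Inf
  ord <- order(-v)
  if (is.null(n_good)) {
    fin <- v[is.finite(v)]
    if (!length(fin)) return(integer(0))
    ## require an outstanding class to exist at all, then keep every class
    ## close to the best one
    if (max(fin) < 1.25 * stats::median(fin)) return(integer(0))
    keep <- is.finite(v) & v >= 0.8 * max(fin)
    ord[seq_len(sum(keep))]
  } else ord[seq_len(min(n_good, k))]
}

#' Template-free particle picking by cascaded 2D classification
#'
#' Tiles the (tube-subtracted) segments into overlapping sub-boxes,
#' classifies them with [classify_2d()], keeps the classes ranked good by
#' [rank_classes()], re-classifies their members (the second round of
#' classification separates centered particles from residue that co-sorted
#' with them), and converts the final good-class assignments into centered
#' picks.
#'
#' @param stack subtracted [image_stack()].
#' @param divisions,subbox_size see [tile_subboxes()].
#' @param k classes per round (default 6).
#' @param rounds classification rounds (default 2).
#' @param n_iter,rot_step_deg,max_shift_px passed to [classify_2d()].
#' @param seed RNG seed (per-round seeds derived from it).
#' @param n_good forwarded to [rank_classes()].
#' @return pick data frame (see [picks_from_classes()]).
#' @export
pick_by_classification <- function(stack, divisions, subbox_size, k = 6,
                                   rounds = 2, n_iter = 10,
                                   rot_step_deg = 90, max_shift_px = NULL,
                                   seed = 1, n_good = NULL) {
  tiles <- tile_stack(stack, divisions, subbox_size)
  if (is.null(max_shift_px)) max_shift_px <- floor(subbox_size * 0.4)
  boxes <- tiles$boxes; grid <- tiles$grid
  keep <- seq_len(nrow(grid))
  cs <- NULL
  for (r in seq_len(rounds)) {
    cs <- classify_2d(boxes[, , keep, drop = FALSE], k = min(k, length(keep)),
                      n_iter = n_iter, seed = seed + r,
                      rot_step_deg = rot_step_deg,
                      max_shift_px = max_shift_px)
    good <- rank_classes(cs, n_good)
    if (r < rounds) {
      keep <- keep[cs$assignment %in% good]
      if (length(keep) < 2 * k) break
    }
  }
  picks <- picks_from_classes(cs, grid[keep, , drop = FALSE], good)
  ## template-free re-centering: intensity-weighted centroid of the
  ## subtracted segment around each pick (the in-class shifts are integer
  ## valued and share any residual reference offset). The pick score is
  ## replaced by the local smoothed-image evidence, so that duplicate
  ## elimination keeps the best-centered copy of each particle.
  if (nrow(picks) > 0) {
    hw <- round(subbox_size / 5)
    seg_index <- match(picks$segment_id, stack$metadata$segment_id)
    ns <- dim(stack$data)[1]
    ks <- fft_freqs(ns)
    gk <- exp(-2 * pi^2 * (subbox_size / 8)^2 *
              outer(ks^2, ks^2, "+") / ns^2)
    sm_cache <- list()
    for (j in seq_len(nrow(picks))) {
      si <- seg_index[j]
      key <- as.character(si)
      if (is.null(sm_cache[[key]]))
        sm_cache[[key]] <- Re(stats::fft(stats::fft(stack$data[, , si]) * gk,
                                         inverse = TRUE)) / ns^2
      img <- sm_cache[[key]]
      x <- round(picks$local_x[j]) + 1; y <- round(picks$local_y[j]) + 1
      xs <- max(1, x - hw):min(ns, x + hw)
      ys <- max(1, y - hw):min(ns, y + hw)
      w <- img[xs, ys, drop = FALSE]
      w <- pmax(w - stats::median(w), 0)^2
      if (sum(w) > 0) {
        nx2 <- sum(outer(xs, rep(1, length(ys))) * w) / sum(w) - 1
        ny2 <- sum(outer(rep(1, length(xs)), ys) * w) / sum(w) - 1
        picks$global_x[j] <- picks$global_x[j] + (nx2 - picks$local_x[j])
        picks$global_y[j] <- picks$global_y[j] + (ny2 - picks$local_y[j])
        picks$local_x[j] <- nx2; picks$local_y[j] <- ny2
      }
      picks$score[j] <- sm_cache[[key]][min(max(round(picks$local_x[j]) + 1,
                                                1), ns),
                                        min(max(round(picks$local_y[j]) + 1,
                                                1), ns)]
    }
    ## evidence pruning: picks whose local density is far below the bulk of
    ## the selected class are residue/noise boxes that slipped through the
    ## class selection
    picks <- picks[picks$score >= 0.4 * stats::median(picks$score), ,
                   drop = FALSE]
  }
  picks
}

#' Convert class assignments of sub-boxes into particle picks
#'
#' Every sub-box assigned to a good class yields one pick at the sub-box
#' center corrected by the in-class alignment (rotation/shift), mapped to
#' micrograph coordinates through the segment origin.
#'
#' @param classset `class_set` from [classify_2d()] run on tiled sub-boxes.
#' @param grid the tiling table: one row per sub-box with `center_x`,
#'   `center_y` (segment-local 0-based), `segment_id`, `micrograph_id`,
#'   `origin_x`, `origin_y`, `segment_size`.
#' @param good_classes integer vector of accepted class indices.
#' @return pick data frame (as [pick_by_template()]); zero rows with a
#'   warning when `good_classes` is empty.
#' @export
picks_from_classes <- function(classset, grid, good_classes) {
  if (length(good_classes) == 0) {
    warning("picks_from_classes: no good classes selected")
    return(data.frame(segment_id = integer(0), micrograph_id = integer(0),
                      local_x = numeric(0), local_y = numeric(0),
                      global_x = numeric(0), global_y = numeric(0),
                      score = numeric(0)))
  }
  sel <- which(classset$assignment %in% good_classes)
  if (!length(sel))
    return(data.frame(segment_id = integer(0), micrograph_id = integer(0),
                      local_x = numeric(0), local_y = numeric(0),
                      global_x = numeric(0), global_y = numeric(0),
                      score = numeric(0)))
  a <- classset$rot_deg[sel] * pi / 180
  sx <- classset$shift_x[sel]; sy <- classset$shift_y[sel]
  ## the aligner rotated the sub-box by rot and then found the particle
  ## displaced by (sx, sy); undoing the rotation puts the particle at
  ## R(-rot) (sx, sy) from the sub-box center.
  dx <- cos(a) * sx + sin(a) * sy
  dy <- -sin(a) * sx + cos(a) * sy
  c0 <- grid_center(grid$segment_size[sel])
  lx <- grid$center_x[sel] + dx
  ly <- grid$center_y[sel] + dy
  data.frame(segment_id = grid$segment_id[sel],
             micrograph_id = grid$micrograph_id[sel],
             local_x = lx, local_y = ly,
             global_x = grid$origin_x[sel] + (lx - c0),
             global_y = grid$origin_y[sel] + (ly - c0),
             score = classset$score[sel])
}

#' Tile every usable segment of a stack into sub-boxes
#'
#' Convenience wrapper around [tile_subboxes()] that concatenates the
#' sub-boxes of all segments (rows with `align_ok == 1` when present) and
#' returns a grid table carrying the per-box segment metadata needed by
#' [picks_from_classes()].
#'
#' @param stack an [image_stack()] (normally tube-subtracted).
#' @param divisions,subbox_size see [tile_subboxes()].
#' @return list with `boxes` (array `subbox x subbox x total`) and `grid`
#'   (data frame: segment_id, micrograph_id, origin_x, origin_y,
#'   segment_size, center_x, center_y).
#' @export
tile_stack <- function(stack, divisions, subbox_size) {
  md <- stack$metadata
  use <- if ("align_ok" %in% names(md)) which(md$align_ok == 1)
         else seq_len(n_images(stack))
  ns <- dim(stack$data)[1]
  all_boxes <- list(); all_grid <- list()
  for (i in use) {
    t <- tile_subboxes(stack$data[, , i], divisions, subbox_size)
    g <- t$grid
    g$segment_id <- md$segment_id[i]
    g$micrograph_id <- md$micrograph_id[i]
    g$origin_x <- md$origin_x[i]; g$origin_y <- md$origin_y[i]
    g$segment_size <- ns
    all_boxes[[length(all_boxes) + 1]] <- t$boxes
    all_grid[[length(all_grid) + 1]] <- g
  }
  list(boxes = array(unlist(all_boxes),
                     c(subbox_size, subbox_size,
                       sum(vapply(all_boxes, function(b) dim(b)[3],
                                  numeric(1))))),
       grid = do.call(rbind, all_grid))
}

#' Extract boxed images at pick positions
#'
#' @param stack the (subtracted) [image_stack()] the picks refer to.
#' @param picks pick data frame (`segment_id`, `local_x`, `local_y`).
#' @param box_size box side in pixels.
#' @return array `box_size x box_size x n_picks`; picks too close to the
#'   segment border are zero-padded.
#' @export
extract_boxes <- function(stack, picks, box_size) {
  n <- nrow(picks)
  out <- array(0, c(box_size, box_size, max(n, 1)))
  seg_index <- match(picks$segment_id, stack$metadata$segment_id)
  half <- (box_size - 1) / 2
  ns <- dim(stack$data)[1]
  for (j in seq_len(n)) {
    img <- stack$data[, , seg_index[j]]
    x0 <- round(picks$local_x[j] - half) + 1
    y0 <- round(picks$local_y[j] - half) + 1
    xs <- x0:(x0 + box_size - 1); ys <- y0:(y0 + box_size - 1)
    okx <- xs >= 1 & xs <= ns; oky <- ys >= 1 & ys <= ns
    out[which(okx), which(oky), j] <- img[xs[okx], ys[oky]]
  }
  out
}

## Peak NCC between two equal boxes over integer shifts up to max_shift.
ncc_shift_peak <- function(a, b, max_shift = 2) {
  best <- -1
  n <- nrow(a)
  for (dx in -max_shift:max_shift) {
    for (dy in -max_shift:max_shift) {
      xs_a <- max(1, 1 + dx):min(n, n + dx)
      ys_a <- max(1, 1 + dy):min(n, n + dy)
      xs_b <- xs_a - dx; ys_b <- ys_a - dy
      v <- ncc(a[xs_a, ys_a], b[xs_b, ys_b])
      if (v > best) best <- v
    }
  }
  best
}

#' Eliminate duplicate picks from overlapping segments
#'
#' Two picks are duplicates iff they lie on the same micrograph within
#' `dist_px` AND the peak normalized cross-correlation of their boxed
#' images over a +/-2 px shift search exceeds `ncc_threshold`. Duplicates
#' are resolved by keeping the highest-score pick; the procedure is greedy
#' over picks sorted by descending score (deterministic tie-break on
#' coordinates), hence independent of input order and idempotent.
#'
#' @param picks pick data frame with global coordinates and scores.
#' @param boxed_images array from [extract_boxes()] aligned with `picks`
#'   rows.
#' @param dist_px distance gate in pixels (default: box side / 2).
#' @param ncc_threshold correlation gate (default 0.8).
#' @param max_shift_px half-width of the shift search in the pairwise
#'   cross-correlation (default 2; increase when pick centering is coarser
#'   than a couple of pixels).
#' @return the retained subset of `picks` (row order by descending score).
#' @export
eliminate_duplicates <- function(picks, boxed_images, dist_px = NULL,
                                 ncc_threshold = 0.8, max_shift_px = 2) {
  n <- nrow(picks)
  if (n == 0) return(picks)
  if (is.null(dist_px)) dist_px <- dim(boxed_images)[1] / 2
  ord <- order(-picks$score, picks$global_x, picks$global_y,
               picks$segment_id)
  kept <- integer(0)
  for (j in ord) {
    dup <- FALSE
    for (m in kept) {
      if (picks$micrograph_id[m] != picks$micrograph_id[j]) next
      d2 <- (picks$global_x[m] - picks$global_x[j])^2 +
            (picks$global_y[m] - picks$global_y[j])^2
      if (d2 >= dist_px^2) next
      if (ncc_shift_peak(boxed_images[, , j], boxed_images[, , m],
                         max_shift = max_shift_px) >
          ncc_threshold) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, j)
  }
  picks[kept, , drop = FALSE]
}
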