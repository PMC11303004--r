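test_that("template picking finds its own signal and ignores blank noise", {
  ps <- 6.875
  tpl <- rastr:::particle_projection(gaussian_particle(pixel_size = ps))
  n <- 96
  blank <- matrix(0, n, n)
  pos <- c(40, 61)   # 0-based target position
  nt <- nrow(tpl); half <- (nt - 1) / 2
  xs <- round(pos[1] - half) + 1; ys <- round(pos[2] - half) + 1
  blank[xs:(xs + nt - 1), ys:(ys + nt - 1)] <- tpl
  p <- pick_by_template(blank, tpl, origin_x = 100, origin_y = 100)
  expect_equal(nrow(p), 1)
  expect_lt(sqrt((p$local_x - pos[1])^2 + (p$local_y - pos[2])^2), 1)
  expect_gt(p$score, 0.98)
  ## blank noise frames give no picks at the default threshold for the
  ## vast majority of seeds
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    nrow(pick_by_template(matrix(stats::rnorm(n * n), n, n), tpl))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("sub-box tiling counts, covers and respects bounds", {
  seg <- matrix(0, 384, 384)
  t16 <- tile_subboxes(seg, 4, 128)
  expect_equal(dim(t16$boxes)[3], 16)     # 4 x 4 divisions -> 16 pieces
  t1 <- tile_subboxes(seg, 1, 128)
  expect_equal(dim(t1$boxes)[3], 1)
  expect_equal(t1$grid$center_x, (384 - 1) / 2)
  expect_error(tile_subboxes(matrix(0, 64, 64), 2, 96), "larger")
  ## coverage: when the sub-box is at least the grid spacing, every
  ## interior pixel is inside at least one box
  tt <- tile_subboxes(matrix(0, 96, 96), 5, 32)
  covered <- matrix(FALSE, 96, 96)
  for (b in seq_len(nrow(tt$grid))) {
    x0 <- round(tt$grid$center_x[b] - 15.5) + 1
    y0 <- round(tt$grid$center_y[b] - 15.5) + 1
    covered[x0:(x0 + 31), y0:(y0 + 31)] <- TRUE
  }
  expect_true(all(covered[17:80, 17:80]))
  ## count law nx * ny
  t23 <- tile_subboxes(matrix(0, 96, 96), c(2, 3), 32)
  expect_equal(dim(t23$boxes)[3], 6)
})

test_that("classification separates two noiseless views perfectly", {
  nb <- 32; g <- 0:(nb - 1); c0 <- (nb - 1) / 2
  v1 <- outer(exp(-(g - c0)^2 / 20), exp(-(g - c0)^2 / 20))
  v2 <- outer(exp(-(g - c0)^2 / 60), exp(-(g - c0)^2 / 8))
  data <- array(0, c(nb, nb, 200))
  lab <- rep(1:2, each = 100)
  for (i in 1:200) data[, , i] <- if (lab[i] == 1) v1 else v2
  cs <- classify_2d(data, k = 2, n_iter = 8, seed = 4, rot_step_deg = 45,
                    max_shift_px = 4)
  tab <- table(cs$assignment, lab)
  expect_equal(sum(apply(tab, 1, max)) / 200, 1)
  expect_true(all(diff(cs$objective) >= -1e-6))
  ## k = 1 degenerates to a single aligned mean
  cs1 <- classify_2d(data[, , 1:50], k = 1, n_iter = 3, seed = 1)
  expect_true(all(cs1$assignment == 1))
  ## k > n errors
  expect_error(classify_2d(data[, , 1:3], k = 5, seed = 1), "exceeds")
  ## deterministic under seed
  cs2 <- classify_2d(data, k = 2, n_iter = 8, seed = 4, rot_step_deg = 45,
                     max_shift_px = 4)
  expect_identical(cs$assignment, cs2$assignment)
})

test_that("class picks center particles through the in-class alignment", {
  set.seed(2)
  nb <- 48; n_img <- 50
  blob <- function(cx, cy) {
    g <- 0:(nb - 1); outer(exp(-(g - cx)^2 / 18), exp(-(g - cy)^2 / 18))
  }
  c0 <- (nb - 1) / 2
  offs <- matrix(stats::runif(2 * n_img, -8, 8), ncol = 2)
  data <- array(0, c(nb, nb, n_img))
  for (i in seq_len(n_img))
    data[, , i] <- blob(c0 + offs[i, 1], c0 + offs[i, 2]) +
      matrix(stats::rnorm(nb * nb, 0, 0.15), nb, nb)
  cs <- classify_2d(data, k = 1, n_iter = 6, seed = 3, rot_step_deg = 90,
                    max_shift_px = 14)
  grid <- data.frame(center_x = c0, center_y = c0, segment_id = 1,
                     micrograph_id = 1, origin_x = c0, origin_y = c0,
                     segment_size = nb)[rep(1, n_img), ]
  p <- picks_from_classes(cs, grid, 1)
  err <- sqrt((p$local_x - (c0 + offs[, 1]))^2 +
              (p$local_y - (c0 + offs[, 2]))^2)
  expect_lt(stats::median(err), 1.5)
  expect_lt(max(err), 3)
  ## empty good set warns and returns nothing
  expect_warning(p0 <- picks_from_classes(cs, grid, integer(0)), "no good")
  expect_equal(nrow(p0), 0)
})

test_that("duplicate elimination keeps one pick per particle and is
           idempotent and order independent", {
  ## disjoint picks are all retained
  set.seed(11)
  boxes <- array(stats::rnorm(24 * 24 * 3), c(24, 24, 3))
  far <- data.frame(segment_id = 1:3, micrograph_id = 1,
                    local_x = c(10, 10, 10), local_y = c(10, 10, 10),
                    global_x = c(0, 200, 400), global_y = c(0, 0, 0),
                    score = c(3, 2, 1))
  expect_equal(nrow(eliminate_duplicates(far, boxes, dist_px = 20)), 3)
  ## three overlapping windows of one micrograph see the same particle
  sim <- simulate_tube_dataset(n_tubes = 1, segments_per_tube = 3,
                               segment_step_px = 16, image_size = 96,
                               pixel_size = 6.875,
                               particle = gaussian_particle(pixel_size = 6.875),
                               particles_per_segment = 1, snr = 1,
                               max_offset_px = 2, seed = 1)
  vis <- sim$truth$visible
  seen3 <- names(which(table(vis$particle_id) == 3))
  expect_gte(length(seen3), 1)
  st <- align_stack(sim$stack, seed = 2)
  sub <- subtract_stack(st)
  tpl <- rastr:::particle_projection(gaussian_particle(pixel_size = 6.875))
  picks <- pick_stack_by_template(sub, tpl)
  bx <- extract_boxes(sub, picks, 26)
  dd <- eliminate_duplicates(picks, bx, dist_px = 25, ncc_threshold = 0.6,
                             max_shift_px = 8)
  expect_equal(nrow(dd), length(unique(vis$particle_id)))
  ## idempotent
  dd2 <- eliminate_duplicates(dd, extract_boxes(sub, dd, 26), dist_px = 25,
                              ncc_threshold = 0.6, max_shift_px = 8)
  expect_equal(nrow(dd2), nrow(dd))
  ## order independent
  perm <- sample(nrow(picks))
  ddp <- eliminate_duplicates(picks[perm, ], bx[, , perm, drop = FALSE],
                              dist_px = 25, ncc_threshold = 0.6,
                              max_shift_px = 8)
  expect_equal(sort(ddp$global_x), sort(dd$global_x), tolerance = 1e-9)
  ## empty input passes through
  expect_equal(nrow(eliminate_duplicates(far[0, ], boxes)), 0)
})
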