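# tiny trained model shared across prediction tests (upsampling 2 keeps the
# upsampled grid small so training runs in seconds)
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(41)
      n <- 48
      patches <- array(0, c(16, 16, n))
      labels <- vector("list", n)
      for (i in seq_len(n)) {
        k <- sample(1:3, 1)
        xy <- cbind(runif(k, 1, 15), runif(k, 1, 15))
        img <- matrix(10, 16, 16)
        for (j in seq_len(k))
          img <- img + hdpaint:::cpp_render_spot(xy[j, 1], xy[j, 2], 2000,
                                                 1.2, 16, 16)
        patches[, , i] <- img + rnorm(256, 0, 3)
        labels[[i]] <- xy
      }
      ps <- patch_set(patches, labels, meta = list(pixel_size_nm = 157))
      cfg <- train_config(upsampling = 2, batch_size = 8, epochs = 200,
                          learning_rate = 2e-3, val_split = 0.15, seed = 5)
      cache <<- train_model(build_model(cfg), ps)
    }
    cache
  }
})

test_that("the network honours its shape contracts at any input size", {
  cfg <- train_config(upsampling = 2, seed = 3)
  m <- build_model(cfg)
  # 16 x 16 patch -> 16u x 16u map
  x16 <- array(rnorm(32 * 32), c(32, 32, 1))
  o <- hdpaint:::cpp_cnn_predict(m$params, x16)
  expect_equal(dim(o), c(32, 32, 1))
  # fully convolutional: a full frame passes through the same weights
  x64 <- array(rnorm(128 * 128), c(128, 128, 1))
  o2 <- hdpaint:::cpp_cnn_predict(m$params, x64)
  expect_equal(dim(o2), c(128, 128, 1))
  expect_true(all(o2 >= 0))
  # identical seeds give identical initial weights
  m2 <- build_model(train_config(upsampling = 2, seed = 3))
  expect_identical(m$params, m2$params)
  expect_false(identical(
    m$params$e1_W, build_model(train_config(upsampling = 2, seed = 4))$params$e1_W))
})

test_that("the 3x3 convolution layer matches a direct R implementation", {
  set.seed(3)
  H <- 7; W <- 9; Cin <- 3; Cout <- 2
  X <- array(rnorm(H * W * Cin), c(H, W, Cin))
  Wt <- matrix(rnorm(Cin * 9 * Cout), Cin * 9, Cout)
  b <- rnorm(Cout)
  Y <- hdpaint:::cpp_conv3(X, Wt, b)
  ref <- array(0, c(H, W, Cout))
  for (co in 1:Cout) {
    acc <- matrix(b[co], H, W)
    for (ci in 1:Cin) for (dc in -1:1) for (dr in -1:1) {
      w <- Wt[(ci - 1) * 9 + (dr + 1) + 3 * (dc + 1) + 1, co]
      Xp <- matrix(0, H + 2, W + 2)
      Xp[2:(H + 1), 2:(W + 1)] <- X[, , ci]
      acc <- acc + w * Xp[(2:(H + 1)) + dr, (2:(W + 1)) + dc]
    }
    ref[, , co] <- acc
  }
  expect_lt(max(abs(Y - ref)), 1e-12)
})

test_that("training splits, records history, and can overfit a tiny set", {
  # split arithmetic at the published scale (computed, not run)
  expect_equal(floor(0.15 * 30000), 4500)
  m <- tiny_model()
  h <- m$history
  expect_equal(h$n_train + h$n_val, 48)
  expect_equal(h$n_val, floor(0.15 * 48))
  expect_equal(length(h$train_loss), 200)
  expect_true(all(is.finite(h$train_loss)))
  # overfit probe: enough capacity to drive the loss down by an order of
  # magnitude on a small set
  expect_gt(h$train_loss[1] / min(h$train_loss), 10)
  # the trained model beats the all-zero predictor on held-out patches
  # (the zero predictor's blurred-MSE loss equals mean(label^2))
  expect_lt(min(h$val_loss), Inf)
  expect_gt(min(h$val_loss), 0)
})

test_that("prediction is deterministic and per-frame independent", {
  m <- tiny_model()
  set.seed(9)
  frames <- array(rpois(24 * 24 * 4, 60), c(24, 24, 4)) + 100L
  stack <- frame_stack(frames, camera_model())
  p1 <- predict_maps(m, stack)
  p2 <- predict_maps(m, stack)
  expect_identical(p1$maps, p2$maps)
  expect_true(all(p1$maps >= 0))
  expect_equal(dim(p1$maps), c(48, 48, 4))
  # permuting the frame order permutes the outputs identically
  perm <- c(3, 1, 4, 2)
  p3 <- predict_maps(m, frame_stack(frames[, , perm], camera_model()))
  expect_equal(p3$maps, p1$maps[, , perm])
})

# synthetic prediction maps with a known blob count per map; blobs keep a
# minimum separation so every blob is its own local maximum
synthetic_maps <- function(n_maps = 30, blobs_per_map = 40, seed = 17) {
  hdpaint:::with_seed(seed, {
    maps <- array(0, c(128, 128, n_maps))
    for (k in seq_len(n_maps)) {
      m <- matrix(0, 128, 128)
      xy <- matrix(0, 0, 2)
      while (nrow(xy) < blobs_per_map) {
        p <- runif(2, 4, 124)
        if (!nrow(xy) || min((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2) > 25)
          xy <- rbind(xy, p)
      }
      amp <- runif(blobs_per_map, 0.5, 3)
      for (j in seq_len(blobs_per_map))
        m <- m + amp[j] * hdpaint:::cpp_render_spot(xy[j, 1], xy[j, 2],
                                                    4, 1.0, 128, 128)
      maps[, , k] <- m
    }
    structure(list(maps = maps, upsampling = 8,
                   frames = seq_len(n_maps) - 1L, pixel_size_nm = 157,
                   frame_size_px = c(16, 16), n_frames = n_maps,
                   threshold = NA_real_),
              class = "prediction_maps")
  })
}

test_that("threshold calibration reproduces a reference count within 2%", {
  maps <- synthetic_maps()
  cand <- hdpaint:::map_candidates(maps)
  # count vs threshold is non-increasing (bisection precondition)
  ts <- seq(0, max(cand$candidates$value), length.out = 30)
  counts <- vapply(ts, function(t) hdpaint:::count_at_threshold(cand, t),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # fixed point: reference constructed at a known threshold
  t0 <- stats::quantile(cand$candidates$value, 0.4, names = FALSE)
  ref <- hdpaint:::count_at_threshold(cand, t0)
  thr <- calibrate_threshold(cand, ref)
  n_thr <- hdpaint:::count_at_threshold(cand, thr)
  expect_lt(abs(n_thr - ref) / ref, 0.02)
  # known emitter total: calibrated extraction yields it within 2%
  total <- 30 * 40
  thr2 <- calibrate_threshold(cand, total)
  locs <- extract_localizations(cand, thr2)
  expect_lt(abs(nrow(locs) - total) / total, 0.02)
  # unattainable reference falls back to zero with a warning
  expect_warning(z <- calibrate_threshold(cand, 10 * nrow(cand$candidates)),
                 "unattainable")
  expect_equal(z, 0)
})

test_that("extraction uses local-averaging centroids and window mass", {
  m <- matrix(0, 32, 32)
  m[10, 12] <- 5 # single pixel: row 10 = y, col 12 = x (1-based)
  maps <- structure(list(maps = array(m, c(32, 32, 1)), upsampling = 8,
                         frames = 0L, pixel_size_nm = 157,
                         frame_size_px = c(4, 4), n_frames = 1,
                         threshold = NA_real_),
                    class = "prediction_maps")
  locs <- extract_localizations(maps, 1)
  expect_equal(nrow(locs), 1)
  expect_equal(locs$x, 11.5 / 8) # pixel center (0-based 11 + 0.5) / u
  expect_equal(locs$y, 9.5 / 8)
  expect_equal(locs$photons, 5)

  # asymmetric 3x3 blob: centroid equals the hand-computed weighted mean
  m2 <- matrix(0, 32, 32)
  m2[9:11, 11:13] <- matrix(c(1, 2, 1, 2, 6, 1, 1, 1, 1), 3, byrow = TRUE)
  maps$maps <- array(m2, c(32, 32, 1))
  locs2 <- extract_localizations(maps, 3)
  w <- matrix(c(1, 2, 1, 2, 6, 1, 1, 1, 1), 3, byrow = TRUE)
  cx <- sum(w %*% diag(c(10.5, 11.5, 12.5))) / sum(w)
  cy <- sum(diag(c(8.5, 9.5, 10.5)) %*% w) / sum(w)
  expect_equal(nrow(locs2), 1)
  expect_equal(locs2$x * 8, cx)
  expect_equal(locs2$y * 8, cy)
  expect_equal(locs2$photons, sum(w))

  # two maxima farther apart than the neighborhood give two rows
  m3 <- matrix(0, 32, 32)
  m3[5, 5] <- 2; m3[20, 25] <- 3
  maps$maps <- array(m3, c(32, 32, 1))
  expect_equal(nrow(extract_localizations(maps, 1)), 2)
  # all-zero map above threshold: nothing extracted
  maps$maps <- array(0, c(32, 32, 1))
  expect_equal(nrow(extract_localizations(maps, 0.5)), 0)
})

test_that("a frame sweep at the full count matches a direct full run", {
  m <- tiny_model()
  # frames with real emitters so the model has something to find
  cam <- camera_model()
  set.seed(13)
  frames <- array(0L, c(24, 24, 8))
  gt_rows <- list()
  for (f in 1:8) {
    xy <- cbind(runif(3, 3, 21), runif(3, 3, 21))
    ph <- matrix(10, 24, 24)
    for (j in 1:3)
      ph <- ph + hdpaint:::cpp_render_spot(xy[j, 1], xy[j, 2], 2000, 1.2,
                                           24, 24)
    adu <- ph * cam$em_gain * cam$quantum_efficiency / cam$sensitivity +
      cam$baseline_offset
    frames[, , f] <- as.integer(round(adu + rnorm(576, 0, 3)))
    gt_rows[[f]] <- data.frame(frame = f - 1L, x = xy[, 1], y = xy[, 2])
  }
  stack <- frame_stack(frames, cam)
  gt <- quick_locs(do.call(rbind, gt_rows), W = 24, n_frames = 8)
  sw <- frame_sweep(m, stack, gt, frame_counts = c(4, 8), oversampling = 2)
  expect_equal(nrow(sw), 2)
  expect_true(all(is.finite(sw$pcc)))
  # the k = n_frames row equals a direct full-stack extraction
  cand <- predict_candidates(m, stack)
  thr <- calibrate_threshold(cand, nrow(gt))
  expect_equal(sw$n_locs[2], nrow(extract_localizations(cand, thr)))
})

test_that("chunked candidate collection matches single-shot prediction", {
  m <- tiny_model()
  set.seed(11)
  frames <- array(rpois(24 * 24 * 7, 60), c(24, 24, 7)) + 100L
  stack <- frame_stack(frames, camera_model())
  a <- hdpaint:::map_candidates(predict_maps(m, stack))
  b <- predict_candidates(m, stack, chunk = 3)
  expect_equal(a$candidates, b$candidates, ignore_attr = TRUE)
})
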