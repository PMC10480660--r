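test_that("spot detection finds isolated emitters and nothing on flat frames", {
  expect_equal(nrow(detect_spots(matrix(0, 40, 40), 7, 10)), 0)

  img <- hdpaint:::cpp_render_spot(20.5, 30.5, 3000, 1.2, 40, 40)
  hits <- detect_spots(img, 7, 10)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$row, hits$col), c(30, 20)) # 0-based (row=y, col=x)

  # two spots far apart -> both found at the right pixels (exhaustive check)
  img2 <- hdpaint:::cpp_render_spot(8.5, 9.5, 3000, 1.2, 40, 40) +
    hdpaint:::cpp_render_spot(30.5, 28.5, 3000, 1.2, 40, 40)
  hits2 <- detect_spots(img2, 7, 10)
  expect_equal(nrow(hits2), 2)
  truth <- rbind(c(9, 8), c(28, 30))
  found <- as.matrix(hits2[order(hits2$row), c("row", "col")])
  expect_true(all(abs(found - truth) <= 1))
})

test_that("integrated-Gaussian MLE recovers noiseless spots exactly", {
  roi <- hdpaint:::cpp_render_spot(3.5, 3.5, 5000, 1.2, 7, 7) + 10
  fit <- fit_spot_mle(roi)
  expect_lt(abs(fit$x - 3.5), 1e-6) # symmetric spot: exact center
  expect_lt(abs(fit$y - 3.5), 1e-6)

  roi2 <- hdpaint:::cpp_render_spot(3.3, 3.6, 5000, 1.2, 7, 7) + 10
  fit2 <- fit_spot_mle(roi2)
  expect_lt(abs(fit2$x - 3.3), 1e-3)
  expect_lt(abs(fit2$y - 3.6), 1e-3)
  expect_lt(abs(fit2$photons / 5000 - 1), 0.02)
  expect_lt(abs(fit2$sx - 1.2), 0.02)
})

test_that("MLE precision approaches the Mortensen bound under Poisson noise", {
  cam <- camera_model(em_gain = 1, quantum_efficiency = 1) # no excess noise
  mu <- hdpaint:::cpp_render_spot(3.65, 3.8, 5000, 1.2, 7, 7) + 10
  res <- hdpaint:::with_seed(21, t(vapply(1:200, function(i) {
    roi <- matrix(rpois(49, mu), 7, 7)
    unlist(fit_spot_mle(roi, cam)[c("x", "y", "photons", "lpx")])
  }, numeric(4))))
  rmse_x <- sqrt(mean((res[, 1] - 3.65)^2))
  expect_lt(rmse_x, 1.2 * mean(res[, 4]))
  expect_lt(abs(mean(res[, 3]) / 5000 - 1), 0.02)
})

test_that("table filtering drops out-of-range rows and is idempotent", {
  df <- data.frame(frame = 0:9, x = 1:10, y = 1:10, photons = 1000, bg = 5,
                   sx = c(rep(1.2, 7), 0.3, 2.5, 1.1),
                   sy = 1.2, lpx = 0.05, lpy = 0.05)
  tb <- quick_locs(df)
  expect_equal(nrow(filter_table(tb)), 8)
  all_in <- filter_table(tb, sx = c(0, 10), sy = c(0, 10),
                         lpx = c(0, 10), lpy = c(0, 10))
  expect_equal(as.data.frame(all_in), as.data.frame(tb))
  once <- filter_table(tb)
  expect_equal(as.data.frame(filter_table(once)), as.data.frame(once))
  expect_warning(filter_table(tb, sx = c(9, 10)), "all localizations")
})

test_that("NeNA recovers the localization precision of jittered emitters", {
  for (sig in c(0.10, 0.30)) {
    est <- estimate_nena(jitter_table(sig))
    tol <- if (sig == 0.10) 0.02 else 0.05
    expect_lt(abs(est$nena_px - sig), tol)
  }
  # scale equivariance: doubling the jitter doubles the estimate
  a <- estimate_nena(jitter_table(0.08, seed = 5))$nena_px
  b <- estimate_nena(jitter_table(0.16, seed = 5))$nena_px
  expect_lt(abs(b / a - 2), 0.3)
  expect_error(estimate_nena(quick_locs(
    data.frame(frame = 0, x = 1, y = 1))), "2 frames")
})

test_that("linking merges within the dark-time budget and not beyond", {
  df <- data.frame(frame = c(1, 2, 10, 16, 20, 27),
                   x = c(5, 5.05, 10, 10.02, 20, 20.01),
                   y = c(5, 5.02, 10, 10.01, 20, 20))
  tb <- quick_locs(df)
  lk <- link_localizations(tb, radius_px = 0.3, max_dark_frames = 5)
  # frames 1+2 merge; 10+16 merge (dark time exactly 5); 20+27 stay apart
  expect_equal(nrow(lk), 4)
  expect_equal(sort(lk$n_linked), c(1, 1, 2, 2))
  m <- lk[lk$frame == 1, ]
  expect_equal(m$photons, 2000)          # photons summed
  expect_equal(m$x, mean(c(5, 5.05)))    # equal weights -> plain mean
  expect_equal(m$frame, 1)               # first frame of the chain

  # blinking traces: on 3 frames, dark gaps <= 5 -> one row per trace
  traces <- hdpaint:::with_seed(31, {
    do.call(rbind, lapply(1:40, function(k) {
      x0 <- runif(1, 3, 29); y0 <- runif(1, 3, 29)
      f0 <- sample(0:50, 1)
      bursts <- c(f0, f0 + 1, f0 + 2, f0 + 2 + sample(1:6, 1) + 0:1)
      data.frame(frame = bursts, x = x0 + rnorm(length(bursts), 0, 0.02),
                 y = y0 + rnorm(length(bursts), 0, 0.02), trace = k)
    }))
  })
  tb2 <- quick_locs(traces[order(traces$frame),
                           c("frame", "x", "y")], n_frames = 70)
  lk2 <- link_localizations(tb2, radius_px = 0.3, max_dark_frames = 5)
  expect_lte(nrow(lk2), 40 / 0.95) # >= 95% of traces collapse to one row
})

test_that("RCC recovers linear drift and is a no-op on undrifted data", {
  fx <- localized_fixture()
  locs <- fx$locs
  nf <- 2000
  drift <- cbind(2 * (0:(nf - 1)) / (nf - 1), 0.5 * (0:(nf - 1)) / (nf - 1))
  dr <- locs
  dr$x <- dr$x + drift[dr$frame + 1, 1]
  dr$y <- dr$y + drift[dr$frame + 1, 2]
  dr <- hdpaint:::relabel_locs(dr, locs)
  res <- rcc_drift_correct(dr, segment_frames = 200)
  err <- res$trajectory - sweep(drift, 2, drift[1, ])
  expect_lt(sqrt(mean(err^2)), 0.2)

  null <- rcc_drift_correct(locs, segment_frames = 200)
  expect_lt(max(abs(null$trajectory)), 0.1)
  # correction must not degrade the precision estimate
  n0 <- estimate_nena(dr)$nena_px
  n1 <- estimate_nena(res$table)$nena_px
  expect_lt(n1, n0 * 1.05)
})

test_that("raw-frame cross-correlation recovers a constant shift", {
  st <- generate_structure("filaments", 7.5, seed = 11)
  ev <- sample_binding_events(st, 1.3, 50, seed = 12)
  base <- render_frames(ev, camera = camera_model(), seed = 13)
  # physically drifted re-acquisition: same events, positions moved 1.5 px
  ev2 <- ev
  ev2$events$x_nm <- ev2$events$x_nm + 1.5 * 157
  moved <- render_frames(ev2, camera = camera_model(), seed = 14)
  frames <- base$frames
  frames[, , 2:50] <- moved$frames[, , 2:50]
  drifted <- frame_stack(frames, base$camera)

  res <- frame_xcorr_drift(drifted)
  rel <- res$trajectory[-1, 1] - res$trajectory[1, 1]
  expect_lt(abs(mean(rel) - 1.5), 0.1)

  # fixed point: correcting then re-estimating leaves little residual
  res2 <- frame_xcorr_drift(res$stack)
  expect_lt(mean(abs(res2$trajectory[-1, 1] - res2$trajectory[1, 1])), 0.3)

  null <- frame_xcorr_drift(base)
  expect_lt(mean(abs(null$trajectory)), 0.3)
})

test_that("rendering conserves counts on the oversampled grid", {
  tb <- quick_locs(data.frame(frame = 0, x = 10.3, y = 20.7))
  img <- render_locs(tb, 16)
  expect_equal(sum(img), 1)
  expect_equal(attr(img, "rendered_pixel_nm"), 157 / 16)
  expect_equal(dim(img), c(32 * 16, 32 * 16))
  # interior blur preserves mass
  tb2 <- quick_locs(data.frame(frame = 0, x = 16.2, y = 15.8))
  img2 <- render_locs(tb2, 8, blur_sigma_px = 1)
  expect_lt(abs(sum(img2) - 1), 1e-3)
  # empty table renders a zero image
  expect_equal(sum(render_locs(quick_locs(
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0)),
    n_frames = 1), 4)), 0)
})

test_that("localize_stack recovers isolated active emitters at low density", {
  fx <- localized_fixture()
  truth <- fx$stack$true_locs
  locs <- fx$locs
  frames <- 0:299
  matched <- 0; tot <- 0; fp <- 0; det <- 0
  for (f in frames) {
    a <- truth[truth$frame == f, ]
    b <- locs[locs$frame == f, ]
    if (nrow(a)) {
      # single-emitter MLE only claims emitters whose fit box is free of
      # neighbours; overlapping-PSF frames belong to the network instead
      inter <- a$x > 4 & a$x < 44 & a$y > 4 & a$y < 44
      dmin <- if (nrow(a) > 1)
        apply(as.matrix(dist(cbind(a$x, a$y))) + diag(Inf, nrow(a)), 1, min)
      else Inf
      aa <- a[inter & dmin > 7, ]
      tot <- tot + nrow(aa)
      if (nrow(aa) && nrow(b)) {
        d2 <- outer(aa$x, b$x, "-")^2 + outer(aa$y, b$y, "-")^2
        matched <- matched + sum(apply(d2, 1, min) < 1)
      }
    }
    if (nrow(b)) {
      det <- det + nrow(b)
      if (nrow(a)) {
        d2 <- outer(b$x, a$x, "-")^2 + outer(b$y, a$y, "-")^2
        fp <- fp + sum(apply(d2, 1, min) > 1.5^2)
      } else fp <- fp + nrow(b)
    }
  }
  expect_gt(tot, 500)
  expect_gt(matched / tot, 0.95)  # recall on isolated emitters
  expect_lt(fp / det, 0.05)       # false positives after filtering
})
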