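make_low_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- generate_structure("filaments", 6, seed = 21)
      ev <- sample_binding_events(st, 0.109, 800, seed = 22)
      cache <<- render_frames(ev, camera = camera_model(), seed = 23)
    }
    cache
  }
})

test_that("patch extraction re-expresses labels in the patch frame", {
  stack <- make_low_stack()
  ps <- extract_patches(stack, stack$true_locs, patch_px = 17, n = 400,
                        seed = 7)
  expect_equal(dim(ps$patches), c(17, 17, 400))
  # every label must match a truth row shifted by the patch corner
  tl <- stack$true_locs
  ok <- TRUE
  for (i in seq_len(40)) {
    l <- ps$labels[[i]]
    if (!nrow(l)) next
    for (j in seq_len(nrow(l))) {
      frac_match <- any(abs((tl$x - l[j, 1]) %% 1) < 1e-9 |
                          abs((tl$x - l[j, 1]) %% 1 - 1) < 1e-9)
      ok <- ok && frac_match
    }
  }
  expect_true(ok)
  expect_true(all(vapply(ps$labels, function(l)
    !nrow(l) || (min(l) >= 0 && max(l) < 17), logical(1))))
  # determinism
  ps2 <- extract_patches(stack, stack$true_locs, patch_px = 17, n = 400,
                         seed = 7)
  expect_identical(ps$patches, ps2$patches)
  expect_identical(ps$labels, ps2$labels)
})

test_that("mean labels per patch follows density x patch area", {
  stack <- make_low_stack()
  ps <- extract_patches(stack, stack$true_locs, patch_px = 17, n = 3000,
                        seed = 8)
  counts <- vapply(ps$labels, nrow, integer(1))
  # exhaustive-expectation oracle: a localization at (x, y) falls inside a
  # uniformly drawn 17-px patch with probability cov(x) cov(y) / n_corners^2
  # (emitters near the field border are covered by fewer corner choices)
  tl <- stack$true_locs
  n_corners <- dim(stack$frames)[1] - 17 + 1
  cov1 <- function(u) pmax(0, pmin(floor(u), n_corners - 1) -
                              pmax(ceiling(u - 17), 0) + 1)
  expected <- sum(cov1(tl$x) * cov1(tl$y)) / (n_frames(stack) * n_corners^2)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # and the naive density x area arithmetic holds up to the border factor
  naive <- nrow(tl) / n_frames(stack) / 36 * (17 * 0.157)^2
  expect_lt(abs(mean(counts) - naive) / naive, 17 / dim(stack$frames)[1])
})

test_that("summing conserves emitters and photons exactly", {
  stack <- make_low_stack()
  low <- extract_patches(stack, stack$true_locs, patch_px = 17, n = 200,
                         seed = 9)
  hi <- sum_patches(low, k_per_sum = 12, n_out = 150, seed = 10)
  # reproduce the random selection to verify exact conservation
  sel <- hdpaint:::with_seed(10, matrix(sample.int(200, 150 * 12,
                                                   replace = TRUE), 150, 12))
  for (i in c(1, 50, 150)) {
    img <- Reduce(`+`, lapply(sel[i, ], function(j) low$patches[, , j]))
    expect_equal(hi$patches[, , i], img)
    expect_equal(nrow(hi$labels[[i]]),
                 sum(vapply(sel[i, ], function(j) nrow(low$labels[[j]]),
                            integer(1))))
  }
  # k = 1 is the identity on the selected patches
  one <- sum_patches(low, k_per_sum = 1, n_out = 50, seed = 11)
  sel1 <- hdpaint:::with_seed(11, matrix(sample.int(200, 50), 50, 1))
  expect_equal(one$patches[, , 5], low$patches[, , sel1[5, 1]])
})

test_that("summing multiplies the mean density by k", {
  stack <- make_low_stack()
  low <- extract_patches(stack, stack$true_locs, patch_px = 17, n = 2000,
                         seed = 12)
  hi <- sum_patches(low, k_per_sum = 12, n_out = 2000, seed = 13)
  cl <- vapply(low$labels, nrow, integer(1))
  ch <- vapply(hi$labels, nrow, integer(1))
  se <- sqrt(12 * var(cl) / length(ch))
  expect_lt(abs(mean(ch) - 12 * mean(cl)), 3 * se + 0.3)
  expect_equal(patch_density(hi) / patch_density(low), mean(ch) / mean(cl))
})

test_that("background adjustment shifts the median additively", {
  stack <- make_low_stack()
  ps <- extract_patches(stack, stack$true_locs, patch_px = 17, n = 100,
                        seed = 14)
  cur <- median(ps$patches)
  same <- adjust_background(ps, list(median = cur))
  expect_equal(same$patches, ps$patches)
  up <- adjust_background(ps, list(median = cur + 50))
  expect_lt(abs(median(up$patches) - (cur + 50)), 1)
  expect_equal(up$patches - ps$patches,
               array(up$meta$bg_offset, dim(ps$patches)))
  expect_identical(up$labels, ps$labels)
  expect_error(adjust_background(ps, list(median = NaN)), "finite")

  # measured pairs: after adjustment the medians agree closely
  st2 <- generate_structure("filaments", 6, seed = 31)
  hd <- render_frames(sample_binding_events(st2, 1.3, 30, seed = 32),
                      camera = camera_model(), seed = 33, bg_photons = 25)
  tgt <- background_stats(hd)
  adj <- adjust_background(ps, tgt)
  expect_lt(abs(median(adj$patches) - tgt$median), 2)
})

test_that("label maps deposit unit mass at the containing upsampled pixel", {
  patches <- array(0, c(16, 16, 3))
  labels <- list(matrix(numeric(0), 0, 2),
                 matrix(c(8, 8), 1, 2),
                 matrix(c(4.2, 4.21, 7.9, 7.9), 2, 2))
  ps <- patch_set(patches, labels, meta = list(pixel_size_nm = 157))
  maps <- make_label_maps(ps, 8)
  expect_equal(dim(maps), c(128, 128, 3))
  expect_equal(sum(maps[, , 1]), 0)
  expect_equal(sum(maps[, , 2]), 1)
  expect_equal(maps[8 * 8 + 1, 8 * 8 + 1, 2], 1) # row y*u, col x*u (0-based)
  # two labels in the same upsampled pixel accumulate
  expect_equal(sum(maps[, , 3]), 2)
  expect_equal(max(maps[, , 3]), 2)
  # label on the boundary of validity
  bad <- patch_set(patches[, , 1, drop = FALSE],
                   list(matrix(c(8, 8), 1, 2)), meta = list())
  bad$labels[[1]][1] <- 16.5
  expect_error(make_label_maps(bad, 8), "outside")
})

test_that("center cropping keeps geometry consistent", {
  patches <- array(seq_len(17 * 17 * 2), c(17, 17, 2))
  labels <- list(matrix(c(0.2, 5, 0.3, 5), 2, 2, byrow = TRUE),
                 matrix(c(16.8, 10), 1, 2))
  ps <- patch_set(patches, labels, meta = list(patch_px = 17))
  cr <- crop_patches(ps, 16)
  expect_equal(dim(cr$patches), c(16, 16, 2))
  expect_equal(cr$patches[, , 1], patches[1:16, 1:16, 1])
  expect_equal(nrow(cr$labels[[1]]), 2)   # x = 0.2 survives (offset 0)
  expect_equal(nrow(cr$labels[[2]]), 0)   # x = 16.8 cropped away
})
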