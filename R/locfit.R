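#' Detect candidate spots in a single frame
#'
#' Net-gradient detection: a candidate is a strict local maximum whose summed
#' gradient projection toward the center, over a `box_px` box, exceeds
#' `min_net_gradient`. Candidates closer than `box_px/2` to a border are
#' discarded.
#'
#' @param frame Numeric matrix (ADU or photons).
#' @param box_px Odd box size >= 5.
#' @param min_net_gradient Detection threshold (same units as the frame).
#' @return Data frame with integer (0-based) `row`, `col` and `net_gradient`.
#' @export
detect_spots <- function(frame, box_px = 7, min_net_gradient = 5000) {
  stopifnot(box_px %% 2 == 1, box_px >= 5)
  m <- cpp_detect_net_gradient(frame, box_px, min_net_gradient)
  data.frame(row = as.integer(m[, 1]), col = as.integer(m[, 2]),
             net_gradient = m[, 3])
}

# Mortensen MLE precision for a pixel-integrated Gaussian, optionally with
# the EMCCD excess-noise factor 2 (em_gain > 1). Pixel units (a = 1).
mortensen_precision <- function(sigma_px, photons, bg, excess = 1) {
  sa2 <- sigma_px^2 + 1 / 12
  v <- excess * (sa2 / photons) * (16 / 9 + 8 * pi * sa2 * bg / photons)
  sqrt(pmax(v, 0))
}

#' Fit one spot by integrated-Gaussian MLE
#'
#' Maximizes the Poisson likelihood of a pixel-integrated 2-D Gaussian over
#' a photon-converted ROI (Fisher-scoring updates on x, y, photons,
#' background, sx, sy). Localization precision `lpx`, `lpy` follows the
#' Mortensen MLE formula from the fitted photon count, background and
#' widths; when the camera uses electron multiplication the excess-noise
#' factor 2 is included.
#'
#' @param roi Square matrix in photon units.
#' @param camera A [camera_model()]; only the EM setting is consulted for
#'   the precision formula.
#' @param max_iter,tol Fisher-scoring controls.
#' @return One-row data frame (x, y in ROI coordinates, photons, bg, sx, sy,
#'   lpx, lpy, converged).
#' @export
fit_spot_mle <- function(roi, camera = camera_model(), max_iter = 100,
                         tol = 1e-4) {
  r <- cpp_fit_roi(roi, max_iter, tol, TRUE, 1.2)
  excess <- if (camera$em_gain > 1) 2 else 1
  data.frame(x = r[1], y = r[2], photons = r[3], bg = r[4], sx = r[5],
             sy = r[6],
             lpx = mortensen_precision(r[5], r[3], r[4], excess),
             lpy = mortensen_precision(r[6], r[3], r[4], excess),
             converged = r[7] > 0)
}

#' Localize a full stack
#'
#' Runs net-gradient detection and integrated-Gaussian MLE fitting on every
#' frame. ROIs are converted from ADU to photons via the camera gains before
#' fitting; non-converged fits are dropped.
#'
#' @param stack A `frame_stack`.
#' @param box_px Fit/detection box (odd).
#' @param min_net_gradient Detection threshold in photon units.
#' @param camera Camera used for photon conversion (default: the stack's).
#' @return A [loc_table()].
#' @export
localize_stack <- function(stack, box_px = 7, min_net_gradient = 400,
                           camera = NULL) {
  if (is.null(camera)) camera <- stack$camera
  nf <- n_frames(stack)
  H <- dim(stack$frames)[1]; W <- dim(stack$frames)[2]
  rad <- box_px %/% 2
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- adu_to_photons(stack$frames[, , f], camera)
    cand <- cpp_detect_net_gradient(img, box_px, min_net_gradient)
    if (!nrow(cand)) next
    rois <- array(0, c(box_px, box_px, nrow(cand)))
    for (i in seq_len(nrow(cand))) {
      r0 <- cand[i, 1] - rad + 1; c0 <- cand[i, 2] - rad + 1
      rois[, , i] <- img[r0:(r0 + box_px - 1), c0:(c0 + box_px - 1)]
    }
    fit <- cpp_fit_rois(rois, 100, 1e-4, TRUE, 1.2)
    # keep finite fits that stayed inside the ROI; the convergence flag alone
    # does not invalidate a settled fit, and hard failures run off the box
    ok <- apply(is.finite(fit), 1, all) &
      fit[, 1] > 0.5 & fit[, 1] < box_px - 0.5 &
      fit[, 2] > 0.5 & fit[, 2] < box_px - 0.5
    if (!any(ok)) next
    fit <- fit[ok, , drop = FALSE]
    cand <- cand[ok, , drop = FALSE]
    excess <- if (camera$em_gain > 1) 2 else 1
    rows[[f]] <- data.frame(
      frame = f - 1L,
      x = cand[, 2] - rad + fit[, 1],
      y = cand[, 1] - rad + fit[, 2],
      photons = fit[, 3], bg = fit[, 4], sx = fit[, 5], sy = fit[, 6],
      lpx = mortensen_precision(fit[, 5], fit[, 3], fit[, 4], excess),
      lpy = mortensen_precision(fit[, 6], fit[, 3], fit[, 4], excess))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               photons = numeric(0), bg = numeric(0), sx = numeric(0),
               sy = numeric(0), lpx = numeric(0), lpy = numeric(0))
  df <- df[df$x >= 0 & df$x <= W & df$y >= 0 & df$y <= H, , drop = FALSE]
  loc_table(df, pixel_size_nm = camera$pixel_size_nm,
            frame_size_px = c(H, W), n_frames = nf, source = "mle-fit")
}

#' Filter a localization table on PSF width and precision
#'
#' Removes rows whose `sx`, `sy`, `lpx` or `lpy` fall outside closed
#' intervals; row order is preserved and the operation is idempotent.
#'
#' @param table A [loc_table()].
#' @param sx,sy Length-2 closed intervals for the PSF widths (px).
#' @param lpx,lpy Length-2 closed intervals for the precision (px).
#' @return The filtered [loc_table()].
#' @export
filter_table <- function(table, sx = c(0.6, 2.0), sy = c(0.6, 2.0),
                         lpx = c(0, 0.3), lpy = c(0, 0.3)) {
  keep <- table$sx >= sx[1] & table$sx <= sx[2] &
          table$sy >= sy[1] & table$sy <= sy[2] &
          table$lpx >= lpx[1] & table$lpx <= lpx[2] &
          table$lpy >= lpy[1] & table$lpy <= lpy[2]
  out <- relabel_locs(table[keep, , drop = FALSE], table)
  if (!nrow(out)) warning("filter removed all localizations")
  out
}

#' Estimate localization precision by nearest-neighbor analysis (NeNA)
#'
#' Computes nearest-neighbor distances between localizations in consecutive
#' frames and fits their histogram with the NeNA model: a 2-D distance
#' distribution for repeated localizations of the same emitter
#' (`d/(2s^2) exp(-d^2/(4s^2))`, variance 2 s^2 per axis for two
#' measurements of precision s) plus a linear background term for unrelated
#' neighbors.
#'
#' @param table A [loc_table()].
#' @param max_dist_px Histogram range (px).
#' @param n_bins Number of histogram bins.
#' @return A `nena_estimate` with element `nena_px` and the fit curve.
#' @export
estimate_nena <- function(table, max_dist_px = 2, n_bins = 80) {
  frames <- sort(unique(table$frame))
  if (length(frames) < 2) stop("need localizations in at least 2 frames")
  byf <- split(data.frame(x = table$x, y = table$y), table$frame)
  dists <- list()
  for (i in seq_len(length(frames) - 1)) {
    if (frames[i + 1] != frames[i] + 1) next
    a <- byf[[as.character(frames[i])]]
    b <- byf[[as.character(frames[i + 1])]]
    if (!nrow(a) || !nrow(b)) next
    d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
    dists[[length(dists) + 1]] <- sqrt(apply(d2, 1, min))
  }
  d <- unlist(dists)
  d <- d[d <= max_dist_px]
  if (length(d) < 50) stop("too few consecutive-frame neighbor pairs for NeNA")
  h <- graphics::hist(d, breaks = seq(0, max_dist_px, length.out = n_bins + 1),
                      plot = FALSE)
  df <- data.frame(r = h$mids, p = h$density)
  s0 <- sqrt(mean(d[d < stats::quantile(d, 0.5)]^2) / 4)
  fit <- minpack.lm::nlsLM(
    p ~ a * (r / (2 * s^2)) * exp(-r^2 / (4 * s^2)) + b * r,
    data = df, start = list(a = 0.8, s = max(s0, 1e-3), b = 0.05),
    lower = c(0, 1e-4, 0), control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  structure(list(nena_px = unname(cf["s"]),
                 fit_curve = cbind(df, fitted = stats::fitted(fit)),
                 coefficients = cf, n_pairs = length(d)),
            class = "nena_estimate")
}

#' @export
print.nena_estimate <- function(x, ...) {
  cat(sprintf("<nena_estimate> precision %.4f px (%d pairs)\n",
              x$nena_px, x$n_pairs))
  invisible(x)
}

#' Link localizations of the same binding event across frames
#'
#' Transitively links localizations that reappear within `radius_px` with
#' dark gaps of at most `max_dark_frames` consecutive frames, and merges
#' every chain to one row: photon-weighted mean position, summed photons,
#' mean background/widths, combined precision, first frame of the chain.
#'
#' @param table A [loc_table()].
#' @param radius_px Link radius (px); the conventional choice is 4x the NeNA
#'   precision.
#' @param max_dark_frames Maximum number of consecutive dark frames inside a
#'   chain (default 5).
#' @return A [loc_table()] with merged rows carrying `link_id` and `n_linked`.
#' @export
link_localizations <- function(table, radius_px, max_dark_frames = 5) {
  stopifnot(radius_px > 0)
  n <- nrow(table)
  if (!n) return(table)
  ord <- order(table$frame)
  tb <- table[ord, , drop = FALSE]
  link <- integer(n)
  # active chains: last x, y, frame, id
  act_x <- numeric(0); act_y <- numeric(0); act_f <- integer(0); act_id <- integer(0)
  next_id <- 1L
  i <- 1L
  while (i <= n) {
    f <- tb$frame[i]
    j <- i
    while (j < n && tb$frame[j + 1] == f) j <- j + 1L
    alive <- act_f >= f - max_dark_frames - 1L
    act_x <- act_x[alive]; act_y <- act_y[alive]
    act_f <- act_f[alive]; act_id <- act_id[alive]
    used <- rep(FALSE, length(act_id))
    for (k in i:j) {
      if (length(act_id)) {
        d2 <- (act_x - tb$x[k])^2 + (act_y - tb$y[k])^2
        d2[used] <- Inf
        best <- which.min(d2)
        if (length(best) && d2[best] <= radius_px^2) {
          link[k] <- act_id[best]
          act_x[best] <- tb$x[k]; act_y[best] <- tb$y[k]; act_f[best] <- f
          used[best] <- TRUE
          next
        }
      }
      link[k] <- next_id
      act_x <- c(act_x, tb$x[k]); act_y <- c(act_y, tb$y[k])
      act_f <- c(act_f, f); act_id <- c(act_id, next_id)
      used <- c(used, TRUE)
      next_id <- next_id + 1L
    }
    i <- j + 1L
  }
  tb$link_id <- link
  merged <- do.call(rbind, lapply(split(tb, tb$link_id), function(g) {
    w <- g$photons / sum(g$photons)
    data.frame(frame = min(g$frame),
               x = sum(w * g$x), y = sum(w * g$y),
               photons = sum(g$photons), bg = mean(g$bg),
               sx = mean(g$sx), sy = mean(g$sy),
               lpx = sqrt(sum((w * g$lpx)^2)),
               lpy = sqrt(sum((w * g$lpy)^2)),
               link_id = g$link_id[1], n_linked = nrow(g))
  }))
  merged <- merged[order(merged$frame, merged$x), , drop = FALSE]
  rownames(merged) <- NULL
  relabel_locs(merged, table, source = "linked")
}

# cross-correlation shift between two images by FFT, with sub-pixel
# refinement by local matrix-DFT upsampling around the integer peak (avoids
# the peak-locking bias of 3-point parabolic interpolation).
xcorr_shift <- function(a, b, method = c("xcorr", "phase"),
                        refine_step = 0.02, refine_halfwidth = 1) {
  method <- match.arg(method)
  H <- nrow(a); W <- ncol(a)
  A <- fft(a - mean(a)); B <- fft(b - mean(b))
  CP <- A * Conj(B)
  if (method == "phase") {
    mag <- Mod(CP)
    CP <- CP / (mag + 1e-9 * max(mag))
  }
  cc <- Re(fft(CP, inverse = TRUE)) / (H * W)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dr0 <- pk[1] - 1; dc0 <- pk[2] - 1
  if (dr0 > H / 2) dr0 <- dr0 - H
  if (dc0 > W / 2) dc0 <- dc0 - W
  # evaluate cc on a fine local grid: cc(dy,dx) ~ Re(t(Er) CP Ec)
  kr <- c(0:floor((H - 1) / 2), -(ceiling((H - 1) / 2):1)) # signed freqs
  kc <- c(0:floor((W - 1) / 2), -(ceiling((W - 1) / 2):1))
  dys <- dr0 + seq(-refine_halfwidth, refine_halfwidth, by = refine_step)
  dxs <- dc0 + seq(-refine_halfwidth, refine_halfwidth, by = refine_step)
  Er <- exp(outer(dys, kr) * (2i * pi / H))       # ny x H
  Ec <- exp(outer(kc, dxs) * (2i * pi / W))       # W x nx
  ccf <- Re(Er %*% CP %*% Ec)
  pf <- which(ccf == max(ccf), arr.ind = TRUE)[1, ]
  # cc peak at (dy, dx) means a is b shifted by (+dy rows, +dx cols)
  c(dx = dxs[pf[2]], dy = dys[pf[1]])
}

#' Redundant cross-correlation (RCC) drift correction
#'
#' Renders the table in temporal segments, estimates all pairwise shifts
#' between segment images by cross-correlation with sub-pixel refinement,
#' solves the over-determined linear system for per-segment drift by least
#' squares, interpolates per frame, and subtracts the trajectory from the
#' coordinates.
#'
#' @param table A [loc_table()].
#' @param segment_frames Frames per segment (default 200).
#' @param oversampling Rendering oversampling for the segment images.
#' @return List with `table` (corrected) and `trajectory` (n_frames x 2,
#'   px, first frame at zero by convention).
#' @export
rcc_drift_correct <- function(table, segment_frames = 200, oversampling = 4) {
  nf <- attr(table, "n_frames")
  if (nf < 2 * segment_frames)
    stop("need at least two segments: n_frames < 2 * segment_frames")
  n_seg <- nf %/% segment_frames
  bounds <- floor(seq(0, nf, length.out = n_seg + 1))
  centers <- (head(bounds, -1) + tail(bounds, -1)) / 2
  imgs <- lapply(seq_len(n_seg), function(s) {
    rows <- table$frame >= bounds[s] & table$frame < bounds[s + 1]
    seg <- relabel_locs(table[rows, , drop = FALSE], table)
    cpp_gauss_blur(render_locs(seg, oversampling), 1)
  })
  pairs <- utils::combn(n_seg, 2)
  shifts <- apply(pairs, 2, function(p)
    xcorr_shift(imgs[[p[2]]], imgs[[p[1]]]) / oversampling)
  # least squares: d[j] - d[i] = shift_ij, d[1] = 0
  A <- matrix(0, ncol(pairs), n_seg - 1)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (j > 1) A[k, j - 1] <- 1
    if (i > 1) A[k, i - 1] <- -1
  }
  sol <- qr.solve(A, t(shifts))          # (n_seg-1) x 2
  d_seg <- rbind(c(0, 0), sol)
  fr <- seq_len(nf) - 1
  traj <- cbind(approx(centers, d_seg[, 1], xout = fr, rule = 2)$y,
                approx(centers, d_seg[, 2], xout = fr, rule = 2)$y)
  traj <- sweep(traj, 2, traj[1, ])
  out <- table
  out$x <- out$x - traj[out$frame + 1L, 1]
  out$y <- out$y - traj[out$frame + 1L, 2]
  list(table = relabel_locs(out, table, source = "rcc-corrected"),
       trajectory = traj)
}

#' Raw-frame drift correction by cross-correlation
#'
#' Estimates the lateral drift of a raw stack from sub-pixel
#' cross-correlation of consecutive frames and integrates the increments
#' into a per-frame trajectory (in transient-binding data, consecutive
#' frames share most of their active emitters, giving a sharp correlation
#' peak that a fixed distant reference frame does not). Frames are then
#' resampled by bilinear interpolation. Intended for high-density stacks
#' ahead of network prediction.
#'
#' @param stack A `frame_stack`.
#' @param reference `"mean"` (every frame against the blurred stack mean,
#'   default) or `"first"` (against frame 1).
#' @param smooth_frames Temporal running-mean window applied to the raw
#'   trajectory (0 = none); single-frame estimates on transient-binding
#'   data carry constellation noise that temporal smoothing suppresses when
#'   the physical drift is slow.
#' @return List with `stack` (resampled) and `trajectory` (n_frames x 2 px).
#' @export
frame_xcorr_drift <- function(stack, reference = c("mean", "first"),
                              smooth_frames = 0) {
  reference <- match.arg(reference)
  nf <- n_frames(stack)
  stopifnot(nf >= 2)
  ref <- cpp_gauss_blur(
    if (reference == "mean") mean_image(stack) else stack$frames[, , 1], 1)
  traj <- matrix(0, nf, 2)
  for (i in seq_len(nf))
    traj[i, ] <- xcorr_shift(cpp_gauss_blur(stack$frames[, , i], 1), ref)
  if (max(abs(traj)) == 0) warning("no shift detected; featureless frames?")
  if (smooth_frames > 1) {
    k <- rep(1 / smooth_frames, smooth_frames)
    traj[, 1] <- stats::filter(traj[, 1], k, sides = 2)
    traj[, 2] <- stats::filter(traj[, 2], k, sides = 2)
    traj[is.na(traj)] <- 0
  }
  traj <- sweep(traj, 2, traj[1, ])
  out <- stack$frames
  for (i in seq_len(nf)) {
    if (any(traj[i, ] != 0))
      out[, , i] <- cpp_shift_bilinear(stack$frames[, , i],
                                       -traj[i, 1], -traj[i, 2])
  }
  corrected <- frame_stack(array(as.integer(round(out)), dim(out)),
                           stack$camera, stack$true_locs)
  list(stack = corrected, trajectory = traj)
}
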