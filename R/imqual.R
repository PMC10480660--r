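#' Preprocess a GT/prediction image pair for comparison
#'
#' If the shapes differ, the second image is bilinearly resampled to the
#' first image's grid. Both images then receive a 2-px Gaussian blur and
#' are min-max scaled and quantized to 8-bit (0..255). Non-constant inputs
#' map their extrema exactly to 0 and 255.
#'
#' @param gt_image,pred_image Numeric matrices.
#' @param blur_sigma_px Blur applied before quantization (default 2).
#' @return List with `gt8`, `pred8` (integer-valued matrices) and the
#'   preprocessing record.
#' @export
preprocess_pair <- function(gt_image, pred_image, blur_sigma_px = 2) {
  if (!all(dim(gt_image) == dim(pred_image)))
    pred_image <- cpp_resize_bilinear(pred_image, nrow(gt_image), ncol(gt_image))
  to8 <- function(img) {
    img <- cpp_gauss_blur(img, blur_sigma_px)
    rng <- range(img)
    if (rng[2] == rng[1]) {
      warning("constant image maps to all zeros")
      return(matrix(0, nrow(img), ncol(img)))
    }
    round((img - rng[1]) / (rng[2] - rng[1]) * 255)
  }
  list(gt8 = to8(gt_image), pred8 = to8(pred_image),
       record = list(blur_sigma_px = blur_sigma_px, bit_depth = 8L))
}

#' Foreground mask of the target structure
#'
#' Otsu global threshold on the (already blurred) 8-bit GT image, followed
#' by a 3x3 morphological closing; used to restrict similarity metrics to
#' the structure.
#'
#' @param gt8 8-bit image (matrix of integers 0..255).
#' @return Logical matrix.
#' @export
make_mask <- function(gt8) {
  v <- as.vector(gt8)
  counts <- tabulate(v + 1L, nbins = 256)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  thr <- which.max(sigma_b) - 1L
  mask <- gt8 > thr
  # 3x3 closing: dilation then erosion
  dil <- cpp_mean_filter(mask * 1, 3) > 1e-9
  mask <- cpp_mean_filter(dil * 1, 3) > 1 - 1e-9
  if (!any(mask)) stop("empty foreground mask")
  mask
}

# SSIM map with an 11x11 Gaussian window (sigma 1.5), standard constants,
# dynamic range L. Returns mean SSIM and mean contrast-structure term.
ssim_pair <- function(a, b, L = 255, win = 11, sigma = 1.5) {
  K1 <- 0.01; K2 <- 0.03
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  rad <- (win - 1) / 2
  k1 <- exp(-0.5 * ((-rad:rad) / sigma)^2); k1 <- k1 / sum(k1)
  # valid-region filtering via separable convolution
  f <- function(img) {
    a1 <- apply(img, 2, function(cc) as.numeric(stats::filter(cc, k1, sides = 2)))
    t(apply(a1, 1, function(rr) as.numeric(stats::filter(rr, k1, sides = 2))))
  }
  mu_a <- f(a); mu_b <- f(b)
  saa <- f(a * a) - mu_a^2; sbb <- f(b * b) - mu_b^2
  sab <- f(a * b) - mu_a * mu_b
  l <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  cs <- (2 * sab + C2) / (saa + sbb + C2)
  valid <- !is.na(l) & !is.na(cs)
  list(ssim = mean((l * cs)[valid]), cs = mean(cs[valid]),
       lum = mean(l[valid]))
}

#' Similarity metrics between two 8-bit images
#'
#' Pearson correlation (optionally mask-restricted), SSIM (11x11 Gaussian
#' window, sigma 1.5, standard constants, dynamic range 255), MS-SSIM with
#' the canonical 5-scale weights, mean absolute error, and PSNR
#' (10 log10(255^2 / MSE); +Inf for identical images).
#'
#' @param gt8,pred8 Equal-shape 8-bit images (see [preprocess_pair()]).
#' @param mask Optional logical matrix restricting PCC and MAE.
#' @return A `metric_report` list: pcc, ssim, ms_ssim, mae, psnr_db and the
#'   preprocessing/mask record.
#' @export
similarity_metrics <- function(gt8, pred8, mask = NULL) {
  stopifnot(all(dim(gt8) == dim(pred8)))
  a <- as.numeric(gt8); b <- as.numeric(pred8)
  if (!is.null(mask)) {
    av <- a[mask]; bv <- b[mask]
  } else { av <- a; bv <- b }
  pcc <- if (sd(av) == 0 || sd(bv) == 0) NA_real_ else cor(av, bv)
  mae <- mean(abs(av - bv))
  mse <- mean((a - b)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(255^2 / mse)
  ss <- ssim_pair(gt8, pred8)
  # MS-SSIM, 5 scales: product of cs^w at scales 1..4 and (l*cs)^w at scale 5
  w <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  a2 <- gt8; b2 <- pred8; msv <- 1
  down2 <- function(img) {
    H <- nrow(img) %/% 2; W <- ncol(img) %/% 2
    img <- img[seq_len(2 * H), seq_len(2 * W)]
    (img[seq(1, 2 * H, 2), seq(1, 2 * W, 2)] +
     img[seq(2, 2 * H, 2), seq(1, 2 * W, 2)] +
     img[seq(1, 2 * H, 2), seq(2, 2 * W, 2)] +
     img[seq(2, 2 * H, 2), seq(2, 2 * W, 2)]) / 4
  }
  ms_ssim <- NA_real_
  if (min(dim(gt8)) >= 11 * 2^4) {
    for (s in 1:5) {
      sp <- ssim_pair(a2, b2)
      msv <- msv * (if (s < 5) max(sp$cs, 0) else max(sp$ssim, 0))^w[s]
      if (s < 5) { a2 <- down2(a2); b2 <- down2(b2) }
    }
    ms_ssim <- msv
  }
  structure(list(pcc = pcc, ssim = ss$ssim, ms_ssim = ms_ssim, mae = mae,
                 psnr_db = psnr,
                 record = list(masked = !is.null(mask))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> PCC %.3f  SSIM %.3f  MS-SSIM %s  MAE %.2f  PSNR %.2f dB%s\n",
    x$pcc, x$ssim,
    if (is.na(x$ms_ssim)) "NA" else sprintf("%.3f", x$ms_ssim),
    x$mae, x$psnr_db, if (isTRUE(x$record$masked)) " (masked)" else ""))
  invisible(x)
}

# radial edge apodization (cosine taper over the outer fraction of the field)
apodize <- function(img, fraction = 0.1) {
  H <- nrow(img); W <- ncol(img)
  wr <- function(n) {
    k <- max(2, round(fraction * n))
    w <- rep(1, n)
    ramp <- 0.5 * (1 - cos(pi * (seq_len(k) - 1) / (k - 1)))
    w[seq_len(k)] <- ramp
    w[n + 1 - seq_len(k)] <- ramp
    w
  }
  img_c <- img - mean(img)
  img_c * (wr(H) %o% wr(W))
}

#' Image resolution by decorrelation analysis
#'
#' Parameter-free resolution estimate from the correlation between an
#' image's Fourier transform and its phase-normalized, low-pass-masked
#' version. The decorrelation curve d(r) is computed over `n_radii` mask
#' radii for the raw image and `n_filters` Gaussian high-pass
#' pre-filtered versions; the cutoff frequency is the highest local-maximum
#' position across the curves, and
#' `resolution_nm = 2 * rendered_pixel_nm / cutoff`.
#'
#' @param image Numeric matrix (rendered super-resolution image).
#' @param rendered_pixel_nm Pixel pitch of the image (nm).
#' @param n_radii Number of mask radii in (0, 1].
#' @param n_filters Number of high-pass filter widths.
#' @return A `resolution_estimate`: resolution_nm, cutoff_frequency
#'   (Nyquist = 1), and the family of decorrelation curves. When no
#'   maximum exists the resolution is `NA` (unresolved).
#' @export
decorrelation_resolution <- function(image, rendered_pixel_nm,
                                     n_radii = 50, n_filters = 10) {
  img <- apodize(image)
  H <- nrow(img); W <- ncol(img)
  FI <- fft(img)
  fr <- c(seq(0, floor(H / 2)), seq(ceiling(H / 2) - 1, 1)) / (H / 2)
  fc <- c(seq(0, floor(W / 2)), seq(ceiling(W / 2) - 1, 1)) / (W / 2)
  KR <- sqrt(outer(fr^2, fc^2, "+"))       # normalized |k|, Nyquist = 1
  radii <- seq_len(n_radii) / n_radii
  sigmas <- exp(seq(log(0.05), log(0.5), length.out = n_filters)) # in |k| units
  curve_for <- function(FIh) {
    In <- FIh / pmax(Mod(FIh), 1e-12)
    num0 <- FIh * Conj(In)
    den1 <- sqrt(sum(Mod(FIh)^2))
    vapply(radii, function(r) {
      m <- KR <= r
      nu <- sum(Re(num0[m]))
      de <- den1 * sqrt(sum(m))
      if (de == 0) 0 else nu / de
    }, numeric(1))
  }
  peak_of <- function(d) {
    n <- length(d)
    if (n < 3) return(NA_real_)
    # a curve still rising monotonically through its final quarter signals a
    # flat (noise-like) spectrum carrying information to Nyquist
    tail_i <- ceiling(0.75 * n):n
    if (which.max(d) == n && all(diff(d[tail_i]) >= -1e-6)) return(radii[n])
    # otherwise reject boundary maxima (interpolation/noise replica rises)
    # by stripping trailing points while the maximum sits at the end
    m <- n
    while (m > 2 && which.max(d[1:m]) == m) m <- m - 1
    pk <- which.max(d[1:m])
    if (d[pk] < 0.05) return(NA_real_)
    radii[pk]
  }
  curves <- matrix(0, n_filters + 1, n_radii)
  curves[1, ] <- curve_for(FI)
  for (i in seq_len(n_filters)) {
    Hfilt <- 1 - exp(-KR^2 / (2 * sigmas[i]^2))   # Gaussian high-pass
    curves[i + 1, ] <- curve_for(FI * Hfilt)
  }
  cut <- suppressWarnings(max(apply(curves, 1, peak_of), na.rm = TRUE))
  if (!is.finite(cut) || cut <= 0) {
    res <- NA_real_; cut <- NA_real_
  } else res <- 2 * rendered_pixel_nm / cut
  structure(list(resolution_nm = res, cutoff_frequency = cut,
                 curves = curves, radii = radii, n_filters = n_filters,
                 n_radii = n_radii, rendered_pixel_nm = rendered_pixel_nm),
            class = "resolution_estimate")
}

#' @export
print.resolution_estimate <- function(x, ...) {
  cat(sprintf("<resolution_estimate> %.1f nm (cutoff %.3f x Nyquist, px %.2f nm)\n",
              x$resolution_nm, x$cutoff_frequency, x$rendered_pixel_nm))
  invisible(x)
}

#' Frame-number sufficiency sweep
#'
#' For each frame count k, predicts the first k frames of the high-density
#' stack, calibrates the threshold against the GT count scaled to k,
#' extracts and renders localizations, and computes similarity metrics and
#' decorrelation resolution against the GT render. Used to judge how many
#' input frames are needed for a stable prediction.
#'
#' @param model A trained `dd_model`.
#' @param hd_stack High-density `frame_stack`.
#' @param gt_table Ground-truth [loc_table()].
#' @param frame_counts Ascending frame counts (<= n_frames).
#' @param oversampling Render oversampling for GT and prediction.
#' @param mask Use a structure mask for the metrics.
#' @return Data frame with one row per count: pcc, ssim, ms_ssim, mae,
#'   psnr_db, resolution_gt_nm, resolution_pred_nm, n_locs.
#' @export
frame_sweep <- function(model, hd_stack, gt_table, frame_counts,
                        oversampling = NULL, mask = FALSE) {
  stopifnot(!is.unsorted(frame_counts), max(frame_counts) <= n_frames(hd_stack))
  u <- model$config$upsampling
  if (is.null(oversampling)) oversampling <- u
  gt_img <- render_locs(gt_table, oversampling, blur_sigma_px = 1)
  cand_all <- predict_candidates(model, hd_stack,
                                 seq_len(max(frame_counts)))
  res_gt <- decorrelation_resolution(gt_img, attr(gt_img, "rendered_pixel_nm"))
  out <- lapply(frame_counts, function(k) {
    cand <- cand_all
    cand$candidates <- cand$candidates[cand$candidates$frame < k, , drop = FALSE]
    ref <- nrow(gt_table) * k / attr(gt_table, "n_frames")
    thr <- calibrate_threshold(cand, ref)
    locs <- extract_localizations(cand, thr)
    pred_img <- render_locs(locs, oversampling, blur_sigma_px = 1)
    pp <- preprocess_pair(gt_img, pred_img)
    msk <- if (mask) make_mask(pp$gt8) else NULL
    m <- similarity_metrics(pp$gt8, pp$pred8, msk)
    rp <- decorrelation_resolution(pred_img, attr(gt_img, "rendered_pixel_nm"))
    data.frame(frames = k, n_locs = nrow(locs), pcc = m$pcc, ssim = m$ssim,
               ms_ssim = m$ms_ssim, mae = m$mae, psnr_db = m$psnr_db,
               resolution_gt_nm = res_gt$resolution_nm,
               resolution_pred_nm = rp$resolution_nm)
  })
  do.call(rbind, out)
}
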