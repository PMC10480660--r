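#' Training patch set
#'
#' Paired high-density image patches (photon units) and their emitter
#' coordinate lists, with density and background metadata. Constructed by
#' [extract_patches()] and [sum_patches()].
#'
#' @param patches Numeric array P x P x n (photon units).
#' @param labels List of n matrices with columns x, y (patch-frame px).
#' @param meta List of provenance fields (densities, patch size, seed, ...).
#' @return A `patch_set`.
#' @export
patch_set <- function(patches, labels, meta = list()) {
  stopifnot(length(dim(patches)) == 3, dim(patches)[3] == length(labels))
  P <- dim(patches)[1]
  ok <- vapply(labels, function(l) !nrow(l) ||
                 (all(l[, 1] >= 0) && all(l[, 1] < P) &&
                  all(l[, 2] >= 0) && all(l[, 2] < P)), logical(1))
  if (!all(ok)) stop("label coordinates outside [0, patch_px)")
  structure(list(patches = patches, labels = labels, meta = meta),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  d <- dim(x$patches)
  cat(sprintf("<patch_set> %d patches of %d x %d px, mean %.2f labels/patch\n",
              d[3], d[1], d[2],
              mean(vapply(x$labels, nrow, integer(1)))))
  invisible(x)
}

#' Mean emitter density of a patch set
#'
#' @param ps A [patch_set()].
#' @param pixel_size_nm Camera pixel size; default from meta.
#' @return Mean emitters per µm² per patch.
#' @export
patch_density <- function(ps, pixel_size_nm = NULL) {
  if (is.null(pixel_size_nm)) pixel_size_nm <- ps$meta$pixel_size_nm
  P <- dim(ps$patches)[1]
  area_um2 <- (P * pixel_size_nm / 1000)^2
  mean(vapply(ps$labels, nrow, integer(1))) / area_um2
}

#' Extract random low-density patches from a stack
#'
#' Cuts `n` patches at uniformly random (frame, corner) positions. Patch
#' pixel values are converted to photon units; each patch carries the
#' localization-table rows falling inside it, re-expressed in the patch
#' coordinate frame (a localization at image (x, y) inside a patch with
#' corner (cx, cy) becomes (x - cx, y - cy)).
#'
#' @param stack A `frame_stack`.
#' @param table A [loc_table()] aligned to the stack (fitted positions; pass
#'   `stack$true_locs` for simulator ground truth).
#' @param patch_px Patch side (default 17).
#' @param n Number of patches.
#' @param seed Integer seed.
#' @return A [patch_set()].
#' @export
extract_patches <- function(stack, table, patch_px = 17, n = 1000, seed = 1) {
  H <- dim(stack$frames)[1]; W <- dim(stack$frames)[2]
  stopifnot(patch_px <= H, patch_px <= W)
  nf <- n_frames(stack)
  byframe <- split(seq_len(nrow(table)), table$frame)
  draw <- with_seed(seed, {
    data.frame(f = sample.int(nf, n, replace = TRUE),
               r0 = sample.int(H - patch_px + 1, n, replace = TRUE) - 1L,
               c0 = sample.int(W - patch_px + 1, n, replace = TRUE) - 1L)
  })
  patches <- array(0, c(patch_px, patch_px, n))
  labels <- vector("list", n)
  cam <- stack$camera
  for (i in seq_len(n)) {
    f <- draw$f[i]; r0 <- draw$r0[i]; c0 <- draw$c0[i]
    patches[, , i] <- adu_to_photons(
      stack$frames[r0 + seq_len(patch_px), c0 + seq_len(patch_px), f], cam)
    rows <- byframe[[as.character(f - 1L)]]
    if (is.null(rows)) {
      labels[[i]] <- matrix(0, 0, 2, dimnames = list(NULL, c("x", "y")))
    } else {
      x <- table$x[rows] - c0; y <- table$y[rows] - r0
      inside <- x >= 0 & x < patch_px & y >= 0 & y < patch_px
      labels[[i]] <- cbind(x = x[inside], y = y[inside])
    }
  }
  src_density <- nrow(table) / nf /
    (H * W * (cam$pixel_size_nm / 1000)^2)
  patch_set(patches, labels,
            meta = list(patch_px = patch_px, seed = seed,
                        pixel_size_nm = cam$pixel_size_nm,
                        source_density = src_density, n_summed = 1L,
                        baseline_photons = median(patches)))
}

#' Sum low-density patches into high-density training patches
#'
#' Each output patch is the pixel-wise sum of `k_per_sum` randomly chosen
#' (with replacement) input patches; its label list is the concatenation of
#' the selected label lists. Emitter counts and photons are exactly
#' conserved, so the mean output density is `k_per_sum` times the input
#' density. With the low-density regime of ~0.109 emitters/µm², the default
#' `k_per_sum = 12` lands at ~1.3 emitters/µm².
#'
#' @param low_patches A [patch_set()] of low-density patches.
#' @param k_per_sum Number of patches per sum (default 12).
#' @param n_out Number of output patches.
#' @param seed Integer seed.
#' @return A [patch_set()].
#' @export
sum_patches <- function(low_patches, k_per_sum = 12, n_out = 1000, seed = 1) {
  stopifnot(k_per_sum >= 1)
  n_in <- dim(low_patches$patches)[3]
  P <- dim(low_patches$patches)[1]
  sel <- with_seed(seed,
                   matrix(sample.int(n_in, n_out * k_per_sum, replace = TRUE),
                          n_out, k_per_sum))
  patches <- array(0, c(P, P, n_out))
  labels <- vector("list", n_out)
  for (i in seq_len(n_out)) {
    acc <- matrix(0, P, P)
    lab <- list()
    for (k in seq_len(k_per_sum)) {
      j <- sel[i, k]
      acc <- acc + low_patches$patches[, , j]
      lab[[k]] <- low_patches$labels[[j]]
    }
    patches[, , i] <- acc
    labels[[i]] <- do.call(rbind, lab)
  }
  meta <- low_patches$meta
  meta$n_summed <- k_per_sum
  meta$seed_sum <- seed
  patch_set(patches, labels, meta)
}

#' Adjust the patch background to a reference level
#'
#' Applies a global additive offset so the median background of the patch
#' set matches the median background of a reference high-density
#' acquisition. Label coordinates are unchanged.
#'
#' @param ps A [patch_set()].
#' @param target_bg_stats List with `median` (and optionally `mad`) of the
#'   reference background in photon units; see [background_stats()].
#' @return The adjusted [patch_set()].
#' @export
adjust_background <- function(ps, target_bg_stats) {
  tgt <- target_bg_stats$median
  if (!is.finite(tgt)) stop("target background statistics are not finite")
  cur <- median(ps$patches)
  ps$patches <- ps$patches + (tgt - cur)
  ps$meta$bg_offset <- tgt - cur
  ps
}

#' Background statistics of a stack
#'
#' Median and MAD of the photon-converted pixel values; with sparse or
#' moderately dense emitters the median is dominated by background pixels.
#'
#' @param stack A `frame_stack`.
#' @param n_sample_frames Number of frames to sample for the statistics.
#' @return List with `median` and `mad` in photons.
#' @export
background_stats <- function(stack, n_sample_frames = 50) {
  nf <- n_frames(stack)
  idx <- unique(round(seq(1, nf, length.out = min(n_sample_frames, nf))))
  v <- adu_to_photons(stack$frames[, , idx], stack$camera)
  list(median = median(v), mad = mad(v))
}

#' Rasterize patch labels into upsampled spike maps
#'
#' Each label deposits unit mass at the upsampled pixel containing it
#' (accumulating when several labels share a pixel), so the map sum equals
#' the label count.
#'
#' @param ps A [patch_set()].
#' @param upsampling Positive integer grid factor (8 for live-cell models,
#'   16 for fixed-cell models).
#' @return Array (P*u) x (P*u) x n of spike maps.
#' @export
make_label_maps <- function(ps, upsampling) {
  stopifnot(upsampling >= 1, upsampling == round(upsampling))
  P <- dim(ps$patches)[1]
  n <- dim(ps$patches)[3]
  M <- P * upsampling
  out <- array(0, c(M, M, n))
  for (i in seq_len(n)) {
    l <- ps$labels[[i]]
    if (!nrow(l)) next
    if (any(l < 0) || any(l >= P)) stop("label outside patch")
    out[, , i] <- cpp_hist2d(l[, 1] * upsampling, l[, 2] * upsampling,
                             M, M, numeric(0))
  }
  out
}

#' Center-crop a patch set
#'
#' Crops every patch (and its labels) to `crop_px`, dropping labels that
#' fall outside; used to go from 17 px extraction patches to the 16 px
#' training size.
#'
#' @param ps A [patch_set()].
#' @param crop_px Target side length.
#' @return The cropped [patch_set()].
#' @export
crop_patches <- function(ps, crop_px = 16) {
  P <- dim(ps$patches)[1]
  stopifnot(crop_px <= P)
  off <- (P - crop_px) %/% 2
  idx <- off + seq_len(crop_px)
  patches <- ps$patches[idx, idx, , drop = FALSE]
  labels <- lapply(ps$labels, function(l) {
    if (!nrow(l)) return(l)
    x <- l[, 1] - off; y <- l[, 2] - off
    keep <- x >= 0 & x < crop_px & y >= 0 & y < crop_px
    cbind(x = x[keep], y = y[keep])
  })
  meta <- ps$meta
  meta$patch_px <- crop_px
  patch_set(patches, labels, meta)
}
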