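#' Training configuration for the density-map network
#'
#' Hyperparameters of the encoder-decoder training. The fidelity defaults
#' mirror the full-scale recipe (30,000 patches, batch 256, 100 epochs,
#' 15% validation split, initial learning rate 1e-5); [desk_preset()]
#' provides a reduced profile for desk-scale runs.
#'
#' @param upsampling Grid factor between camera pixels and the predicted
#'   map (8 for live-cell, 16 for fixed-cell models).
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param val_split Fraction of patches held out for validation.
#' @param learning_rate Initial Adam learning rate.
#' @param loss_blur_sigma_px Sigma (upsampled px) of the Gaussian kernel
#'   applied to prediction and label inside the MSE loss.
#' @param l1_weight Weight of the L1 sparsity penalty on the raw prediction.
#' @param widths Channel widths of the three encoder stages.
#' @param label_scale Amplitude given to each unit label spike.
#' @param patch_px Training patch side after center cropping.
#' @param seed Integer seed (weight init, shuffling, validation split).
#' @return A `train_config` list.
#' @export
train_config <- function(upsampling = 16, batch_size = 256, epochs = 100,
                         val_split = 0.15, learning_rate = 1e-5,
                         loss_blur_sigma_px = 1, l1_weight = 0.01,
                         widths = c(4, 8, 16), label_scale = 100,
                         patch_px = 16, seed = 1) {
  stopifnot(val_split > 0, val_split < 1, upsampling >= 1, batch_size >= 1)
  structure(list(upsampling = as.integer(upsampling),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), val_split = val_split,
                 learning_rate = learning_rate,
                 loss_blur_sigma_px = loss_blur_sigma_px,
                 l1_weight = l1_weight, widths = as.integer(widths),
                 label_scale = label_scale, patch_px = as.integer(patch_px),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' A reduced profile (2,000 patches, 20 epochs, batch 64, upsampling 8)
#' whose learning rate is raised to 5e-4 to compensate for the ~20x shorter
#' schedule; intended for end-to-end runs on a single CPU.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_preset <- function(...) {
  args <- modifyList(list(upsampling = 8, batch_size = 64, epochs = 20,
                          learning_rate = 5e-4), list(...))
  do.call(train_config, args)
}

#' Build an (untrained) density-map network
#'
#' Fully convolutional encoder-decoder: the input frame is bilinearly
#' resized to the upsampled grid, passed through three conv(3x3) +
#' batch-norm + ReLU blocks with 2x max-pooling, mirrored by three
#' nearest-upsample + conv blocks, and a final 1x1 convolution to a single
#' nonnegative channel. The parameter count is independent of the input
#' size, so a model trained on 16 px patches predicts full frames.
#'
#' @param config A [train_config()].
#' @return A `dd_model` (weights, config, normalization slots).
#' @export
build_model <- function(config = train_config()) {
  params <- cpp_cnn_init(config$widths, config$seed)
  structure(list(params = params, config = config,
                 norm = NULL, history = NULL),
            class = "dd_model")
}

#' @export
print.dd_model <- function(x, ...) {
  npar <- sum(vapply(x$params[grepl("_W|_b$", names(x$params))], length,
                     numeric(1)))
  cat(sprintf("<dd_model> upsampling %d, widths %s, %d weights, %s\n",
              x$config$upsampling,
              paste(x$config$widths, collapse = "/"), round(npar),
              if (is.null(x$norm)) "untrained"
              else sprintf("trained %d epochs", length(x$history$train_loss))))
  invisible(x)
}

#' Train the density-map network on a patch set
#'
#' Patches are center-cropped to the training size, standardized by the
#' training-set mean and standard deviation (stored in the model for
#' prediction), and bilinearly resized to the upsampled grid. Labels are
#' rasterized to spike maps and blurred with the loss kernel. The loss is
#' MSE between the blurred prediction and blurred label plus an L1 sparsity
#' penalty; optimization is Adam at the configured initial rate.
#'
#' @param model A [build_model()] result.
#' @param ps A [patch_set()] (e.g. from [sum_patches()]).
#' @param config Optional override of the model's [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained `dd_model` with `history` (per-epoch train/val loss).
#' @export
train_model <- function(model, ps, config = NULL, verbose = FALSE) {
  cfg <- if (is.null(config)) model$config else config
  if (dim(ps$patches)[1] != cfg$patch_px) ps <- crop_patches(ps, cfg$patch_px)
  P <- cfg$patch_px; u <- cfg$upsampling
  n <- dim(ps$patches)[3]
  if (!n) stop("empty patch set")
  mu <- mean(ps$patches); sdv <- sd(ps$patches)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  M <- P * u
  x <- array(0, c(M, M, n))
  for (i in seq_len(n))
    x[, , i] <- cpp_resize_bilinear((ps$patches[, , i] - mu) / sdv, M, M)
  lab <- make_label_maps(ps, u)
  y <- array(0, c(M, M, n))
  for (i in seq_len(n))
    y[, , i] <- cpp_blur_zero(lab[, , i], cfg$loss_blur_sigma_px) *
      cfg$label_scale
  res <- cpp_cnn_train(model$params, x, y,
                       list(epochs = cfg$epochs, batch_size = cfg$batch_size,
                            learning_rate = cfg$learning_rate,
                            l1_weight = cfg$l1_weight,
                            val_split = cfg$val_split,
                            loss_blur_sigma_px = cfg$loss_blur_sigma_px,
                            seed = cfg$seed, verbose = verbose))
  model$params <- res$params
  model$config <- cfg
  model$norm <- list(mean = mu, sd = sdv)
  model$history <- list(train_loss = as.numeric(res$train_loss),
                        val_loss = as.numeric(res$val_loss),
                        n_train = res$n_train, n_val = res$n_val)
  model
}

# photon-convert + standardize + resize frames for the network
prep_frames <- function(model, stack, frame_idx) {
  u <- model$config$upsampling
  H <- dim(stack$frames)[1]; W <- dim(stack$frames)[2]
  x <- array(0, c(H * u, W * u, length(frame_idx)))
  for (k in seq_along(frame_idx)) {
    img <- adu_to_photons(stack$frames[, , frame_idx[k]], stack$camera)
    img <- (img - model$norm$mean) / model$norm$sd
    x[, , k] <- cpp_resize_bilinear(img, H * u, W * u)
  }
  x
}

#' Predict localization-density maps for a stack
#'
#' Per-frame prediction on the upsampled grid. Frames are photon-converted
#' and standardized with the statistics stored at training time. The input
#' stack should be drift-corrected (see [frame_xcorr_drift()]) when the
#' acquisition drifted. Prediction is deterministic given the weights.
#'
#' @param model A trained `dd_model`.
#' @param stack A `frame_stack`.
#' @param frame_idx 1-based frame indices to predict (default: all).
#' @return A `prediction_maps` object: nonnegative cube
#'   (H*u x W*u x n), upsampling factor, frame indices, pixel size.
#' @export
predict_maps <- function(model, stack, frame_idx = NULL) {
  if (is.null(model$norm)) stop("model is untrained")
  if (is.null(frame_idx)) frame_idx <- seq_len(n_frames(stack))
  u <- model$config$upsampling
  x <- prep_frames(model, stack, frame_idx)
  # three pooling stages need multiples of 8: edge-pad, predict, crop back
  H <- dim(x)[1]; W <- dim(x)[2]
  H8 <- ceiling(H / 8) * 8; W8 <- ceiling(W / 8) * 8
  if (H8 != H || W8 != W) {
    xp <- array(0, c(H8, W8, dim(x)[3]))
    ri <- pmin(seq_len(H8), H); ci <- pmin(seq_len(W8), W)
    for (k in seq_len(dim(x)[3])) xp[, , k] <- x[ri, ci, k]
    maps <- cpp_cnn_predict(model$params, xp)[seq_len(H), seq_len(W), ,
                                              drop = FALSE]
  } else {
    maps <- cpp_cnn_predict(model$params, x)
  }
  structure(list(maps = maps, upsampling = u,
                 frames = as.integer(frame_idx) - 1L,
                 pixel_size_nm = stack$camera$pixel_size_nm,
                 frame_size_px = dim(stack$frames)[1:2],
                 n_frames = n_frames(stack), threshold = NA_real_),
            class = "prediction_maps")
}

#' @export
print.prediction_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<prediction_maps> %d maps of %d x %d (upsampling %d)\n",
              d[3], d[1], d[2], x$upsampling))
  invisible(x)
}

# all local maxima (any positive value) of all maps, with window centroids:
# the threshold-independent candidate list that extraction filters
map_candidates <- function(maps, neighborhood = 3) {
  stopifnot(neighborhood %% 2 == 1)
  out <- vector("list", dim(maps$maps)[3])
  for (k in seq_along(out)) {
    m <- cpp_map_maxima(maps$maps[, , k], 0, neighborhood)
    if (nrow(m))
      out[[k]] <- data.frame(frame = maps$frames[k], value = m[, 3],
                             cx = m[, 4], cy = m[, 5], mass = m[, 6],
                             px = m[, 2], py = m[, 1])
  }
  cand <- do.call(rbind, out)
  if (is.null(cand))
    cand <- data.frame(frame = integer(0), value = numeric(0),
                       cx = numeric(0), cy = numeric(0), mass = numeric(0),
                       px = numeric(0), py = numeric(0))
  structure(list(candidates = cand, upsampling = maps$upsampling,
                 pixel_size_nm = maps$pixel_size_nm,
                 frame_size_px = maps$frame_size_px,
                 n_frames = maps$n_frames,
                 n_maps = dim(maps$maps)[3], neighborhood = neighborhood),
            class = "dd_candidates")
}

count_at_threshold <- function(cand, threshold) sum(cand$candidates$value >= threshold)

#' Calibrate the extraction threshold against a reference count
#'
#' Monotone bisection over the threshold so that the total number of
#' extracted localizations across the maps matches `reference_count`
#' (within `tol`, default 2%). For an acquisition with a ground-truth
#' table, the reference is the GT row count scaled by the frame-count
#' ratio. If even threshold zero yields fewer localizations than the
#' reference, zero is returned with a warning.
#'
#' @param maps A `prediction_maps` or `dd_candidates` object.
#' @param reference_count Target total localization count (> 0).
#' @param tol Relative tolerance on the count.
#' @param neighborhood Extraction neighborhood (see
#'   [extract_localizations()]).
#' @param max_steps Bisection step cap.
#' @return The calibrated threshold (map intensity units).
#' @export
calibrate_threshold <- function(maps, reference_count, tol = 0.02,
                                neighborhood = 3, max_steps = 60) {
  stopifnot(reference_count > 0)
  cand <- if (inherits(maps, "dd_candidates")) maps
          else map_candidates(maps, neighborhood)
  if (count_at_threshold(cand, 0) < reference_count * (1 - tol)) {
    warning("reference count unattainable even at threshold 0")
    return(0)
  }
  lo <- 0; hi <- max(cand$candidates$value) * (1 + 1e-9)
  for (i in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    n <- count_at_threshold(cand, mid)
    if (abs(n - reference_count) <= tol * reference_count) return(mid)
    if (n > reference_count) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Extract localizations from prediction maps
#'
#' Finds local maxima at or above the threshold on each map; each maximum
#' becomes one localization at the intensity-weighted centroid of its
#' neighborhood window (local averaging; window mass becomes the photon
#' surrogate), converted to camera-pixel coordinates by dividing by the
#' upsampling factor.
#'
#' @param maps A `prediction_maps` or `dd_candidates` object.
#' @param threshold Map intensity threshold (see [calibrate_threshold()]).
#' @param neighborhood Odd window size for local averaging.
#' @param local_averaging If `FALSE`, the maximum's pixel center is used
#'   instead of the window centroid.
#' @return A [loc_table()]; `sx`, `sy`, `lpx`, `lpy` carry the map grid
#'   half-pitch as a nominal placeholder.
#' @export
extract_localizations <- function(maps, threshold, neighborhood = 3,
                                  local_averaging = TRUE) {
  cand <- if (inherits(maps, "dd_candidates")) maps
          else map_candidates(maps, neighborhood)
  d <- cand$candidates[cand$candidates$value >= threshold, , drop = FALSE]
  u <- cand$upsampling
  grid_px <- 0.5 / u
  nr <- nrow(d)
  df <- data.frame(frame = d$frame,
                   x = (if (local_averaging) d$cx else d$px + 0.5) / u,
                   y = (if (local_averaging) d$cy else d$py + 0.5) / u,
                   photons = d$mass, bg = rep(0, nr),
                   sx = rep(grid_px, nr), sy = rep(grid_px, nr),
                   lpx = rep(grid_px, nr), lpy = rep(grid_px, nr))
  loc_table(df, pixel_size_nm = cand$pixel_size_nm,
            frame_size_px = cand$frame_size_px, n_frames = cand$n_frames,
            source = "network-prediction")
}

#' Predict a stack in chunks and collect extraction candidates
#'
#' Memory-bounded driver for long stacks: predicts `chunk` frames at a
#' time, reduces each map to its local-maxima candidate list and discards
#' the map. The result feeds [calibrate_threshold()] and
#' [extract_localizations()].
#'
#' @param model A trained `dd_model`.
#' @param stack A `frame_stack`.
#' @param frame_idx 1-based frames to predict (default all).
#' @param chunk Frames per chunk.
#' @param neighborhood Extraction neighborhood.
#' @return A `dd_candidates` object.
#' @export
predict_candidates <- function(model, stack, frame_idx = NULL, chunk = 50,
                               neighborhood = 3) {
  if (is.null(frame_idx)) frame_idx <- seq_len(n_frames(stack))
  parts <- split(frame_idx, ceiling(seq_along(frame_idx) / chunk))
  acc <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    pm <- predict_maps(model, stack, parts[[i]])
    acc[[i]] <- map_candidates(pm, neighborhood)
  }
  cand <- do.call(rbind, lapply(acc, function(a) a$candidates))
  out <- acc[[1]]
  out$candidates <- cand
  out$n_maps <- length(frame_idx)
  out
}
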