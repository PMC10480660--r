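#' Write a frame stack as 16-bit TIFF with a YAML sidecar
#'
#' ImageJ-compatible multi-page 16-bit unsigned TIFF; camera metadata
#' (pixel size, integration time, gains) goes to `<path>.yaml`.
#'
#' @param stack A `frame_stack`.
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  frames <- lapply(seq_len(n_frames(stack)),
                   function(i) stack$frames[, , i] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(c(stack$camera[], list(n_frames = n_frames(stack))),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a frame stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param indices Optional 1-based frame indices to read (chunked access
#'   for long stacks).
#' @return A `frame_stack`. A missing sidecar falls back to camera
#'   defaults with a warning.
#' @export
read_stack <- function(path, indices = NULL) {
  if (!file.exists(path)) stop("no such TIFF: ", path)
  imgs <- tryCatch(
    tiff::readTIFF(path, all = if (is.null(indices)) TRUE else indices,
                   as.is = TRUE),
    error = function(e) stop("not a readable TIFF: ", path, call. = FALSE))
  if (is.matrix(imgs)) imgs <- list(imgs)
  side <- paste0(path, ".yaml")
  cam <- if (file.exists(side)) {
    y <- yaml::read_yaml(side)
    do.call(camera_model, y[setdiff(names(y), "n_frames")])
  } else {
    warning("missing sidecar ", side, "; using camera defaults")
    camera_model()
  }
  arr <- array(0L, c(nrow(imgs[[1]]), ncol(imgs[[1]]), length(imgs)))
  for (i in seq_along(imgs)) arr[, , i] <- as.integer(imgs[[i]])
  frame_stack(arr, cam)
}

#' Write a localization table (CSV + YAML sidecar)
#'
#' Plain CSV with the Picasso-convention columns (frame, x, y, photons,
#' sx, sy, bg, lpx, lpy and any link fields); pixel size, frame geometry
#' and processing provenance go to `<path>.yaml`. Coordinates are stored
#' in camera-pixel units; nm conversion happens at render time only.
#'
#' @param table A [loc_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_locs <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  yaml::write_yaml(list(pixel_size_nm = attr(table, "pixel_size_nm"),
                        frame_size_px = attr(table, "frame_size_px"),
                        n_frames = attr(table, "n_frames"),
                        source = attr(table, "source")),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a localization table written by [write_locs()]
#'
#' @param path CSV path.
#' @return A [loc_table()]. Missing mandatory columns raise an error that
#'   names the column; a missing sidecar falls back to defaults with a
#'   warning.
#' @export
read_locs <- function(path) {
  df <- read.csv(path)
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
  } else {
    warning("missing sidecar ", side, "; using defaults")
    meta <- list(pixel_size_nm = 157,
                 frame_size_px = c(ceiling(max(df$y, 1)), ceiling(max(df$x, 1))),
                 n_frames = max(df$frame) + 1L, source = "unknown")
  }
  loc_table(df, pixel_size_nm = meta$pixel_size_nm,
            frame_size_px = unlist(meta$frame_size_px),
            n_frames = meta$n_frames, source = meta$source)
}

#' Save / load a training patch set
#'
#' Patches go to a 32-bit float TIFF, labels to a CSV (patch index, x, y)
#' and metadata to YAML, all sharing the `path` stem.
#'
#' @param ps A [patch_set()].
#' @param path Stem path (without extension).
#' @return Invisibly, the stem path.
#' @export
save_patchset <- function(ps, path) {
  d <- dim(ps$patches)
  scale <- max(ps$patches, 1)
  tiff::writeTIFF(lapply(seq_len(d[3]), function(i) ps$patches[, , i] / scale),
                  paste0(path, ".tif"), bits.per.sample = 32)
  lab <- do.call(rbind, lapply(seq_along(ps$labels), function(i) {
    l <- ps$labels[[i]]
    if (!nrow(l)) NULL else data.frame(patch = i, x = l[, 1], y = l[, 2])
  }))
  if (is.null(lab)) lab <- data.frame(patch = integer(0), x = numeric(0),
                                      y = numeric(0))
  write.csv(lab, paste0(path, "_labels.csv"), row.names = FALSE)
  yaml::write_yaml(c(ps$meta, list(n_patches = d[3], intensity_scale = scale)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_patchset
#' @export
load_patchset <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  imgs <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  if (is.matrix(imgs)) imgs <- list(imgs)
  arr <- array(0, c(nrow(imgs[[1]]), ncol(imgs[[1]]), length(imgs)))
  for (i in seq_along(imgs)) arr[, , i] <- imgs[[i]] * meta$intensity_scale
  lab <- read.csv(paste0(path, "_labels.csv"))
  labels <- lapply(seq_along(imgs), function(i) {
    l <- lab[lab$patch == i, , drop = FALSE]
    cbind(x = as.numeric(l$x), y = as.numeric(l$y))
  })
  sc <- meta$intensity_scale
  meta$intensity_scale <- NULL; meta$n_patches <- NULL
  patch_set(arr, labels, meta)
}

#' Save / load a trained model checkpoint
#'
#' Single-file archive holding the weights, the normalization statistics
#' and the training configuration.
#'
#' @param model A `dd_model`.
#' @param path Checkpoint path.
#' @return Invisibly `path`; `load_model` returns the `dd_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "dd_model"))
  m
}

# ---------------------------------------------------------------------------
# configuration files

config_schema <- list(
  simulate = c("structure", "field_size_um", "density", "frames",
               "mean_on_frames", "photon_rate", "bg_photons", "psf_sigma_px",
               "seed"),
  camera = c("pixel_size_nm", "integration_time_ms", "em_gain", "preamp_gain",
             "quantum_efficiency", "read_noise_e", "baseline_offset",
             "sensitivity"),
  localize = c("box_px", "min_net_gradient"),
  filter = c("sx", "sy", "lpx", "lpy"),
  train = c("upsampling", "batch_size", "epochs", "val_split",
            "learning_rate", "loss_blur_sigma_px", "l1_weight", "widths",
            "label_scale", "patch_px", "seed"),
  movie = c("window_frames", "step_frames", "saturation_percentile",
            "mean_filter_px", "gauss_sigma_px", "fps", "upsampling"),
  global = c("seed", "out_dir", "log_level"))

#' Read a pipeline configuration file
#'
#' YAML with sections `simulate`, `camera`, `localize`, `filter`, `train`,
#' `movie`, `global`; unknown sections or keys are rejected so typos fail
#' loudly.
#'
#' @param path YAML path.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in names(cfg)) {
    if (!sec %in% names(config_schema))
      stop("unknown config section: ", sec)
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
  }
  cfg
}

# ---------------------------------------------------------------------------
# command-line interface

cli_usage <- "usage: hdpaint <command> [--key value ...]

commands:
  simulate       --structure filaments --density 0.109 --frames 1000 --seed 7
                 --field 7.5 --out stack.tif
  localize       --in stack.tif --out locs.csv [--box 7 --min-gradient 400]
  filter         --in locs.csv --out f.csv [--sx-min --sx-max --lp-max]
  link           --in locs.csv --out l.csv [--radius px --max-dark 5]
  undrift-rcc    --in locs.csv --out u.csv [--segment 200]
  undrift-frames --in stack.tif --out u.tif
  render         --in locs.csv --out img.tif [--oversampling 8 --blur 1]
  sum-patches    --in stack.tif --locs locs.csv --k 12 --n 2000 --patch 17
                 --seed 1 --out train
  train          --patches train --upsampling 8 --epochs 20 --out model.ckpt
  predict        --model model.ckpt --stack hd.tif --gt gt.csv --out pred.csv
  metrics        --gt gt.tif --pred pred.tif [--mask] --out report.json
  sweep          --model m.ckpt --stack hd.tif --gt gt.csv --counts 100,400
                 --out sweep.csv
  movie          --locs pred.csv --window 400 --step 20 --fps 30 --out dir
  demo           --preset smoke --out dir [--seed 1]
"

cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE; i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  opts
}

opt_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) return(default)
  as.numeric(opts[[key]])
}
opt_chr <- function(opts, key, default = NULL) {
  v <- opts[[key]]
  if (is.null(v)) default else as.character(v)
}
need_opt <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required option --", key)
  opts[[key]]
}

read_tiff_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(img)) img <- img[[1]]
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (see the package README); designed
#' to be called from the thin `Rscript` wrapper installed under
#' `inst/cli/hdpaint`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code: 0 success, 1 runtime failure, 2 usage or
#'   configuration error.
#' @export
hdpaint_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage); return(invisible(0L))
  }
  cmd <- args[1]
  opts <- tryCatch(cli_opts(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts)); cat(cli_usage); return(invisible(2L))
  }
  run <- function() switch(
    cmd,
    simulate = {
      seed <- opt_num(opts, "seed", 1)
      st <- generate_structure(opt_chr(opts, "structure", "filaments"),
                               field_size_um = opt_num(opts, "field", 7.5),
                               seed = seed)
      ev <- sample_binding_events(st, opt_num(opts, "density", 0.109),
                                  opt_num(opts, "frames", 1000),
                                  photon_rate = opt_num(opts, "photon-rate", 2000),
                                  seed = seed + 1)
      stack <- render_frames(ev, camera = camera_model(), seed = seed + 2,
                             bg_photons = opt_num(opts, "bg", 10))
      out <- need_opt(opts, "out")
      write_stack(stack, out)
      write_locs(stack$true_locs, paste0(tools::file_path_sans_ext(out),
                                         "_truth.csv"))
      message("wrote ", out, " (", n_frames(stack), " frames)")
    },
    localize = {
      stack <- read_stack(need_opt(opts, "in"))
      locs <- localize_stack(stack, box_px = opt_num(opts, "box", 7),
                             min_net_gradient = opt_num(opts, "min-gradient", 400))
      write_locs(locs, need_opt(opts, "out"))
      message(nrow(locs), " localizations")
    },
    filter = {
      locs <- read_locs(need_opt(opts, "in"))
      out <- filter_table(locs,
                          sx = c(opt_num(opts, "sx-min", 0.6), opt_num(opts, "sx-max", 2)),
                          sy = c(opt_num(opts, "sx-min", 0.6), opt_num(opts, "sx-max", 2)),
                          lpx = c(0, opt_num(opts, "lp-max", 0.3)),
                          lpy = c(0, opt_num(opts, "lp-max", 0.3)))
      write_locs(out, need_opt(opts, "out"))
      message(nrow(out), "/", nrow(locs), " kept")
    },
    link = {
      locs <- read_locs(need_opt(opts, "in"))
      r <- opt_num(opts, "radius", NA)
      if (is.na(r)) r <- 4 * estimate_nena(locs)$nena_px
      out <- link_localizations(locs, r, opt_num(opts, "max-dark", 5))
      write_locs(out, need_opt(opts, "out"))
      message(nrow(out), " linked localizations (radius ", round(r, 3), " px)")
    },
    `undrift-rcc` = {
      locs <- read_locs(need_opt(opts, "in"))
      res <- rcc_drift_correct(locs, opt_num(opts, "segment", 200))
      write_locs(res$table, need_opt(opts, "out"))
      message("max |drift| ", round(max(abs(res$trajectory)), 3), " px")
    },
    `undrift-frames` = {
      stack <- read_stack(need_opt(opts, "in"))
      res <- frame_xcorr_drift(stack)
      write_stack(res$stack, need_opt(opts, "out"))
      message("max |drift| ", round(max(abs(res$trajectory)), 3), " px")
    },
    render = {
      locs <- read_locs(need_opt(opts, "in"))
      img <- render_locs(locs, opt_num(opts, "oversampling", 8),
                         opt_num(opts, "blur", 1))
      tiff::writeTIFF(img / max(img, 1), need_opt(opts, "out"),
                      bits.per.sample = 32)
      message("rendered ", nrow(img), " x ", ncol(img))
    },
    `sum-patches` = {
      stack <- read_stack(need_opt(opts, "in"))
      locs <- read_locs(need_opt(opts, "locs"))
      lp <- extract_patches(stack, locs, opt_num(opts, "patch", 17),
                            n = opt_num(opts, "n", 2000),
                            seed = opt_num(opts, "seed", 1))
      hp <- sum_patches(lp, opt_num(opts, "k", 12),
                        n_out = opt_num(opts, "n", 2000),
                        seed = opt_num(opts, "seed", 1) + 1)
      save_patchset(hp, need_opt(opts, "out"))
      message("mean density ", round(patch_density(hp), 3), " emitters/um^2")
    },
    train = {
      ps <- load_patchset(need_opt(opts, "patches"))
      cfg <- desk_preset(upsampling = opt_num(opts, "upsampling", 8),
                         epochs = opt_num(opts, "epochs", 20),
                         seed = opt_num(opts, "seed", 1))
      model <- train_model(build_model(cfg), ps, verbose = TRUE)
      save_model(model, need_opt(opts, "out"))
      message("final val loss ", signif(tail(model$history$val_loss, 1), 4))
    },
    predict = {
      model <- load_model(need_opt(opts, "model"))
      stack <- read_stack(need_opt(opts, "stack"))
      gt <- read_locs(need_opt(opts, "gt"))
      cand <- predict_candidates(model, stack)
      ref <- nrow(gt) * n_frames(stack) / attr(gt, "n_frames")
      thr <- calibrate_threshold(cand, ref)
      locs <- extract_localizations(cand, thr)
      write_locs(locs, need_opt(opts, "out"))
      message(nrow(locs), " localizations at threshold ", signif(thr, 4))
    },
    metrics = {
      gt <- read_tiff_image(need_opt(opts, "gt"))
      pred <- read_tiff_image(need_opt(opts, "pred"))
      pp <- preprocess_pair(gt, pred)
      msk <- if (isTRUE(opts$mask)) make_mask(pp$gt8) else NULL
      m <- similarity_metrics(pp$gt8, pp$pred8, msk)
      jsonlite::write_json(m[c("pcc", "ssim", "ms_ssim", "mae", "psnr_db")],
                           need_opt(opts, "out"), auto_unbox = TRUE,
                           digits = NA, na = "null")
      print(m)
    },
    sweep = {
      model <- load_model(need_opt(opts, "model"))
      stack <- read_stack(need_opt(opts, "stack"))
      gt <- read_locs(need_opt(opts, "gt"))
      counts <- as.integer(strsplit(need_opt(opts, "counts"), ",")[[1]])
      tab <- frame_sweep(model, stack, gt, sort(counts))
      write.csv(tab, need_opt(opts, "out"), row.names = FALSE)
      message("swept ", nrow(tab), " frame counts")
    },
    movie = {
      locs <- read_locs(need_opt(opts, "locs"))
      cfg <- movie_config(window_frames = opt_num(opts, "window", 400),
                          step_frames = opt_num(opts, "step", 20),
                          fps = opt_num(opts, "fps", 30))
      mv <- build_movie(locs, cfg)
      res <- stitch_movie(mv, need_opt(opts, "out"))
      message(length(mv$frames), " movie frames, ",
              round(res$duration_s, 2), " s at ", cfg$fps, " fps")
    },
    demo = cli_demo(opts),
    stop("unknown command: ", cmd)
  )
  code <- tryCatch({ run(); 0L },
                   error = function(e) {
                     message("error: ", conditionMessage(e))
                     if (grepl("unknown command|missing required|unknown config",
                               conditionMessage(e))) 2L else 1L
                   })
  invisible(code)
}

# End-to-end demonstration: simulate GT + HD acquisitions, build training
# data, train, predict, measure, and write a movie — from one seed.
cli_demo <- function(opts) {
  preset <- opt_chr(opts, "preset", "smoke")
  seed <- opt_num(opts, "seed", 1)
  out_dir <- opt_chr(opts, "out", "hdpaint_demo")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- switch(preset,
    smoke = list(gt_frames = 400, hd_frames = 60, patches = 200, epochs = 3,
                 field = 4, pred_frames = 60),
    desk = list(gt_frames = 5000, hd_frames = 1000, patches = 2000,
                epochs = 20, field = 7.5, pred_frames = 400),
    stop("unknown config preset: ", preset))
  res <- run_experiment(gt_frames = sizes$gt_frames,
                        hd_frames = sizes$hd_frames,
                        n_patches = sizes$patches, epochs = sizes$epochs,
                        field_size_um = sizes$field,
                        pred_frames = sizes$pred_frames, seed = seed)
  jsonlite::write_json(list(pcc_prediction = res$pcc_pred,
                            pcc_widefield = res$pcc_widefield,
                            resolution_pred_nm = res$resolution_pred_nm,
                            resolution_widefield_nm = res$resolution_widefield_nm,
                            n_predicted_locs = res$n_pred_locs,
                            threshold = res$threshold, seed = seed,
                            preset = preset),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_locs(res$pred_locs, file.path(out_dir, "predicted_locs.csv"))
  message("PCC prediction ", round(res$pcc_pred, 3), " vs widefield ",
          round(res$pcc_widefield, 3))
  invisible(res)
}
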