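#' Movie rendering configuration
#'
#' @param window_frames Raw frames per super-resolved snapshot (default 400).
#' @param step_frames Window step; with a 50 ms integration time the default
#'   of 20 gives a 1 s temporal spacing between snapshots.
#' @param saturation_percentile Per-frame clip percentile (default 99).
#' @param mean_filter_px Side of the mean filter applied after
#'   normalization (default 3).
#' @param gauss_sigma_px Final Gaussian smoothing sigma (default 1.5 px).
#' @param fps Playback rate of the stitched movie.
#' @param upsampling Render grid factor (8 for live-cell data).
#' @return A `movie_config` list.
#' @export
movie_config <- function(window_frames = 400, step_frames = 20,
                         saturation_percentile = 99, mean_filter_px = 3,
                         gauss_sigma_px = 1.5, fps = 30, upsampling = 8) {
  stopifnot(step_frames >= 1, step_frames <= window_frames,
            saturation_percentile > 0, saturation_percentile <= 100)
  structure(list(window_frames = as.integer(window_frames),
                 step_frames = as.integer(step_frames),
                 saturation_percentile = saturation_percentile,
                 mean_filter_px = as.integer(mean_filter_px),
                 gauss_sigma_px = gauss_sigma_px, fps = fps,
                 upsampling = as.integer(upsampling)),
            class = "movie_config")
}

#' Plan sliding windows over an acquisition
#'
#' Windows are `[i*step, i*step + window)` for
#' `i = 0 .. floor((n_frames - window)/step)`; consecutive windows overlap
#' by `window - step` frames.
#'
#' @param n_frames Total raw frames.
#' @param window Window length in frames.
#' @param step Step between window starts.
#' @return Data frame with 0-based `start` (inclusive) and `end`
#'   (exclusive). If `n_frames < window` a single truncated window is
#'   returned with a warning.
#' @export
plan_windows <- function(n_frames, window = 400, step = 20) {
  if (n_frames < window) {
    warning("fewer frames than one window; returning a truncated window")
    return(data.frame(start = 0L, end = as.integer(n_frames)))
  }
  starts <- seq.int(0L, n_frames - window, by = step)
  data.frame(start = as.integer(starts), end = as.integer(starts + window))
}

#' Render one window of localizations
#'
#' 2-D histogram of the rows with `start <= frame < end` on the upsampled
#' grid. Empty windows give a zero image (kept for temporal continuity).
#'
#' @param table A [loc_table()].
#' @param start,end Window bounds (0-based, end exclusive).
#' @param upsampling Render grid factor.
#' @return Matrix (H*u x W*u).
#' @export
window_image <- function(table, start, end, upsampling = 8) {
  rows <- table$frame >= start & table$frame < end
  render_locs(relabel_locs(table[rows, , drop = FALSE], table), upsampling)
}

#' Style a rendered window for display
#'
#' Clips at the per-frame saturation percentile, normalizes to [0, 1],
#' applies a mean filter to suppress isolated background localizations,
#' and convolves with a Gaussian kernel for smooth structures. An all-zero
#' frame is returned unchanged.
#'
#' @param image Nonnegative matrix from [window_image()].
#' @param config A [movie_config()].
#' @return Matrix with values in [0, 1].
#' @export
style_frame <- function(image, config = movie_config()) {
  stopifnot(all(image >= 0))
  if (max(image) == 0) return(image)
  clip <- quantile(image[image > 0], config$saturation_percentile / 100,
                   names = FALSE)
  if (clip <= 0) clip <- max(image)
  img <- pmin(image, clip) / clip
  if (config$mean_filter_px > 1) img <- cpp_mean_filter(img, config$mean_filter_px)
  if (config$gauss_sigma_px > 0) img <- cpp_gauss_blur(img, config$gauss_sigma_px)
  pmin(pmax(img, 0), 1)
}

#' Build a super-resolution movie from a localization table
#'
#' Runs the full sliding-window pipeline: [plan_windows()],
#' [window_image()] and [style_frame()] per window.
#'
#' @param table A [loc_table()] (e.g. network extractions of a live-cell
#'   acquisition).
#' @param config A [movie_config()].
#' @param integration_time_ms Raw-frame integration time, for timestamps.
#' @return A `sr_movie`: list of styled frames, window plan, per-frame
#'   timestamps in seconds (`start * integration_time`), and the config.
#' @export
build_movie <- function(table, config = movie_config(),
                        integration_time_ms = 50) {
  plan <- plan_windows(attr(table, "n_frames"), config$window_frames,
                       config$step_frames)
  frames <- lapply(seq_len(nrow(plan)), function(i)
    style_frame(window_image(table, plan$start[i], plan$end[i],
                             config$upsampling), config))
  structure(list(frames = frames, plan = plan,
                 timestamps_s = plan$start * integration_time_ms / 1000,
                 config = config,
                 integration_time_ms = integration_time_ms),
            class = "sr_movie")
}

#' @export
print.sr_movie <- function(x, ...) {
  cat(sprintf("<sr_movie> %d frames, %.2f s spacing, %.1f s span, %d fps playback\n",
              length(x$frames),
              x$config$step_frames * x$integration_time_ms / 1000,
              if (length(x$timestamps_s)) max(x$timestamps_s) else 0,
              x$config$fps))
  invisible(x)
}

#' Write a movie to disk
#'
#' Writes the styled frames as a numbered 8-bit grayscale PNG sequence with
#' a JSON sidecar (window plan, timestamps, fps). If an `ffmpeg` encoder is
#' available on the PATH an MP4 is additionally encoded; otherwise the
#' image sequence is the product.
#'
#' @param movie A [build_movie()] result.
#' @param out_dir Output directory (created if needed).
#' @param basename Stem for frame files and sidecar.
#' @return Invisibly, a list with the file paths and the video duration in
#'   seconds (`n_frames / fps`).
#' @export
stitch_movie <- function(movie, out_dir, basename = "movie") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(movie$frames)
  stopifnot(n >= 1)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(out_dir, sprintf("%s_%05d.png", basename, i))
    png::writePNG(movie$frames[[i]], paths[i])
  }
  sidecar <- file.path(out_dir, paste0(basename, ".json"))
  jsonlite::write_json(list(fps = movie$config$fps,
                            n_frames = n,
                            duration_s = n / movie$config$fps,
                            step_frames = movie$config$step_frames,
                            window_frames = movie$config$window_frames,
                            integration_time_ms = movie$integration_time_ms,
                            timestamps_s = movie$timestamps_s,
                            plan = movie$plan),
                       sidecar, auto_unbox = TRUE, digits = NA)
  mp4 <- NA_character_
  ffmpeg <- Sys.which("ffmpeg")
  if (nzchar(ffmpeg)) {
    mp4 <- file.path(out_dir, paste0(basename, ".mp4"))
    status <- system2(ffmpeg, c("-y", "-loglevel", "error", "-framerate",
                                movie$config$fps, "-i",
                                file.path(out_dir, paste0(basename, "_%05d.png")),
                                "-pix_fmt", "yuv420p", mp4))
    if (status != 0) mp4 <- NA_character_
  }
  invisible(list(frames = paths, sidecar = sidecar, mp4 = mp4,
                 duration_s = n / movie$config$fps))
}
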