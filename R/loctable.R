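#' Localization table
#'
#' A data frame of per-emitter records with the Picasso-convention column
#' set: `frame` (0-based), `x`, `y` (camera pixels, continuous, origin at the
#' corner of pixel (0,0), x rightwards along columns, y downwards along
#' rows), `photons`, `bg` (photons/px), `sx`, `sy` (PSF widths, px), `lpx`,
#' `lpy` (localization precision, px). Metadata (pixel size, frame geometry,
#' provenance) is carried in attributes.
#'
#' @param df Data frame with at least columns frame, x, y, photons, bg, sx,
#'   sy, lpx, lpy.
#' @param pixel_size_nm Camera pixel size (nm).
#' @param frame_size_px Integer vector (H, W) of the source frames.
#' @param n_frames Number of frames in the source acquisition.
#' @param source Free-text provenance flag.
#' @return A `loc_table` (data frame subclass).
#' @export
loc_table <- function(df, pixel_size_nm, frame_size_px, n_frames,
                      source = "unknown") {
  need <- c("frame", "x", "y", "photons", "bg", "sx", "sy", "lpx", "lpy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(df$frame >= 0))
  structure(as.data.frame(df),
            pixel_size_nm = pixel_size_nm,
            frame_size_px = as.integer(frame_size_px),
            n_frames = as.integer(n_frames),
            source = source,
            class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, %d frames, %d x %d px @ %.0f nm (%s)\n",
              nrow(x), attr(x, "n_frames"), attr(x, "frame_size_px")[1],
              attr(x, "frame_size_px")[2], attr(x, "pixel_size_nm"),
              attr(x, "source")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# rebuild a loc_table around a plain data frame, inheriting metadata
relabel_locs <- function(df, template, source = NULL) {
  loc_table(df,
            pixel_size_nm = attr(template, "pixel_size_nm"),
            frame_size_px = attr(template, "frame_size_px"),
            n_frames = attr(template, "n_frames"),
            source = if (is.null(source)) attr(template, "source") else source)
}

#' Render localizations into a super-resolution image
#'
#' 2-D histogram of (x, y) on a grid of `pixel_size / oversampling`,
#' optionally Gaussian blurred. Before blurring, the image sum equals the
#' number of in-field rows.
#'
#' @param table A [loc_table()].
#' @param oversampling Integer >= 1; rendered pixel = camera pixel / this.
#' @param blur_sigma_px Gaussian blur sigma in rendered pixels (0 = none).
#' @return Matrix (H*oversampling x W*oversampling) with attribute
#'   `rendered_pixel_nm`.
#' @export
render_locs <- function(table, oversampling = 8, blur_sigma_px = 0) {
  stopifnot(oversampling >= 1)
  fs <- attr(table, "frame_size_px")
  H <- fs[1] * oversampling; W <- fs[2] * oversampling
  img <- cpp_hist2d(table$x * oversampling, table$y * oversampling, H, W,
                    numeric(0))
  if (blur_sigma_px > 0) img <- cpp_gauss_blur(img, blur_sigma_px)
  attr(img, "rendered_pixel_nm") <- attr(table, "pixel_size_nm") / oversampling
  img
}
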