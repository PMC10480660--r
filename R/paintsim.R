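#' @useDynLib hdpaint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois rgamma rnorm rgeom runif approx coef cor fft
#'   lm median quantile sd mad
#' @importFrom utils head read.csv write.csv tail modifyList
NULL

# evaluate expr under a local, seeded RNG without disturbing the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' EMCCD camera model
#'
#' Bundles the detector parameters of the acquisition: an EM gain register
#' modeled as a gamma-distributed amplification of photoelectrons, Gaussian
#' read noise, and an analog-to-digital conversion with offset. Defaults
#' follow a back-illuminated EMCCD operated at 5 MHz readout with an
#' effective pixel size of 157 nm.
#'
#' @param pixel_size_nm Back-projected pixel size in the sample plane (nm).
#' @param integration_time_ms Frame integration time (ms); 150 ms is typical
#'   for fixed-cell acquisitions and 50 ms for live-cell acquisitions.
#' @param em_gain Electron-multiplying gain (unitless, > 0).
#' @param preamp_gain Pre-amplifier gain setting.
#' @param quantum_efficiency Photon-to-photoelectron conversion probability.
#' @param read_noise_e Read noise RMS in electrons.
#' @param baseline_offset Camera offset in ADU.
#' @param sensitivity Conversion factor in electrons per ADU.
#' @return An object of class `cam_model`.
#' @export
camera_model <- function(pixel_size_nm = 157, integration_time_ms = 150,
                         em_gain = 50, preamp_gain = 1,
                         quantum_efficiency = 0.9, read_noise_e = 60,
                         baseline_offset = 100, sensitivity = 12.5) {
  stopifnot(pixel_size_nm > 0, em_gain > 0, preamp_gain > 0,
            quantum_efficiency > 0, quantum_efficiency <= 1, sensitivity > 0)
  structure(list(pixel_size_nm = pixel_size_nm,
                 integration_time_ms = integration_time_ms,
                 em_gain = em_gain, preamp_gain = preamp_gain,
                 quantum_efficiency = quantum_efficiency,
                 read_noise_e = read_noise_e,
                 baseline_offset = baseline_offset,
                 sensitivity = sensitivity),
            class = "cam_model")
}

#' Convert camera counts to expected photon numbers
#'
#' Inverts the mean EMCCD gain chain: photons =
#' (ADU - offset) * sensitivity / (em_gain * QE).
#'
#' @param adu Numeric array of camera counts.
#' @param camera A [camera_model()].
#' @return Array of the same shape in photon units.
#' @export
adu_to_photons <- function(adu, camera) {
  (adu - camera$baseline_offset) * camera$sensitivity /
    (camera$em_gain * camera$quantum_efficiency)
}

#' Generate a labeled target structure
#'
#' Draws a synthetic intracellular target decorated with binding sites at a
#' fixed spacing: `"filaments"` (smooth random curves, emulating intermediate
#' filaments such as vimentin), `"tubules"` (curves with transverse spread,
#' emulating membrane tubules such as the ER), or `"network"` (random nodes
#' joined by straight edges, emulating an interconnected organelle network).
#' Site positions are reported in nm with the origin at the field corner.
#'
#' @param kind One of `"filaments"`, `"tubules"`, `"network"`.
#' @param field_size_um Side length of the square field of view (µm).
#' @param structure_params List of structure controls: `n_filaments`,
#'   `filament_length_um`, `site_spacing_nm`, `curvature` (rad per step),
#'   `tubule_width_nm` (tubules), `n_nodes`/`n_neighbors` (network).
#' @param seed Integer seed; identical seed and parameters give identical
#'   point sets.
#' @return A `structure_model` with a two-column `points` matrix (x, y in nm).
#' @export
generate_structure <- function(kind = c("filaments", "tubules", "network"),
                               field_size_um = 10,
                               structure_params = list(), seed = 1) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown structure kind", call. = FALSE))
  stopifnot(field_size_um > 0)
  p <- modifyList(list(n_filaments = 6, filament_length_um = 8,
                       site_spacing_nm = 10, curvature = 0.15,
                       tubule_width_nm = 60, n_nodes = 20, n_neighbors = 2),
                  structure_params)
  field_nm <- field_size_um * 1000
  pts <- with_seed(seed, {
    if (kind %in% c("filaments", "tubules")) {
      out <- list()
      n_fil <- p$n_filaments
      if (n_fil > 0) {
        for (i in seq_len(n_fil)) {
          n_sites <- floor(round(p$filament_length_um * 1000 / p$site_spacing_nm, 9))
          xy <- matrix(0, n_sites, 2)
          pos <- runif(2, 0.1, 0.9) * field_nm
          theta <- runif(1, 0, 2 * pi)
          dthetas <- rnorm(n_sites, 0, p$curvature)
          for (k in seq_len(n_sites)) {
            xy[k, ] <- pos
            theta <- theta + dthetas[k]
            step <- p$site_spacing_nm * c(cos(theta), sin(theta))
            pos <- pos + step
            # bounce off field borders
            for (d in 1:2) {
              if (pos[d] < 0) { pos[d] <- -pos[d]; theta <- if (d == 1) pi - theta else -theta }
              if (pos[d] > field_nm) { pos[d] <- 2 * field_nm - pos[d]; theta <- if (d == 1) pi - theta else -theta }
            }
          }
          if (kind == "tubules")
            xy <- xy + matrix(rnorm(2 * n_sites, 0, p$tubule_width_nm / 2),
                              n_sites, 2)
          out[[i]] <- xy
        }
      }
      pts <- if (length(out)) do.call(rbind, out) else matrix(0, 0, 2)
      pts
    } else { # network
      nodes <- matrix(runif(2 * p$n_nodes, 0.05, 0.95) * field_nm, ncol = 2)
      segs <- list()
      for (i in seq_len(p$n_nodes)) {
        d <- sqrt(rowSums((nodes - matrix(nodes[i, ], p$n_nodes, 2, byrow = TRUE))^2))
        nb <- order(d)[2:(1 + p$n_neighbors)]
        for (j in nb) if (j > i || !any(vapply(segs, function(s)
          identical(s$ij, c(j, i)), logical(1)))) {
          len <- d[j]
          n_sites <- max(1L, floor(len / p$site_spacing_nm))
          tt <- (seq_len(n_sites) - 1) / n_sites
          segs[[length(segs) + 1]] <- list(
            ij = c(i, j),
            xy = cbind(nodes[i, 1] + tt * (nodes[j, 1] - nodes[i, 1]),
                       nodes[i, 2] + tt * (nodes[j, 2] - nodes[i, 2])))
        }
      }
      if (length(segs)) do.call(rbind, lapply(segs, `[[`, "xy")) else matrix(0, 0, 2)
    }
  })
  pts <- pts[pts[, 1] >= 0 & pts[, 1] <= field_nm &
             pts[, 2] >= 0 & pts[, 2] <= field_nm, , drop = FALSE]
  colnames(pts) <- c("x_nm", "y_nm")
  structure(list(kind = kind, points = pts, field_size_um = field_size_um,
                 params = p, seed = seed),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> kind=%s, %d sites, field %.1f x %.1f um\n",
              x$kind, nrow(x$points), x$field_size_um, x$field_size_um))
  invisible(x)
}

#' Sample transient binding events
#'
#' Draws a stationary stream of binding events on the structure's sites.
#' Exchangeable labels rebind indefinitely, so the per-frame expected number
#' of active emitters is constant over the whole acquisition (no bleaching
#' or decay term exists in the model). Event starts follow a Poisson process
#' with rate `mean_density * area / mean_on_frames` per frame; on-times are
#' geometric (memoryless) with mean `mean_on_frames`; binding sites are drawn
#' uniformly with replacement.
#'
#' @param structure A [generate_structure()] result.
#' @param mean_density Target mean active-emitter density (emitters/µm²/frame).
#' @param n_frames Number of camera frames.
#' @param mean_on_frames Mean on-time in frames (>= 1).
#' @param photon_rate Expected photons emitted per frame while bound.
#' @param seed Integer seed.
#' @return A `binding_events` object; `events` has columns x_nm, y_nm,
#'   start_frame, end_frame (inclusive, 0-based), photon_rate.
#' @export
sample_binding_events <- function(structure, mean_density, n_frames,
                                  mean_on_frames = 3, photon_rate = 2000,
                                  seed = 1) {
  stopifnot(mean_density >= 0, mean_on_frames >= 1, n_frames >= 1)
  if (photon_rate < 0) stop("negative photon rate")
  area <- structure$field_size_um^2
  if (mean_density > 0 && nrow(structure$points) == 0)
    stop("structure has no binding sites but mean_density > 0")
  target_active <- mean_density * area
  start_rate <- target_active / mean_on_frames
  ev <- with_seed(seed, {
    if (target_active == 0) {
      data.frame(x_nm = numeric(0), y_nm = numeric(0), start_frame = integer(0),
                 end_frame = integer(0), photon_rate = numeric(0))
    } else {
      # warm-up before frame 0 so frame 0 already carries stationary occupancy
      warm <- ceiling(10 * mean_on_frames)
      starts0 <- rep(seq(-warm, n_frames - 1),
                     rpois(n_frames + warm, start_rate))
      durs <- rgeom(length(starts0), 1 / mean_on_frames) + 1L
      ends <- starts0 + durs - 1L
      keep <- ends >= 0 & starts0 <= n_frames - 1
      starts0 <- starts0[keep]; ends <- ends[keep]
      sites <- structure$points[sample.int(nrow(structure$points),
                                           length(starts0), replace = TRUE), ,
                                drop = FALSE]
      data.frame(x_nm = sites[, 1], y_nm = sites[, 2],
                 start_frame = pmax(starts0, 0L),
                 end_frame = pmin(ends, n_frames - 1L),
                 photon_rate = photon_rate)
    }
  })
  structure(list(events = ev, n_frames = as.integer(n_frames),
                 mean_density = mean_density,
                 field_size_um = structure$field_size_um, seed = seed),
            class = "binding_events")
}

#' Per-frame active-emitter counts
#'
#' @param events A [sample_binding_events()] result.
#' @return Integer vector of length `n_frames`.
#' @export
active_counts <- function(events) {
  n <- events$n_frames
  counts <- integer(n)
  if (nrow(events$events)) {
    d <- events$events
    for (i in seq_len(nrow(d))) {
      f0 <- d$start_frame[i] + 1L; f1 <- d$end_frame[i] + 1L
      counts[f0:f1] <- counts[f0:f1] + 1L
    }
  }
  counts
}

#' Render camera frames from binding events
#'
#' Forward model of the acquisition: each active emitter deposits a
#' pixel-integrated 2-D Gaussian of expected photons `photon_rate` per frame;
#' a uniform background rate is added; the photon field then passes through
#' the EMCCD chain — Poisson shot noise on photoelectrons, gamma-distributed
#' EM amplification (shape = electrons, scale = em_gain), Gaussian read
#' noise — and is digitized (divide by sensitivity, add offset, clip to
#' 16-bit).
#'
#' @param events A [sample_binding_events()] result.
#' @param psf_sigma_px PSF standard deviation in camera pixels.
#' @param camera A [camera_model()].
#' @param seed Integer seed for the noise chain.
#' @param bg_photons Uniform background photon rate per pixel per frame.
#' @param frame_px Frame side length in pixels; defaults to the structure
#'   field size divided by the pixel size.
#' @return A `frame_stack`: 16-bit integer array (H x W x n_frames), the
#'   camera model, and the exact ground-truth localization table `true_locs`.
#' @export
render_frames <- function(events, psf_sigma_px = 1.3, camera = camera_model(),
                          seed = 1, bg_photons = 10, frame_px = NULL) {
  stopifnot(psf_sigma_px > 0)
  if (is.null(frame_px))
    frame_px <- round(events$field_size_um * 1000 / camera$pixel_size_nm)
  H <- W <- as.integer(frame_px)
  d <- events$events
  if (nrow(d) && any(d$photon_rate < 0)) stop("negative photon rate")
  # expand events to per-frame emitter instances
  if (nrow(d)) {
    reps <- d$end_frame - d$start_frame + 1L
    idx <- rep.int(seq_len(nrow(d)), reps)
    fr <- unlist(lapply(seq_len(nrow(d)),
                        function(i) d$start_frame[i]:d$end_frame[i]))
    inst <- data.frame(frame = fr,
                       x = d$x_nm[idx] / camera$pixel_size_nm,
                       y = d$y_nm[idx] / camera$pixel_size_nm,
                       photons = d$photon_rate[idx])
  } else {
    inst <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                       photons = numeric(0))
  }
  lam <- cpp_render_frames(as.integer(inst$frame), inst$x, inst$y,
                           inst$photons, psf_sigma_px, events$n_frames, H, W)
  lam <- lam + bg_photons
  adu <- with_seed(seed, {
    phe <- rpois(length(lam), lam * camera$quantum_efficiency)
    elec <- numeric(length(phe))
    nz <- phe > 0
    elec[nz] <- rgamma(sum(nz), shape = phe[nz], scale = camera$em_gain)
    elec <- elec + rnorm(length(elec), 0, camera$read_noise_e)
    round(elec / camera$sensitivity + camera$baseline_offset)
  })
  adu <- pmin(pmax(adu, 0), 65535)
  frames <- array(as.integer(adu), dim = dim(lam))
  nr <- nrow(inst)
  true_locs <- loc_table(
    data.frame(frame = as.integer(inst$frame), x = inst$x, y = inst$y,
               photons = inst$photons, bg = rep(bg_photons, nr),
               sx = rep(psf_sigma_px, nr), sy = rep(psf_sigma_px, nr),
               lpx = rep(0, nr), lpy = rep(0, nr)),
    pixel_size_nm = camera$pixel_size_nm, frame_size_px = c(H, W),
    n_frames = events$n_frames, source = "simulation-truth")
  frame_stack(frames, camera, true_locs = true_locs)
}

#' Construct a frame stack
#'
#' @param frames Integer array H x W x n_frames (ADU).
#' @param camera A [camera_model()].
#' @param true_locs Optional ground-truth [loc_table()].
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, camera, true_locs = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 1, all(frames >= 0))
  if (!is.null(true_locs))
    stopifnot(all(true_locs$frame < dim(frames)[3]))
  structure(list(frames = frames, camera = camera, true_locs = true_locs),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%.0f nm px)%s\n",
              d[3], d[1], d[2], x$camera$pixel_size_nm,
              if (!is.null(x$true_locs)) sprintf(", %d true locs", nrow(x$true_locs))
              else ""))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `frame_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Apply a lateral drift trajectory to a stack
#'
#' Shifts frame i by `trajectory[i, ]` pixels using bilinear interpolation;
#' ground-truth localizations, if present, are shifted identically.
#'
#' @param stack A `frame_stack`.
#' @param drift_trajectory_px n_frames x 2 matrix of (dx, dy) in pixels.
#' @return The drifted `frame_stack`.
#' @export
apply_drift <- function(stack, drift_trajectory_px) {
  tr <- as.matrix(drift_trajectory_px)
  if (nrow(tr) != n_frames(stack))
    stop("trajectory length must equal the number of frames")
  out <- stack$frames
  for (i in seq_len(nrow(tr))) {
    if (tr[i, 1] == 0 && tr[i, 2] == 0) next
    out[, , i] <- cpp_shift_bilinear(stack$frames[, , i], tr[i, 1], tr[i, 2])
  }
  tl <- stack$true_locs
  if (!is.null(tl)) {
    sh <- tr[tl$frame + 1L, , drop = FALSE]
    tl$x <- tl$x + sh[, 1]
    tl$y <- tl$y + sh[, 2]
  }
  frame_stack(array(as.integer(round(out)), dim(out)), stack$camera, tl)
}

#' Mean (widefield-equivalent) image of a stack
#'
#' @param stack A `frame_stack`.
#' @return Matrix H x W, mean ADU per pixel.
#' @export
mean_image <- function(stack) {
  apply(stack$frames, c(1, 2), mean)
}
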