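#' Run the full simulate-train-predict experiment
#'
#' Desk-scale rehearsal of the acceleration pipeline on simulated PAINT
#' data: (1) draw a filament structure; (2) simulate a low-density
#' ground-truth (GT) acquisition and a high-density (HD) acquisition of the
#' same structure; (3) localize and filter the GT stack with the MLE chain;
#' (4) build high-density training patches by summing random low-density
#' patches and matching the HD background; (5) train the encoder-decoder;
#' (6) predict the HD stack, calibrate the extraction threshold against the
#' GT-derived expected count, and extract localizations; (7) render GT,
#' prediction and the widefield mean image, and score PCC and
#' decorrelation resolution.
#'
#' @param gt_frames Frames in the low-density GT acquisition.
#' @param hd_frames Frames in the high-density acquisition.
#' @param n_patches Training patches after summing.
#' @param epochs Training epochs (desk preset).
#' @param field_size_um Field of view side (µm).
#' @param pred_frames HD frames used for prediction.
#' @param gt_density,hd_density Mean active-emitter densities
#'   (emitters/µm²/frame).
#' @param k_per_sum Patches summed per training patch.
#' @param upsampling Network grid factor.
#' @param photon_rate Expected photons per emitter per frame.
#' @param seed Master seed; all stages derive their substreams from it.
#' @param verbose Print training progress.
#' @return List with the trained model, localization tables, renders,
#'   PCC/resolution comparisons and the calibrated threshold.
#' @export
run_experiment <- function(gt_frames = 5000, hd_frames = 1000,
                           n_patches = 2000, epochs = 20,
                           field_size_um = 7.5, pred_frames = 400,
                           gt_density = 0.109, hd_density = 1.3,
                           k_per_sum = 12, upsampling = 8,
                           photon_rate = 2000, seed = 1, verbose = FALSE) {
  cam <- camera_model()
  st <- generate_structure("filaments", field_size_um, seed = seed)

  gt_ev <- sample_binding_events(st, gt_density, gt_frames,
                                 photon_rate = photon_rate, seed = seed + 101)
  gt_stack <- render_frames(gt_ev, camera = cam, seed = seed + 102)
  gt_locs <- filter_table(localize_stack(gt_stack))

  hd_ev <- sample_binding_events(st, hd_density, hd_frames,
                                 photon_rate = photon_rate, seed = seed + 201)
  hd_stack <- render_frames(hd_ev, camera = cam, seed = seed + 202)

  low <- extract_patches(gt_stack, gt_locs, patch_px = 17, n = n_patches,
                         seed = seed + 301)
  high <- sum_patches(low, k_per_sum = k_per_sum, n_out = n_patches,
                      seed = seed + 302)
  high <- adjust_background(high, background_stats(hd_stack))

  cfg <- desk_preset(upsampling = upsampling, epochs = epochs,
                     seed = seed + 401)
  model <- train_model(build_model(cfg), high, verbose = verbose)

  cand <- predict_candidates(model, hd_stack, seq_len(pred_frames))
  # expected emitter instances in the predicted window, estimated from the
  # GT acquisition and the density ratio of the two acquisitions
  ref <- nrow(gt_locs) * (pred_frames * hd_density) / (gt_frames * gt_density)
  thr <- calibrate_threshold(cand, ref)
  pred_locs <- extract_localizations(cand, thr)

  gt_img <- render_locs(gt_locs, upsampling, blur_sigma_px = 1)
  pred_img <- render_locs(pred_locs, upsampling, blur_sigma_px = 1)
  wf <- mean_image(frame_stack(hd_stack$frames[, , seq_len(pred_frames),
                                               drop = FALSE], cam))
  wf_img <- cpp_resize_bilinear(wf, nrow(gt_img), ncol(gt_img))

  pp_pred <- preprocess_pair(gt_img, pred_img)
  pp_wf <- preprocess_pair(gt_img, wf_img)
  m_pred <- similarity_metrics(pp_pred$gt8, pp_pred$pred8)
  m_wf <- similarity_metrics(pp_wf$gt8, pp_wf$pred8)
  px_nm <- attr(gt_img, "rendered_pixel_nm")
  res_pred <- decorrelation_resolution(pred_img, px_nm)
  res_wf <- decorrelation_resolution(wf_img, px_nm)
  res_gt <- decorrelation_resolution(gt_img, px_nm)

  list(structure = st, camera = cam,
       gt_stack = gt_stack, gt_locs = gt_locs,
       hd_stack = hd_stack, model = model,
       threshold = thr, pred_locs = pred_locs, n_pred_locs = nrow(pred_locs),
       gt_img = gt_img, pred_img = pred_img, wf_img = wf_img,
       pcc_pred = m_pred$pcc, pcc_widefield = m_wf$pcc,
       metrics_pred = m_pred, metrics_widefield = m_wf,
       resolution_pred_nm = res_pred$resolution_nm,
       resolution_widefield_nm = res_wf$resolution_nm,
       resolution_gt_nm = res_gt$resolution_nm,
       reference_count = ref, pred_frames = pred_frames)
}

#' Acceleration factor of a prediction relative to its ground truth
#'
#' The fold reduction in acquisition time when a structure is
#' reconstructed from `pred_frames` high-density frames instead of
#' `gt_frames` low-density frames (e.g. 25,000-frame GT vs 1,000-frame
#' prediction gives 25).
#'
#' @param gt_frames Frames of the low-density GT acquisition.
#' @param pred_frames Frames used for the prediction.
#' @return The ratio `gt_frames / pred_frames`.
#' @export
acceleration_factor <- function(gt_frames, pred_frames) {
  stopifnot(gt_frames > 0, pred_frames > 0)
  gt_frames / pred_frames
}

#' Timing summary of a sliding-window live-cell acquisition
#'
#' @param n_frames Total raw frames recorded.
#' @param integration_time_ms Raw-frame integration time.
#' @param step_frames Window step between snapshots.
#' @return List with `acquisition_min` (total acquisition time, minutes)
#'   and `temporal_spacing_s` (time between movie snapshots, seconds).
#' @export
live_timing <- function(n_frames = 15000, integration_time_ms = 50,
                        step_frames = 20) {
  list(acquisition_min = n_frames * integration_time_ms / 1000 / 60,
       temporal_spacing_s = step_frames * integration_time_ms / 1000)
}

#' Predicted pixel size for an upsampling factor
#'
#' @param pixel_size_nm Camera pixel size (nm).
#' @param upsampling Grid factor.
#' @return Predicted-image pixel size in nm (rounded to the nearest nm).
#' @export
predicted_pixel_nm <- function(pixel_size_nm = 157, upsampling) {
  round(pixel_size_nm / upsampling)
}
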