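# shared fixture builders (everything is generated in code at test time)

# localization table of fixed emitters re-observed every frame with Gaussian
# jitter of sd `sigma` (the classic NeNA calibration scenario)
jitter_table <- function(sigma, n_frames = 300, n_emitters = 30, W = 32,
                         p_on = 0.5, seed = 99) {
  hdpaint:::with_seed(seed, {
    ex <- runif(n_emitters, 2, W - 2)
    ey <- runif(n_emitters, 2, W - 2)
    df <- do.call(rbind, lapply(seq_len(n_frames) - 1L, function(f) {
      on <- runif(n_emitters) < p_on
      data.frame(frame = f, x = ex[on] + rnorm(sum(on), 0, sigma),
                 y = ey[on] + rnorm(sum(on), 0, sigma),
                 photons = 1000, bg = 5, sx = 1.2, sy = 1.2,
                 lpx = sigma, lpy = sigma)
    }))
    loc_table(df, pixel_size_nm = 157, frame_size_px = c(W, W),
              n_frames = n_frames, source = "jitter-sim")
  })
}

# small localized acquisition reused by the drift tests (cached per session)
localized_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- generate_structure("filaments", 7.5, seed = 11)
      ev <- sample_binding_events(st, 0.109, 2000, seed = 12)
      stack <- render_frames(ev, camera = camera_model(), seed = 13)
      cache <<- list(structure = st, stack = stack,
                     locs = filter_table(localize_stack(stack)))
    }
    cache
  }
})

# minimal loc_table wrapper around a data frame of x, y, frame
quick_locs <- function(df, W = 32, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- max(df$frame) + 1L
  defaults <- list(photons = 1000, bg = 5, sx = 1.2, sy = 1.2,
                   lpx = 0.05, lpy = 0.05)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  loc_table(df, pixel_size_nm = 157, frame_size_px = c(W, W),
            n_frames = n_frames, source = "test")
}
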