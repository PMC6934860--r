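# Shared fixture builders.  Everything is generated in code at test
# time; seeds are fixed per call site.

# Labelled single frames spanning the inhomogeneity amplitudes used in
# the segmentation experiments.
make_seg_frames <- function(n, seed0, img_size = 128,
                            amps = c(0, 0.3, 0.6)) {
  ph <- mdr_phenotypes()
  imgs <- list(); msks <- list(); amp_of <- numeric(n)
  for (i in seq_len(n)) {
    amp_of[i] <- amps[(i %% length(amps)) + 1]
    radius <- round((img_size / 128) * (22 + ((i * 7) %% 18)))
    geo <- spheroid_geometry(radius = radius,
                             inhomogeneity_amplitude = amp_of[i])
    s <- make_spheroid_stack(ph$sensitive, geo, frame_interval_min = 120,
                             duration_h = 6, img_size = img_size,
                             seed = seed0 + i)
    f <- 1 + (i %% 4)
    imgs[[i]] <- s$stack$phase[[f]]
    msks[[i]] <- s$masks[[f]]
  }
  list(imgs = imgs, msks = msks, amps = amp_of)
}

# One clean, high-contrast 64x64 disk frame that a small network can
# overfit quickly.
make_easy_frame <- function(seed = 5, img_size = 64) {
  geo <- spheroid_geometry(radius = 18, inhomogeneity_amplitude = 0,
                           background_noise_sd = 200)
  s <- make_spheroid_stack(mdr_phenotypes()$sensitive, geo,
                           frame_interval_min = 60, duration_h = 1,
                           img_size = img_size, seed = seed)
  list(img = s$stack$phase[[1]], mask = s$masks[[1]])
}

# Reduced-scale network configuration used by the training tests.
tiny_pnet_config <- function(max_epochs = 6, seed = 1) {
  pnet_config(channels = 4, input_size = 64, dropout_rate = 0.2,
              learning_rate = 1e-3, max_epochs = max_epochs,
              batch_size = 2, seed = seed)
}
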