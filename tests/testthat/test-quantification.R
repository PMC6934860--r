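test_that("masked means equal a brute-force pixel loop", {
  brute <- function(frame, mask) {
    tot <- 0; n <- 0
    for (i in seq_len(nrow(frame)))
      for (j in seq_len(ncol(frame)))
        if (mask[i, j] == 1) { tot <- tot + frame[i, j]; n <- n + 1 }
    tot / n
  }
  withr::with_seed(99, {
    for (rep in 1:100) {
      d <- sample(3:8, 2)
      frame <- matrix(runif(d[1] * d[2], 0, 1000), d[1], d[2])
      mask <- matrix(rbinom(d[1] * d[2], 1, 0.5), d[1], d[2])
      if (sum(mask) == 0) mask[1, 1] <- 1L
      expect_identical(mean_channel_over_mask(frame, mask),
                       brute(frame, mask))
      expect_identical(mean_over_edges(frame, mask),
                       brute(frame, mask))
    }
  })
  expect_equal(mean_channel_over_mask(matrix(5, 3, 3),
                                      matrix(c(1, 0, 1), 3, 3)), 5)
  expect_error(mean_channel_over_mask(matrix(1, 2, 2),
                                      matrix(0, 2, 2)), "empty")
  expect_error(mean_over_edges(matrix(1, 2, 2), matrix(0, 2, 2)),
               "empty")
})

test_that("LoG edge maps localize steps and ignore uniform frames", {
  expect_equal(sum(log_edge_map(matrix(7, 32, 32))), 0)

  step <- cbind(matrix(0, 64, 32), matrix(1000, 64, 32))
  edges <- log_edge_map(step, sigma = 2)
  cols <- which(edges == 1, arr.ind = TRUE)[, 2]
  expect_true(all(abs(cols - 32.5) <= 2 * 2 + 1))

  # edge mask recovers the perimeter of a rendered blob
  blob <- matrix(0, 64, 64)
  xs <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  ys <- matrix(seq_len(64), 64, 64)
  r <- sqrt((xs - 32)^2 + (ys - 32)^2)
  blob[r <= 15] <- 1000
  e <- log_edge_map(blob, sigma = 2, magnitude_percentile = 85)
  perim <- (r >= 14) & (r <= 16)
  near_edge <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(e), EBImage::makeBrush(5, "box"))) > 0
  recall <- sum(perim & near_edge) / sum(perim)
  expect_gte(recall, 0.8)
})

test_that("accumulated fluorescence is an exact trapezoidal integral", {
  ph <- mdr_phenotypes()$sensitive
  geo <- spheroid_geometry(radius = 20, background_noise_sd = 0,
                           inhomogeneity_amplitude = 0)
  s <- make_spheroid_stack(ph, geo, 120, 12, 96, seed = 2)
  ks <- uptake_timeseries(s$stack, s$masks)
  expect_equal(ks$accumulated,
               pracma::trapz(ks$times_h, ks$mean_fluorescence))

  # constant series over 12 h accumulates 12 * c
  const <- spheroMDR:::new_kinetic_series(seq(0, 12, 2), rep(40, 7),
                                          "green", "MCS", "x")
  expect_equal(const$accumulated, 12 * 40)

  # refining a piecewise-linear series does not change the integral
  t1 <- c(0, 2, 5, 9, 12); v1 <- c(0, 10, 13, 30, 31)
  fine_t <- sort(unique(c(t1, seq(0, 12, 0.25))))
  fine_v <- approx(t1, v1, xout = fine_t)$y
  expect_equal(pracma::trapz(t1, v1), pracma::trapz(fine_t, fine_v),
               tolerance = 1e-12)
})

test_that("empty-mask frames are dropped, mismatches rejected", {
  ph <- mdr_phenotypes()$sensitive
  geo <- spheroid_geometry(radius = 20)
  s <- make_spheroid_stack(ph, geo, 60, 2, 96, seed = 3)
  expect_error(uptake_timeseries(s$stack, s$masks[1:2]), "one mask")
  masks <- s$masks
  masks[[2]] <- seg_mask(matrix(0L, 96, 96), 2, "pnet", TRUE)
  expect_message(ks <- uptake_timeseries(s$stack, masks), "dropped 1")
  expect_equal(length(ks$times_h), n_frames(s$stack) - 1L)
  expect_equal(ks$dropped_frames, 2L)
})

test_that("ROS decay flag follows the fitted slope", {
  # exact arithmetic series 9, 7, 5, 3: slope -2 per frame, certain decay
  stack <- spheroMDR:::new_stack(
    phase = replicate(4, matrix(1000L, 8, 8), simplify = FALSE),
    green = lapply(c(9, 7, 5, 3), function(v) matrix(v, 8, 8)),
    times_h = 0:3, frame_interval_min = 60,
    meta = list(kind = "spheroid-ros", phenotype = "toy"))
  masks <- lapply(1:4, function(k) seg_mask(matrix(1L, 8, 8), k))
  ks <- ros_timeseries(stack, masks)
  expect_equal(ks$slope, -2)
  expect_true(ks$decay_flag)

  ph <- mdr_phenotypes()
  geo <- spheroid_geometry(radius = 25)
  up <- make_spheroid_stack(ph$sensitive, geo, 20, 1, 96, mode = "ros",
                            seed = 8)
  expect_true(ros_timeseries(up$stack, up$masks)$decay_flag)
  flat <- make_spheroid_stack(ph$resistant, geo, 20, 1, 96,
                              mode = "ros", seed = 8)
  expect_false(ros_timeseries(flat$stack, flat$masks)$decay_flag)
})

test_that("ANOVA/Tukey reduces to known identities", {
  same <- list(a = 1:3, b = 1:3, c = 1:3)
  gc <- anova_tukey(same)
  expect_equal(gc$F, 0)
  expect_equal(gc$p, 1)

  # two groups: F equals the squared pooled-variance t statistic
  withr::with_seed(7, {
    x <- rnorm(8, 10); y <- rnorm(9, 12)
  })
  gc2 <- anova_tukey(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(gc2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(gc2$p, tt$p.value, tolerance = 1e-10)

  withr::with_seed(8, {
    far <- list(a = rnorm(3, 0, 0.01), b = rnorm(3, 10, 0.01),
                c = rnorm(3, 20, 0.01))
  })
  gc3 <- anova_tukey(far)
  expect_true(all(gc3$tukey$p_adj < 0.001))
  expect_true(all(gc3$tukey$stars == "***"))
  expect_error(anova_tukey(list(a = 1:3)), ">= 2 groups")
})

test_that("density independence verdicts match the generating design", {
  ph <- mdr_phenotypes()$sensitive
  series_for <- function(radius, seeds, scale_uptake = FALSE) {
    lapply(seeds, function(sd) {
      p <- if (scale_uptake)
        synthetic_phenotype("sensitive", uptake_rate = 1500 * radius / 20)
      else ph
      geo <- spheroid_geometry(radius = radius)
      s <- make_spheroid_stack(p, geo, 120, 6, 96, seed = sd)
      uptake_timeseries(s$stack, s$masks)
    })
  }
  ind <- density_independence_check(list(
    d1 = series_for(16, 1:3), d2 = series_for(22, 4:6),
    d3 = series_for(28, 7:9)))
  expect_identical(ind$verdict, "independent")

  dep <- density_independence_check(list(
    d1 = series_for(16, 1:3, TRUE), d2 = series_for(22, 4:6, TRUE),
    d3 = series_for(28, 7:9, TRUE)))
  expect_identical(dep$verdict, "dependent")

  one <- series_for(20, 1:2)
  expect_equal(density_independence_check(list(a = one, b = one))$p, 1)
  expect_error(density_independence_check(list(a = one)), "2 densities")
})
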