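test_that("parameter count matches the analytic layer-shape formula", {
  for (C in c(3, 8)) {
    cfg <- pnet_config(channels = C, input_size = 64)
    model <- build_pnet(cfg)
    expected <- (9 * 1 * C + C) +            # first conv (1 input channel)
      12 * (9 * C * C + C) +                 # remaining 12 convs
      (5 * C * C + C) +                      # 1x1 classifier 1 on concat
      (C * 2 + 2)                            # 1x1 classifier 2
    expect_identical(pnet_n_parameters(model), as.integer(expected))
  }
})

test_that("forward pass preserves resolution and is seed-reproducible", {
  cfg <- pnet_config(channels = 3, input_size = 64, seed = 11)
  m1 <- build_pnet(cfg)
  m2 <- build_pnet(cfg)
  expect_identical(m1$params, m2$params)

  x <- matrix(rnorm(48 * 48), 48, 48)
  fwd <- spheroMDR:::pnet_forward(m1, x)
  expect_equal(dim(fwd$scores), c(48 * 48, 2L))
})

test_that("weighted cross-entropy matches hand-computed values", {
  # perfect prediction: probability ~1 at every true pixel
  truth <- matrix(c(1, 0, 0, 1), 2, 2)
  perfect <- cbind(ifelse(as.vector(truth) == 1, -50, 50),
                   ifelse(as.vector(truth) == 1, 50, -50))
  expect_lt(weighted_cross_entropy(perfect, truth), 1e-6)

  # one foreground pixel with p = exp(-1): contribution 10 * 1
  s <- matrix(c(log(1 - exp(-1)), log(exp(-1))), 1, 2)
  expect_equal(weighted_cross_entropy(s, matrix(1, 1, 1)), 10,
               tolerance = 1e-10)

  # uniform p = 0.5 on a half-foreground mask: mean of {log2, 10 log2}
  half <- matrix(rep(c(0L, 1L), each = 8), 4, 4)
  s0 <- matrix(0, 16, 2)
  expect_equal(weighted_cross_entropy(s0, half), 5.5 * log(2),
               tolerance = 1e-12)

  expect_error(weighted_cross_entropy(s0, matrix(1, 3, 3)), "shapes")
})

test_that("dice handles identity, disjoint and partial overlap", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, b), 0.0)
  cshift <- matrix(0L, 4, 4); cshift[2:3, 1:2] <- 1L  # 2 of 4 px shared
  expect_equal(dice(a, cshift), 0.5)
  expect_equal(dice(matrix(0L, 2, 2), matrix(0L, 2, 2)), 1.0)
  expect_error(dice(a, matrix(0L, 3, 3)), "shapes")
})

test_that("augmenting image and mask together preserves overlap", {
  fx <- make_easy_frame()
  for (k in 0:7) {
    ti <- spheroMDR:::dihedral_transform(fx$img, k)
    tm <- spheroMDR:::dihedral_transform(mask_pixels(fx$mask), k)
    expect_identical(dim(ti), dim(tm))
    expect_equal(dice(tm, tm), 1.0)
    # the transform is a bijection on pixels: foreground area unchanged
    expect_identical(sum(tm), sum(mask_pixels(fx$mask)))
  }
})

test_that("training reduces the loss and can overfit one easy frame", {
  fx <- make_easy_frame()
  res <- train_pnet(list(fx$img), list(fx$mask),
                    tiny_pnet_config(max_epochs = 30, seed = 2))
  expect_true(all(is.finite(res$report$loss)))
  expect_lt(res$report$loss[length(res$report$loss)],
            res$report$loss[1])
  pred <- segment(res$model, fx$img)
  expect_s3_class(pred, "SegMask")
  expect_identical(pred$source, "pnet")
  expect_gte(dice(pred, fx$mask), 0.95)
})

test_that("training is deterministic for a fixed seed", {
  fx <- make_easy_frame()
  cfg <- tiny_pnet_config(max_epochs = 2, seed = 4)
  r1 <- train_pnet(list(fx$img), list(fx$mask), cfg)
  r2 <- train_pnet(list(fx$img), list(fx$mask), cfg)
  expect_identical(r1$report$loss, r2$report$loss)
  expect_identical(r1$model$params, r2$model$params)
  expect_error(train_pnet(list(), list(), cfg), "non-empty")
})

test_that("final-epoch loss beats first-epoch loss across seeds", {
  fx <- make_seg_frames(3, seed0 = 300, img_size = 64)
  first <- numeric(0); last <- numeric(0)
  for (s in 1:3) {
    res <- train_pnet(fx$imgs, fx$msks,
                      tiny_pnet_config(max_epochs = 3, seed = s))
    first <- c(first, res$report$loss[1])
    last <- c(last, res$report$loss[length(res$report$loss)])
  }
  expect_lt(median(last), median(first))
})

test_that("baseline segmentation is near-perfect on clean disks", {
  geo <- spheroid_geometry(radius = 34, inhomogeneity_amplitude = 0,
                           background_noise_sd = 300)
  s <- make_spheroid_stack(mdr_phenotypes()$sensitive, geo, 60, 1, 128,
                           seed = 12)
  expect_gte(dice(baseline_segment(s$stack$phase[[1]]), s$masks[[1]]),
             0.98)
  blank <- baseline_segment(matrix(100, 64, 64))
  expect_true(blank$empty_flag)
  expect_equal(sum(mask_pixels(blank)), 0)
})

test_that("an all-background score map yields a flagged empty mask", {
  cfg <- pnet_config(channels = 3, input_size = 64, seed = 1)
  model <- build_pnet(cfg)
  # bias the final classifier so background always wins
  model$params$fc2_W[] <- 0
  model$params$fc2_b <- c(10, -10)
  expect_warning(m <- segment(model, matrix(rnorm(64 * 64), 64, 64)),
                 "no foreground")
  expect_true(m$empty_flag)
  expect_equal(sum(mask_pixels(m)), 0)
})
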