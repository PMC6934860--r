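test_that("uptake curve matches its closed form and limits", {
  lin <- synthetic_phenotype("sensitive", uptake_rate = 2)
  expect_equal(uptake_curve(lin, c(0, 1, 2)), c(0, 2, 4))

  sat <- synthetic_phenotype("resistant", uptake_rate = 10,
                             efflux_rate = 1)
  expect_equal(uptake_curve(sat, 1e6), 10, tolerance = 1e-12)

  mid <- synthetic_phenotype("moderate", uptake_rate = 10,
                             efflux_rate = 0.5)
  expect_equal(uptake_curve(mid, 2), (10 / 0.5) * (1 - exp(-1)),
               tolerance = 1e-12)

  expect_error(uptake_curve(lin, c(-1, 0)), "non-negative")
  expect_error(uptake_curve(lin, c(2, 1)), "ascending")
})

test_that("uptake curve is non-decreasing and bounded by u/e", {
  for (s in 1:20) {
    withr::with_seed(s, {
      u <- runif(1, 10, 5000); e <- runif(1, 0.01, 3)
      ph <- synthetic_phenotype("moderate", uptake_rate = u,
                                efflux_rate = e)
      ts <- sort(runif(30, 0, 24))
      cv <- uptake_curve(ph, ts)
      expect_true(all(diff(cv) >= -1e-9))
      expect_true(all(cv <= u / e + 1e-9))
    })
  }
})

test_that("phenotype and geometry invariants are enforced", {
  expect_error(synthetic_phenotype("sensitive", uptake_rate = -1))
  expect_error(synthetic_phenotype("sensitive", 1, penetration_max = 2))
  expect_error(spheroid_geometry(radius = 0))
  expect_error(spheroid_geometry(radius = 10,
                                 inhomogeneity_amplitude = 1))
})

test_that("spheroid stacks are deterministic and carry exact masks", {
  ph <- mdr_phenotypes()
  geo <- spheroid_geometry(radius = 30)
  a <- make_spheroid_stack(ph$sensitive, geo, 60, 2, 128, seed = 9)
  b <- make_spheroid_stack(ph$sensitive, geo, 60, 2, 128, seed = 9)
  expect_identical(a$stack$phase, b$stack$phase)
  expect_identical(a$stack$green, b$stack$green)

  # ground-truth masks are the geometry disk, identical across frames
  expect_equal(dice(a$masks[[1]], a$masks[[3]]), 1.0)
  area <- sum(mask_pixels(a$masks[[1]]))
  expect_lt(abs(area - pi * 30^2) / (pi * 30^2), 0.05)

  expect_error(
    make_spheroid_stack(ph$sensitive, spheroid_geometry(radius = 80),
                        60, 1, 128),
    "does not fit")
})

test_that("green kinetics in rendered stacks follow the phenotype", {
  ph <- mdr_phenotypes()
  geo <- spheroid_geometry(radius = 30)
  sens <- make_spheroid_stack(ph$sensitive, geo, 60, 12, 128, seed = 21)
  ks <- uptake_timeseries(sens$stack, sens$masks, subject = "sens")
  # sensitive phenotype: mean green over the true mask never decreases
  expect_true(all(diff(ks$mean_fluorescence) >= -1))

  res <- make_spheroid_stack(ph$resistant, geo, 60, 12, 128, seed = 21)
  kr <- uptake_timeseries(res$stack, res$masks, subject = "res")
  expect_lt(kr$accumulated, ks$accumulated)
})

test_that("monolayer stacks are deterministic with sane edge kinetics", {
  ph <- mdr_phenotypes()
  a <- make_monolayer_stack(ph$sensitive, n_cells = 60, duration_h = 6,
                            frame_interval_min = 180, img_size = 128,
                            seed = 3)
  b <- make_monolayer_stack(ph$sensitive, n_cells = 60, duration_h = 6,
                            frame_interval_min = 180, img_size = 128,
                            seed = 3)
  expect_identical(a$green, b$green)

  z <- make_monolayer_stack(ph$sensitive, n_cells = 10, duration_h = 0,
                            img_size = 64, seed = 1)
  expect_equal(n_frames(z), 1L)
  expect_error(make_monolayer_stack(ph$sensitive, n_cells = 0),
               "n_cells")

  # edge-mean green at 6 h exceeds the value at t = 0
  e0 <- mean_over_edges(a$green[[1]], log_edge_map(a$green[[1]]))
  e6 <- mean_over_edges(a$green[[3]], log_edge_map(a$green[[3]]))
  expect_gt(e6, e0)
})

test_that("plates encode 4PL viability exactly when noiseless", {
  sp <- plate_spec("drugX", c(1, 5, 25, 50, 125, 625), true_ic50 = 50,
                   hill = 1, top = 100, bottom = 0, noise_sd = 0)
  plate <- make_plate(sp, seed = 1)
  expect_identical(plate, make_plate(sp, seed = 1))
  v <- plate_viability(plate)
  at_ic50 <- v$viability[v$conc_uM == 50]
  expect_equal(at_ic50, rep(50, 3), tolerance = 1e-12)
  expect_error(plate_spec("d", c(5, 1, 25), true_ic50 = 10),
               "increasing")
})

test_that("flow event tables honour the generating spec", {
  fs <- flow_spec(n_events = 4000, dead_fraction = 0, replicates = 1)
  ev <- make_flow_events(fs, seed = 6)
  expect_identical(ev, make_flow_events(fs, seed = 6))
  # no dead events: all PI values sit in the live mode
  expect_lt(max(ev$pi), 5000)

  fs2 <- flow_spec(n_events = 10000, dead_fraction = 0.1,
                   baseline_mfi = 500, replicates = 1)
  ev2 <- make_flow_events(fs2, seed = 7)
  ctrl <- ev2$green[ev2$tube == "control"]
  # empirical median within 2 SE of the generating median
  se_med <- 1 / (2 * stats::dlnorm(500, log(500), 0.5) *
                   sqrt(length(ctrl)))
  expect_lt(abs(median(ctrl) - 500), 2 * se_med)

  expect_error(flow_spec(retention_ratio = c(MDR1 = 1, MRP1 = 1,
                                             BCRP = 1, control = 2)),
               "control")
})
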