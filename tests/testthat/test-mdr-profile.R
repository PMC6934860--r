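mk_series <- function(acc, subject = "s") {
  ks <- spheroMDR:::new_kinetic_series(c(0, 6, 12), c(0, acc / 18, acc / 9),
                                       "green", "MCS", subject)
  ks
}
mk_ros <- function(flag) {
  ks <- mk_series(100)
  ks$decay_flag <- flag
  ks
}
mk_flow <- function(ratios) {
  structure(list(ratios = data.frame(transporter = names(ratios),
                                     ratio = unname(ratios))),
            class = "TransporterReport")
}

test_that("evidence vectors are cohort-normalized with missing markers", {
  subjects <- list(
    a = list(kinetics = mk_series(900), ros = mk_ros(TRUE),
             fits = list(d1 = 10, d2 = 5),
             flow = mk_flow(c(MDR1 = 1.5, MRP1 = 2, BCRP = 3))),
    b = list(kinetics = mk_series(500), ros = mk_ros(FALSE),
             fits = list(d1 = 40, d2 = 20),
             flow = mk_flow(c(MDR1 = 1.6, MRP1 = 1.5, BCRP = 1.2))),
    c = list(kinetics = mk_series(100), ros = mk_ros(FALSE),
             fits = list(d1 = 90, d2 = 80),
             flow = mk_flow(c(MDR1 = 1.1, MRP1 = 1.1, BCRP = 1.2))))
  ev <- build_evidence(subjects)
  expect_equal(ev$a$accumulated_calcein_norm, 1)
  expect_equal(ev$c$accumulated_calcein_norm, 0)
  expect_equal(ev$b$accumulated_calcein_norm, 0.5)
  expect_equal(ev$a$ic50_rank_norm, 0)
  expect_equal(ev$c$ic50_rank_norm, 1)
  expect_equal(ev$a$retention_norm, 1)

  # missing flow stream is marked, not fatal
  subjects$b$flow <- NULL
  ev2 <- build_evidence(subjects)
  expect_true(is.na(ev2$b$mean_retention_ratio))
  pr <- classify_resistance(ev2$b)
  expect_s3_class(pr, "ResistanceProfile")
  expect_match(pr$rationale, "missing")

  # identical subjects produce identical vectors
  twins <- list(x = subjects$a, y = subjects$a)
  evt <- build_evidence(twins)
  expect_equal(unclass(evt$x)[-1], unclass(evt$y)[-1])
})

test_that("classification tracks the evidence direction", {
  sens_ev <- structure(
    list(subject = "s", accumulated_calcein = 900,
         accumulated_calcein_norm = 1, ic50_rank_norm = 0,
         ros_decay = TRUE, mean_retention_ratio = 2.2,
         retention_norm = 1),
    class = "EvidenceVector")
  res_ev <- sens_ev
  res_ev$accumulated_calcein_norm <- 0
  res_ev$ic50_rank_norm <- 1
  res_ev$ros_decay <- FALSE
  res_ev$retention_norm <- 0

  expect_identical(classify_resistance(sens_ev)$class, "sensitive")
  expect_identical(classify_resistance(res_ev)$class,
                   "highly_resistant")

  all_na <- sens_ev
  all_na$accumulated_calcein_norm <- NA_real_
  all_na$ic50_rank_norm <- NA_real_
  all_na$ros_decay <- NA
  all_na$retention_norm <- NA_real_
  expect_identical(classify_resistance(all_na)$class, "unclassifiable")
})

test_that("lower accumulated calcein never lowers the resistance score", {
  withr::with_seed(31, {
    for (i in 1:25) {
      ev <- structure(
        list(subject = "s", accumulated_calcein = 1,
             accumulated_calcein_norm = runif(1),
             ic50_rank_norm = runif(1),
             ros_decay = runif(1) < 0.5,
             mean_retention_ratio = 1.5, retention_norm = runif(1)),
        class = "EvidenceVector")
      lower <- ev
      lower$accumulated_calcein_norm <-
        ev$accumulated_calcein_norm * runif(1)
      expect_gte(classify_resistance(lower)$score,
                 classify_resistance(ev)$score)
    }
  })
})

test_that("cohort order does not affect any profile", {
  subjects <- list(
    a = list(kinetics = mk_series(900), ros = mk_ros(TRUE)),
    b = list(kinetics = mk_series(500), ros = mk_ros(FALSE)),
    c = list(kinetics = mk_series(100), ros = mk_ros(FALSE)))
  fwd <- lapply(build_evidence(subjects), classify_resistance)
  rev_ev <- lapply(build_evidence(rev(subjects)), classify_resistance)
  for (nm in names(subjects))
    expect_equal(unclass(fwd[[nm]]), unclass(rev_ev[[nm]]))
})

test_that("a cohort of one is flagged as unnormalizable", {
  ev <- build_evidence(list(solo = list(kinetics = mk_series(500),
                                        ros = mk_ros(TRUE))))
  expect_true(is.na(ev$solo$accumulated_calcein_norm))
  pr <- classify_resistance(ev$solo)
  expect_identical(pr$class, "sensitive")  # ROS decay is the only stream
})

test_that("the qualitative three-line pattern maps to the three classes", {
  # uptake LK0917 > LK0902 > LK1108; LK1108 highest IC50s for all drugs;
  # ROS decay only in the sensitive line; BCRP-dominant retention there
  subjects <- list(
    LK0917 = list(kinetics = mk_series(880, "LK0917"), ros = mk_ros(TRUE),
                  fits = list(cisplatin = 14, doxorubicin = 650,
                              methotrexate = 7),
                  flow = mk_flow(c(MDR1 = 1.5, MRP1 = 2, BCRP = 3))),
    LK0902 = list(kinetics = mk_series(470, "LK0902"), ros = mk_ros(FALSE),
                  fits = list(cisplatin = 45, doxorubicin = 2100,
                              methotrexate = 19),
                  flow = mk_flow(c(MDR1 = 1.7, MRP1 = 1.7, BCRP = 1.3))),
    LK1108 = list(kinetics = mk_series(90, "LK1108"), ros = mk_ros(FALSE),
                  fits = list(cisplatin = 130, doxorubicin = 6500,
                              methotrexate = 55),
                  flow = mk_flow(c(MDR1 = 1.1, MRP1 = 1.1, BCRP = 1.2))))
  classes <- vapply(build_evidence(subjects), function(e)
    classify_resistance(e)$class, character(1))
  expect_identical(unname(classes),
                   c("sensitive", "moderately_resistant",
                     "highly_resistant"))
})

test_that("the pipeline runs end to end, skips stages, and is reproducible", {
  cfg <- default_cohort_config(seed = 5, img_size = 96,
                               frame_interval_min = 90,
                               n_flow_events = 2000)
  cfg$segmentation <- "ground_truth"
  rep1 <- run_pipeline(cfg)
  expect_s3_class(rep1, "CohortReport")
  expect_identical(unname(rep1$classes),
                   c("sensitive", "moderately_resistant",
                     "highly_resistant"))

  rep2 <- run_pipeline(cfg)
  expect_identical(cohort_report_json(rep1), cohort_report_json(rep2))

  noflow <- run_pipeline(cfg, stages = c("kinetics", "ros", "ic50"))
  expect_true(all(vapply(noflow$evidence, function(e)
    is.na(e$mean_retention_ratio), logical(1))))
  expect_true(all(noflow$classes %in%
                    c("sensitive", "moderately_resistant",
                      "highly_resistant")))

  out <- file.path(tempdir(), "cohort-report-test")
  run_pipeline(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "kinetics.csv")))
  unlink(out, recursive = TRUE)
})
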