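#' Build normalized evidence vectors for a cohort
#'
#' Assembles the four evidence streams of the workflow -- IC50 ranks
#' from drug screening, accumulated calcein from uptake imaging, the
#' ROS decay flag, and mean inhibitor retention ratios from flow
#' cytometry -- into one normalized vector per subject.  Accumulated
#' calcein and mean retention are min-max normalized across the cohort;
#' IC50 mean ranks are mapped so the most sensitive line (lowest IC50s)
#' is 0 and the most resistant is 1.  Missing streams are marked
#' explicitly and skipped by the classifier.  Normalization needs a
#' cohort of at least 2; for a single subject the normalized fields are
#' flagged as unnormalizable.
#'
#' @param subjects named list; each element is a list with components
#'   `kinetics` (a `KineticSeries`, required), and optionally `fits`
#'   (named list drug -> [fit_dose_response()]), `ros` (a
#'   [ros_timeseries()] result) and `flow` (a [analyze_flow()] report).
#' @return Named list of `"EvidenceVector"` objects.
#' @export
build_evidence <- function(subjects) {
  if (length(subjects) == 0) stop("build_evidence: empty cohort")
  if (any(vapply(subjects, function(s) is.null(s$kinetics), logical(1))))
    stop("build_evidence: every subject needs calcein kinetics")
  nsub <- length(subjects)
  acc <- vapply(subjects, function(s) s$kinetics$accumulated, numeric(1))
  minmax <- function(x) {
    if (length(x) < 2 || diff(range(x, na.rm = TRUE)) == 0)
      return(rep(NA_real_, length(x)))
    (x - min(x, na.rm = TRUE)) / diff(range(x, na.rm = TRUE))
  }
  acc_norm <- minmax(acc)

  have_fits <- vapply(subjects, function(s)
    !is.null(s$fits) && length(s$fits) > 0, logical(1))
  rank_norm <- rep(NA_real_, nsub)
  if (all(have_fits) && nsub >= 2) {
    rk <- tryCatch(
      resistance_rank_from_ic50(lapply(subjects, `[[`, "fits")),
      error = function(e) NULL)
    if (!is.null(rk)) {
      mr <- setNames(rk$mean_rank, rk$cell_line)[names(subjects)]
      rank_norm <- as.numeric(minmax(mr))
    }
  }

  ret <- vapply(subjects, function(s) {
    if (is.null(s$flow)) NA_real_ else mean(s$flow$ratios$ratio)
  }, numeric(1))
  ret_norm <- if (sum(is.finite(ret)) >= 2) {
    rn <- rep(NA_real_, nsub)
    rn[is.finite(ret)] <- minmax(ret[is.finite(ret)])
    rn
  } else rep(NA_real_, nsub)

  out <- lapply(seq_len(nsub), function(i) {
    s <- subjects[[i]]
    structure(
      list(subject = names(subjects)[i],
           accumulated_calcein = unname(acc[i]),
           accumulated_calcein_norm = unname(acc_norm[i]),
           ic50_rank_norm = unname(rank_norm[i]),
           ros_decay = if (is.null(s$ros)) NA else s$ros$decay_flag,
           mean_retention_ratio = unname(ret[i]),
           retention_norm = unname(ret_norm[i])),
      class = "EvidenceVector")
  })
  names(out) <- names(subjects)
  out
}

#' Classify the resistance status of one subject
#'
#' Combines the evidence vector into a resistance score in `[0, 1]`
#' with declared default weights
#' `0.4 (1 - accumulated_norm) + 0.3 ic50_rank_norm +
#'  0.2 (1 - ros_decay) + 0.1 (1 - retention_norm)`,
#' renormalized over the evidence streams that are present.  Scores
#' below 1/3 are called `sensitive`, below 2/3 `moderately_resistant`,
#' else `highly_resistant`.  Weights and thresholds are configurable
#' and echoed in the result; the rationale text cites every evidence
#' component.
#'
#' @param evidence an `"EvidenceVector"` from [build_evidence()].
#' @param weights named weights for `uptake`, `ic50`, `ros`,
#'   `retention`.
#' @param thresholds length-2 increasing vector of class cut points on
#'   the score.
#' @return An object of class `"ResistanceProfile"`.
#' @export
classify_resistance <- function(evidence,
                                weights = c(uptake = 0.4, ic50 = 0.3,
                                            ros = 0.2, retention = 0.1),
                                thresholds = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(evidence, "EvidenceVector"),
            all(c("uptake", "ic50", "ros", "retention") %in%
                  names(weights)),
            length(thresholds) == 2, diff(thresholds) > 0)
  comp <- c(
    uptake = if (is.finite(evidence$accumulated_calcein_norm))
      unname(1 - evidence$accumulated_calcein_norm) else NA_real_,
    ic50 = if (is.finite(evidence$ic50_rank_norm))
      unname(evidence$ic50_rank_norm) else NA_real_,
    ros = if (!is.na(evidence$ros_decay))
      1 - as.numeric(evidence$ros_decay) else NA_real_,
    retention = if (is.finite(evidence$retention_norm))
      unname(1 - evidence$retention_norm) else NA_real_)
  present <- !is.na(comp)
  if (!any(present))
    return(structure(
      list(subject = evidence$subject, class = "unclassifiable",
           score = NA_real_, evidence = evidence,
           weights = weights, thresholds = thresholds,
           rationale = "No usable evidence stream."),
      class = "ResistanceProfile"))
  w <- weights[names(comp)][present]
  score <- sum(w * comp[present]) / sum(w)
  cls <- if (score < thresholds[1]) "sensitive"
         else if (score < thresholds[2]) "moderately_resistant"
         else "highly_resistant"
  fmt <- function(x) ifelse(is.na(x), "missing", sprintf("%.3f", x))
  rationale <- sprintf(
    paste0("score %.3f -> %s. Evidence: accumulated calcein norm %s ",
           "(uptake term %s); IC50 rank norm %s; ROS decay %s; ",
           "retention norm %s (mean ratio %s). Missing streams were ",
           "skipped and weights renormalized."),
    score, cls, fmt(evidence$accumulated_calcein_norm),
    fmt(comp[["uptake"]]), fmt(evidence$ic50_rank_norm),
    if (is.na(evidence$ros_decay)) "missing"
    else as.character(evidence$ros_decay),
    fmt(evidence$retention_norm), fmt(evidence$mean_retention_ratio))
  structure(
    list(subject = evidence$subject, class = cls, score = score,
         evidence = evidence, weights = weights,
         thresholds = thresholds, rationale = rationale),
    class = "ResistanceProfile")
}

#' @export
print.ResistanceProfile <- function(x, ...) {
  cat(sprintf("ResistanceProfile %s: %s (score %s)\n", x$subject,
              x$class, if (is.na(x$score)) "NA" else sprintf("%.3f",
                                                             x$score)))
  cat(" ", x$rationale, "\n")
  invisible(x)
}

#' Map generator phenotype names to resistance classes
#' @param phenotype `"sensitive"`, `"moderate"` or `"resistant"`.
#' @return The corresponding class label used by
#'   [classify_resistance()].
#' @export
phenotype_to_class <- function(phenotype) {
  unname(c(sensitive = "sensitive",
           moderate = "moderately_resistant",
           resistant = "highly_resistant")[phenotype])
}

#' Default simulated three-line cohort configuration
#'
#' The study design used by [run_pipeline()] when no custom
#' configuration is given: three subjects carrying the reference
#' phenotypes ([mdr_phenotypes()]), screened against the three-drug
#' panel at its standard dose ranges (cisplatin 3.33-333 uM,
#' doxorubicin 170-17000 uM, methotrexate 2.2-220 uM), with generating
#' IC50s increasing from the sensitive to the resistant line, and flow
#' retention-ratio patterns that are BCRP-dominant for the sensitive
#' line, MDR1/MRP1-led for the moderate line and uniformly near 1 for
#' the resistant line.
#'
#' @param seed master seed for the run.
#' @param img_size frame side in pixels for simulated stacks.
#' @param frame_interval_min calcein acquisition interval (minutes).
#' @param duration_h calcein acquisition duration (hours).
#' @param n_flow_events flow events per tube.
#' @param plate_noise_sd absorbance noise SD per well.
#' @param segmentation `"baseline"`, `"ground_truth"`, or a trained
#'   `pnet_model`.
#' @return Config list for [run_pipeline()].
#' @export
default_cohort_config <- function(seed = 1, img_size = 256,
                                  frame_interval_min = 20,
                                  duration_h = 12,
                                  n_flow_events = 10000,
                                  plate_noise_sd = 0.04,
                                  segmentation = "baseline") {
  ph <- mdr_phenotypes()
  doses <- function(lo, hi) exp(seq(log(lo), log(hi), length.out = 8))
  list(
    seed = as.integer(seed),
    img_size = img_size,
    frame_interval_min = frame_interval_min,
    duration_h = duration_h,
    ros_interval_min = 20, ros_duration_h = 1,
    segmentation = segmentation,
    radius_frac = 0.27,
    inhomogeneity_amplitude = 0.3,
    background_noise_sd = 500,
    drugs = list(cisplatin = doses(3.33, 333),
                 doxorubicin = doses(170, 17000),
                 methotrexate = doses(2.2, 220)),
    plate_noise_sd = plate_noise_sd,
    plate_replicates = 3,
    flow = list(n_events = n_flow_events, dead_fraction = 0.1,
                baseline_mfi = 500, log_sd = 0.5, replicates = 3),
    subjects = list(
      line_sensitive = list(
        phenotype = ph$sensitive,
        ic50 = c(cisplatin = 15, doxorubicin = 700, methotrexate = 8),
        retention = c(MDR1 = 1.5, MRP1 = 2, BCRP = 3, control = 1)),
      line_moderate = list(
        phenotype = ph$moderate,
        ic50 = c(cisplatin = 40, doxorubicin = 2000, methotrexate = 20),
        retention = c(MDR1 = 1.75, MRP1 = 1.7, BCRP = 1.3, control = 1)),
      line_resistant = list(
        phenotype = ph$resistant,
        ic50 = c(cisplatin = 120, doxorubicin = 6000, methotrexate = 60),
        retention = c(MDR1 = 1.15, MRP1 = 1.1, BCRP = 1.25,
                      control = 1))))
}

# Deterministic per-(subject, stage) sub-seed below 2^31.
derive_seed <- function(seed, subject_i, stage_i) {
  as.integer((as.numeric(seed) * 7919 + subject_i * 101 + stage_i * 13) %%
               2147483563)
}

#' Run the full MDR profiling pipeline on a simulated cohort
#'
#' Executes the whole workflow per subject -- simulate calcein and ROS
#' spheroid stacks, segment, quantify uptake and ROS kinetics, simulate
#' and fit MTS plates for every drug, simulate and analyze the flow
#' assay -- then builds cohort-normalized evidence and classifies every
#' subject.  Any stage may be disabled (`stages`) or fail; the report
#' carries a per-stage status and classification proceeds on the
#' remaining evidence.  The run is a pure function of the config
#' (including its seed).
#'
#' @param config list from [default_cohort_config()] (possibly
#'   modified).
#' @param stages character subset of `c("kinetics", "ros", "ic50",
#'   "flow")`; `"kinetics"` is mandatory.
#' @param out_dir optional directory; when given, writes
#'   `report.json` and tidy `kinetics.csv` / `profiles.csv` there.
#' @return An object of class `"CohortReport"`.
#' @export
run_pipeline <- function(config = default_cohort_config(),
                         stages = c("kinetics", "ros", "ic50", "flow"),
                         out_dir = NULL) {
  stopifnot("kinetics" %in% stages)
  subjects <- config$subjects
  status <- list()
  per_subject <- list()
  for (i in seq_along(subjects)) {
    nm <- names(subjects)[i]
    sub <- subjects[[i]]
    rec <- list()

    geo <- spheroid_geometry(
      radius = round(config$radius_frac * config$img_size),
      inhomogeneity_amplitude = config$inhomogeneity_amplitude,
      background_noise_sd = config$background_noise_sd)

    rec$kinetics <- tryCatch({
      sim <- make_spheroid_stack(
        sub$phenotype, geo,
        frame_interval_min = config$frame_interval_min,
        duration_h = config$duration_h, img_size = config$img_size,
        mode = "calcein", seed = derive_seed(config$seed, i, 1))
      masks <- pipeline_masks(sim, config$segmentation)
      uptake_timeseries(sim$stack, masks, mode = "spheroid",
                        subject = nm)
    }, error = function(e) {
      status[[paste0(nm, ".kinetics")]] <<- conditionMessage(e); NULL
    })

    if ("ros" %in% stages) {
      rec$ros <- tryCatch({
        sim <- make_spheroid_stack(
          sub$phenotype, geo,
          frame_interval_min = config$ros_interval_min,
          duration_h = config$ros_duration_h,
          img_size = config$img_size, mode = "ros",
          seed = derive_seed(config$seed, i, 2))
        masks <- pipeline_masks(sim, config$segmentation)
        ros_timeseries(sim$stack, masks, subject = nm)
      }, error = function(e) {
        status[[paste0(nm, ".ros")]] <<- conditionMessage(e); NULL
      })
    }

    if ("ic50" %in% stages) {
      rec$fits <- tryCatch({
        fits <- list()
        for (d in names(config$drugs)) {
          spec <- plate_spec(
            drug = d, concentrations = config$drugs[[d]],
            true_ic50 = sub$ic50[[d]],
            replicates = config$plate_replicates,
            noise_sd = config$plate_noise_sd, mode = "MCS")
          plate <- make_plate(
            spec, seed = derive_seed(config$seed, i,
                                     10 + match(d, names(config$drugs))))
          fits[[d]] <- fit_dose_response(plate_viability(plate))
        }
        fits
      }, error = function(e) {
        status[[paste0(nm, ".ic50")]] <<- conditionMessage(e); NULL
      })
    }

    if ("flow" %in% stages) {
      rec$flow <- tryCatch({
        fs <- flow_spec(
          n_events = config$flow$n_events,
          dead_fraction = config$flow$dead_fraction,
          baseline_mfi = config$flow$baseline_mfi,
          retention_ratio = sub$retention,
          log_sd = config$flow$log_sd,
          replicates = config$flow$replicates)
        analyze_flow(make_flow_events(
          fs, seed = derive_seed(config$seed, i, 3)))
      }, error = function(e) {
        status[[paste0(nm, ".flow")]] <<- conditionMessage(e); NULL
      })
    }
    per_subject[[nm]] <- rec
  }

  usable <- !vapply(per_subject, function(r) is.null(r$kinetics),
                    logical(1))
  evidence <- build_evidence(per_subject[usable])
  profiles <- lapply(evidence, classify_resistance,
                     weights = config$weights %||%
                       c(uptake = 0.4, ic50 = 0.3, ros = 0.2,
                         retention = 0.1))
  report <- structure(
    list(profiles = profiles, evidence = evidence,
         subject_data = per_subject,
         stage_status = if (length(status)) status else "all stages ok",
         seed = config$seed,
         weights = profiles[[1]]$weights,
         classes = vapply(profiles, `[[`, character(1), "class")),
    class = "CohortReport")
  if (!is.null(out_dir)) write_cohort_report(report, out_dir)
  report
}

pipeline_masks <- function(sim, segmentation) {
  if (inherits(segmentation, "pnet_model")) {
    lapply(sim$stack$phase, function(f) segment(segmentation, f))
  } else if (identical(segmentation, "baseline")) {
    lapply(sim$stack$phase, baseline_segment)
  } else if (identical(segmentation, "ground_truth")) {
    sim$masks
  } else stop("unknown segmentation setting")
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("CohortReport (seed", x$seed, ")\n")
  for (p in x$profiles)
    cat(sprintf("  %s: %s (score %.3f)\n", p$subject, p$class, p$score))
  if (!identical(x$stage_status, "all stages ok"))
    cat("  stage failures:",
        paste(names(x$stage_status), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a cohort report to JSON
#'
#' Deterministic JSON rendering of the classification outcome (used
#' both for writing reports and for byte-identity checks on reruns).
#'
#' @param report a `CohortReport`.
#' @return JSON string.
#' @export
cohort_report_json <- function(report) {
  x <- list(
    seed = report$seed,
    weights = as.list(report$weights),
    subjects = lapply(report$profiles, function(p) list(
      subject = p$subject, class = p$class,
      score = round(p$score, 10),
      evidence = list(
        accumulated_calcein = round(p$evidence$accumulated_calcein, 6),
        accumulated_calcein_norm =
          round(p$evidence$accumulated_calcein_norm, 10),
        ic50_rank_norm = round(p$evidence$ic50_rank_norm, 10),
        ros_decay = p$evidence$ros_decay,
        mean_retention_ratio =
          round(p$evidence$mean_retention_ratio, 6)),
      rationale = p$rationale)),
    stage_status = report$stage_status)
  jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, na = "null")
}

write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(cohort_report_json(report),
             file.path(out_dir, "report.json"))
  kin <- do.call(rbind, lapply(names(report$subject_data), function(nm) {
    ks <- report$subject_data[[nm]]$kinetics
    if (is.null(ks)) return(NULL)
    data.frame(subject = nm, mode = ks$culture_mode,
               channel = ks$channel, time_h = ks$times_h,
               mean_fl = ks$mean_fluorescence,
               accumulated = ks$accumulated)
  }))
  write.csv(kin, file.path(out_dir, "kinetics.csv"), row.names = FALSE)
  prof <- data.frame(
    subject = names(report$classes), class = unname(report$classes),
    score = vapply(report$profiles, `[[`, numeric(1), "score"))
  write.csv(prof, file.path(out_dir, "profiles.csv"), row.names = FALSE)
  invisible(out_dir)
}
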