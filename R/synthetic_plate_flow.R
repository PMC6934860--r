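four_pl <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Simulate an MTS absorbance plate
#'
#' Generates per-well 490 nm and 650 nm absorbances for a dose series
#' plus untreated-control and blank wells.  The blank-corrected
#' A490 - A650 signal of a treated well equals
#' `ctrl_signal * V(c) / 100` where `V` is the generating 4PL viability
#' curve; Gaussian noise of SD `noise_sd` is added to every A490
#' reading.  With `noise_sd = 0` the plate converts back to viability
#' exactly, so dose-response fitting recovers the generating parameters
#' to numerical precision.
#'
#' @param spec a [plate_spec()].
#' @param seed integer seed (pure function of `(spec, seed)`).
#' @return Data frame with columns `well`, `row`, `col`, `drug`,
#'   `conc_uM`, `mode`, `replicate`, `role` (`treated`/`control`/`blank`),
#'   `a490`, `a650`.
#' @export
make_plate <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "PlateSpec"))
  conc <- spec$concentrations
  viab <- four_pl(conc, spec$top, spec$bottom, spec$true_ic50, spec$hill)
  rows <- expand.grid(replicate = seq_len(spec$replicates),
                      conc_uM = conc)
  rows$role <- "treated"
  rows$signal <- spec$ctrl_signal *
    four_pl(rows$conc_uM, spec$top, spec$bottom, spec$true_ic50,
            spec$hill) / 100
  extra <- expand.grid(replicate = seq_len(spec$replicates),
                       conc_uM = NA_real_,
                       role = c("control", "blank"),
                       stringsAsFactors = FALSE)
  extra$signal <- ifelse(extra$role == "control", spec$ctrl_signal, 0)
  wells <- rbind(rows[c("replicate", "conc_uM", "role", "signal")], extra)
  n <- nrow(wells)
  wells$row <- LETTERS[((seq_len(n) - 1) %/% 12) + 1]
  wells$col <- ((seq_len(n) - 1) %% 12) + 1
  wells$well <- paste0(wells$row, wells$col)
  wells$drug <- spec$drug
  wells$mode <- spec$mode
  withr::with_seed(seed, {
    noise <- rnorm(n, sd = spec$noise_sd)
  })
  wells$a650 <- spec$a650
  wells$a490 <- spec$a650 + spec$blank_abs + wells$signal + noise
  wells[c("well", "row", "col", "drug", "conc_uM", "mode", "replicate",
          "role", "a490", "a650")]
}

.flow_tubes <- c(control = "control", MDR1 = "MDR1_verapamil",
                 MRP1 = "MRP1_MK571", BCRP = "BCRP_novobiocin")

#' Simulate a flow-cytometry efflux-assay event table
#'
#' One tube per condition (vehicle control plus the MDR1/verapamil,
#' MRP1/MK-571 and BCRP/novobiocin inhibitor tubes), `replicates` tube
#' sets.  Live/dead status is Bernoulli(`dead_fraction`); PI intensity is
#' log-normal around 1e2 a.u. for live and 1e4 a.u. for dead events;
#' green intensity is log-normal with median
#' `baseline_mfi * retention_ratio[tube]`.
#'
#' @param spec a [flow_spec()].
#' @param seed integer seed (pure function of `(spec, seed)`).
#' @return Data frame with columns `event_id`, `tube`, `replicate`,
#'   `green`, `pi`.
#' @export
make_flow_events <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "FlowSpec"))
  n <- spec$n_events
  out <- withr::with_seed(seed, {
    pieces <- list()
    for (rep_i in seq_len(spec$replicates)) {
      for (tr in names(.flow_tubes)) {
        med <- spec$baseline_mfi * spec$retention_ratio[[tr]]
        green <- rlnorm(n, meanlog = log(med), sdlog = spec$log_sd)
        dead <- runif(n) < spec$dead_fraction
        pi_int <- rlnorm(n, meanlog = ifelse(dead, log(1e4), log(1e2)),
                         sdlog = 0.4)
        pieces[[length(pieces) + 1L]] <- data.frame(
          tube = .flow_tubes[[tr]], replicate = rep_i,
          green = green, pi = pi_int)
      }
    }
    do.call(rbind, pieces)
  })
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("event_id", "tube", "replicate", "green", "pi")]
}
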