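#' Synthetic MDR phenotype
#'
#' Phenomenological description of how a cell line handles calcein-AM and
#' reactive oxygen species (ROS) in the synthetic generator.  Calcein
#' accumulation follows saturating uptake/efflux kinetics
#' \eqn{C(t) = (u/e)(1 - e^{-et})} (linear \eqn{C(t) = ut} when the efflux
#' rate is zero), dye penetration into the spheroid deepens as
#' \eqn{\delta(t) = \delta_{max}(1 - e^{-k_p t})}, and baseline ROS signal
#' decays as \eqn{R(t) = R_0 e^{-\lambda t}}.
#'
#' @param name phenotype label, one of `"sensitive"`, `"moderate"`,
#'   `"resistant"`.
#' @param uptake_rate calcein uptake rate `u` (fluorescence units / hour),
#'   must be positive.
#' @param efflux_rate first-order efflux rate `e` (1/hour), non-negative.
#'   Zero means no active efflux and linear accumulation.
#' @param penetration_max maximal dye penetration depth as a fraction of
#'   the spheroid radius, in `[0, 1]`.  1 means the dye eventually reaches
#'   the core; small values confine fluorescence to the rim.
#' @param penetration_rate rate `k_p` (1/hour) at which the penetration
#'   front deepens.
#' @param ros_init initial ROS fluorescence (arbitrary units) in the
#'   DCFDA assay; zero for phenotypes without measurable ROS activity.
#' @param ros_decay exponential decay rate (1/hour) of the ROS signal.
#'
#' @return An object of class `"SyntheticPhenotype"`.
#' @seealso [mdr_phenotypes()] for the three reference phenotypes,
#'   [uptake_curve()], [make_spheroid_stack()].
#' @export
synthetic_phenotype <- function(name = c("sensitive", "moderate", "resistant"),
                                uptake_rate,
                                efflux_rate = 0,
                                penetration_max = 1,
                                penetration_rate = 1,
                                ros_init = 0,
                                ros_decay = 0) {
  name <- match.arg(name)
  stopifnot(
    "uptake_rate must be > 0" = is.numeric(uptake_rate) && uptake_rate > 0,
    "efflux_rate must be >= 0" = is.numeric(efflux_rate) && efflux_rate >= 0,
    "penetration_max must be in [0, 1]" =
      penetration_max >= 0 && penetration_max <= 1,
    "penetration_rate must be >= 0" = penetration_rate >= 0,
    "ros_init must be >= 0" = ros_init >= 0,
    "ros_decay must be >= 0" = ros_decay >= 0
  )
  structure(
    list(name = name, uptake_rate = uptake_rate, efflux_rate = efflux_rate,
         penetration_max = penetration_max,
         penetration_rate = penetration_rate,
         ros_init = ros_init, ros_decay = ros_decay),
    class = "SyntheticPhenotype"
  )
}

#' Reference phenotypes for the three-line MDR study design
#'
#' The default study conditions used throughout the package: a treatment
#' sensitive line (no efflux, full core penetration, measurable ROS
#' activity that subsides over an hour), a moderately resistant line
#' (slow efflux, partial penetration, no ROS signal) and a highly
#' resistant line (fast efflux, rim-only penetration, no ROS signal).
#' These emulate the qualitative uptake/ROS contrasts seen between a
#' sensitive, a moderately resistant and a highly resistant head-and-neck
#' cancer line grown as spheroids.
#'
#' @return Named list of three [synthetic_phenotype()] objects
#'   (`sensitive`, `moderate`, `resistant`).
#' @export
mdr_phenotypes <- function() {
  list(
    sensitive = synthetic_phenotype(
      "sensitive", uptake_rate = 1500, efflux_rate = 0,
      penetration_max = 1, penetration_rate = 1,
      ros_init = 8000, ros_decay = 1.5),
    moderate = synthetic_phenotype(
      "moderate", uptake_rate = 1500, efflux_rate = 0.12,
      penetration_max = 0.6, penetration_rate = 0.6,
      ros_init = 0, ros_decay = 0),
    resistant = synthetic_phenotype(
      "resistant", uptake_rate = 1500, efflux_rate = 1.5,
      penetration_max = 0.15, penetration_rate = 0.6,
      ros_init = 0, ros_decay = 0)
  )
}

#' Spheroid rendering geometry
#'
#' Geometry and nuisance structure for a rendered spheroid: a disk of
#' given radius whose phase-contrast edge is softened over
#' `boundary_softness` pixels, whose interior intensity is modulated by a
#' smooth multiplicative inhomogeneity field of relative amplitude
#' `inhomogeneity_amplitude`, on top of additive Gaussian pixel noise.
#' Amplitude 0 gives a clean, easily thresholded disk; amplitudes around
#' 0.6 push interior patches below the background level, reproducing the
#' intensity inhomogeneity and poor boundary contrast that defeat
#' classical thresholding of real spheroid images.
#'
#' @param radius spheroid radius in pixels (> 0).
#' @param center integer vector `c(x, y)` in pixels, or `NULL` for the
#'   image center.
#' @param boundary_softness width in pixels of the soft phase-contrast
#'   edge (>= 0).
#' @param inhomogeneity_amplitude relative amplitude in `[0, 1)` of the
#'   low-frequency multiplicative intensity field.
#' @param background_noise_sd standard deviation (fluorescence units) of
#'   additive Gaussian noise on the phase channel; the green channel uses
#'   0.3 times this value.
#' @return An object of class `"SpheroidGeometry"`.
#' @export
spheroid_geometry <- function(radius,
                              center = NULL,
                              boundary_softness = 2,
                              inhomogeneity_amplitude = 0.3,
                              background_noise_sd = 500) {
  stopifnot(
    "radius must be > 0" = is.numeric(radius) && radius > 0,
    "boundary_softness must be >= 0" = boundary_softness >= 0,
    "inhomogeneity_amplitude must be in [0, 1)" =
      inhomogeneity_amplitude >= 0 && inhomogeneity_amplitude < 1,
    "background_noise_sd must be >= 0" = background_noise_sd >= 0
  )
  structure(
    list(radius = radius, center = center,
         boundary_softness = boundary_softness,
         inhomogeneity_amplitude = inhomogeneity_amplitude,
         background_noise_sd = background_noise_sd),
    class = "SpheroidGeometry"
  )
}

#' MTS plate specification
#'
#' Describes one simulated 96-well MTS viability plate: a dose series of
#' one drug plus untreated-control and blank wells.  True viability
#' follows a four-parameter logistic (4PL) curve
#' \eqn{V(c) = bottom + (top - bottom) / (1 + (c/IC_{50})^{hill})} and the
#' blank-corrected A490 - A650 signal is proportional to viability, with
#' Gaussian absorbance noise added per well.
#'
#' @param drug drug label, e.g. `"cisplatin"`.
#' @param concentrations strictly positive, strictly increasing dose
#'   vector in micromolar.
#' @param true_ic50 generating IC50 in micromolar.
#' @param hill Hill slope (dimensionless, > 0).
#' @param top,bottom asymptotic viabilities in percent (`bottom < top`).
#' @param replicates wells per dose (>= 1).
#' @param noise_sd per-well absorbance noise SD (absorbance units).
#' @param ctrl_signal blank-corrected absorbance of untreated controls.
#' @param blank_abs blank-corrected absorbance of blank wells above the
#'   650 nm reference.
#' @param a650 reference-wavelength absorbance common to all wells.
#' @param mode culture mode label, `"2D"` or `"MCS"`.
#' @return An object of class `"PlateSpec"`.
#' @export
plate_spec <- function(drug, concentrations, true_ic50, hill = 1.2,
                       top = 100, bottom = 0, replicates = 3,
                       noise_sd = 0, ctrl_signal = 1.2,
                       blank_abs = 0.05, a650 = 0.04,
                       mode = c("2D", "MCS")) {
  mode <- match.arg(mode)
  stopifnot(
    "concentrations must be strictly positive" = all(concentrations > 0),
    "concentrations must be strictly increasing" =
      all(diff(concentrations) > 0),
    "replicates must be >= 1" = replicates >= 1,
    "true_ic50 must be > 0" = true_ic50 > 0,
    "hill must be > 0" = hill > 0,
    "bottom must be < top" = bottom < top,
    "noise_sd must be >= 0" = noise_sd >= 0,
    "ctrl_signal must be > 0" = ctrl_signal > 0
  )
  structure(
    list(drug = drug, concentrations = concentrations,
         true_ic50 = true_ic50, hill = hill, top = top, bottom = bottom,
         replicates = replicates, noise_sd = noise_sd,
         ctrl_signal = ctrl_signal, blank_abs = blank_abs, a650 = a650,
         mode = mode),
    class = "PlateSpec"
  )
}

#' Flow-cytometry experiment specification
#'
#' Describes a simulated efflux assay run: four reaction tubes (vehicle
#' control plus one per transporter inhibitor), each with `n_events`
#' cells.  Green-detection intensities are log-normal with per-tube
#' median `baseline_mfi * retention_ratio[tube]`; propidium-iodide (PI)
#' intensities are bimodal log-normal (live mode at 1e2, dead mode at
#' 1e4 a.u.), with a `dead_fraction` chance of each event being dead.
#'
#' @param n_events events per tube per replicate (>= 1).
#' @param dead_fraction probability in `[0, 1]` that an event is dead
#'   (PI-high).
#' @param baseline_mfi median green intensity (a.u.) of the live control
#'   population.
#' @param retention_ratio named numeric vector over
#'   `c("MDR1", "MRP1", "BCRP", "control")`; fold increase in median green
#'   retention under each inhibitor.  `control` must equal 1.
#' @param log_sd SD of log green intensity (dimensionless).
#' @param replicates number of replicate tube sets (paper-style
#'   triplicates by default).
#' @return An object of class `"FlowSpec"`.
#' @export
flow_spec <- function(n_events = 10000, dead_fraction = 0.1,
                      baseline_mfi = 500,
                      retention_ratio = c(MDR1 = 1.5, MRP1 = 2, BCRP = 3,
                                          control = 1),
                      log_sd = 0.5, replicates = 3) {
  stopifnot(
    "n_events must be >= 1" = n_events >= 1,
    "dead_fraction must be in [0, 1]" =
      dead_fraction >= 0 && dead_fraction <= 1,
    "baseline_mfi must be > 0" = baseline_mfi > 0,
    "log_sd must be > 0" = log_sd > 0,
    "replicates must be >= 1" = replicates >= 1
  )
  needed <- c("MDR1", "MRP1", "BCRP", "control")
  if (!all(needed %in% names(retention_ratio)))
    stop("retention_ratio must name MDR1, MRP1, BCRP and control")
  if (abs(retention_ratio[["control"]] - 1) > 1e-12)
    stop("control retention ratio must equal 1")
  if (any(retention_ratio < 1))
    stop("retention ratios must be >= 1")
  structure(
    list(n_events = as.integer(n_events), dead_fraction = dead_fraction,
         baseline_mfi = baseline_mfi,
         retention_ratio = retention_ratio[needed],
         log_sd = log_sd, replicates = as.integer(replicates)),
    class = "FlowSpec"
  )
}

#' @export
print.SyntheticPhenotype <- function(x, ...) {
  cat(sprintf(
    "SyntheticPhenotype '%s': u=%.3g/h, e=%.3g/h, delta_max=%.2f, k_p=%.2f/h, ROS %s\n",
    x$name, x$uptake_rate, x$efflux_rate, x$penetration_max,
    x$penetration_rate,
    if (x$ros_init > 0) sprintf("init %.3g decay %.2f/h", x$ros_init,
                                x$ros_decay) else "absent"))
  invisible(x)
}
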