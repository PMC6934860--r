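#' Viability from MTS absorbances
#'
#' Blank-corrected, reference-wavelength-corrected viability:
#' \deqn{100 \times \frac{(A490_t - A650_t) - \bar{B}}
#'                       {(\bar{A490_c} - \bar{A650_c}) - \bar{B}}}
#' where \eqn{\bar{B}} is the mean corrected blank absorbance.
#'
#' @param a490_t,a650_t treated-well absorbances (vectors).
#' @param a490_ctrl,a650_ctrl untreated-control absorbances (means are
#'   taken).
#' @param a490_blank,a650_blank blank-well absorbances (means are
#'   taken).
#' @return Percent viability, same length as `a490_t`.  May exceed 100
#'   under noise.
#' @export
viability_from_absorbance <- function(a490_t, a650_t, a490_ctrl,
                                      a650_ctrl, a490_blank, a650_blank) {
  blank <- mean(a490_blank - a650_blank)
  ctrl <- mean(a490_ctrl - a650_ctrl) - blank
  if (ctrl <= 0)
    stop("viability_from_absorbance: non-positive control signal")
  100 * ((a490_t - a650_t) - blank) / ctrl
}

#' Convert a plate table to a viability table
#'
#' Applies [viability_from_absorbance()] to every treated well of a
#' plate in the standard schema (as produced by [make_plate()]).
#'
#' @param plate data frame with columns `drug`, `conc_uM`, `mode`,
#'   `replicate`, `role`, `a490`, `a650`.
#' @return Data frame `drug`, `mode`, `conc_uM`, `replicate`,
#'   `viability`.
#' @export
plate_viability <- function(plate) {
  need <- c("drug", "conc_uM", "mode", "replicate", "role", "a490", "a650")
  if (!all(need %in% names(plate)))
    stop("plate_viability: plate is missing columns: ",
         paste(setdiff(need, names(plate)), collapse = ", "))
  tr <- plate[plate$role == "treated", ]
  ct <- plate[plate$role == "control", ]
  bl <- plate[plate$role == "blank", ]
  if (nrow(ct) == 0 || nrow(bl) == 0)
    stop("plate_viability: plate needs control and blank wells")
  v <- viability_from_absorbance(tr$a490, tr$a650, ct$a490, ct$a650,
                                 bl$a490, bl$a650)
  data.frame(drug = tr$drug, mode = tr$mode, conc_uM = tr$conc_uM,
             replicate = tr$replicate, viability = v)
}

# 4PL on the log-concentration scale; lic50 = log(ic50).
four_pl_log <- function(lc, top, bottom, lic50, hill) {
  bottom + (top - bottom) / (1 + exp(hill * (lc - lic50)))
}

fit_4pl_fixed <- function(lc, v, start, fixed_lic50 = NULL) {
  if (is.null(fixed_lic50)) {
    form <- v ~ bottom + (top - bottom) / (1 + exp(hill * (lc - lic50)))
  } else {
    form <- v ~ bottom + (top - bottom) /
      (1 + exp(hill * (lc - fixed_lic50)))
    start$lic50 <- NULL
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(lc = lc, v = v),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(coef = coef(fit), ssr = sum(resid(fit)^2))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \eqn{V(c) = bottom + (top - bottom)/(1 + (c/IC_{50})^{hill})} on the
#' log-concentration scale with multi-start initialization (a grid of
#' IC50 and Hill starting values), plus a profile-likelihood confidence
#' interval for the IC50.  The reported IC50 is the curve's inflection
#' concentration (relative IC50), not the absolute 50%-of-control
#' crossing.  Responses whose dynamic range is below 10% of the top
#' plateau are declared non-converged (no meaningful IC50).
#'
#' @param viab viability table (data frame with `conc_uM` and
#'   `viability`; extra columns are carried into the fit label).
#' @param ci_level profile-likelihood confidence level for the IC50.
#' @return An object of class `"DoseResponseFit"`: `top`, `bottom`,
#'   `hill`, `ic50`, `residual_sd`, `converged`, `ci_ic50`, `n`.
#' @export
fit_dose_response <- function(viab, ci_level = 0.9) {
  stopifnot(all(c("conc_uM", "viability") %in% names(viab)))
  viab <- viab[is.finite(viab$viability) & viab$conc_uM > 0, ]
  concs <- sort(unique(viab$conc_uM))
  if (length(concs) < 4)
    stop("fit_dose_response: need >= 4 distinct concentrations")
  lc <- log(viab$conc_uM); v <- viab$viability
  mean_per_conc <- tapply(v, viab$conc_uM, mean)
  drug <- if ("drug" %in% names(viab)) viab$drug[1] else NA
  mode <- if ("mode" %in% names(viab)) viab$mode[1] else NA
  base <- structure(
    list(drug = drug, mode = mode, top = NA_real_, bottom = NA_real_,
         hill = NA_real_, ic50 = NA_real_, residual_sd = NA_real_,
         converged = FALSE, ci_ic50 = c(NA_real_, NA_real_),
         ci_level = ci_level, n = length(v)),
    class = "DoseResponseFit")
  dyn_range <- diff(range(mean_per_conc))
  if (dyn_range < 0.1 * max(mean_per_conc)) return(base)

  top0 <- max(mean_per_conc); bot0 <- min(mean_per_conc)
  best <- NULL
  for (l0 in quantile(log(concs), c(0.15, 0.35, 0.5, 0.65, 0.85))) {
    for (h0 in c(0.5, 1, 2, 4)) {
      f <- fit_4pl_fixed(lc, v, list(top = top0, bottom = bot0,
                                     lic50 = l0, hill = h0))
      if (!is.null(f) && f$coef[["hill"]] > 0 &&
          (is.null(best) || f$ssr < best$ssr)) best <- f
    }
  }
  if (is.null(best)) return(base)
  cf <- best$coef
  n <- length(v)
  base$top <- cf[["top"]]; base$bottom <- cf[["bottom"]]
  base$hill <- cf[["hill"]]; base$ic50 <- exp(cf[["lic50"]])
  base$residual_sd <- sqrt(best$ssr / max(n - 4, 1))
  base$converged <- TRUE
  base$ci_ic50 <- profile_ci_ic50(lc, v, cf, best$ssr, ci_level)
  base
}

# Profile-likelihood CI on log(ic50): walk outward from the estimate,
# refitting the three remaining parameters, until the profiled SSR
# crosses the F-based threshold; linear interpolation at the crossing.
profile_ci_ic50 <- function(lc, v, cf, ssr_min, level,
                            step = 0.08, max_steps = 80) {
  n <- length(v)
  dfree <- max(n - 4, 1)
  thr <- ssr_min * (1 + qf(level, 1, dfree) / dfree)
  if (thr <= ssr_min + 1e-12) thr <- ssr_min + 1e-9  # noiseless data
  start <- list(top = cf[["top"]], bottom = cf[["bottom"]],
                hill = cf[["hill"]], lic50 = NA)
  walk <- function(dir) {
    prev_l <- cf[["lic50"]]; prev_s <- ssr_min
    for (i in seq_len(max_steps)) {
      li <- cf[["lic50"]] + dir * i * step
      f <- fit_4pl_fixed(lc, v, start, fixed_lic50 = li)
      si <- if (is.null(f)) Inf else f$ssr
      if (si >= thr) {
        frac <- if (is.finite(si)) (thr - prev_s) / (si - prev_s) else 1
        return(prev_l + dir * step * frac)
      }
      prev_l <- li; prev_s <- si
    }
    dir * Inf  # open interval: bound not reached within the walk
  }
  exp(c(walk(-1), walk(1)))
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("DoseResponseFit (%s, %s): not converged (flat response)\n",
                x$drug, x$mode))
  } else {
    cat(sprintf(
      "DoseResponseFit (%s, %s): IC50 = %.4g uM [%.4g, %.4g] (%.0f%% PL CI), hill %.3g, top %.3g, bottom %.3g\n",
      x$drug, x$mode, x$ic50, x$ci_ic50[1], x$ci_ic50[2],
      100 * x$ci_level, x$hill, x$top, x$bottom))
  }
  invisible(x)
}

#' Compare 2D and spheroid dose-response fits
#'
#' Fold difference between the spheroid and monolayer IC50s.  The
#' difference is flagged as "large" when the two profile-likelihood
#' confidence intervals are disjoint and the fold change (in either
#' direction) is at least `fold_threshold` -- a declared rule, since
#' figure annotations of "significantly large" differences come with no
#' stated criterion.
#'
#' @param fit_2d,fit_mcs converged [fit_dose_response()] objects.
#' @param fold_threshold minimal fold change to flag.
#' @return List with `fold` (`ic50_mcs / ic50_2d`), `flagged`, `status`.
#' @export
compare_modes <- function(fit_2d, fit_mcs, fold_threshold = 2) {
  if (!isTRUE(fit_2d$converged) || !isTRUE(fit_mcs$converged))
    return(list(fold = NA_real_, flagged = FALSE,
                status = "not-comparable"))
  fold <- fit_mcs$ic50 / fit_2d$ic50
  disjoint <- fit_mcs$ci_ic50[1] > fit_2d$ci_ic50[2] ||
    fit_2d$ci_ic50[1] > fit_mcs$ci_ic50[2]
  list(fold = fold,
       flagged = disjoint && max(fold, 1 / fold) >= fold_threshold,
       status = "ok")
}

extract_ic50 <- function(x) {
  if (inherits(x, "DoseResponseFit")) {
    if (!isTRUE(x$converged)) return(NA_real_)
    x$ic50
  } else as.numeric(x)
}

#' Rank cell lines by IC50-based resistance
#'
#' For every drug shared by all cell lines, ranks the lines by IC50
#' (rank 1 = lowest IC50 = most sensitive) and aggregates by the mean
#' rank across drugs; the line with the highest mean rank is called the
#' most resistant.  Ties are allowed (mean ranks).
#'
#' @param fits named list (cell line) of named lists (drug) of
#'   [fit_dose_response()] objects or bare IC50 values.
#' @return Data frame with `cell_line`, `mean_rank` and one rank column
#'   per drug, ordered from most sensitive to most resistant.
#' @export
resistance_rank_from_ic50 <- function(fits) {
  if (length(fits) < 2)
    stop("resistance_rank_from_ic50: need >= 2 cell lines")
  ic <- lapply(fits, function(per_drug)
    vapply(per_drug, extract_ic50, numeric(1)))
  shared <- Reduce(intersect, lapply(ic, names))
  shared <- shared[vapply(shared, function(d)
    all(vapply(ic, function(x) is.finite(x[[d]]), logical(1))),
    logical(1))]
  if (length(shared) == 0)
    stop("resistance_rank_from_ic50: no drug with converged fits in all lines")
  ranks <- sapply(shared, function(d)
    rank(vapply(ic, `[[`, numeric(1), d)))
  ranks <- matrix(ranks, nrow = length(fits),
                  dimnames = list(names(fits), shared))
  out <- data.frame(cell_line = names(fits),
                    mean_rank = rowMeans(ranks))
  out <- cbind(out, as.data.frame(ranks))
  out[order(out$mean_rank), , drop = FALSE]
}
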