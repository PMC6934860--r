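.transporters <- c(MDR1 = "MDR1_verapamil", MRP1 = "MRP1_MK571",
                   BCRP = "BCRP_novobiocin")

check_flow_events <- function(events) {
  need <- c("tube", "green", "pi")
  if (!all(need %in% names(events)))
    stop("flow events need columns: ", paste(need, collapse = ", "))
  if (nrow(events) == 0) stop("empty flow event table")
  if (!"replicate" %in% names(events)) events$replicate <- 1L
  events
}

#' Gate out PI-positive (dead) events
#'
#' Keeps events whose propidium-iodide intensity lies below a
#' threshold.  In `"auto"` mode the threshold is the minimum of a
#' kernel-density estimate of log10 PI between the live and dead modes;
#' when the PI distribution is unimodal (no valley between two clear
#' modes) a warning is issued and the threshold falls back to the 99th
#' percentile of a declared live reference (or of all events when no
#' reference is given).
#'
#' @param events flow event table (`tube`, `replicate`, `green`, `pi`).
#' @param threshold numeric PI cutoff, or `"auto"`.
#' @param live_reference optional numeric vector of PI values from a
#'   known-live population, used by the fallback.
#' @return The subset of `events` with `pi < threshold`; the threshold
#'   used is attached as attribute `"threshold"`.
#' @export
gate_pi_negative <- function(events, threshold = "auto",
                             live_reference = NULL) {
  events <- check_flow_events(events)
  if (identical(threshold, "auto")) {
    lp <- log10(events$pi + 1)
    if (diff(range(lp)) == 0) {
      # degenerate constant PI: everything is on one side, retain all
      out <- events
      attr(out, "threshold") <- events$pi[1]
      return(out)
    }
    d <- density(lp, n = 512)
    # interior local maxima of the KDE; a genuine live/dead split needs
    # two well-separated modes with a deep valley between them (spurious
    # KDE ripples on a unimodal sample fail both conditions)
    ymax <- which(diff(sign(diff(d$y))) == -2) + 1
    ymax <- ymax[d$y[ymax] > 0.05 * max(d$y)]
    bimodal <- FALSE
    if (length(ymax) >= 2) {
      lo <- min(ymax); hi <- max(ymax)
      valley <- lo + which.min(d$y[lo:hi]) - 1
      bimodal <- (d$x[hi] - d$x[lo] > 0.75) &&
        (d$y[valley] < 0.5 * min(d$y[lo], d$y[hi]))
    }
    if (bimodal) {
      threshold <- 10^d$x[valley] - 1
    } else {
      warning("gate_pi_negative: unimodal PI distribution; using 99th-percentile fallback")
      ref <- if (!is.null(live_reference)) live_reference else events$pi
      threshold <- quantile(ref, 0.99)
    }
  }
  out <- events[events$pi <= threshold, , drop = FALSE]
  attr(out, "threshold") <- as.numeric(threshold)
  out
}

#' Median fluorescence intensity
#'
#' Median of the green-detection intensities of a gated population.
#' For an even number of events the mean of the two middle values is
#' used (flow-software conventions differ; this one is stated).
#'
#' @param events gated flow event table (or numeric vector of green
#'   intensities).
#' @return Scalar MFI (a.u.).
#' @export
mfi <- function(events) {
  g <- if (is.numeric(events)) events else check_flow_events(events)$green
  if (length(g) == 0) stop("mfi: no events")
  median(g)
}

#' Inhibitor retention ratios
#'
#' Ratio of each inhibitor tube's MFI to the control tube's MFI,
#' computed per replicate and averaged.  Ratios near 1 across all
#' inhibitors mean the inhibitors could not raise dye retention --
#' the signature of strong constitutive efflux (a resistant profile).
#'
#' @param tube_mfis data frame with columns `tube`, `replicate`, `mfi`
#'   (as produced by [analyze_flow()]'s intermediate step), or a named
#'   numeric vector of per-tube MFIs for a single replicate.
#' @return Data frame `transporter`, `ratio`, `sd`.
#' @export
retention_ratios <- function(tube_mfis) {
  if (is.numeric(tube_mfis) && !is.null(names(tube_mfis))) {
    tube_mfis <- data.frame(tube = names(tube_mfis), replicate = 1L,
                            mfi = as.numeric(tube_mfis))
  }
  if (!"control" %in% tube_mfis$tube)
    stop("retention_ratios: missing control tube")
  per_rep <- lapply(split(tube_mfis, tube_mfis$replicate), function(df) {
    ctrl <- df$mfi[df$tube == "control"]
    if (length(ctrl) != 1 || !is.finite(ctrl) || ctrl <= 0)
      stop("retention_ratios: control MFI must be a single positive value")
    vapply(names(.transporters), function(tr) {
      m <- df$mfi[df$tube == .transporters[[tr]]]
      if (length(m) != 1) NA_real_ else m / ctrl
    }, numeric(1))
  })
  mat <- do.call(rbind, per_rep)
  data.frame(transporter = colnames(mat),
             ratio = colMeans(mat),
             sd = apply(mat, 2, function(x)
               if (length(x) > 1) sd(x) else NA_real_),
             row.names = NULL)
}

#' Rank transporters by inhibitor retention
#'
#' Orders the three ABC transporters by decreasing retention ratio.
#' Ties are broken alphabetically and flagged.  The interpretation
#' string states whether the pattern looks like effective inhibition
#' (clear retention increase, low-efflux/sensitive profile) or
#' ineffective inhibition of efflux-pump activity (all ratios near 1,
#' resistant profile).
#'
#' @param ratios data frame from [retention_ratios()] (or named numeric
#'   vector of ratios for MDR1/MRP1/BCRP).
#' @param low_ratio_cutoff all ratios below this value trigger the
#'   "ineffective inhibition" reading.
#' @return List with `ranking` (character vector), `ratios`, `tie_flag`,
#'   `interpretation`.
#' @export
rank_transporters <- function(ratios, low_ratio_cutoff = 1.3) {
  r <- if (is.data.frame(ratios))
    setNames(ratios$ratio, ratios$transporter) else ratios
  if (!all(names(.transporters) %in% names(r)))
    stop("rank_transporters: need ratios for MDR1, MRP1 and BCRP")
  r <- r[names(.transporters)]
  ord <- order(-r, names(r))  # descending ratio, alphabetical ties
  ranking <- names(r)[ord]
  tie_flag <- any(duplicated(r))
  interpretation <- if (all(r < low_ratio_cutoff)) {
    paste0("All retention ratios are close to 1: ineffective inhibition",
           " of efflux pump activity, consistent with a resistant",
           " (high constitutive efflux) profile.")
  } else {
    sprintf(paste0("Inhibition of %s raises dye retention most ",
                   "(ratio %.2f), consistent with %s-dominant efflux."),
            ranking[1], r[ranking[1]], ranking[1])
  }
  list(ranking = ranking, ratios = r, tie_flag = tie_flag,
       interpretation = interpretation)
}

#' Full flow-cytometry MDR analysis
#'
#' PI-negative gating, per-tube per-replicate MFI, retention ratios and
#' transporter ranking in one step.
#'
#' @param events flow event table (`tube`, `replicate`, `green`, `pi`).
#' @param threshold PI gate threshold, or `"auto"` (see
#'   [gate_pi_negative()]).
#' @return An object of class `"TransporterReport"`: `tube_mfis`,
#'   `ratios`, `ranking`, `interpretation`, `pi_threshold`,
#'   `live_fraction`.
#' @export
analyze_flow <- function(events, threshold = "auto") {
  events <- check_flow_events(events)
  gated <- gate_pi_negative(events, threshold)
  tube_mfis <- do.call(rbind, lapply(
    split(gated, list(gated$tube, gated$replicate), drop = TRUE),
    function(df) data.frame(tube = df$tube[1],
                            replicate = df$replicate[1],
                            mfi = mfi(df$green))))
  rownames(tube_mfis) <- NULL
  ratios <- retention_ratios(tube_mfis)
  rk <- rank_transporters(ratios)
  structure(
    list(tube_mfis = tube_mfis, ratios = ratios, ranking = rk$ranking,
         tie_flag = rk$tie_flag, interpretation = rk$interpretation,
         pi_threshold = attr(gated, "threshold"),
         live_fraction = nrow(gated) / nrow(events)),
    class = "TransporterReport")
}

#' @export
print.TransporterReport <- function(x, ...) {
  cat(sprintf(
    "TransporterReport: live fraction %.3f (PI gate %.3g)\n",
    x$live_fraction, x$pi_threshold))
  for (i in seq_len(nrow(x$ratios)))
    cat(sprintf("  %s: retention ratio %.3f +/- %.3f\n",
                x$ratios$transporter[i], x$ratios$ratio[i],
                x$ratios$sd[i]))
  cat("  ranking:", paste(x$ranking, collapse = " > "), "\n")
  cat(" ", x$interpretation, "\n")
  invisible(x)
}
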