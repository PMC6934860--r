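#' Saturating calcein uptake/efflux curve
#'
#' Mean intracellular calcein fluorescence after `t` hours of loading at
#' constant uptake rate `u` with first-order efflux `e`:
#' \deqn{C(t) = \frac{u}{e}\left(1 - e^{-e t}\right)}
#' reducing to the linear limit \eqn{C(t) = u t} when `e = 0`.  The curve
#' is non-negative, non-decreasing and bounded by `u/e` for positive
#' efflux, which is what distinguishes efflux-competent (resistant)
#' phenotypes from sensitive ones in the real assay.
#'
#' @param phenotype a [synthetic_phenotype()].
#' @param times non-negative, ascending times in hours.
#' @return Fluorescence values (a.u.), same length as `times`.
#' @export
uptake_curve <- function(phenotype, times) {
  stopifnot(inherits(phenotype, "SyntheticPhenotype"))
  if (any(times < 0)) stop("uptake_curve: times must be non-negative")
  if (is.unsorted(times)) stop("uptake_curve: times must be ascending")
  u <- phenotype$uptake_rate; e <- phenotype$efflux_rate
  if (e == 0) u * times else (u / e) * (1 - exp(-e * times))
}

#' Radial dye penetration factor
#'
#' Attenuation of calcein fluorescence with depth inside the spheroid.
#' Depth is measured from the boundary as a fraction of the radius; the
#' dye front has reached depth `delta`, so pixels shallower than `delta`
#' fluoresce fully while deeper pixels are attenuated exponentially with
#' a fixed 0.05-radius decay length:
#' \deqn{g(d; \delta) = 1 \; (d \le \delta), \quad
#'       e^{-(d-\delta)/0.05} \; (d > \delta)}
#' This yields rim-only fluorescence for low-penetration (resistant)
#' phenotypes and core-filling fluorescence for sensitive ones.
#'
#' @param depth normalized depth-from-boundary in `[0, 1]`.
#' @param delta current front depth in `[0, 1]`.
#' @return Attenuation factors in `(0, 1]`.
#' @export
penetration_factor <- function(depth, delta) {
  ifelse(depth <= delta, 1, exp(-(depth - delta) / 0.05))
}

# Smooth 2-octave multiplicative inhomogeneity field in [1-a, 1+a].
# Coarse Gaussian grids are bilinearly upsampled so the structure is
# low-frequency; normalization by the max absolute value makes the
# amplitude interpretation exact for every seed.
inhomogeneity_field <- function(h, w, amplitude) {
  if (amplitude == 0) return(matrix(1, h, w))
  oct <- function(n, weight) {
    g <- matrix(rnorm(n * n), n, n)
    up <- EBImage::resize(EBImage::Image(g), w = h, h = w)
    weight * EBImage::imageData(up)
  }
  f <- oct(6, 1) + oct(12, 0.5)
  f <- f / max(abs(f))
  1 + amplitude * f
}

quantize16 <- function(x) {
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  matrix(as.integer(round(x)), nrow(x), ncol(x))
}

new_stack <- function(phase, green, times_h, frame_interval_min, meta) {
  structure(
    list(phase = phase, green = green, times_h = times_h,
         frame_interval_min = frame_interval_min, meta = meta),
    class = "TimeLapseStack"
  )
}

#' @export
print.TimeLapseStack <- function(x, ...) {
  d <- dim(x$phase[[1]])
  cat(sprintf(
    "TimeLapseStack: %d frames of %dx%d px (%s), %.1f h at %.0f-min intervals\n",
    length(x$times_h), d[1], d[2],
    paste(x$meta$kind, x$meta$phenotype, sep = "/"),
    max(x$times_h), x$frame_interval_min))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `TimeLapseStack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$times_h)

# Background/foreground intensity levels of the rendered channels
# (16-bit a.u.).  Phase contrast is deliberately low-contrast
# (~1.23x over background) so that segmentation difficulty comes from
# the inhomogeneity field rather than a trivial intensity gap.
.render_levels <- list(phase_bg = 22000, phase_fg = 27000, green_bg = 300)

#' Render a spheroid time-lapse stack with ground-truth masks
#'
#' Renders a two-channel (phase contrast + green fluorescence) image
#' series of one spheroid.  The green signal inside the spheroid follows
#' the phenotype's uptake kinetics ([uptake_curve()]) modulated by the
#' radial penetration front ([penetration_factor()]) with
#' \eqn{\delta(t) = \delta_{max}(1 - e^{-k_p t})}; in `"ros"` mode it
#' instead decays as \eqn{R_0 e^{-\lambda t}} uniformly across the
#' spheroid.  The phase channel shows the disk with a soft edge and a
#' smooth multiplicative intensity-inhomogeneity field (fixed per stack),
#' plus per-frame Gaussian noise in both channels.  Pixels are 16-bit
#' integers.  Identical seeds give bit-identical stacks.
#'
#' @param phenotype a [synthetic_phenotype()].
#' @param geometry a [spheroid_geometry()].
#' @param frame_interval_min acquisition interval in minutes (> 0).
#'   Real acquisitions use 15- or 20-minute intervals; 20 is the default.
#' @param duration_h total duration in hours (> 0; 12 h for calcein,
#'   1 h for ROS runs).
#' @param img_size image side in pixels (square frames).
#' @param mode `"calcein"` for uptake kinetics, `"ros"` for DCFDA decay.
#' @param seed integer seed; the generator is a pure function of
#'   (arguments, seed) and does not disturb the global RNG stream.
#' @return List with `stack` (a `TimeLapseStack`) and `masks` (list of
#'   ground-truth [seg_mask()]s, one per frame, matching the geometry
#'   disk exactly).
#' @export
make_spheroid_stack <- function(phenotype, geometry,
                                frame_interval_min = 20, duration_h = 12,
                                img_size = 256,
                                mode = c("calcein", "ros"),
                                seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(phenotype, "SyntheticPhenotype"),
            inherits(geometry, "SpheroidGeometry"),
            "frame_interval_min must be > 0" = frame_interval_min > 0,
            "duration_h must be > 0" = duration_h > 0)
  h <- w <- as.integer(img_size)
  ctr <- geometry$center %||% c((w + 1) / 2, (h + 1) / 2)
  if (ctr[1] - geometry$radius < 1 || ctr[1] + geometry$radius > w ||
      ctr[2] - geometry$radius < 1 || ctr[2] + geometry$radius > h)
    stop("make_spheroid_stack: geometry does not fit inside the frame")

  times <- seq(0, duration_h, by = frame_interval_min / 60)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  r <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2)
  inside <- r <= geometry$radius
  depth <- pmax(0, (geometry$radius - r) / geometry$radius)  # 0 at rim
  soft <- if (geometry$boundary_softness > 0)
    stats::plogis((geometry$radius - r) / geometry$boundary_softness)
  else as.numeric(inside)

  lv <- .render_levels
  withr::with_seed(seed, {
    inhom <- inhomogeneity_field(h, w, geometry$inhomogeneity_amplitude)
    phase <- vector("list", length(times))
    green <- vector("list", length(times))
    for (k in seq_along(times)) {
      t <- times[k]
      sig <- if (mode == "calcein") {
        delta <- phenotype$penetration_max *
          (1 - exp(-phenotype$penetration_rate * t))
        uptake_curve(phenotype, t) * penetration_factor(depth, delta)
      } else {
        matrix(phenotype$ros_init * exp(-phenotype$ros_decay * t), h, w)
      }
      ph <- lv$phase_bg + (lv$phase_fg * inhom - lv$phase_bg) * soft +
        rnorm(h * w, sd = geometry$background_noise_sd)
      gr <- lv$green_bg + sig * inhom * soft +
        rnorm(h * w, sd = 0.3 * geometry$background_noise_sd)
      phase[[k]] <- quantize16(ph)
      green[[k]] <- quantize16(gr)
    }
  })
  masks <- lapply(seq_along(times), function(k)
    seg_mask(inside, frame_index = k, source = "ground_truth"))
  stack <- new_stack(phase, green, times, frame_interval_min,
                     meta = list(kind = paste0("spheroid-", mode),
                                 phenotype = phenotype$name,
                                 radius = geometry$radius, seed = seed))
  list(stack = stack, masks = masks)
}

#' Render a monolayer (2D culture) time-lapse stack
#'
#' Scattered cell-sized Gaussian blobs whose green fluorescence follows
#' the phenotype's [uptake_curve()]; the spatial pattern of cells is
#' fixed over time so the kinetics are exact, with per-frame noise on
#' top.  A `duration_h` of 0 yields a single frame at t = 0.
#'
#' @inheritParams make_spheroid_stack
#' @param n_cells number of cells to scatter (>= 1).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @return A `TimeLapseStack` (no masks; monolayers are quantified over
#'   edge maps, see [log_edge_map()]).
#' @export
make_monolayer_stack <- function(phenotype, n_cells = 150,
                                 frame_interval_min = 20, duration_h = 12,
                                 img_size = 256, noise_sd = 150,
                                 seed = 1) {
  stopifnot(inherits(phenotype, "SyntheticPhenotype"),
            "frame_interval_min must be > 0" = frame_interval_min > 0,
            "duration_h must be >= 0" = duration_h >= 0)
  if (n_cells < 1) stop("make_monolayer_stack: n_cells must be >= 1")
  h <- w <- as.integer(img_size)
  times <- if (duration_h == 0) 0
           else seq(0, duration_h, by = frame_interval_min / 60)
  lv <- .render_levels
  withr::with_seed(seed, {
    cx <- runif(n_cells, 8, w - 8)
    cy <- runif(n_cells, 8, h - 8)
    cr <- runif(n_cells, 3, 5)
    amp <- exp(rnorm(n_cells, 0, 0.25))
    field <- matrix(0, h, w)
    for (i in seq_len(n_cells)) {
      x0 <- max(1, floor(cx[i] - 3 * cr[i])); x1 <- min(w, ceiling(cx[i] + 3 * cr[i]))
      y0 <- max(1, floor(cy[i] - 3 * cr[i])); y1 <- min(h, ceiling(cy[i] + 3 * cr[i]))
      gx <- exp(-((x0:x1) - cx[i])^2 / (2 * (cr[i] / 1.5)^2))
      gy <- exp(-((y0:y1) - cy[i])^2 / (2 * (cr[i] / 1.5)^2))
      field[y0:y1, x0:x1] <- pmax(field[y0:y1, x0:x1],
                                  amp[i] * outer(gy, gx))
    }
    conc <- uptake_curve(phenotype, times)
    phase <- vector("list", length(times))
    green <- vector("list", length(times))
    for (k in seq_along(times)) {
      ph <- lv$phase_bg + 4000 * field + rnorm(h * w, sd = noise_sd)
      gr <- lv$green_bg + conc[k] * field + rnorm(h * w, sd = noise_sd)
      phase[[k]] <- quantize16(ph)
      green[[k]] <- quantize16(gr)
    }
  })
  new_stack(phase, green, times, frame_interval_min,
            meta = list(kind = "monolayer", phenotype = phenotype$name,
                        n_cells = n_cells, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
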