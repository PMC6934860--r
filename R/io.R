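#' Write a time-lapse stack to multi-page TIFF
#'
#' Writes `<prefix>_phase.tif` and `<prefix>_green.tif` (one 16-bit
#' page per frame) plus a `<prefix>.yaml` sidecar holding the
#' acquisition times and metadata.
#'
#' @param stack a `TimeLapseStack`.
#' @param prefix path prefix (directories are created).
#' @return `prefix`, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  for (ch in c("phase", "green")) {
    pages <- lapply(stack[[ch]], function(m) m / 65535)
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 16)
  }
  yaml::write_yaml(
    list(times_h = as.numeric(stack$times_h),
         frame_interval_min = stack$frame_interval_min,
         meta = stack$meta),
    paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' Read a time-lapse stack written by [write_stack()]
#' @param prefix path prefix used when writing.
#' @return A `TimeLapseStack`.
#' @export
read_stack <- function(prefix) {
  side <- yaml::read_yaml(paste0(prefix, ".yaml"))
  chans <- lapply(c(phase = "phase", green = "green"), function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    lapply(pages, function(m)
      matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
  })
  new_stack(chans$phase, chans$green, as.numeric(side$times_h),
            side$frame_interval_min, side$meta)
}

#' Write ground-truth or predicted masks to multi-page TIFF
#' @param masks list of [seg_mask()]s.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(lapply(masks, function(m) mask_pixels(m) * 1.0), path,
                  bits.per.sample = 8)
  invisible(path)
}

#' Read masks written by [write_masks()]
#' @param path `.tif` path.
#' @param source provenance label to attach.
#' @return List of [seg_mask()]s.
#' @export
read_masks <- function(path, source = "ground_truth") {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(seq_along(pages), function(k)
    seg_mask(pages[[k]] > 0.5, frame_index = k, source = source))
}

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Read an MTS plate table from CSV
#'
#' Schema: `well, row, col, drug, conc_uM, mode, replicate, role, a490,
#' a650` with `role` in treated/control/blank.
#'
#' @param path CSV path.
#' @return Validated plate data frame.
#' @export
read_plate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, c("well", "drug", "conc_uM", "mode",
                           "replicate", "role", "a490", "a650"),
                     "plate table")
  bad <- setdiff(unique(df$role), c("treated", "control", "blank"))
  if (length(bad)) stop("plate table has unknown roles: ",
                        paste(bad, collapse = ", "))
  df
}

#' Read a flow-cytometry event table from CSV
#'
#' Schema: `event_id, tube, replicate, green, pi`; `tube` must come
#' from the fixed set (control plus the three inhibitor tubes).
#'
#' @param path CSV path.
#' @return Validated event data frame.
#' @export
read_flow_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, c("tube", "green", "pi"), "flow event table")
  allowed <- c("control", unname(.transporters))
  bad <- setdiff(unique(df$tube), allowed)
  if (length(bad)) stop("flow event table has unknown tubes: ",
                        paste(bad, collapse = ", "))
  if (any(df$green < 0) || any(df$pi < 0))
    stop("flow intensities must be non-negative")
  df
}
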