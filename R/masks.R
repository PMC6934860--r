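#' Binary segmentation mask
#'
#' Thin container for a single-frame binary spheroid mask together with
#' its provenance.
#'
#' @param pixels binary (0/1) matrix.
#' @param frame_index 1-based index of the frame the mask belongs to.
#' @param source provenance: `"pnet"`, `"baseline"` or `"ground_truth"`.
#' @param empty_flag set when a segmenter produced no foreground.
#' @return An object of class `"SegMask"`.
#' @export
seg_mask <- function(pixels, frame_index = 1L,
                     source = c("ground_truth", "pnet", "baseline"),
                     empty_flag = FALSE) {
  source <- match.arg(source)
  pixels <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  structure(
    list(pixels = pixels, frame_index = as.integer(frame_index),
         source = source, original_size = dim(pixels),
         empty_flag = isTRUE(empty_flag)),
    class = "SegMask"
  )
}

mask_pixels <- function(m) {
  if (inherits(m, "SegMask")) m$pixels else matrix(as.integer(m != 0),
                                                   nrow(m), ncol(m))
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` for two binary masks of identical shape.
#' Two empty masks are defined to agree perfectly (Dice 1).
#'
#' @param a,b `SegMask` objects or binary matrices of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  pa <- mask_pixels(a); pb <- mask_pixels(b)
  if (!all(dim(pa) == dim(pb)))
    stop("dice: masks have different shapes")
  sa <- sum(pa); sb <- sum(pb)
  if (sa + sb == 0) return(1.0)
  2 * sum(pa & pb) / (sa + sb)
}

#' @export
print.SegMask <- function(x, ...) {
  cat(sprintf("SegMask %dx%d (frame %d, source %s): %d foreground px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$frame_index, x$source,
              sum(x$pixels), if (x$empty_flag) " [empty-flagged]" else ""))
  invisible(x)
}
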