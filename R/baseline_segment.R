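#' Classical threshold-based spheroid segmentation
#'
#' The comparator pipeline that works on easy images and degrades when
#' intensity inhomogeneity is strong: Gaussian smoothing, Otsu
#' thresholding, morphological closing, largest connected component,
#' hole filling.
#'
#' @param frame single-channel matrix.
#' @param sigma Gaussian smoothing SD in pixels.
#' @param brush_size diameter of the disc structuring element used for
#'   closing (odd integer).
#' @return A [seg_mask()] with source `"baseline"`; blank (constant)
#'   frames give an empty mask.
#' @export
baseline_segment <- function(frame, sigma = 2, brush_size = 7) {
  rng <- range(frame)
  if (diff(rng) == 0)
    return(seg_mask(matrix(0L, nrow(frame), ncol(frame)),
                    source = "baseline", empty_flag = TRUE))
  img <- EBImage::Image((frame - rng[1]) / diff(rng))
  sm <- EBImage::gblur(img, sigma = sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  bin <- sm > thr
  bin <- EBImage::closing(bin, EBImage::makeBrush(brush_size, "disc"))
  m <- EBImage::imageData(bin)
  if (sum(m) == 0)
    return(seg_mask(matrix(0L, nrow(frame), ncol(frame)),
                    source = "baseline", empty_flag = TRUE))
  seg_mask(postprocess_mask(matrix(as.integer(m), nrow(m), ncol(m))),
           source = "baseline")
}
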