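#' Knock-in cluster intensity in a colocalized mask
#'
#' Quantifies endogenous-tag levels (e.g. eGFP-beta-actin) inside
#' presynaptic boutons: both confocal channels are filtered by a Gaussian
#' blur (sigma = 2 pixels), auto-thresholded with Otsu's method, and their
#' binary masks intersected (marker-positive AND tag-positive). Connected
#' components of the intersection become ROIs and the mean of the
#' super-resolved (STED) channel is reported inside each.
#'
#' @param confocal_marker Confocal bouton-marker image (matrix, e.g. vGLUT1).
#' @param confocal_tag Confocal image of the tagged protein.
#' @param sted_tag Registered STED image of the tagged protein.
#' @param blur_sigma Gaussian blur SD in pixels.
#' @return A tibble with `roi_id`, `area_px`, `mean_sted`. If the masks are
#'   disjoint the tibble is empty and attribute `zero_rois` is `TRUE`
#'   (check with [has_zero_rois()]).
#' @export
ki_cluster_intensity <- function(confocal_marker, confocal_tag, sted_tag,
                                 blur_sigma = 2) {
  dims <- list(dim(confocal_marker), dim(confocal_tag), dim(sted_tag))
  if (length(unique(dims)) != 1) {
    abort("The three images must have identical dimensions.")
  }
  mask <- otsu_mask(confocal_marker, blur_sigma) &
    otsu_mask(confocal_tag, blur_sigma)
  if (!any(mask)) {
    return(structure(tibble(roi_id = integer(), area_px = integer(),
                            mean_sted = numeric()),
                     zero_rois = TRUE))
  }
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  out <- purrr::map_dfr(seq_len(max(labels)), function(lab) {
    pix <- which(labels == lab)
    tibble(roi_id = lab, area_px = length(pix),
           mean_sted = mean(sted_tag[pix]))
  })
  structure(out, zero_rois = FALSE)
}

#' @rdname ki_cluster_intensity
#' @param x A [ki_cluster_intensity()] result.
#' @export
has_zero_rois <- function(x) isTRUE(attr(x, "zero_rois"))

otsu_mask <- function(img, blur_sigma) {
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                          sigma = blur_sigma))
  rng <- range(sm)
  if (diff(rng) <= .Machine$double.eps) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  sm01 <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(sm01), range = c(0, 1))
  sm01 > thr
}
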