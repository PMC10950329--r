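#' Detect responding boutons in a time-lapse video
#'
#' Builds a stimulus-response difference image (mean of `k_post` frames after
#' stimulus onset minus the mean baseline frame; sign flipped for the
#' down-going CypHer indicator), smooths it with a Gaussian, thresholds it by
#' Otsu's method, labels connected components within the configured area
#' bounds and keeps components whose trace shows a peak deflection
#' dF/F0 of at least `response_threshold`. Videos yielding fewer than
#' `min_responders` ROIs (20 by default, the per-video analysis floor) are
#' flagged excluded rather than silently analysed.
#'
#' @param video Numeric array (height x width x frames) or the list returned
#'   by [simulate_video()] / [load_timelapse()].
#' @param protocol The [stim_protocol()] of the recording.
#' @param indicator `"phluorin"` or `"cypher"`.
#' @param smooth_sigma Gaussian smoothing SD, pixels.
#' @param k_post Number of post-onset frames averaged for the difference
#'   image; defaults to the frames spanning the stimulus train.
#' @param min_area,max_area Component area bounds, pixels.
#' @param response_threshold Minimum peak dF/F0 for a responder.
#' @param min_responders Exclusion floor (videos below it are flagged).
#' @return A tibble of class `bouton_rois`, sorted by descending response
#'   amplitude, with columns `roi_id`, `centroid_x`, `centroid_y`, `area`,
#'   `amplitude` (peak dF/F0) and a list-column `pixels` of linear pixel
#'   indices. Attributes: `excluded` (logical), `exclusion_reason`.
#' @examples
#' sim <- simulate_video(sim_config(seed = 3), n_boutons = 6, n_silent = 2,
#'                       frame_shape = c(64, 64), min_separation = 12)
#' rois <- detect_responding_boutons(sim$video, sim$protocol, "phluorin",
#'                                   min_responders = 5)
#' nrow(rois)
#' @export
detect_responding_boutons <- function(video, protocol,
                                      indicator = c("phluorin", "cypher"),
                                      smooth_sigma = 2, k_post = NULL,
                                      min_area = 4, max_area = 400,
                                      response_threshold = 0.05,
                                      min_responders = 20) {
  if (is.list(video) && !is.null(video$video)) video <- video$video
  indicator <- match.arg(indicator)
  stopifnot(inherits(protocol, "stim_protocol"))
  n_frames <- dim(video)[3]
  onset_frame <- floor(protocol$stim_onset / protocol$frame_interval) + 1
  n_base <- baseline_frames(indicator)
  if (n_frames < onset_frame + 2 || onset_frame <= n_base) {
    abort("Video must contain the baseline window and post-stimulus frames.")
  }
  k_post <- k_post %||%
    max(2L, ceiling(protocol$duration / protocol$frame_interval) + 1L)
  post_idx <- seq(onset_frame + 1, min(onset_frame + k_post, n_frames))

  base_img <- apply(video[, , seq_len(n_base), drop = FALSE], c(1, 2), mean)
  post_img <- apply(video[, , post_idx, drop = FALSE], c(1, 2), mean)
  diff_img <- if (indicator == "phluorin") post_img - base_img else
    base_img - post_img
  diff_img[diff_img < 0] <- 0

  sm <- EBImage::gblur(EBImage::Image(diff_img), sigma = smooth_sigma)
  sm <- EBImage::imageData(sm)
  rng <- range(sm)
  if (diff(rng) <= .Machine$double.eps) {
    return(empty_rois("no stimulus-locked signal in the difference image"))
  }
  sm01 <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(sm01), range = c(0, 1))
  # Otsu always splits the histogram somewhere; require the threshold to
  # clear a robust noise floor so a response-free video yields no ROIs.
  floor_val <- stats::median(sm01) + 5 * stats::mad(sm01)
  thr <- max(thr, floor_val)
  if (!any(sm01 > thr)) {
    return(empty_rois("no stimulus-locked signal above the noise floor"))
  }
  labels <- EBImage::bwlabel(EBImage::Image(sm01 > thr))
  labels <- EBImage::imageData(labels)
  n_lab <- max(labels)
  if (n_lab == 0) {
    return(empty_rois("no components above the Otsu threshold"))
  }

  rois <- vector("list", n_lab)
  keep <- 0L
  for (lab in seq_len(n_lab)) {
    pix <- which(labels == lab)
    if (length(pix) < min_area || length(pix) > max_area) next
    tr <- roi_trace(video, pix)
    f0 <- mean(tr[seq_len(n_base)])
    if (f0 <= 0) next
    sign <- if (indicator == "cypher") -1 else 1
    amp <- max(sign * (tr - f0)) / f0
    if (amp < response_threshold) next
    rc <- arrayInd(pix, dim(video)[1:2])
    keep <- keep + 1L
    rois[[keep]] <- tibble(
      roi_id = NA_integer_, centroid_x = mean(rc[, 2]),
      centroid_y = mean(rc[, 1]), area = length(pix),
      amplitude = amp, pixels = list(pix))
  }
  if (keep == 0L) {
    return(empty_rois("no components passed the response threshold"))
  }
  out <- dplyr::bind_rows(rois[seq_len(keep)]) |>
    dplyr::arrange(dplyr::desc(.data$amplitude)) |>
    dplyr::mutate(roi_id = dplyr::row_number())
  excluded <- nrow(out) < min_responders
  structure(out, class = c("bouton_rois", class(tibble())),
            excluded = excluded,
            exclusion_reason = if (excluded) {
              sprintf("only %d responding boutons (floor %d)",
                      nrow(out), min_responders)
            } else NA_character_)
}

empty_rois <- function(reason) {
  structure(tibble(roi_id = integer(), centroid_x = numeric(),
                   centroid_y = numeric(), area = integer(),
                   amplitude = numeric(), pixels = list()),
            class = c("bouton_rois", class(tibble())),
            excluded = TRUE, exclusion_reason = reason)
}

#' @rdname detect_responding_boutons
#' @param rois A `bouton_rois` tibble.
#' @export
is_excluded <- function(rois) isTRUE(attr(rois, "excluded"))

#' @rdname detect_responding_boutons
#' @export
exclusion_reason <- function(rois) attr(rois, "exclusion_reason")

roi_trace <- function(video, pixels) {
  npix <- dim(video)[1] * dim(video)[2]
  n_frames <- dim(video)[3]
  mat <- matrix(video, nrow = npix, ncol = n_frames)
  colMeans(mat[pixels, , drop = FALSE])
}

#' Measure background-corrected ROI traces
#'
#' For each ROI, F(t) is the mean pixel intensity inside the ROI minus the
#' mean intensity of the background region, per frame. The background region
#' must be disjoint from every ROI; by default it is chosen automatically as
#' the dimmest decile of baseline-image pixels outside all ROIs.
#'
#' @param video Numeric array (height x width x frames) or a
#'   [simulate_video()] / [load_timelapse()] result.
#' @param rois A `bouton_rois` tibble from [detect_responding_boutons()].
#' @param protocol The recording's [stim_protocol()].
#' @param indicator `"phluorin"` or `"cypher"`.
#' @param background_region Optional integer vector of linear pixel indices;
#'   overlapping any ROI is an error.
#' @return A `fluor_trace` tibble (`roi_id`, `frame`, `time_s`, `f`) with the
#'   indicator and protocol attached.
#' @export
measure_roi_traces <- function(video, rois, protocol,
                               indicator = c("phluorin", "cypher"),
                               background_region = NULL) {
  if (is.list(video) && !is.null(video$video)) video <- video$video
  indicator <- match.arg(indicator)
  roi_pixels <- unlist(rois$pixels)
  if (is.null(background_region)) {
    # Select dim pixels on the mean over ALL frames: selecting on a subset
    # of frames would correlate the region with those frames' noise and
    # bias the baseline of every trace.
    mean_img <- apply(video, c(1, 2), mean)
    candidates <- setdiff(seq_along(mean_img), roi_pixels)
    cutoff <- quantile(mean_img[candidates], 0.1)
    background_region <- candidates[mean_img[candidates] <= cutoff]
  } else if (length(intersect(background_region, roi_pixels)) > 0) {
    abort("`background_region` overlaps an ROI.")
  }
  bg <- roi_trace(video, background_region)
  t <- frame_times(protocol)
  traces <- purrr::map2(rois$roi_id, rois$pixels, function(id, pix) {
    tibble(roi_id = as.character(id), frame = seq_along(t), time_s = t,
           f = roi_trace(video, pix) - bg)
  })
  new_fluor_trace(dplyr::bind_rows(traces), indicator = indicator,
                  protocol = protocol)
}
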