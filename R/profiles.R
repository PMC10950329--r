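#' Specify a line profile across the synaptic cleft
#'
#' The line is placed perpendicular to the synaptic cleft: `length` nm along
#' the synaptic axis, averaged over `width` nm perpendicular to it, sampled
#' every `sample_spacing` nm (the pixel size). At the defaults (1000 nm, 18.9
#' nm spacing) the profile has `floor(1000/18.9) + 1 = 53` samples.
#'
#' @param center Line centre in pixel coordinates, `c(x, y)`.
#' @param direction Direction of the synaptic axis (need not be normalised).
#' @param length Profile length, nm.
#' @param width Averaging width perpendicular to the line, nm.
#' @param sample_spacing Sample spacing, nm.
#' @return An object of class `line_spec`.
#' @export
line_spec <- function(center, direction = c(1, 0), length = 1000,
                      width = 400, sample_spacing = 18.9) {
  if (length <= 0 || width <= 0 || sample_spacing <= 0) {
    abort("`length`, `width` and `sample_spacing` must be positive.")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) abort("`direction` must be non-zero.")
  structure(list(center = center, direction = direction / nrm,
                 length = length, width = width,
                 sample_spacing = sample_spacing),
            class = "line_spec")
}

bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  if (any(x < 1 | x > w | y < 1 | y > h)) {
    abort("Line footprint falls outside the image bounds.")
  }
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Extract a multichannel line profile
#'
#' Samples each channel along the line of `line`, averaging over the line
#' width perpendicular to it using bilinear interpolation of pixel values.
#'
#' @param image A `sted_image` from [simulate_sted_synapse()], a named list
#'   of channel matrices, or a 3-D array (height x width x channel).
#' @param line A [line_spec()].
#' @param pixel_size Image pixel size in nm (taken from a `sted_image`
#'   automatically).
#' @return A tibble of class `line_profile` with `sample`, `offset_nm`
#'   (signed distance from the line centre), `channel`, `intensity`.
#' @export
extract_line_profile <- function(image, line, pixel_size = NULL) {
  if (inherits(image, "sted_image")) {
    pixel_size <- pixel_size %||% image$pixel_size
    channels <- image$channels
  } else if (is.array(image) && length(dim(image)) == 3) {
    channels <- lapply(seq_len(dim(image)[3]), function(k) image[, , k])
    names(channels) <- dimnames(image)[[3]] %||%
      paste0("ch", seq_along(channels))
  } else {
    channels <- image
  }
  if (is.null(pixel_size)) abort("`pixel_size` is required.")
  stopifnot(inherits(line, "line_spec"))

  n_axis <- floor(line$length / line$sample_spacing) + 1
  axis_off <- (seq_len(n_axis) - (n_axis + 1) / 2) * line$sample_spacing
  n_w <- floor(line$width / line$sample_spacing) + 1
  width_off <- (seq_len(n_w) - (n_w + 1) / 2) * line$sample_spacing
  d <- line$direction
  p <- c(-d[2], d[1])

  grid <- expand.grid(a = axis_off, w = width_off)
  xs <- line$center[1] + (grid$a * d[1] + grid$w * p[1]) / pixel_size
  ys <- line$center[2] + (grid$a * d[2] + grid$w * p[2]) / pixel_size

  prof <- purrr::imap(channels, function(img, nm) {
    vals <- bilinear_sample(img, xs, ys)
    tibble(sample = seq_len(n_axis), offset_nm = axis_off, channel = nm,
           intensity = rowMeans(matrix(vals, nrow = n_axis)))
  })
  structure(dplyr::bind_rows(prof),
            class = c("line_profile", class(tibble())),
            sample_spacing = line$sample_spacing)
}

#' Align a profile to the reference maximum and orient it
#'
#' Shifts positions so the raw maximum of the reference (presynaptic marker)
#' channel sits at 0 nm — ties broken toward the profile centre — and flips
#' the axis, if needed, so the postsynaptic channel's intensity-weighted
#' centroid lies at negative positions. With this convention the presynaptic
#' compartment extends toward positive positions and the asymmetric
#' integration window (-37.8 to +151.4 nm) points away from the postsynapse.
#' The operation is idempotent.
#'
#' @param profile A [extract_line_profile()] result or an already-aligned
#'   `synapse_profile`.
#' @param reference_channel,post_channel Channel names of the presynaptic
#'   reference and the postsynaptic marker.
#' @return A tibble of class `synapse_profile` with `position_nm` (0 at the
#'   reference maximum), `channel`, `raw` and `norm` (per-channel
#'   max-normalized). Attribute `flipped` records the orientation flip.
#' @export
align_and_orient <- function(profile, reference_channel = "ref",
                             post_channel = "post") {
  dat <- as_tibble(profile)
  pos_col <- if ("position_nm" %in% names(dat)) "position_nm" else "offset_nm"
  val_col <- if ("raw" %in% names(dat)) "raw" else "intensity"
  spacing <- attr(profile, "sample_spacing") %||% {
    ps <- sort(unique(dat[[pos_col]]))
    min(diff(ps))
  }
  ref <- dat[dat$channel == reference_channel, ]
  if (nrow(ref) == 0) abort("Reference channel not found in the profile.")
  ref <- ref[order(ref[[pos_col]]), ]
  if (diff(range(ref[[val_col]])) <= .Machine$double.eps) {
    abort("Reference channel is flat; cannot align.")
  }
  n <- nrow(ref)
  vmax <- max(ref[[val_col]])
  cand <- which(ref[[val_col]] == vmax)
  centre <- (n + 1) / 2
  idx_max <- cand[which.min(abs(cand - centre))]
  shift <- ref[[pos_col]][idx_max]

  out <- dat
  out$position_nm <- out[[pos_col]] - shift
  out$raw <- out[[val_col]]

  post <- out[out$channel == post_channel, ]
  tot <- sum(post$raw)
  centroid <- if (tot > 0) sum(post$position_nm * post$raw) / tot else 0
  flipped <- centroid > 0
  if (flipped) out$position_nm <- -out$position_nm
  already <- isTRUE(attr(profile, "flipped"))
  out <- out |>
    dplyr::select("position_nm", "channel", "raw") |>
    dplyr::arrange(.data$channel, .data$position_nm) |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(norm = .data$raw / max(.data$raw)) |>
    dplyr::ungroup()
  structure(out, class = c("synapse_profile", class(tibble())),
            flipped = xor(flipped, already), sample_spacing = spacing)
}

#' Average max-normalized localization profiles across synapses
#'
#' Each channel of each synapse profile is divided by its own maximum (set to
#' 1) and the normalized profiles are averaged pointwise on the common
#' position grid (the intersection of the aligned grids), giving mean and SEM
#' per channel and position.
#'
#' @param profiles A list of `synapse_profile` objects, or one tibble with a
#'   `synapse_id` column.
#' @return A tibble of class `localization_profile` with `position_nm`,
#'   `channel`, `mean_norm`, `sem`, `n`.
#' @export
localization_profile <- function(profiles) {
  if (inherits(profiles, "synapse_profile")) profiles <- list(profiles)
  if (is.list(profiles) && !is.data.frame(profiles)) {
    spacings <- vapply(profiles, function(p) {
      attr(p, "sample_spacing") %||% NA_real_
    }, numeric(1))
    if (length(unique(round(spacings, 9))) != 1) {
      abort("Profiles have inconsistent sample spacings.")
    }
    dat <- dplyr::bind_rows(
      purrr::imap(profiles, function(p, i) {
        dplyr::mutate(as_tibble(p), synapse_id = i)
      }))
  } else {
    dat <- as_tibble(profiles)
    if (!"synapse_id" %in% names(dat)) dat$synapse_id <- 1L
  }
  if (nrow(dat) == 0) abort("At least one profile is required.")

  dat$pos_key <- round(dat$position_nm, 4)
  common <- dat |>
    dplyr::distinct(.data$synapse_id, .data$pos_key) |>
    dplyr::count(.data$pos_key) |>
    dplyr::filter(.data$n == dplyr::n_distinct(dat$synapse_id))
  if (nrow(common) == 0) {
    abort("Aligned profiles share no common position grid.")
  }
  dat |>
    dplyr::filter(.data$pos_key %in% common$pos_key) |>
    dplyr::group_by(position_nm = .data$pos_key, .data$channel) |>
    dplyr::summarise(
      mean_norm = mean(.data$norm),
      sem = if (dplyr::n() > 1) sd(.data$norm) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop") |>
    structure(class = c("localization_profile", class(tibble())))
}

#' The presynaptic integration window
#'
#' The closed window over which raw protein-of-interest profiles are
#' integrated: the span of the averaged reference (Bassoon) distribution,
#' -37.8 to +151.4 nm around its maximum, i.e. -2 to +8 samples on the
#' 18.9 nm grid (11 samples).
#'
#' @param lower,upper Window bounds in nm; `lower < 0 < upper`.
#' @return An object of class `presyn_window`.
#' @export
presyn_window <- function(lower = -37.8, upper = 151.4) {
  if (!(lower < 0 && 0 < upper)) abort("Window must satisfy lower < 0 < upper.")
  structure(list(lower = lower, upper = upper), class = "presyn_window")
}

#' Integrate the presynaptic level of a protein of interest
#'
#' Sums the raw (non-normalized) samples of `channel` at aligned positions p
#' with `lower <= p <= upper` (closed window; 11 samples at the defaults).
#' The sum is linear in the channel intensity, so constant factors cancel in
#' percent-of-control comparisons.
#'
#' @param profile An aligned `synapse_profile`.
#' @param window A [presyn_window()].
#' @param channel Channel to integrate (default `"poi"`).
#' @return The integrated level (raw intensity units), a single number.
#' @export
integrate_presynaptic_level <- function(profile, window = presyn_window(),
                                        channel = "poi") {
  stopifnot(inherits(window, "presyn_window"))
  dat <- as_tibble(profile)
  ch <- dat[dat$channel == channel, ]
  if (nrow(ch) == 0) abort(sprintf("Channel '%s' not in profile.", channel))
  span <- range(ch$position_nm)
  if (window$lower < span[1] - 1e-6 || window$upper > span[2] + 1e-6) {
    abort("Integration window extends outside the profile span.")
  }
  tol <- 1e-6
  sel <- ch$position_nm >= window$lower - tol &
    ch$position_nm <= window$upper + tol
  sum(ch$raw[sel])
}

#' @rdname integrate_presynaptic_level
#' @param profiles A list of aligned `synapse_profile` objects.
#' @return `presynaptic_levels()`: a tibble with `synapse_id` and `level`.
#' @export
presynaptic_levels <- function(profiles, window = presyn_window(),
                               channel = "poi") {
  tibble(
    synapse_id = seq_along(profiles),
    level = vapply(profiles, integrate_presynaptic_level, numeric(1),
                   window = window, channel = channel))
}

#' Normalize levels to a control group set to 100
#'
#' Divides every level by the mean level of the control group and multiplies
#' by 100, so the control mean maps to 100 by construction.
#'
#' @param levels A tibble with columns `group` and `level`.
#' @param control_label The control group's label.
#' @return The input with an added `percent_of_control` column.
#' @examples
#' normalize_levels(
#'   tibble::tibble(group = c("ctr", "ctr", "ctr", "kd", "kd"),
#'                  level = c(2, 2, 2, 1, 3)), "ctr")
#' @export
normalize_levels <- function(levels, control_label) {
  dat <- as_tibble(levels)
  ctrl <- dat$level[dat$group == control_label]
  if (length(ctrl) == 0) abort("Control group is empty.")
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) {
    abort("Control group mean must be positive.")
  }
  dplyr::mutate(dat, percent_of_control = .data$level / m * 100)
}
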