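#' Surface normalization of background-corrected traces
#'
#' Computes the basal fluorescence F0 (mean of the first 5 frames for
#' pHluorin, first 10 for CypHer — always that fixed window, regardless of
#' when the stimulus starts) and normalises each trace to it. For pHluorin
#' the fold increase max(F)/F0 reports apparent exocytosis; for CypHer the
#' exocytic amplitude is the downward deflection F0 - min(F), also reported
#' as a fraction of F0.
#'
#' @param traces A `fluor_trace` tibble (one or more `roi_id` groups),
#'   background-corrected (and bleach-corrected for CypHer).
#' @return The trace tibble with added columns `f0` and `f_surf` (= F/F0).
#'   A per-ROI summary tibble (`roi_id`, `f0`, `fold_increase`,
#'   `exo_amplitude`, `exo_fraction_of_f0`) is attached as attribute
#'   `"surface_summary"` and returned by [surface_summary()].
#' @examples
#' tr <- simulate_trace(sim_config(noise_sd_fraction = 0))
#' surface_summary(surface_normalize(tr))
#' @export
surface_normalize <- function(traces) {
  ind <- trace_indicator(traces)
  if (is.null(ind)) abort("`traces` must carry an indicator attribute.")
  nb <- baseline_frames(ind)
  dat <- as_tibble(traces)
  summ <- dat |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(
      f0 = mean(.data$f[seq_len(nb)]),
      fmax = max(.data$f), fmin = min(.data$f), .groups = "drop") |>
    dplyr::mutate(
      fold_increase = if (ind == "phluorin") .data$fmax / .data$f0 else NA_real_,
      exo_amplitude = if (ind == "cypher") .data$f0 - .data$fmin else NA_real_,
      exo_fraction_of_f0 = .data$exo_amplitude / .data$f0) |>
    dplyr::select(-"fmax", -"fmin")
  if (any(summ$f0 <= 0)) {
    abort(sprintf("Non-positive F0 for ROI(s) %s; trace rejected.",
                  paste(summ$roi_id[summ$f0 <= 0], collapse = ", ")))
  }
  out <- dat |>
    dplyr::left_join(dplyr::select(summ, "roi_id", "f0"), by = "roi_id") |>
    dplyr::mutate(f_surf = .data$f / .data$f0)
  out <- restore_trace_attrs(out, traces)
  attr(out, "surface_summary") <- summ
  out
}

#' @rdname surface_normalize
#' @param x A trace tibble returned by [surface_normalize()].
#' @export
surface_summary <- function(x) attr(x, "surface_summary")

#' Peak normalization: baseline-subtracted traces scaled to their maximum
#'
#' Subtracts F0 from every frame to yield the deflection dF — for CypHer the
#' sign is flipped (dF = F0 - F) so both indicators become positive-going —
#' and divides by the peak deflection dFmax, giving norm. dF in \[~0, 1\]
#' with an exact maximum of 1 at the peak frame (earliest frame on ties).
#' The result is invariant to affine rescaling aF + b (a > 0) of the raw
#' trace.
#'
#' @param traces A background-corrected (and, for CypHer, bleach-corrected)
#'   `fluor_trace` tibble.
#' @param on_nonresponder What to do with traces whose peak deflection is not
#'   positive: `"error"` (default) or `"drop"` them with a warning.
#' @return A tibble of class `norm_traces` with columns `roi_id`, `frame`,
#'   `time_s`, `norm_df`. Per-ROI `f0`, `df_max`, `peak_index`, `peak_time`
#'   are attached as attribute `"peak_summary"` ([peak_summary()]).
#' @examples
#' tr <- simulate_trace(sim_config(noise_sd_fraction = 0))
#' nt <- peak_normalize(tr)
#' max(nt$norm_df)
#' @export
peak_normalize <- function(traces, on_nonresponder = c("error", "drop")) {
  on_nonresponder <- match.arg(on_nonresponder)
  ind <- trace_indicator(traces)
  if (is.null(ind)) abort("`traces` must carry an indicator attribute.")
  nb <- baseline_frames(ind)
  sign <- if (ind == "cypher") -1 else 1
  dat <- as_tibble(traces)

  protocol <- trace_protocol(traces)
  per_roi <- dat |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::mutate(f0 = mean(.data$f[seq_len(nb)]),
                  df = sign * (.data$f - .data$f0)) |>
    dplyr::mutate(peak_index = find_peak(.data$time_s, .data$df, protocol),
                  df_max = .data$df[.data$peak_index[1]]) |>
    dplyr::ungroup()

  bad <- per_roi |>
    dplyr::distinct(.data$roi_id, .data$df_max) |>
    dplyr::filter(.data$df_max <= 0)
  if (nrow(bad) > 0) {
    msg <- sprintf("Non-responding trace(s) (peak deflection <= 0): %s",
                   paste(bad$roi_id, collapse = ", "))
    if (on_nonresponder == "error") abort(msg)
    warn(paste(msg, "- dropped."))
    per_roi <- dplyr::filter(per_roi, !.data$roi_id %in% bad$roi_id)
    if (nrow(per_roi) == 0) abort("All traces were non-responders.")
  }

  summ <- per_roi |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(f0 = .data$f0[1], df_max = .data$df_max[1],
                     peak_index = .data$peak_index[1],
                     peak_time = .data$time_s[.data$peak_index[1]],
                     .groups = "drop")
  out <- per_roi |>
    dplyr::mutate(norm_df = .data$df / .data$df_max) |>
    dplyr::select("roi_id", "frame", "time_s", "norm_df")
  out <- structure(out, class = c("norm_traces", class(tibble())),
                   indicator = ind, protocol = trace_protocol(traces))
  attr(out, "peak_summary") <- summ
  out
}

#' @rdname peak_normalize
#' @param x A `norm_traces` tibble.
#' @export
peak_summary <- function(x) attr(x, "peak_summary")

# Peak frame of the stimulus response. When the stimulation protocol is
# known, the search is restricted to the train window plus a two-frame lag
# (the physiological extremum sits at the end of the train); otherwise the
# global maximum is used. Earliest frame wins ties either way.
find_peak <- function(time_s, y, protocol = NULL) {
  if (!is.null(protocol)) {
    lo <- protocol$stim_onset
    hi <- protocol$stim_onset + protocol$duration +
      2 * protocol$frame_interval
    idx <- which(time_s >= lo - 1e-9 & time_s <= hi + 1e-9)
    if (length(idx) > 0) return(idx[which.max(y[idx])])
  }
  which.max(y)
}

#' Average raw bouton traces into one per-video trace
#'
#' The ROI analysis averages the background-corrected fluorescence of all
#' responding boutons of a video at each time point, yielding one raw trace
#' per video; normalization and fitting then operate on that per-video
#' trace. Each ROI contributes with equal weight.
#'
#' @param traces A multi-ROI `fluor_trace` tibble from one video.
#' @param roi_id Identifier given to the averaged trace.
#' @return A single-ROI `fluor_trace` tibble.
#' @export
video_mean_trace <- function(traces, roi_id = "video") {
  dat <- as_tibble(traces)
  out <- dat |>
    dplyr::group_by(.data$frame, .data$time_s) |>
    dplyr::summarise(f = mean(.data$f), .groups = "drop") |>
    dplyr::arrange(.data$frame) |>
    dplyr::mutate(roi_id = roi_id) |>
    dplyr::select("roi_id", "frame", "time_s", "f")
  restore_trace_attrs(out, traces)
}

#' Pointwise average of peak-normalized traces
#'
#' Averages norm. dF traces on their common time base, returning the
#' per-frame mean, SEM and n. The averaging unit is whatever `unit_col`
#' identifies — per-video mean traces in the standard workflow (each video
#' contributing the average of its >= 20 responding boutons), or individual
#' boutons when `unit_col = "roi_id"`.
#'
#' @param traces A `norm_traces` tibble, or any tibble with `time_s`, a value
#'   column and a unit column.
#' @param unit_col Column identifying the averaging unit.
#' @param value_col Column holding the normalized deflection.
#' @return A tibble of class `avg_trace` with `frame`, `time_s`, `norm_df`
#'   (mean), `sem` and `n`.
#' @export
average_traces <- function(traces, unit_col = "roi_id",
                           value_col = "norm_df") {
  dat <- as_tibble(traces)
  if (!all(c(unit_col, value_col, "time_s") %in% names(dat))) {
    abort("`traces` must contain time_s, the unit column and the value column.")
  }
  lens <- dat |>
    dplyr::group_by(.data[[unit_col]]) |>
    dplyr::summarise(n = dplyr::n(), t0 = min(.data$time_s),
                     t1 = max(.data$time_s), .groups = "drop")
  if (dplyr::n_distinct(lens$n) != 1 || dplyr::n_distinct(lens$t0) != 1 ||
      dplyr::n_distinct(lens$t1) != 1) {
    abort("Traces do not share a common time base (mixed protocols?).")
  }
  n_units <- nrow(lens)
  out <- dat |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(
      sem = if (dplyr::n() > 1) sd(.data[[value_col]]) / sqrt(dplyr::n()) else 0,
      norm_df = mean(.data[[value_col]]),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$time_s) |>
    dplyr::mutate(frame = dplyr::row_number()) |>
    dplyr::select("frame", "time_s", "norm_df", "sem", "n")
  structure(out, class = c("avg_trace", class(tibble())),
            indicator = attr(traces, "indicator"),
            protocol = attr(traces, "protocol"),
            n_units = n_units)
}
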