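#' Configure a multi-condition simulated experiment
#'
#' Bundles the per-condition simulator settings, the stimulation protocol and
#' the analysis options of an end-to-end run. Exactly one condition is the
#' control (the first by default).
#'
#' @param conditions Named list of [sim_config()] objects, one per condition;
#'   names must be unique.
#' @param control Label of the control condition.
#' @param protocol A [stim_protocol()] shared by all conditions.
#' @param n_videos Videos per condition.
#' @param n_boutons,n_silent Responding and silent boutons per video.
#' @param frame_shape Video height and width, pixels.
#' @param min_responders Per-video analysis floor (videos with fewer
#'   responding boutons are excluded).
#' @param normalize_unit `"video"` (default): boutons of a video are averaged
#'   into one raw trace which is then corrected and peak-normalized, matching
#'   the per-video ROI-average analysis; `"bouton"`: each bouton trace is
#'   normalized first and the normalized traces averaged.
#' @param detect_args Extra arguments passed to
#'   [detect_responding_boutons()].
#' @param video_args Extra arguments passed to [simulate_video()].
#' @param seed Master seed; per-video seeds are derived from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(conditions, control = names(conditions)[1],
                              protocol = NULL, n_videos = 8, n_boutons = 25,
                              n_silent = 5, frame_shape = c(128, 128),
                              min_responders = 20,
                              normalize_unit = c("video", "bouton"),
                              detect_args = list(),
                              video_args = list(), seed = 1L) {
  normalize_unit <- match.arg(normalize_unit)
  if (is.null(names(conditions)) || anyDuplicated(names(conditions))) {
    abort("`conditions` must be a uniquely named list.")
  }
  ok <- vapply(conditions, inherits, logical(1), "sim_config")
  if (!all(ok)) abort("Every condition must be a `sim_config`.")
  if (!control %in% names(conditions)) {
    abort("`control` must name one of the conditions.")
  }
  indicators <- unique(vapply(conditions, `[[`, character(1), "indicator"))
  if (length(indicators) != 1) {
    abort("All conditions must use the same indicator.")
  }
  protocol <- protocol %||% protocol_200ap(indicators)
  structure(
    list(conditions = conditions, control = control, protocol = protocol,
         indicator = indicators, n_videos = n_videos, n_boutons = n_boutons,
         n_silent = n_silent, frame_shape = frame_shape,
         min_responders = min_responders, normalize_unit = normalize_unit,
         detect_args = detect_args,
         video_args = video_args, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run the end-to-end two-condition experiment
#'
#' For every condition and video: simulate the time-lapse, detect responding
#' boutons, exclude videos under the responder floor, measure
#' background-corrected traces, bleach-correct (CypHer), peak-normalize,
#' average the video's boutons, and fit the video's tau. Each condition's
#' headline tau comes from fitting the average of its per-video mean traces
#' (videos are the averaging unit). Per-video tau values feed the
#' normality-gated comparison across conditions. Fully reproducible given
#' the config seed; the report carries a config hash for provenance.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, the report (JSON) and tidy
#'   CSVs of per-video fits are written there.
#' @return A list of class `run_report`: `conditions` (tibble with tau, rss,
#'   n_videos, n_boutons), `video_fits` (per-video tau), `excluded` (video,
#'   condition, reason), `stats` (a `stat_result` or `NULL`), `config_hash`,
#'   `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  protocol <- config$protocol
  indicator <- config$indicator
  cond_names <- names(config$conditions)

  video_fits <- list()
  excluded <- list()
  cond_rows <- list()
  video_avgs <- list()

  for (ci in seq_along(cond_names)) {
    cname <- cond_names[ci]
    base_cfg <- config$conditions[[cname]]
    taus <- numeric(0)
    n_boutons_total <- 0L
    avgs <- list()
    for (vj in seq_len(config$n_videos)) {
      vseed <- derive_seed(config$seed, ci, vj)
      vcfg <- modify_config(base_cfg, seed = vseed)
      sim <- do.call(simulate_video, c(
        list(config = vcfg, protocol = protocol,
             n_boutons = config$n_boutons, n_silent = config$n_silent,
             frame_shape = config$frame_shape),
        config$video_args))
      rois <- do.call(detect_responding_boutons, c(
        list(video = sim$video, protocol = protocol, indicator = indicator,
             min_responders = config$min_responders),
        config$detect_args))
      if (is_excluded(rois)) {
        excluded[[length(excluded) + 1]] <- tibble(
          condition = cname, video = vj,
          reason = paste0("below_responder_floor: ", exclusion_reason(rois)))
        next
      }
      traces <- measure_roi_traces(sim$video, rois, protocol, indicator)
      if (config$normalize_unit == "video") {
        vt <- video_mean_trace(traces)
        if (indicator == "cypher") vt <- bleach_correct(vt)
        nt <- peak_normalize(vt)
        avg <- average_traces(nt, unit_col = "roi_id")
      } else {
        if (indicator == "cypher") traces <- bleach_correct(traces)
        nt <- peak_normalize(traces, on_nonresponder = "drop")
        avg <- average_traces(nt, unit_col = "roi_id")
      }
      fit <- fit_decay(avg)
      taus <- c(taus, fit$tau)
      n_boutons_total <- n_boutons_total + nrow(rois)
      video_fits[[length(video_fits) + 1]] <- tibble(
        condition = cname, video = vj, tau = fit$tau, rss = fit$rss,
        n_boutons = nrow(rois), converged = fit$converged)
      avgs[[length(avgs) + 1]] <- dplyr::mutate(as_tibble(avg), video = vj)
    }
    if (length(avgs) == 0) {
      cond_rows[[ci]] <- tibble(condition = cname, tau = NA_real_,
                                rss = NA_real_, n_videos = 0L,
                                n_boutons = 0L, excluded = TRUE)
      next
    }
    cond_avg <- average_traces(dplyr::bind_rows(avgs), unit_col = "video")
    attr(cond_avg, "protocol") <- protocol
    cond_fit <- fit_decay(cond_avg)
    cond_rows[[ci]] <- tibble(condition = cname, tau = cond_fit$tau,
                              rss = cond_fit$rss,
                              n_videos = length(taus),
                              n_boutons = n_boutons_total, excluded = FALSE)
    video_avgs[[cname]] <- cond_avg
  }

  video_fits <- dplyr::bind_rows(video_fits)
  conditions <- dplyr::bind_rows(cond_rows)
  excluded <- if (length(excluded)) dplyr::bind_rows(excluded) else
    tibble(condition = character(), video = integer(), reason = character())

  stats <- NULL
  usable <- conditions$condition[!conditions$excluded]
  if (length(usable) >= 2 && nrow(video_fits) > 0) {
    tau_tbl <- video_fits |>
      dplyr::filter(.data$condition %in% usable) |>
      dplyr::transmute(group = .data$condition, value = .data$tau)
    plan <- normality_gate(tau_tbl,
                           n_experiments = min(table(tau_tbl$group)))
    stats <- compare_groups(tau_tbl, plan)
  }

  report <- structure(
    list(conditions = conditions, video_fits = video_fits,
         excluded = excluded, stats = stats,
         condition_averages = video_avgs,
         control = config$control,
         config_hash = rlang::hash(config), seed = config$seed),
    class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

derive_seed <- function(seed, condition_index, video_index) {
  as.integer((seed * 7919 + condition_index * 613 + video_index * 17) %%
               .Machine$integer.max)
}

modify_config <- function(config, ...) {
  args <- utils::modifyList(unclass(config), list(...))
  do.call(sim_config, args)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$conditions)
  if (nrow(x$excluded) > 0) {
    cat(sprintf("%d excluded video(s)\n", nrow(x$excluded)))
  }
  if (!is.null(x$stats)) {
    cat(sprintf("comparison: %s, p = %.3g\n", x$stats$test[1],
                x$stats$p_value[1]))
  }
  invisible(x)
}

write_run_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write.csv(report$video_fits, file.path(out_dir, "video_fits.csv"),
            row.names = FALSE)
  write.csv(report$conditions, file.path(out_dir, "conditions.csv"),
            row.names = FALSE)
  write.csv(report$excluded, file.path(out_dir, "excluded.csv"),
            row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    out <- list(
      conditions = report$conditions, excluded = report$excluded,
      stats = if (!is.null(report$stats)) as_tibble(report$stats) else NULL,
      config_hash = report$config_hash, seed = report$seed)
    jsonlite::write_json(out, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out_dir)
}
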