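#' Write and read time-lapse videos as multi-frame TIFF
#'
#' Videos are stored as multi-frame grayscale TIFF (16-bit by default) with a
#' YAML sidecar (`<path>.yaml`) recording the frame interval and any extra
#' metadata, so a written video can be re-loaded without external context.
#' Pixel values are rounded to integers and clamped to the sample depth, so
#' integer-valued videos round-trip bitwise.
#'
#' @param video Numeric array, height x width x frames (counts), or a
#'   [simulate_video()] result.
#' @param path Output TIFF path.
#' @param frame_interval Acquisition interval in seconds (taken from an
#'   attached protocol if available).
#' @param bits 8 or 16 bit sample depth.
#' @param metadata Named list of extra sidecar fields (e.g. indicator, seed).
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(video, path, frame_interval = NULL, bits = 16,
                            metadata = list()) {
  if (is.list(video) && !is.null(video$video)) {
    frame_interval <- frame_interval %||% video$protocol$frame_interval
    video <- video$video
  }
  if (is.null(frame_interval)) abort("`frame_interval` is required.")
  if (!bits %in% c(8, 16)) abort("`bits` must be 8 or 16.")
  maxval <- 2^bits - 1
  frames <- lapply(seq_len(dim(video)[3]), function(k) {
    pmin(pmax(round(video[, , k]), 0), maxval) / maxval
  })
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  sidecar <- c(list(frame_interval = frame_interval, bits = bits,
                    n_frames = dim(video)[3]), metadata)
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_timelapse
#' @param protocol Optional [stim_protocol()]; the frame count must match.
#' @return `load_timelapse()`: a list with `video` (integer counts array),
#'   `frame_interval`, `bits` and `path`.
#' @export
load_timelapse <- function(path, frame_interval = NULL, protocol = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  sidecar_path <- paste0(path, ".yaml")
  sidecar <- if (file.exists(sidecar_path)) {
    yaml::read_yaml(sidecar_path)
  } else {
    list()
  }
  frame_interval <- frame_interval %||% sidecar$frame_interval
  if (is.null(frame_interval)) {
    abort("Frame interval missing: no sidecar metadata and no override given.")
  }
  if (!is.null(protocol) && length(frames) != protocol$n_frames) {
    abort(sprintf("Video has %d frames but the protocol specifies %d.",
                  length(frames), protocol$n_frames))
  }
  video <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (k in seq_along(frames)) video[, , k] <- frames[[k]]
  bits <- sidecar$bits %||% if (max(video) > 255) 16 else 8
  list(video = video, frame_interval = frame_interval, bits = bits,
       path = path)
}

#' Export tidy per-ROI traces to CSV
#'
#' @param traces A `fluor_trace` or `norm_traces` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  write.csv(as_tibble(traces), path, row.names = FALSE)
  invisible(path)
}

#' Read and write experiment configurations as YAML
#'
#' Serialises an [experiment_config()] (including its simulator conditions
#' and protocol) to a versioned YAML schema and back.
#'
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @return `write_experiment_config()` returns `path` invisibly;
#'   `read_experiment_config()` returns the reconstructed
#'   `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  ser <- list(
    schema = "endokin/experiment-config/1",
    conditions = lapply(config$conditions, unclass),
    control = config$control,
    protocol = unclass(config$protocol),
    n_videos = config$n_videos, n_boutons = config$n_boutons,
    n_silent = config$n_silent, frame_shape = config$frame_shape,
    min_responders = config$min_responders, seed = config$seed)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "endokin/experiment-config/1")) {
    abort("Unrecognised experiment-config schema.")
  }
  conditions <- lapply(raw$conditions, function(cc) {
    do.call(sim_config, cc[setdiff(names(cc), character(0))])
  })
  prot <- raw$protocol
  experiment_config(
    conditions = conditions, control = raw$control,
    protocol = stim_protocol(prot$frequency, prot$duration, prot$stim_onset,
                             prot$frame_interval, prot$total_duration),
    n_videos = raw$n_videos, n_boutons = raw$n_boutons,
    n_silent = raw$n_silent, frame_shape = unlist(raw$frame_shape),
    min_responders = raw$min_responders, seed = raw$seed)
}
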