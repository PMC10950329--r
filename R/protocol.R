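#' Define an action-potential stimulation protocol
#'
#' A protocol describes the electrical field stimulation and acquisition
#' timing of a live-imaging experiment: an AP train of `frequency` Hz lasting
#' `duration` s, delivered `stim_onset` s into a recording of
#' `total_duration` s sampled every `frame_interval` s.
#'
#' The number of APs is `round(frequency * duration)`. Frames are indexed from
#' 1 with frame 1 at t = 0, so a 100 s recording at 2 s intervals has 50
#' frames and a `stim_onset` of 10 s means frames 1-5 are pre-stimulus
#' baseline.
#'
#' @param frequency Stimulation frequency in Hz.
#' @param duration Train duration in seconds.
#' @param stim_onset Time of the first AP in seconds.
#' @param frame_interval Acquisition interval in seconds (0.5 Hz frame rate
#'   gives 2 s).
#' @param total_duration Recording length in seconds; must be an integer
#'   multiple of `frame_interval`.
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol(40, 5)            # 200 AP train
#' protocol_40ap()
#' @export
stim_protocol <- function(frequency = 40, duration = 5, stim_onset = 10,
                          frame_interval = 2, total_duration = 100) {
  vals <- c(frequency = frequency, duration = duration,
            stim_onset = stim_onset, frame_interval = frame_interval,
            total_duration = total_duration)
  if (!all(is.finite(vals))) {
    abort("All protocol parameters must be finite numbers.")
  }
  if (frequency <= 0 || duration <= 0 || frame_interval <= 0 ||
      total_duration <= 0 || stim_onset < 0) {
    abort("Protocol times and rates must be positive.")
  }
  n_frames <- total_duration / frame_interval
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    abort("`total_duration` must be an integer multiple of `frame_interval`.")
  }
  if (stim_onset + duration > total_duration) {
    abort("The stimulus train must end within the recording.")
  }
  structure(
    list(frequency = frequency, duration = duration,
         n_aps = as.integer(round(frequency * duration)),
         stim_onset = stim_onset, frame_interval = frame_interval,
         total_duration = total_duration,
         n_frames = as.integer(round(n_frames))),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d AP (%g Hz, %g s), onset %g s, %d frames @ %g s\n",
              x$n_aps, x$frequency, x$duration, x$stim_onset,
              x$n_frames, x$frame_interval))
  invisible(x)
}

#' Standard stimulation protocols
#'
#' The three train protocols used throughout the pipeline: 200 AP (40 Hz,
#' 5 s), 80 AP (40 Hz, 2 s) and 40 AP (20 Hz, 2 s), acquired at 0.5 Hz for
#' 100 s. The stimulus onset leaves the baseline window the indicator
#' requires: 5 frames (10 s) for pHluorin, 10 frames (20 s) for CypHer.
#'
#' @param indicator `"phluorin"` or `"cypher"`; sets the stimulus onset so the
#'   required baseline window precedes it.
#' @return A [stim_protocol()].
#' @export
protocol_200ap <- function(indicator = "phluorin") {
  stim_protocol(40, 5, stim_onset = default_onset(indicator))
}

#' @rdname protocol_200ap
#' @export
protocol_80ap <- function(indicator = "phluorin") {
  stim_protocol(40, 2, stim_onset = default_onset(indicator))
}

#' @rdname protocol_200ap
#' @export
protocol_40ap <- function(indicator = "phluorin") {
  stim_protocol(20, 2, stim_onset = default_onset(indicator))
}

default_onset <- function(indicator) {
  switch(match.arg(indicator, c("phluorin", "cypher")),
         phluorin = 10, cypher = 20)
}

#' Number of baseline frames for an indicator
#'
#' The basal fluorescence F0 is the mean of the first 5 frames for pHluorin
#' and the first 10 frames for CypHer.
#'
#' @param indicator `"phluorin"` or `"cypher"`.
#' @return Integer frame count.
#' @export
baseline_frames <- function(indicator) {
  switch(match.arg(indicator, c("phluorin", "cypher")),
         phluorin = 5L, cypher = 10L)
}

check_baseline_window <- function(protocol, indicator) {
  need <- baseline_frames(indicator) * protocol$frame_interval
  if (protocol$stim_onset < need) {
    abort(sprintf(
      "Stimulus onset (%g s) precedes the %d-frame (%g s) baseline window required for %s.",
      protocol$stim_onset, baseline_frames(indicator), need, indicator))
  }
  invisible(protocol)
}

frame_times <- function(protocol) {
  (seq_len(protocol$n_frames) - 1) * protocol$frame_interval
}
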