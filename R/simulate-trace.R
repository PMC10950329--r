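#' Simulate a single-bouton fluorescence trace
#'
#' Samples the surface-pool kinetic model described in [sim_config()] on the
#' acquisition grid of `protocol` and returns a per-frame intensity trace for
#' one bouton. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param protocol A [stim_protocol()]; defaults to the 200 AP train with the
#'   onset appropriate for the indicator.
#' @param amplitude Bouton intensity scale in counts; defaults to
#'   `config$amplitude_mean`.
#' @param roi_id Identifier recorded in the output.
#' @return A tibble of class `fluor_trace` with columns `roi_id`, `frame`,
#'   `time_s` and `f` (raw intensity, counts). The indicator, protocol,
#'   config and the noiseless ground truth are stored as attributes
#'   (retrievable with `trace_truth()`).
#' @examples
#' tr <- simulate_trace(sim_config(tau_endo = 20, noise_sd_fraction = 0))
#' head(tr)
#' @export
simulate_trace <- function(config, protocol = NULL,
                           amplitude = config$amplitude_mean,
                           roi_id = "bouton_1") {
  stopifnot(inherits(config, "sim_config"))
  protocol <- protocol %||% default_protocol(config)
  stopifnot(inherits(protocol, "stim_protocol"))
  check_baseline_window(protocol, config$indicator)

  t <- frame_times(protocol)
  s <- surface_pool(t, config$tau_endo, config$exo_fraction,
                    protocol$stim_onset, protocol$duration)
  signal <- reporter_signal(s, config$resting_surface_fraction,
                            config$indicator)
  noiseless <- amplitude * signal * exp(-t / config$tau_bleach) +
    config$background_level

  set.seed(config$seed)
  noise <- if (config$noise_sd_fraction > 0) {
    rnorm(length(t), sd = config$noise_sd_fraction * amplitude)
  } else {
    numeric(length(t))
  }

  out <- tibble(roi_id = roi_id, frame = seq_along(t), time_s = t,
                f = noiseless + noise)
  new_fluor_trace(out, indicator = config$indicator, protocol = protocol,
                  truth = tibble(frame = seq_along(t), time_s = t,
                                 s_pool = s, noiseless = noiseless),
                  config = config)
}

#' Construct a fluorescence trace from measured data
#'
#' Builds the tidy per-frame trace container used throughout the kinetic
#' analysis from raw vectors, e.g. when importing ROI measurements made
#' outside this package.
#'
#' @param time_s Frame times in seconds (uniformly spaced, increasing).
#' @param f Background-corrected intensity per frame, counts.
#' @param indicator `"phluorin"` or `"cypher"`.
#' @param protocol Optional [stim_protocol()].
#' @param roi_id Trace identifier.
#' @return A `fluor_trace` tibble.
#' @export
fluor_trace <- function(time_s, f, indicator = c("phluorin", "cypher"),
                        protocol = NULL, roi_id = "roi_1") {
  indicator <- match.arg(indicator)
  if (length(time_s) != length(f)) {
    abort("`time_s` and `f` must have equal length.")
  }
  if (length(time_s) >= 2) {
    dt <- diff(time_s)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
      abort("`time_s` must be strictly increasing and uniformly spaced.")
    }
  }
  if (!all(is.finite(f))) abort("`f` must be finite.")
  new_fluor_trace(
    tibble(roi_id = roi_id, frame = seq_along(time_s), time_s = time_s, f = f),
    indicator = indicator, protocol = protocol)
}

new_fluor_trace <- function(data, indicator, protocol, truth = NULL,
                            config = NULL) {
  structure(data,
            class = c("fluor_trace", class(tibble())),
            indicator = indicator, protocol = protocol,
            truth = truth, config = config)
}

#' Metadata accessors for trace objects
#'
#' `trace_indicator()`, `trace_protocol()` and `trace_truth()` return the
#' indicator, acquisition protocol and (for simulated data) the noiseless
#' ground truth attached to a trace tibble.
#'
#' @param x A `fluor_trace` or derived object.
#' @return The requested attribute.
#' @export
trace_indicator <- function(x) attr(x, "indicator")

#' @rdname trace_indicator
#' @export
trace_protocol <- function(x) attr(x, "protocol")

#' @rdname trace_indicator
#' @export
trace_truth <- function(x) attr(x, "truth")

# Rebuild trace metadata after dplyr operations strip attributes.
restore_trace_attrs <- function(out, template) {
  new_fluor_trace(out, indicator = attr(template, "indicator"),
                  protocol = attr(template, "protocol"),
                  truth = attr(template, "truth"),
                  config = attr(template, "config"))
}

#' Combine single-bouton traces into one tidy table
#'
#' @param traces A list of `fluor_trace` tibbles sharing indicator and
#'   protocol.
#' @return One `fluor_trace` tibble with all rows; metadata from the first
#'   element.
#' @export
bind_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  ind <- unique(vapply(traces, trace_indicator, character(1)))
  if (length(ind) != 1) abort("Traces mix indicators.")
  out <- dplyr::bind_rows(lapply(traces, as_tibble))
  restore_trace_attrs(out, traces[[1]])
}
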