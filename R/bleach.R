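#' Photobleaching correction for CypHer traces
#'
#' CypHer recordings bleach appreciably, so before normalization the decay
#' constant of the bleaching curve is estimated by least-squares fitting of
#' the first `fit_frames` (pre-stimulation) frames to a mono-exponential
#' B(t) = b0 * exp(-t / tau_bleach). The default correction adds back the
#' cumulative loss, F_corr(t) = F(t) + (B(0) - B(t)), which leaves a
#' signal-free exponential baseline exactly constant. The literal variant
#' (`mode = "literal"`), which adds B(t) itself, is available for
#' comparison but shifts and tilts the baseline.
#'
#' For each fixed tau the amplitude b0 is profiled out analytically, leaving
#' a one-dimensional least-squares problem in tau solved by golden-section
#' search. A fitted tau at or above `tau_cap` is treated as negligible
#' bleaching and the correction is the identity.
#'
#' @param traces A CypHer `fluor_trace` tibble with at least `fit_frames`
#'   pre-stimulation frames.
#' @param fit_frames Number of initial frames to fit (default 10).
#' @param mode `"cumulative"` (add back B(0) - B(t); default) or `"literal"`
#'   (add B(t)).
#' @param tau_cap Bleach time constants at or above this are treated as no
#'   bleaching (seconds).
#' @return The corrected trace tibble; per-ROI models
#'   (`roi_id`, `b0`, `tau_bleach`, `rss`, `applied`) are attached as
#'   attribute `"bleach_models"` and returned by [bleach_models()].
#' @examples
#' cfg <- sim_config(indicator = "cypher", tau_bleach = 150,
#'                   noise_sd_fraction = 0)
#' corr <- bleach_correct(simulate_trace(cfg))
#' bleach_models(corr)
#' @export
bleach_correct <- function(traces, fit_frames = 10,
                           mode = c("cumulative", "literal"),
                           tau_cap = 1e4) {
  mode <- match.arg(mode)
  ind <- trace_indicator(traces)
  if (is.null(ind) || ind != "cypher") {
    abort("Bleach correction applies to CypHer traces only.")
  }
  protocol <- trace_protocol(traces)
  if (!is.null(protocol)) {
    n_pre <- floor(protocol$stim_onset / protocol$frame_interval + 1e-9)
    if (n_pre < fit_frames) {
      abort(sprintf(
        "Only %d pre-stimulation frames available; %d required for the bleach fit.",
        n_pre, fit_frames))
    }
  }
  dat <- as_tibble(traces)
  roi_ids <- unique(dat$roi_id)
  models <- vector("list", length(roi_ids))
  corrected <- vector("list", length(roi_ids))
  for (i in seq_along(roi_ids)) {
    d <- dat[dat$roi_id == roi_ids[i], ]
    if (nrow(d) < fit_frames) {
      abort(sprintf("ROI %s has fewer than %d frames.", roi_ids[i], fit_frames))
    }
    fit <- fit_bleach(d$time_s[seq_len(fit_frames)], d$f[seq_len(fit_frames)],
                      tau_cap = tau_cap)
    f <- d$f
    if (fit$applied) {
      b <- fit$b0 * exp(-d$time_s / fit$tau_bleach)
      f <- if (mode == "cumulative") f + (fit$b0 - b) else f + b
    }
    d$f <- f
    corrected[[i]] <- d
    models[[i]] <- tibble(roi_id = roi_ids[i], b0 = fit$b0,
                          tau_bleach = fit$tau_bleach, rss = fit$rss,
                          applied = fit$applied)
  }
  out <- restore_trace_attrs(dplyr::bind_rows(corrected), traces)
  attr(out, "bleach_models") <- dplyr::bind_rows(models)
  out
}

#' @rdname bleach_correct
#' @param x A trace tibble returned by [bleach_correct()].
#' @export
bleach_models <- function(x) attr(x, "bleach_models")

fit_bleach <- function(t, f, tau_cap) {
  dt <- t[2] - t[1]
  lo <- dt / 10
  hi <- tau_cap * 10
  sse <- function(tau) {
    e <- exp(-t / tau)
    b0 <- sum(f * e) / sum(e * e)
    sum((f - b0 * e)^2)
  }
  opt <- optimize(sse, c(lo, hi), tol = 1e-12 * hi)
  tau <- opt$minimum
  e <- exp(-t / tau)
  b0 <- sum(f * e) / sum(e * e)
  resid <- f - b0 * e
  if (tau <= lo * 1.01 || b0 <= 0) {
    abort(paste0("Baseline bleach fit did not converge (tau at lower bound ",
                 "or non-positive amplitude). Residuals: ",
                 paste(signif(resid, 4), collapse = ", ")))
  }
  if (tau >= tau_cap) {
    # negligible bleaching: identity correction
    return(list(b0 = mean(f), tau_bleach = Inf, rss = sum((f - mean(f))^2),
                applied = FALSE))
  }
  list(b0 = b0, tau_bleach = tau, rss = sum(resid^2), applied = TRUE)
}
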