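#' Configure the synthetic trace/video generator
#'
#' Collects the kinetic, optical and noise parameters of the surface-pool
#' simulator. The model tracks the fraction S(t) of reporter on the plasma
#' membrane surface: exocytosis injects `exo_fraction` of the pool uniformly
#' over the stimulus window and endocytosis retrieves it as a first-order
#' process with time constant `tau_endo`, so dS/dt = E(t) - S/tau_endo.
#' pHluorin reports the surface pool (intensity proportional to
#' S + `resting_surface_fraction`), CypHer the internal pool (proportional to
#' 1 - S - `resting_surface_fraction`). The noiseless signal is multiplied by
#' a mono-exponential photobleaching factor exp(-t/`tau_bleach`), scaled by a
#' per-bouton amplitude, offset by `background_level` and read out with
#' additive Gaussian noise of SD `noise_sd_fraction * amplitude`.
#'
#' @param tau_endo Ground-truth endocytic time constant in seconds.
#' @param exo_fraction Fraction of the reporter pool fused during the train
#'   (0 to 1; `exo_fraction + resting_surface_fraction` must not exceed 1).
#' @param resting_surface_fraction Fraction of reporter resident on the
#'   surface at rest.
#' @param tau_bleach Photobleaching time constant in seconds; `Inf` disables
#'   bleaching.
#' @param background_level Camera background offset in counts.
#' @param amplitude_mean,amplitude_cv Mean and coefficient of variation of the
#'   per-bouton intensity scale (counts; lognormal across boutons).
#' @param noise_sd_fraction Gaussian noise SD as a fraction of the bouton
#'   amplitude.
#' @param indicator `"phluorin"` (up-going) or `"cypher"` (down-going).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(tau_endo = 30, indicator = "phluorin")
#' @export
sim_config <- function(tau_endo = 30, exo_fraction = 0.3,
                       resting_surface_fraction = 0.1, tau_bleach = Inf,
                       background_level = 100, amplitude_mean = 1000,
                       amplitude_cv = 0.3, noise_sd_fraction = 0.05,
                       indicator = c("phluorin", "cypher"), seed = 1L) {
  indicator <- match.arg(indicator)
  num <- c(tau_endo = tau_endo, exo_fraction = exo_fraction,
           resting_surface_fraction = resting_surface_fraction,
           background_level = background_level,
           amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
           noise_sd_fraction = noise_sd_fraction)
  if (anyNA(num) || !all(is.finite(num))) {
    abort("All simulator parameters except `tau_bleach` must be finite.")
  }
  if (is.na(tau_bleach) || tau_bleach <= 0) {
    abort("`tau_bleach` must be positive (Inf disables bleaching).")
  }
  if (tau_endo <= 0) abort("`tau_endo` must be positive.")
  if (exo_fraction < 0 || exo_fraction > 1) {
    abort("`exo_fraction` must lie in [0, 1].")
  }
  if (resting_surface_fraction < 0 || resting_surface_fraction >= 1) {
    abort("`resting_surface_fraction` must lie in [0, 1).")
  }
  if (exo_fraction + resting_surface_fraction > 1) {
    abort("`exo_fraction` + `resting_surface_fraction` must not exceed 1.")
  }
  if (noise_sd_fraction < 0) abort("`noise_sd_fraction` must be >= 0.")
  if (amplitude_cv < 0) abort("`amplitude_cv` must be >= 0.")
  if (amplitude_mean <= 0) abort("`amplitude_mean` must be positive.")
  if (background_level < 0) abort("`background_level` must be >= 0.")
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer.")
  structure(
    list(tau_endo = tau_endo, exo_fraction = exo_fraction,
         resting_surface_fraction = resting_surface_fraction,
         tau_bleach = tau_bleach, background_level = background_level,
         amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
         noise_sd_fraction = noise_sd_fraction, indicator = indicator,
         seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s, tau_endo = %g s, exo = %g, rest = %g, tau_bleach = %g s\n",
    x$indicator, x$tau_endo, x$exo_fraction, x$resting_surface_fraction,
    x$tau_bleach))
  cat(sprintf("  amplitude %g (CV %g), background %g, noise %g, seed %d\n",
              x$amplitude_mean, x$amplitude_cv, x$background_level,
              x$noise_sd_fraction, x$seed))
  invisible(x)
}

default_protocol <- function(config) {
  protocol_200ap(config$indicator)
}

# Analytic surface-pool fraction S(t) for uniform exocytic injection over
# [t0, t0 + dur] and first-order retrieval with time constant tau.
surface_pool <- function(t, tau_endo, exo_fraction, stim_onset, duration) {
  r <- exo_fraction / duration
  t1 <- stim_onset + duration
  s_end <- r * tau_endo * (1 - exp(-duration / tau_endo))
  ifelse(t <= stim_onset, 0,
         ifelse(t <= t1,
                r * tau_endo * (1 - exp(-(t - stim_onset) / tau_endo)),
                s_end * exp(-(t - t1) / tau_endo)))
}

# Noiseless reporter signal in [0, 1] units before amplitude scaling.
reporter_signal <- function(s_pool, resting_surface_fraction, indicator) {
  if (indicator == "phluorin") {
    s_pool + resting_surface_fraction
  } else {
    1 - s_pool - resting_surface_fraction
  }
}
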