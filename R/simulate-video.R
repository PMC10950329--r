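#' Simulate a time-lapse video of stimulated boutons
#'
#' Renders `n_boutons` responding and `n_silent` silent boutons as 2-D
#' Gaussian footprints whose brightness follows the surface-pool kinetics of
#' [simulate_trace()]. Silent boutons carry the constant resting intensity of
#' a bouton with `exo_fraction = 0`. Bouton centres are placed on integer
#' pixels by rejection sampling with a minimum pairwise separation; per-bouton
#' amplitudes are lognormal with mean `amplitude_mean` and CV `amplitude_cv`.
#' Gaussian read noise of SD `noise_sd_fraction * amplitude_mean` is added to
#' every pixel.
#'
#' @param config A [sim_config()].
#' @param protocol A [stim_protocol()]; defaults per indicator.
#' @param n_boutons Number of responding boutons.
#' @param n_silent Number of silent (non-responding) boutons.
#' @param frame_shape Video height and width in pixels.
#' @param bouton_sigma Gaussian footprint SD in pixels.
#' @param min_separation Minimum centre-to-centre distance in pixels.
#' @param margin Margin kept free of bouton centres, pixels.
#' @param max_tries Placement attempts before giving up.
#' @return A list with `video` (numeric array height x width x frames, counts)
#'   and `truth`, a tibble with one row per bouton: `bouton_id`, `x`, `y`
#'   (centre, pixels), `amplitude`, `responder`, `f0` (expected baseline
#'   centre-pixel intensity), `tau_endo`, `tau_bleach`.
#' @examples
#' sim <- simulate_video(sim_config(seed = 7), n_boutons = 5, n_silent = 2,
#'                       frame_shape = c(64, 64))
#' dim(sim$video)
#' sim$truth
#' @export
simulate_video <- function(config, protocol = NULL, n_boutons = 25,
                           n_silent = 5, frame_shape = c(128, 128),
                           bouton_sigma = 1.8, min_separation = 8,
                           margin = 6, max_tries = 10000) {
  stopifnot(inherits(config, "sim_config"))
  protocol <- protocol %||% default_protocol(config)
  check_baseline_window(protocol, config$indicator)
  n_total <- n_boutons + n_silent
  h <- frame_shape[1]; w <- frame_shape[2]

  set.seed(config$seed)
  centres <- place_boutons(n_total, h, w, margin, min_separation, max_tries)
  amplitudes <- if (config$amplitude_cv > 0) {
    sdlog <- sqrt(log(1 + config$amplitude_cv^2))
    rlnorm(n_total, meanlog = log(config$amplitude_mean) - sdlog^2 / 2,
           sdlog = sdlog)
  } else {
    rep(config$amplitude_mean, n_total)
  }
  responder <- c(rep(TRUE, n_boutons), rep(FALSE, n_silent))

  t <- frame_times(protocol)
  n_frames <- protocol$n_frames
  video <- array(config$background_level, dim = c(h, w, n_frames))
  bleach <- exp(-t / config$tau_bleach)
  rest_signal <- reporter_signal(0, config$resting_surface_fraction,
                                 config$indicator)
  s <- surface_pool(t, config$tau_endo, config$exo_fraction,
                    protocol$stim_onset, protocol$duration)
  resp_signal <- reporter_signal(s, config$resting_surface_fraction,
                                 config$indicator)

  half <- ceiling(4 * bouton_sigma)
  off <- -half:half
  footprint <- exp(-(outer(off^2, off^2, "+")) / (2 * bouton_sigma^2))
  for (i in seq_len(n_total)) {
    brightness <- amplitudes[i] * bleach *
      (if (responder[i]) resp_signal else rep(rest_signal, n_frames))
    rows <- centres$y[i] + off
    cols <- centres$x[i] + off
    rok <- rows >= 1 & rows <= h
    cok <- cols >= 1 & cols <= w
    patch <- footprint[rok, cok, drop = FALSE]
    video[rows[rok], cols[cok], ] <-
      video[rows[rok], cols[cok], , drop = FALSE] +
      outer(patch, brightness)
  }
  if (config$noise_sd_fraction > 0) {
    video <- video + array(
      rnorm(length(video),
            sd = config$noise_sd_fraction * config$amplitude_mean),
      dim = dim(video))
  }

  truth <- tibble(
    bouton_id = seq_len(n_total),
    x = centres$x, y = centres$y,
    amplitude = amplitudes, responder = responder,
    f0 = amplitudes * rest_signal + config$background_level,
    tau_endo = config$tau_endo, tau_bleach = config$tau_bleach
  )
  list(video = video, truth = truth, protocol = protocol, config = config)
}

place_boutons <- function(n, h, w, margin, min_separation, max_tries) {
  xs <- integer(0); ys <- integer(0)
  tries <- 0
  while (length(xs) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort(sprintf(
        paste0("Could not place %d boutons in a %dx%d frame at minimum ",
               "separation %g px after %d tries; reduce the density."),
        n, h, w, min_separation, max_tries))
    }
    x <- sample(seq(margin + 1, w - margin), 1)
    y <- sample(seq(margin + 1, h - margin), 1)
    if (length(xs) == 0 ||
        all((xs - x)^2 + (ys - y)^2 >= min_separation^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  list(x = xs, y = ys)
}
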