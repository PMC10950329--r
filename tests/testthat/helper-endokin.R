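# Shared fixture builders. Everything is generated in code at test time.

# A simulated trace with the camera background already subtracted, as the
# video pipeline delivers it to the normalization stages.
bg_corrected_trace <- function(config, ...) {
  tr <- simulate_trace(config, ...)
  tr$f <- tr$f - config$background_level
  tr
}

# Trace-level tau recovery: simulate n_boutons noisy traces per video,
# average the raw bouton traces into one trace per video, correct and
# peak-normalize the video trace, average across videos, fit.
trace_level_tau <- function(tau_endo, n_boutons, n_videos, noise = 0.05,
                            amplitude_cv = 0.3, base_seed = 1,
                            indicator = "phluorin", tau_bleach = Inf,
                            bleach_correction = (indicator == "cypher")) {
  video_avgs <- lapply(seq_len(n_videos), function(v) {
    traces <- lapply(seq_len(n_boutons), function(b) {
      cfg <- sim_config(tau_endo = tau_endo, noise_sd_fraction = noise,
                        amplitude_cv = 0, indicator = indicator,
                        tau_bleach = tau_bleach,
                        seed = base_seed * 100000 + v * 1000 + b)
      amp <- if (amplitude_cv > 0) {
        sdlog <- sqrt(log(1 + amplitude_cv^2))
        set.seed(base_seed * 100000 + v * 1000 + b + 7)
        exp(rnorm(1, log(1000) - sdlog^2 / 2, sdlog))
      } else 1000
      bg_corrected_trace(cfg, amplitude = amp, roi_id = as.character(b))
    })
    vt <- video_mean_trace(bind_traces(traces))
    if (bleach_correction) vt <- bleach_correct(vt)
    nt <- peak_normalize(vt)
    dplyr::mutate(tibble::as_tibble(nt), video = v)
  })
  prot <- attr(peak_normalize(bg_corrected_trace(
    sim_config(tau_endo = tau_endo, indicator = indicator,
               noise_sd_fraction = 0))), "protocol")
  avg <- average_traces(dplyr::bind_rows(video_avgs), unit_col = "video")
  attr(avg, "protocol") <- prot
  fit_decay(avg)$tau
}

# Independent brute-force Otsu threshold over a 256-bin histogram:
# maximises between-class variance.
brute_force_otsu <- function(x, levels = 256) {
  h <- tabulate(findInterval(x, seq(0, 1, length.out = levels + 1),
                             rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  best <- -Inf; thr <- NA_real_
  for (k in seq_len(levels - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; thr <- mids[k] }
  }
  thr
}

# Direct evaluation of the D'Agostino-Pearson K2 statistic, written
# independently of the package implementation (different parameterisation of
# the same published transformations).
k2_direct <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  s2 <- sum(xc^2) / n
  skew <- (sum(xc^3) / n) / s2^(3 / 2)
  kurt <- (sum(xc^4) / n) / s2^2
  # skewness z
  Y <- skew * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  b2s <- (3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3)) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W <- sqrt(-1 + sqrt(2 * (b2s - 1)))
  d <- 1 / sqrt(log(W))
  a <- sqrt(2 / (W^2 - 1))
  zs <- d * asinh(Y / a)
  # kurtosis z
  meanb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- (24 * n * (n - 2) * (n - 3)) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (kurt - meanb2) / sqrt(varb2)
  sqrtb1 <- (6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9))) *
    sqrt((6 * (n + 3) * (n + 5)) / (n * (n - 2) * (n - 3)))
  A <- 6 + (8 / sqrtb1) * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) *
    sqrt(9 * A / 2)
  zs^2 + zk^2
}

# Match detected ROI centroids to planted bouton positions.
match_centroids <- function(rois, truth_xy, max_dist = 2) {
  if (nrow(rois) == 0) {
    return(list(matched_truth = logical(nrow(truth_xy)),
                matched_roi = logical(0)))
  }
  d <- sqrt(outer(rois$centroid_x, truth_xy$x, "-")^2 +
              outer(rois$centroid_y, truth_xy$y, "-")^2)
  list(matched_truth = apply(d, 2, min) <= max_dist,
       matched_roi = apply(d, 1, min) <= max_dist)
}

# Aligned synthetic synapse profile with Poisson noise.
simulated_profile <- function(poi_offset, seed, poi_amplitude = 1,
                              noise = TRUE) {
  lay <- synapse_layout(poi_offset = poi_offset,
                        poi_amplitude = poi_amplitude)
  img <- simulate_sted_synapse(lay, image_shape = c(64, 64), seed = seed,
                               noise = noise)
  align_and_orient(extract_line_profile(img, line_spec(center = img$centre_px)))
}
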