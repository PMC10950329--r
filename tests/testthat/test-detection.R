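test_that("planted responders are found and silent boutons are not", {
  cfg <- sim_config(seed = 42, noise_sd_fraction = 0.02, amplitude_cv = 0.2)
  sim <- simulate_video(cfg, n_boutons = 25, n_silent = 5,
                        min_separation = 12)
  rois <- detect_responding_boutons(sim$video, sim$protocol, "phluorin")
  expect_false(is_excluded(rois))
  resp <- sim$truth[sim$truth$responder, ]
  silent <- sim$truth[!sim$truth$responder, ]
  m <- match_centroids(rois, resp)
  expect_gte(sum(m$matched_truth), 24)
  expect_true(all(m$matched_roi))
  ms <- match_centroids(rois, silent)
  expect_equal(sum(ms$matched_truth), 0)
  # sorted by descending amplitude
  expect_true(all(diff(rois$amplitude) <= 0))
})

test_that("a video without stimulus response yields no ROIs and is excluded", {
  cfg <- sim_config(seed = 9, exo_fraction = 0, noise_sd_fraction = 0.02)
  sim <- simulate_video(cfg, n_boutons = 10, n_silent = 0,
                        frame_shape = c(96, 96), min_separation = 12)
  rois <- detect_responding_boutons(sim$video, sim$protocol, "phluorin")
  expect_equal(nrow(rois), 0)
  expect_true(is_excluded(rois))
})

test_that("videos under the 20-responder floor are flagged excluded", {
  cfg <- sim_config(seed = 14, noise_sd_fraction = 0.02)
  sim <- simulate_video(cfg, n_boutons = 10, n_silent = 2,
                        frame_shape = c(96, 96), min_separation = 12)
  rois <- detect_responding_boutons(sim$video, sim$protocol, "phluorin")
  expect_true(is_excluded(rois))
  expect_match(exclusion_reason(rois), "floor")
  # same detection with a lower floor is usable
  rois2 <- detect_responding_boutons(sim$video, sim$protocol, "phluorin",
                                     min_responders = 5)
  expect_false(is_excluded(rois2))
})

test_that("ROI traces are background-corrected means over the ROI", {
  # constant silent bouton at 500 counts on a 100-count background
  video <- array(100, dim = c(20, 20, 12))
  block <- as.matrix(expand.grid(9:11, 9:11))
  for (k in 1:12) video[cbind(block, k)] <- 500
  rois <- tibble::tibble(roi_id = 1L,
                         pixels = list((block[, 2] - 1) * 20 + block[, 1]))
  prot <- stim_protocol(40, 5, stim_onset = 10, total_duration = 24)
  bg <- which(array(TRUE, c(20, 20)))[1:40]  # first two columns
  tr <- measure_roi_traces(video, rois, prot, "phluorin",
                           background_region = bg)
  expect_equal(tr$f, rep(400, 12))
})

test_that("a background region overlapping an ROI is rejected", {
  video <- array(100, dim = c(16, 16, 12))
  rois <- tibble::tibble(roi_id = 1L, pixels = list(1:10))
  prot <- stim_protocol(40, 5, stim_onset = 10, total_duration = 24)
  expect_error(
    measure_roi_traces(video, rois, prot, "phluorin",
                       background_region = 5:20),
    "overlaps")
})

test_that("measured peak amplitude tracks the planted response", {
  cfg <- sim_config(seed = 6, noise_sd_fraction = 0, amplitude_cv = 0)
  sim <- simulate_video(cfg, n_boutons = 5, n_silent = 0,
                        frame_shape = c(96, 96), min_separation = 14)
  rois <- detect_responding_boutons(sim$video, sim$protocol, "phluorin",
                                    min_responders = 3)
  tr <- measure_roi_traces(sim$video, rois, sim$protocol, "phluorin")
  s <- peak_summary(peak_normalize(tr))
  # every planted bouton has the same kinetics: peak dF at the ROI mean is
  # proportional to the planted surface-pool deflection
  cfgtruth <- trace_truth(simulate_trace(cfg))
  rel <- max(cfgtruth$s_pool) / 0.1   # peak dS over resting signal
  f0 <- surface_summary(surface_normalize(tr))$f0
  expect_equal(s$df_max / f0, rep(rel, nrow(s)), tolerance = 0.02)
})
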