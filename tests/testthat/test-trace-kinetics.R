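manual_phluorin <- function(f, stim_onset = 10) {
  fluor_trace(seq(0, by = 2, length.out = length(f)), f, "phluorin",
              stim_protocol(40, 5, stim_onset = stim_onset,
                            total_duration = 2 * length(f)))
}

manual_cypher <- function(f, stim_onset = 20) {
  fluor_trace(seq(0, by = 2, length.out = length(f)), f, "cypher",
              stim_protocol(40, 5, stim_onset = stim_onset,
                            total_duration = 2 * length(f)))
}

test_that("surface normalization reports F0, fold increase and amplitude", {
  f <- c(rep(100, 5), 180, 250, 220, 190, 160, 140, 120, 110, 105, 100)
  s <- surface_summary(surface_normalize(manual_phluorin(f)))
  expect_equal(s$f0, 100)
  expect_equal(s$fold_increase, 2.5)
  sn <- surface_normalize(manual_phluorin(f))
  expect_equal(sn$f_surf[1:5], rep(1, 5))

  fc <- c(rep(200, 10), 150, 120, 130, 150, 170, 185, 195, 198, 199, 200)
  sc <- surface_summary(surface_normalize(manual_cypher(fc)))
  expect_equal(sc$f0, 200)
  expect_equal(sc$exo_amplitude, 80)
  expect_equal(sc$exo_fraction_of_f0, 0.4)
})

test_that("F0 uses exactly the first five frames even with a later stimulus", {
  # baseline 100 in frames 1-5, drift to 120 in frames 6-7, stimulus at t=14
  f <- c(rep(100, 5), 120, 120, 300, 280, 260, 240, 220, 200, 190, 180)
  s <- surface_summary(surface_normalize(manual_phluorin(f, stim_onset = 14)))
  expect_equal(s$f0, 100)
  expect_equal(s$fold_increase, 3)
  expect_error(surface_normalize(manual_phluorin(rep(-1, 15))),
               "Non-positive F0")
})

test_that("peak normalization maps deflections onto [<=1] with max exactly 1", {
  cfg <- sim_config(tau_endo = 18, noise_sd_fraction = 0.05, seed = 12)
  nt <- peak_normalize(bg_corrected_trace(cfg))
  expect_equal(max(nt$norm_df), 1)
  ps <- peak_summary(nt)
  expect_equal(nt$norm_df[ps$peak_index], 1)
})

test_that("CypHer deflections are sign-flipped before normalization", {
  f <- c(rep(100, 10), 80, 60, 70, 80, 90, 95, 98, 99, 100, 100)
  nt <- peak_normalize(manual_cypher(f))
  # F0 = 100, Fmin = 60: the frame at F = 80 maps to (100-80)/(100-60) = 0.5
  expect_equal(nt$norm_df[11], 0.5)
  expect_equal(nt$norm_df[12], 1)
})

test_that("peak normalization is invariant to affine rescaling", {
  cfg <- sim_config(tau_endo = 22, noise_sd_fraction = 0.03, seed = 4)
  tr <- bg_corrected_trace(cfg)
  tr2 <- tr
  tr2$f <- 3.7 * tr$f + 250
  expect_equal(peak_normalize(tr)$norm_df, peak_normalize(tr2)$norm_df)
  # and therefore so is the fitted tau
  t1 <- fit_decay(average_traces(peak_normalize(tr)))$tau
  t2 <- fit_decay(average_traces(peak_normalize(tr2)))$tau
  expect_equal(t1, t2)
})

test_that("flat traces are rejected as non-responders", {
  flat <- manual_phluorin(rep(100, 15))
  expect_error(peak_normalize(flat), "Non-responding")
  expect_warning(
    nt <- peak_normalize(
      bind_traces(list(
        bg_corrected_trace(sim_config(noise_sd_fraction = 0), roi_id = "a"),
        flat)),
      on_nonresponder = "drop"),
    "dropped")
  expect_equal(unique(nt$roi_id), "a")
})

test_that("trace averaging returns pointwise mean, SEM and n", {
  cfg <- sim_config(noise_sd_fraction = 0)
  tr <- bg_corrected_trace(cfg)
  nt <- peak_normalize(bind_traces(list(
    `1` = tr,
    `2` = {x <- tr; x$roi_id <- "2"; x},
    `3` = {x <- tr; x$roi_id <- "3"; x})))
  avg <- average_traces(nt)
  expect_equal(avg$norm_df, peak_normalize(tr)$norm_df)
  expect_true(all(avg$sem == 0))
  expect_true(all(avg$n == 3))
  expect_equal(nrow(avg), nrow(tr))

  two <- tibble::tibble(roi_id = rep(c("a", "b"), each = 2),
                        time_s = rep(c(0, 2), 2),
                        norm_df = c(0.4, 0.4, 0.6, 0.6))
  expect_equal(average_traces(two)$norm_df, c(0.5, 0.5))
})

test_that("traces on different time bases refuse to average", {
  a <- tibble::tibble(roi_id = "a", time_s = seq(0, 98, 2),
                      norm_df = runif(50))
  b <- tibble::tibble(roi_id = "b", time_s = seq(0, 58, 2),
                      norm_df = runif(30))
  expect_error(average_traces(dplyr::bind_rows(a, b)), "common time base")
})

test_that("bleach correction restores a pure exponential baseline exactly", {
  t <- seq(0, 98, by = 2)
  b0 <- 800; taub <- 120
  tr <- manual_cypher(b0 * exp(-t / taub))
  corr <- bleach_correct(tr)
  expect_lt(max(abs(corr$f - b0)) / b0, 1e-9)
  m <- bleach_models(corr)
  expect_equal(m$tau_bleach, taub, tolerance = 1e-6)
  # stationarity: post-correction linear slope is numerically zero
  slope <- coef(lm(corr$f ~ t))[2]
  expect_lt(abs(slope), 1e-6 * b0)
})

test_that("bleach correction needs ten pre-stimulation frames", {
  f <- 900 * exp(-seq(0, 98, 2) / 150)
  tr <- fluor_trace(seq(0, 98, 2), f, "cypher",
                    stim_protocol(40, 5, stim_onset = 18))  # 9 frames only
  expect_error(bleach_correct(tr), "pre-stimulation frames")
  expect_error(bleach_correct(manual_phluorin(f)), "CypHer")
})

test_that("corrected CypHer kinetics match the add-back model prediction", {
  # Multiplicative bleaching with additive add-back leaves a residual
  # exp(-t/tau_bleach) factor on the deflection, so the recovered constant
  # is tau*tau_b/(tau + tau_b); the uncorrected trace is far worse (its
  # deflection never decays back).
  cfg <- sim_config(tau_endo = 15, tau_bleach = 150, indicator = "cypher",
                    noise_sd_fraction = 0)
  tr <- bg_corrected_trace(cfg)
  fit_c <- fit_decay(average_traces(peak_normalize(bleach_correct(tr))))
  composite <- 15 * 150 / (15 + 150)
  expect_equal(fit_c$tau, composite, tolerance = 0.01)
  fit_u <- suppressWarnings(
    fit_decay(average_traces(peak_normalize(tr))))
  err_c <- abs(fit_c$tau - 15) / 15
  err_u <- abs(fit_u$tau - 15) / 15
  expect_gt(err_u, 0.15)
  expect_lt(err_c, err_u)
})

test_that("negligible bleaching leaves the trace untouched", {
  cfg <- sim_config(indicator = "cypher", tau_bleach = Inf,
                    noise_sd_fraction = 0)
  tr <- bg_corrected_trace(cfg)
  corr <- bleach_correct(tr)
  expect_equal(corr$f, tr$f)
  expect_false(bleach_models(corr)$applied)
})

test_that("the constrained fitter is exact on exact exponentials", {
  t <- seq(0, 60, by = 2)
  avg <- tibble::tibble(time_s = t, norm_df = exp(-t / 25))
  fit <- fit_decay(avg)
  expect_equal(fit$tau, 25, tolerance = 1e-6)
  expect_true(fit$converged)
  # constraints: the fitted curve equals 1 at the peak and decays to 0
  expect_equal(fit$data$fitted[1], 1)
  expect_lt(exp(-1e6 / fit$tau), 1e-12)
  expect_equal(fit$fit_window[1], fit$peak_index)
})

test_that("the fitter needs at least three post-peak points", {
  avg <- tibble::tibble(time_s = c(0, 2, 4), norm_df = c(0.2, 0.5, 1))
  expect_error(fit_decay(avg), "3 post-peak")
})

test_that("fitter and dense grid search agree on noisy traces", {
  set.seed(77)
  for (i in 1:8) {
    tau <- runif(1, 5, 80)
    t <- seq(0, 98, by = 2)
    y <- exp(-pmax(t - 16, 0) / tau) + rnorm(length(t), sd = 0.03)
    y[t < 16] <- rnorm(sum(t < 16), sd = 0.03)
    avg <- tibble::tibble(time_s = t, norm_df = y)
    f <- fit_decay(avg)
    g <- grid_search_tau(avg)
    expect_lt(abs(f$tau - g$tau) / g$tau, 0.005)
    expect_lte(f$rss, g$rss + 1e-12)
  }
})

test_that("fitted tau ordering matches planted order across replicates", {
  ok <- 0
  for (r in 1:40) {
    t15 <- trace_level_tau(15, n_boutons = 10, n_videos = 1, base_seed = r)
    t27 <- trace_level_tau(27, n_boutons = 10, n_videos = 1,
                           base_seed = r + 500)
    ok <- ok + (t27 > t15)
  }
  expect_gte(ok / 40, 0.95)
})

test_that("tidy and glance summarise decay fits", {
  cfg <- sim_config(tau_endo = 30, noise_sd_fraction = 0)
  fit <- fit_decay(average_traces(peak_normalize(bg_corrected_trace(cfg))))
  td <- tidy(fit)
  expect_equal(td$term, "tau")
  expect_equal(td$estimate, fit$tau)
  gl <- glance(fit)
  expect_named(gl, c("tau", "rss", "n_points", "peak_time", "converged"))
})
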