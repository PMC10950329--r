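test_that("default line specs sample 53 positions at 18.9 nm", {
  img <- simulate_sted_synapse(synapse_layout(), c(64, 64), noise = FALSE)
  prof <- extract_line_profile(img, line_spec(center = img$centre_px))
  expect_equal(nrow(prof), 53 * 3)
  expect_equal(sort(unique(prof$sample)), 1:53)
  expect_equal(diff(sort(unique(prof$offset_nm)))[1], 18.9)
})

test_that("a uniform image yields a constant profile in every channel", {
  chans <- list(ref = matrix(7, 40, 40), post = matrix(7, 40, 40),
                poi = matrix(7, 40, 40))
  prof <- extract_line_profile(chans,
                               line_spec(center = c(20.5, 20.5), length = 400,
                                         width = 200),
                               pixel_size = 18.9)
  expect_true(all(abs(prof$intensity - 7) < 1e-12))
})

test_that("profiles reject lines leaving the image", {
  img <- simulate_sted_synapse(synapse_layout(), c(64, 64), noise = FALSE)
  expect_error(
    extract_line_profile(img, line_spec(center = c(3, 3))),
    "outside the image")
})

test_that("a Gaussian blob on the line peaks at its planted position", {
  img <- simulate_sted_synapse(synapse_layout(poi_offset = 75.6),
                               c(64, 64), noise = FALSE)
  prof <- extract_line_profile(img, line_spec(center = img$centre_px))
  poi <- prof[prof$channel == "poi", ]
  expect_lt(abs(poi$offset_nm[which.max(poi$intensity)] - 75.6), 18.9 + 1e-9)
})

test_that("alignment puts the reference maximum at exactly 0 nm", {
  sp <- simulated_profile(poi_offset = 40, seed = 3)
  ref <- sp[sp$channel == "ref", ]
  expect_equal(ref$position_nm[which.max(ref$raw)], 0)
  expect_true(all(abs(tapply(sp$norm, sp$channel, max) - 1) < 1e-12))
})

test_that("orientation flips the postsynaptic centroid to negative positions", {
  # plant the postsynaptic marker on the positive side: must flip, and a
  # protein at -150 nm must be reported at +150 nm
  lay <- synapse_layout(homer_offset = +150, poi_offset = -150)
  img <- simulate_sted_synapse(lay, c(64, 64), noise = FALSE)
  sp <- align_and_orient(extract_line_profile(img, line_spec(center = img$centre_px)))
  expect_true(attr(sp, "flipped"))
  poi <- sp[sp$channel == "poi", ]
  expect_lt(abs(poi$position_nm[which.max(poi$raw)] - 150), 18.9 / 2)
  post <- sp[sp$channel == "post", ]
  expect_lt(sum(post$position_nm * post$raw) / sum(post$raw), 0)
})

test_that("alignment is idempotent", {
  sp <- simulated_profile(poi_offset = 40, seed = 11)
  sp2 <- align_and_orient(sp)
  expect_equal(as.data.frame(sp2), as.data.frame(sp))
  expect_equal(attr(sp2, "flipped"), attr(sp, "flipped"))
})

test_that("mirrored input images give identical signed positions", {
  lay <- synapse_layout(homer_offset = -120, poi_offset = 40)
  img <- simulate_sted_synapse(lay, c(64, 64), seed = 5)
  sp <- align_and_orient(extract_line_profile(img, line_spec(center = img$centre_px)))
  flipped <- img
  flipped$channels <- lapply(img$channels, function(m) m[, ncol(m):1])
  w <- ncol(img$channels$ref)
  centre2 <- c(w + 1 - img$centre_px["x"], img$centre_px["y"])
  sp2 <- align_and_orient(extract_line_profile(flipped, line_spec(center = centre2)))
  a <- dplyr::arrange(as.data.frame(sp), channel, position_nm)
  b <- dplyr::arrange(as.data.frame(sp2), channel, position_nm)
  expect_equal(a$position_nm, b$position_nm)
  expect_equal(a$raw, b$raw, tolerance = 1e-9)
})

test_that("averaged localization profiles recover a planted offset", {
  profs <- lapply(1:60, function(i) simulated_profile(40, seed = 6000 + i))
  loc <- localization_profile(profs)
  poi <- loc[loc$channel == "poi", ]
  pk <- poi$position_nm[which.max(poi$mean_norm)]
  expect_lte(abs(pk - 40), 18.9)
  # k copies of one profile: SEM identically zero
  loc1 <- localization_profile(rep(list(profs[[1]]), 4))
  expect_true(all(loc1$sem == 0))
  expect_true(all(abs(tapply(loc1$mean_norm, loc1$channel, max) - 1) < 1e-12))
})

test_that("the default presynaptic window covers 11 grid samples", {
  sp <- simulated_profile(poi_offset = 40, seed = 2, noise = FALSE)
  poi <- sp[sp$channel == "poi", ]
  win <- presyn_window()
  sel <- poi$position_nm >= win$lower - 1e-6 & poi$position_nm <= win$upper + 1e-6
  expect_equal(sum(sel), 11)
  pos <- sort(poi$position_nm[sel])
  expect_equal(pos[1], -37.8, tolerance = 1e-9)
  expect_equal(pos[11], 151.2, tolerance = 1e-9)
  expect_false(170.1 %in% round(pos, 1))
  # uniform raw channel of 1 integrates to the sample count
  flat <- sp
  flat$raw[flat$channel == "poi"] <- 1
  expect_equal(integrate_presynaptic_level(flat), 11)
})

test_that("level integration is linear and unaffected by normalization", {
  sp <- simulated_profile(poi_offset = 40, seed = 13)
  lvl <- integrate_presynaptic_level(sp)
  doubled <- sp
  doubled$raw[doubled$channel == "poi"] <-
    2 * doubled$raw[doubled$channel == "poi"]
  expect_equal(integrate_presynaptic_level(doubled), 2 * lvl)
  expect_error(integrate_presynaptic_level(sp, presyn_window(-37.8, 5000)),
               "outside the profile")
})

test_that("percent-of-control normalization fixes the control mean at 100", {
  tab <- normalize_levels(
    tibble::tibble(group = c("ctr", "ctr", "ctr", "kd", "kd"),
                   level = c(2, 2, 2, 1, 3)), "ctr")
  expect_equal(tab$percent_of_control, c(100, 100, 100, 50, 150))
  expect_equal(mean(tab$percent_of_control[tab$group == "ctr"]), 100)
  expect_error(normalize_levels(tibble::tibble(group = "a", level = 1), "b"),
               "empty")
  expect_error(
    normalize_levels(tibble::tibble(group = c("a", "b"), level = c(0, 1)), "a"),
    "positive")
})
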