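#' Describe the ground-truth geometry of a synthetic synapse
#'
#' Positions are in nanometres along the synaptic axis (the line
#' perpendicular to the cleft). The reference (presynaptic active-zone
#' marker, e.g. Bassoon) cluster defines the origin; the postsynaptic marker
#' (e.g. Homer1) sits at `homer_offset` and the protein of interest at
#' `poi_offset`, both signed. Each channel is a Gaussian cluster of SD
#' `cluster_sd` convolved with a Gaussian PSF of FWHM `psf_fwhm`
#' (so the rendered SD is `sqrt(cluster_sd^2 + (psf_fwhm/2.3548)^2)`).
#'
#' @param bassoon_position Reference cluster centre, nm (axial).
#' @param homer_offset Signed offset of the postsynaptic marker, nm
#'   (negative by convention: the analysis orients profiles with the
#'   postsynapse at negative positions).
#' @param poi_offset Signed offset of the protein of interest, nm.
#' @param poi_amplitude Relative peak intensity of the protein-of-interest
#'   channel (reference and postsynaptic channels have amplitude 1).
#' @param cluster_sd Cluster SD per channel, nm (length 3: ref, post, poi).
#' @param psf_fwhm PSF full width at half maximum per channel, nm.
#' @param pixel_size Image pixel size, nm (gSTED default 18.9).
#' @param photon_scale Expected photon count at unit intensity.
#' @return An object of class `synapse_layout`.
#' @export
synapse_layout <- function(bassoon_position = 0, homer_offset = -120,
                           poi_offset = 40, poi_amplitude = 1,
                           cluster_sd = c(80, 80, 80),
                           psf_fwhm = c(60, 60, 60),
                           pixel_size = 18.9, photon_scale = 50) {
  cluster_sd <- rep_len(cluster_sd, 3)
  psf_fwhm <- rep_len(psf_fwhm, 3)
  if (!all(is.finite(c(bassoon_position, homer_offset, poi_offset)))) {
    abort("Cluster offsets must be finite.")
  }
  if (poi_amplitude < 0) abort("`poi_amplitude` must be >= 0.")
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  if (any(cluster_sd <= 0) || any(psf_fwhm <= 0)) {
    abort("`cluster_sd` and `psf_fwhm` must be positive.")
  }
  structure(
    list(bassoon_position = bassoon_position, homer_offset = homer_offset,
         poi_offset = poi_offset, poi_amplitude = poi_amplitude,
         cluster_sd = cluster_sd, psf_fwhm = psf_fwhm,
         pixel_size = pixel_size, photon_scale = photon_scale),
    class = "synapse_layout"
  )
}

# FWHM of a Gaussian = 2 sqrt(2 log 2) sigma
fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Simulate a three-channel STED/confocal synapse image
#'
#' Renders the three marker clusters of `layout` as 2-D Gaussians (cluster
#' convolved with PSF, computed analytically) on a pixel grid, with optional
#' Poisson photon noise at `layout$photon_scale`.
#'
#' @param layout A [synapse_layout()].
#' @param image_shape Height and width in pixels.
#' @param seed Integer seed for the Poisson noise.
#' @param noise If `FALSE`, return the noiseless expectation in photon units.
#' @return A list of class `sted_image` with `channels` (named list of
#'   matrices `ref`, `post`, `poi`, photon counts), `layout`, `pixel_size`
#'   and `centre_px` (the image-centre pixel the offsets are measured from).
#' @examples
#' img <- simulate_sted_synapse(synapse_layout(), image_shape = c(48, 48))
#' names(img$channels)
#' @export
simulate_sted_synapse <- function(layout, image_shape = c(64, 64), seed = 1L,
                                  noise = TRUE) {
  stopifnot(inherits(layout, "synapse_layout"))
  h <- image_shape[1]; w <- image_shape[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  offsets <- c(ref = layout$bassoon_position,
               post = layout$bassoon_position + layout$homer_offset,
               poi = layout$bassoon_position + layout$poi_offset)
  amps <- c(ref = 1, post = 1, poi = layout$poi_amplitude)
  sd_nm <- sqrt(layout$cluster_sd^2 + fwhm_to_sd(layout$psf_fwhm)^2)

  channels <- vector("list", 3)
  names(channels) <- names(offsets)
  for (k in seq_len(3)) {
    xc <- cx + offsets[k] / layout$pixel_size
    sd_px <- sd_nm[k] / layout$pixel_size
    if (amps[k] > 0 &&
        (xc - 3 * sd_px < 1 || xc + 3 * sd_px > w ||
         cy - 3 * sd_px < 1 || cy + 3 * sd_px > h)) {
      abort(sprintf("Channel '%s' cluster is clipped by the image edge.",
                    names(offsets)[k]))
    }
    gx <- exp(-((seq_len(w) - xc)^2) / (2 * sd_px^2))
    gy <- exp(-((seq_len(h) - cy)^2) / (2 * sd_px^2))
    channels[[k]] <- amps[k] * layout$photon_scale * outer(gy, gx)
  }
  if (noise) {
    set.seed(as.integer(seed))
    channels <- lapply(channels, function(m) {
      matrix(rpois(length(m), lambda = m), nrow = nrow(m))
    })
  }
  structure(list(channels = channels, layout = layout,
                 pixel_size = layout$pixel_size, centre_px = c(x = cx, y = cy)),
            class = "sted_image")
}
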