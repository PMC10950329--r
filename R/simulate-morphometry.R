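#' Mean structure densities for the morphometry generator
#'
#' Densities are counts per square micrometre of bouton cross-section for the
#' structures scored in synaptic electron micrographs: synaptic vesicles
#' (SVs), endosome-like vacuoles (ELVs), non-coated plasma-membrane
#' invaginations, clathrin-coated pits and clathrin-coated vesicles. Bouton
#' profile areas are lognormal with the stated mean and CV.
#'
#' @param svs,elvs,invaginations,coated_pits,coated_vesicles Mean densities,
#'   counts per um^2. The SV default matches a typical control bouton
#'   (92.2/um^2); the rarer structures default to low single-figure
#'   densities.
#' @param bouton_area_mean Mean bouton profile area, um^2.
#' @param bouton_area_cv Coefficient of variation of the area.
#' @return An object of class `morphometry_densities`.
#' @export
morphometry_densities <- function(svs = 92.2, elvs = 3, invaginations = 1.5,
                                  coated_pits = 0.8, coated_vesicles = 0.8,
                                  bouton_area_mean = 0.35,
                                  bouton_area_cv = 0.5) {
  dens <- c(svs = svs, elvs = elvs, invaginations = invaginations,
            coated_pits = coated_pits, coated_vesicles = coated_vesicles)
  if (anyNA(dens) || any(dens < 0)) abort("Densities must be >= 0.")
  if (bouton_area_mean <= 0) abort("`bouton_area_mean` must be positive.")
  if (bouton_area_cv < 0) abort("`bouton_area_cv` must be >= 0.")
  structure(list(densities = dens, bouton_area_mean = bouton_area_mean,
                 bouton_area_cv = bouton_area_cv),
            class = "morphometry_densities")
}

#' Simulate per-synapse morphometry count records
#'
#' Samples bouton profile areas from a lognormal distribution and structure
#' counts from Poisson(density x area), one record per synaptic profile.
#'
#' @param densities A [morphometry_densities()].
#' @param n_synapses Number of synaptic profiles.
#' @param seed Integer seed.
#' @param group Optional group label recorded in the output.
#' @return A tibble with `synapse_id`, `group` (if given), `bouton_area_um2`
#'   and one integer count column per structure.
#' @examples
#' simulate_morphometry(morphometry_densities(), n_synapses = 5, seed = 1)
#' @export
simulate_morphometry <- function(densities, n_synapses, seed = 1L,
                                 group = NULL) {
  stopifnot(inherits(densities, "morphometry_densities"))
  if (n_synapses < 1) abort("`n_synapses` must be >= 1.")
  set.seed(as.integer(seed))
  cv <- densities$bouton_area_cv
  area <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n_synapses, meanlog = log(densities$bouton_area_mean) - sdlog^2 / 2,
           sdlog = sdlog)
  } else {
    rep(densities$bouton_area_mean, n_synapses)
  }
  counts <- lapply(densities$densities, function(d) {
    rpois(n_synapses, lambda = d * area)
  })
  out <- tibble(synapse_id = seq_len(n_synapses))
  if (!is.null(group)) out$group <- group
  out$bouton_area_um2 <- area
  dplyr::bind_cols(out, as_tibble(counts))
}
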