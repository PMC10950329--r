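#' Structure densities per bouton area
#'
#' Converts per-synapse structure counts into densities (count per um^2 of
#' bouton profile area). Records with non-positive area are rejected and
#' reported, not silently dropped into the summary.
#'
#' @param records A morphometry tibble as produced by
#'   [simulate_morphometry()] or read from CSV: `synapse_id`, optional
#'   `group`, `bouton_area_um2` and one count column per structure.
#' @param structure Name of the count column to summarise (e.g. `"svs"`).
#' @return A tibble with `synapse_id`, `group` (if present), `count`,
#'   `bouton_area_um2` and `density` (count/um^2). The number of rejected
#'   zero-area records is attached as attribute `n_rejected`.
#' @examples
#' rec <- simulate_morphometry(morphometry_densities(), 10, seed = 2)
#' density_per_area(rec, "svs")
#' @export
density_per_area <- function(records, structure) {
  dat <- as_tibble(records)
  if (!structure %in% names(dat)) {
    abort(sprintf("Structure '%s' not present in the records.", structure))
  }
  if (!"bouton_area_um2" %in% names(dat)) {
    abort("`records` must contain a `bouton_area_um2` column.")
  }
  bad <- dat$bouton_area_um2 <= 0 | !is.finite(dat$bouton_area_um2)
  if (any(bad)) {
    warn(sprintf("%d record(s) with non-positive area rejected.", sum(bad)))
    dat <- dat[!bad, ]
  }
  keep <- intersect(c("synapse_id", "group"), names(dat))
  out <- dat |>
    dplyr::select(dplyr::all_of(keep), "bouton_area_um2",
                  count = dplyr::all_of(structure)) |>
    dplyr::mutate(density = .data$count / .data$bouton_area_um2)
  structure(out, n_rejected = sum(bad))
}

#' @rdname density_per_area
#' @return `density_summary()`: mean density, SEM and n per group.
#' @export
density_summary <- function(records, structure) {
  dens <- density_per_area(records, structure)
  if (!"group" %in% names(dens)) dens$group <- "all"
  dens |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_density = mean(.data$density),
      sem = if (dplyr::n() > 1) sd(.data$density) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop")
}
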