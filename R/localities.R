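#' Build a locality table
#'
#' One row per individual, carrying the planar (km) coordinates of its
#' locality. Locality-level views are obtained with
#' `dplyr::distinct(tbl, locality, x, y)`.
#'
#' @param individual character ids (each appears exactly once).
#' @param locality character locality ids.
#' @param x,y planar coordinates in km.
#' @param species_hint optional species label per individual.
#' @param is_reference optional logical flag (reference-panel individual).
#' @return tibble of class `locality_tbl`.
#' @export
locality_table <- function(individual, locality, x, y,
                           species_hint = NA_character_, is_reference = FALSE) {
  tbl <- tibble::tibble(
    individual = as.character(individual),
    locality = as.character(locality),
    x = as.numeric(x), y = as.numeric(y),
    species_hint = species_hint,
    is_reference = is_reference
  )
  if (anyDuplicated(tbl$individual)) {
    abort("each individual must appear in exactly one locality")
  }
  if (!all(is.finite(tbl$x)) || !all(is.finite(tbl$y))) abort("non-finite coordinates")
  coords <- dplyr::distinct(tbl, .data$locality, .data$x, .data$y)
  if (anyDuplicated(coords$locality)) {
    abort("a locality has inconsistent coordinates across individuals")
  }
  class(tbl) <- c("locality_tbl", class(tbl))
  tbl
}

#' Locality-level coordinates from a locality table
#' @param localities a `locality_tbl`.
#' @return tibble (locality, x, y, n_individuals).
#' @export
locality_points <- function(localities) {
  localities |>
    dplyr::group_by(.data$locality, .data$x, .data$y) |>
    dplyr::summarise(n_individuals = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$locality)
}

#' Build a reference panel
#'
#' @param individual character ids.
#' @param species species label per reference individual.
#' @return tibble of class `reference_panel`.
#' @export
reference_panel <- function(individual, species) {
  tbl <- tibble::tibble(individual = as.character(individual),
                        species = as.character(species))
  if (anyDuplicated(tbl$individual)) abort("reference individuals must be unique across species")
  if (any(table(tbl$species) == 0)) abort("empty reference species set")
  class(tbl) <- c("reference_panel", class(tbl))
  tbl
}

#' Analysis configuration
#'
#' Bundles the explicit knobs of the pipeline so every output can record them.
#'
#' @param seed integer RNG seed.
#' @param admixture_threshold `"reference_min_q"` (1 minus the lowest
#'   own-species Q among reference individuals) or a fixed numeric value.
#' @param grid_resolution interpolation grid size (cells per axis).
#' @param optimizer_restarts multistart count for cline fitting.
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @param sweeps,burnin admixture sampler settings.
#' @param paths named list of file paths (optional).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L,
                            admixture_threshold = "reference_min_q",
                            grid_resolution = 200L,
                            optimizer_restarts = 20L,
                            bootstrap_replicates = 1000L,
                            sweeps = 20000L, burnin = 5000L,
                            paths = list()) {
  cfg <- list(seed = as.integer(seed),
              admixture_threshold = admixture_threshold,
              grid_resolution = as.integer(grid_resolution),
              optimizer_restarts = as.integer(optimizer_restarts),
              bootstrap_replicates = as.integer(bootstrap_replicates),
              sweeps = as.integer(sweeps), burnin = as.integer(burnin),
              paths = paths)
  class(cfg) <- "analysis_config"
  cfg
}
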