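#' Find species-diagnostic markers
#'
#' A locus is diagnostic when every species' reference panel is fixed for a
#' single allele (ignoring missing calls) and the focal species' allele is
#' absent from every other species' panel. Loci at which some species has no
#' scored reference individual are skipped with a warning.
#'
#' @param g a `genotype_tbl`.
#' @param panel a `reference_panel`.
#' @param focal focal species label (must occur in `panel`).
#' @return tibble of class `diagnostic_panel` with columns `locus`,
#'   `species`, `allele` (the fixed allele of that species at that locus);
#'   attribute `focal`.
#' @export
find_diagnostic_markers <- function(g, panel, focal) {
  validate_genotype_table(g)
  if (!focal %in% panel$species) abort(paste("focal species", focal, "not in reference panel"))
  ref <- g |>
    dplyr::inner_join(panel, by = "individual") |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele))
  species <- sort(unique(panel$species))
  per <- ref |>
    dplyr::distinct(.data$locus, .data$species, .data$allele) |>
    dplyr::group_by(.data$locus, .data$species) |>
    dplyr::summarise(n_alleles = dplyr::n(), allele = .data$allele[1], .groups = "drop")
  # species with all-missing panel at a locus
  cover <- per |> dplyr::count(.data$locus)
  short <- cover$locus[cover$n < length(species)]
  if (length(short)) {
    warn(paste("loci skipped (species with all-missing reference panel):",
               paste(short, collapse = ", ")))
  }
  cand <- per |>
    dplyr::filter(!.data$locus %in% short) |>
    dplyr::group_by(.data$locus) |>
    dplyr::filter(all(.data$n_alleles == 1)) |>
    dplyr::mutate(
      diagnostic = sum(.data$allele == .data$allele[.data$species == .env$focal]) == 1
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$diagnostic) |>
    dplyr::select("locus", "species", "allele")
  out <- dplyr::arrange(cand, .data$locus, .data$species)
  attr(out, "focal") <- focal
  class(out) <- c("diagnostic_panel", class(out))
  out
}

panel_focal <- function(panel) {
  attr(panel, "focal") %||% abort("diagnostic panel lacks a focal species attribute")
}

# per-individual focal-allele counts over a diagnostic panel
diagnostic_counts <- function(g, dpanel) {
  focal <- panel_focal(dpanel)
  fmap <- dpanel |> dplyr::filter(.data$species == focal) |>
    dplyr::select("locus", focal_allele = "allele")
  g |>
    dplyr::inner_join(fmap, by = "locus") |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    dplyr::mutate(
      n_focal = (.data$allele_1 == .data$focal_allele) +
        (.data$allele_2 == .data$focal_allele)
    )
}

#' Hybrid index from diagnostic markers
#'
#' The hybrid index is the proportion of diagnostic focal-species alleles
#' among scored diagnostic alleles; missing genotypes drop out of both
#' numerator and denominator. With `by = "locality"` counts are pooled over
#' the locality's individuals.
#'
#' @param g a `genotype_tbl`.
#' @param dpanel a `diagnostic_panel` from [find_diagnostic_markers()].
#' @param localities a `locality_tbl` (needed for `by = "locality"`).
#' @param by `"locality"` or `"individual"`.
#' @return tibble with `h`, `n_genotypes` (scored loci x individuals) and
#'   `n_alleles` per unit. Units with zero scored genotypes are returned
#'   with `h = NA` and flagged via the `scored` column.
#' @export
hybrid_index <- function(g, dpanel, localities = NULL,
                         by = c("locality", "individual")) {
  by <- match.arg(by)
  if (nrow(dpanel) == 0) abort("diagnostic panel is empty")
  cnt <- diagnostic_counts(g, dpanel)
  per_ind <- cnt |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(focal_alleles = sum(.data$n_focal),
                     n_genotypes = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(n_alleles = 2L * .data$n_genotypes)
  if (by == "individual") {
    out <- per_ind |>
      dplyr::mutate(h = .data$focal_alleles / .data$n_alleles, scored = TRUE) |>
      dplyr::select("individual", "h", "n_genotypes", "n_alleles", "scored")
    return(out)
  }
  if (is.null(localities)) abort("localities required for by = 'locality'")
  out <- localities |>
    dplyr::distinct(.data$individual, .data$locality) |>
    dplyr::left_join(per_ind, by = "individual") |>
    dplyr::group_by(.data$locality) |>
    dplyr::summarise(
      focal_alleles = sum(.data$focal_alleles, na.rm = TRUE),
      n_genotypes = sum(.data$n_genotypes, na.rm = TRUE),
      n_alleles = sum(.data$n_alleles, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      scored = .data$n_genotypes > 0,
      h = ifelse(.data$scored, .data$focal_alleles / .data$n_alleles, NA_real_)
    ) |>
    dplyr::select("locality", "h", "n_genotypes", "n_alleles", "scored")
  if (any(!out$scored)) {
    warn(paste("localities with zero scored diagnostic genotypes:",
               paste(out$locality[!out$scored], collapse = ", ")))
  }
  out
}
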