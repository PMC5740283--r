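#' Per-individual heterozygosity and ancestry for a species pair
#'
#' For each individual, over the loci diagnostic for the (focal, other)
#' pair: ancestry `S` is the fraction of scored alleles that are focal
#' alleles, and interclass heterozygosity `H` is the fraction of scored loci
#' heterozygous for one focal and one other-species allele. With fully
#' diagnostic markers these counting estimates coincide with the
#' maximum-likelihood ancestry/heterozygosity estimates used for triangle
#' plots; a pure parental sits at (0, 0) or (1, 0) and an F1 at the apex
#' (0.5, 1). The allele-count identity `H <= 2 min(S, 1 - S)` holds exactly
#' when no third-species alleles are present.
#'
#' @param g a `genotype_tbl`.
#' @param dpanel a `diagnostic_panel`.
#' @param pair character length-2: (focal species, other species); defaults
#'   to the panel's focal species and `other`.
#' @param localities optional `locality_tbl` to attach locality ids.
#' @return tibble of class `triangle_stats`: `individual`, `locality`
#'   (NA when unknown), `S`, `H`, `n_loci`.
#' @export
heterozygosity_ancestry <- function(g, dpanel, pair = NULL, localities = NULL) {
  focal <- panel_focal(dpanel)
  if (is.null(pair)) {
    others <- setdiff(unique(dpanel$species), focal)
    if (length(others) != 1) abort("pair must be given when the panel covers > 2 species")
    pair <- c(focal, others)
  }
  if (pair[1] != focal) abort("pair[1] must be the panel's focal species")
  amap <- dpanel |>
    dplyr::filter(.data$species %in% pair) |>
    tidyr::pivot_wider(names_from = "species", values_from = "allele") |>
    dplyr::rename(f_allele = dplyr::all_of(pair[1]), o_allele = dplyr::all_of(pair[2]))
  stats_tbl <- g |>
    dplyr::inner_join(amap, by = "locus") |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    dplyr::mutate(
      n_focal = (.data$allele_1 == .data$f_allele) + (.data$allele_2 == .data$f_allele),
      het_fo = (.data$allele_1 == .data$f_allele & .data$allele_2 == .data$o_allele) |
        (.data$allele_1 == .data$o_allele & .data$allele_2 == .data$f_allele)
    ) |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(S = sum(.data$n_focal) / (2 * dplyr::n()),
                     H = mean(.data$het_fo),
                     n_loci = dplyr::n(), .groups = "drop")
  dropped <- setdiff(genotype_individuals(g), stats_tbl$individual)
  if (length(dropped)) {
    warn(paste("individuals with zero scored diagnostic loci excluded:",
               paste(dropped, collapse = ", ")))
  }
  if (!is.null(localities)) {
    stats_tbl <- stats_tbl |>
      dplyr::left_join(dplyr::distinct(localities, .data$individual, .data$locality),
                       by = "individual")
  } else {
    stats_tbl$locality <- NA_character_
  }
  out <- dplyr::select(stats_tbl, "individual", "locality", "S", "H", "n_loci")
  class(out) <- c("triangle_stats", class(out))
  out
}

#' Locality averages of triangle statistics
#'
#' @param stats a `triangle_stats` tibble with locality ids.
#' @return tibble (locality, S, H, n_individuals).
#' @export
locality_triangle_summary <- function(stats) {
  if (all(is.na(stats$locality))) abort("triangle stats carry no locality ids")
  stats |>
    dplyr::filter(!is.na(.data$locality)) |>
    dplyr::group_by(.data$locality) |>
    dplyr::summarise(S = mean(.data$S), H = mean(.data$H),
                     n_individuals = dplyr::n(), .groups = "drop")
}

#' Classify localities as range core or range edge
#'
#' A locality is `core` when every adjacent Thiessen polygon has the same
#' genetically dominant species, and `edge` when at least one neighbour is
#' dominated by the alternative species. A neighbour-less polygon is core by
#' the vacuous-truth reading (configurable via `isolated_core`).
#'
#' @param adjacency tibble (locality_a, locality_b) of polygon neighbours
#'   (e.g. `build_thiessen()$adjacency`).
#' @param dominant named character vector or tibble (locality, dominant).
#' @param isolated_core label for neighbour-less localities: core if `TRUE`.
#' @return tibble (locality, dominant, label).
#' @export
classify_core_edge <- function(adjacency, dominant, isolated_core = TRUE) {
  if (is.data.frame(dominant)) {
    dominant <- setNames(dominant$dominant, dominant$locality)
  }
  locs <- names(dominant)
  edges <- dplyr::bind_rows(
    adjacency,
    setNames(adjacency, rev(names(adjacency)))
  )
  missing <- setdiff(unique(c(edges$locality_a, edges$locality_b)), locs)
  if (length(missing)) {
    abort(paste("localities in the adjacency graph lack a dominant label:",
                paste(missing, collapse = ", ")))
  }
  label <- vapply(locs, function(l) {
    nb <- edges$locality_b[edges$locality_a == l]
    if (!length(nb)) return(if (isolated_core) "core" else "edge")
    if (all(dominant[nb] == dominant[l])) "core" else "edge"
  }, "")
  tibble::tibble(locality = locs, dominant = unname(dominant),
                 label = unname(label))
}
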