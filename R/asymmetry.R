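#' Per-locality counts of alleles attributable to each species
#'
#' At each diagnostic locus an allele matching exactly one species' fixed
#' allele is attributed to that species; alleles matching the fixed allele
#' of several species are ambiguous and not attributed.
#'
#' @param g a `genotype_tbl`.
#' @param dpanel a `diagnostic_panel`.
#' @param localities a `locality_tbl`.
#' @return tibble (locality, species, n_alleles, n_scored).
#' @export
allele_counts_by_species <- function(g, dpanel, localities) {
  long <- g |>
    dplyr::inner_join(dplyr::distinct(dpanel, .data$locus) , by = "locus") |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    dplyr::left_join(dplyr::distinct(localities, .data$individual, .data$locality),
                     by = "individual")
  scored <- long |> dplyr::count(.data$locality, name = "n_scored")
  attributed <- long |>
    dplyr::inner_join(dpanel, by = c("locus", "allele"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$locality, .data$locus, .data$individual,
                    .data$name, .data$allele) |>
    dplyr::filter(dplyr::n() == 1) |>  # unambiguous: matches exactly one species
    dplyr::ungroup() |>
    dplyr::count(.data$locality, .data$species, name = "n_alleles")
  tidyr::expand_grid(locality = scored$locality,
                     species = sort(unique(dpanel$species))) |>
    dplyr::left_join(attributed, by = c("locality", "species")) |>
    dplyr::left_join(scored, by = "locality") |>
    dplyr::mutate(n_alleles = tidyr::replace_na(.data$n_alleles, 0L))
}

#' Exclude localities with third-species ancestry from a pairwise comparison
#'
#' A locality is excluded from the (focal, other) comparison when
#' (a) the clustering summary gives a third species a mean Q above the
#' admixture threshold, or (b) an allele diagnostic for a third species is
#' present and a neighbouring Thiessen polygon is dominated by that species
#' (low-frequency introgression corroborated by the neighbourhood).
#'
#' @param q_summary output of [summarize_localities()].
#' @param allele_counts output of [allele_counts_by_species()].
#' @param adjacency tibble (locality_a, locality_b).
#' @param pair character length-2 (focal, other).
#' @param threshold admixture threshold; defaults to the one recorded in
#'   `q_summary`.
#' @return tibble (locality, excluded, reason).
#' @export
exclude_third_species <- function(q_summary, allele_counts, adjacency, pair,
                                  threshold = NULL) {
  if (is.null(adjacency)) abort("adjacency graph required for the neighbour rule")
  threshold <- threshold %||% q_summary$threshold[1]
  species <- sub("^q_", "", grep("^q_", names(q_summary), value = TRUE))
  third <- setdiff(species, pair)
  edges <- dplyr::bind_rows(adjacency, setNames(adjacency, rev(names(adjacency))))
  dominant <- setNames(q_summary$dominant, q_summary$locality)
  out <- lapply(q_summary$locality, function(l) {
    row <- q_summary[q_summary$locality == l, ]
    qa <- vapply(third, function(sp) row[[paste0("q_", sp)]], 0)
    if (length(third) && any(qa > threshold)) {
      return(tibble::tibble(locality = l, excluded = TRUE,
                            reason = paste0("third-species Q > threshold (",
                                            paste(third[qa > threshold], collapse = ","), ")")))
    }
    if (length(third)) {
      cnt <- allele_counts[allele_counts$locality == l &
                             allele_counts$species %in% third &
                             allele_counts$n_alleles > 0, ]
      if (nrow(cnt)) {
        nb <- edges$locality_b[edges$locality_a == l]
        bad <- intersect(cnt$species, dominant[nb])
        if (length(bad)) {
          return(tibble::tibble(locality = l, excluded = TRUE,
                                reason = paste0("third-species alleles with ",
                                                paste(bad, collapse = ","),
                                                "-dominant neighbour")))
        }
      }
    }
    tibble::tibble(locality = l, excluded = FALSE, reason = NA_character_)
  })
  dplyr::bind_rows(out)
}

#' Per-locality introgression records for a species pair
#'
#' Each retained locality is assigned to its dominant species' side; the
#' foreign-allele fraction is the proportion of scored diagnostic alleles
#' attributable to the opposite member of the pair, and presence is a
#' fraction greater than zero.
#'
#' @param allele_counts output of [allele_counts_by_species()].
#' @param dominant named vector or tibble (locality, dominant).
#' @param pair character length-2 (focal, other).
#' @param exclusions optional output of [exclude_third_species()].
#' @return tibble of class `introgression_tbl`: `locality`, `side`,
#'   `foreign_fraction`, `presence`, `n_scored`.
#' @export
introgression_table <- function(allele_counts, dominant, pair, exclusions = NULL) {
  if (is.data.frame(dominant)) dominant <- setNames(dominant$dominant, dominant$locality)
  keep <- unique(allele_counts$locality)
  if (!is.null(exclusions)) {
    keep <- setdiff(keep, exclusions$locality[exclusions$excluded])
  }
  wide <- allele_counts |>
    dplyr::filter(.data$locality %in% keep, .data$species %in% pair) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n_alleles")
  side <- dominant[wide$locality]
  if (anyNA(side)) abort("locality without a dominant-species label")
  drop <- wide$n_scored == 0
  if (any(drop)) {
    warn(paste("localities with no scored diagnostic alleles excluded:",
               paste(wide$locality[drop], collapse = ", ")))
  }
  wide <- wide[!drop & side %in% pair, ]
  side <- side[!drop & side %in% pair]
  foreign_sp <- ifelse(side == pair[1], pair[2], pair[1])
  foreign_n <- as.numeric(purrr::map2_dbl(seq_len(nrow(wide)), foreign_sp,
                                          function(i, sp) wide[[sp]][i]))
  out <- tibble::tibble(
    locality = wide$locality,
    side = unname(side),
    foreign_fraction = foreign_n / wide$n_scored,
    presence = foreign_n > 0,
    n_scored = wide$n_scored
  )
  class(out) <- c("introgression_tbl", class(out))
  out
}

#' Fisher's exact test of asymmetric introgression (presence/absence)
#'
#' Two-sided exact test on the 2 x 2 table of side x foreign-allele
#' presence.
#'
#' @param records an `introgression_tbl`.
#' @return one-row tibble: `test`, `p`, per-side locality and presence
#'   counts.
#' @export
fisher_asymmetry <- function(records) {
  sides <- sort(unique(records$side))
  if (length(sides) != 2) abort("need records on both sides of the pair")
  tab <- table(factor(records$side, sides),
               factor(records$presence, c(FALSE, TRUE)))
  ft <- fisher.test(tab)
  tibble::tibble(
    test = "fisher_exact",
    p = ft$p.value,
    side_1 = sides[1], n_1 = sum(tab[1, ]), present_1 = tab[1, 2],
    side_2 = sides[2], n_2 = sum(tab[2, ]), present_2 = tab[2, 2]
  )
}

#' One-tailed Mann-Whitney U test of asymmetric introgression (fractions)
#'
#' Tests whether foreign-allele fractions on one side are stochastically
#' greater than on the other (by default: greater introgression into the
#' putative invader's side, i.e. the non-focal side). U is computed from
#' rank sums with midranks for ties. For tie-free data with
#' `n1 * n2 <= 400` the one-tailed p comes from the exact null distribution
#' of U; otherwise from the normal approximation with tie-corrected
#' variance and continuity correction. The tie-corrected Z statistic is
#' always reported.
#'
#' @param records an `introgression_tbl`.
#' @param greater_side side label whose fractions are predicted greater
#'   (default: the second side in sorted order; pass explicitly in
#'   pipelines).
#' @return one-row tibble: `test`, `U` (min of U1, U2), `U_greater`, `Z`,
#'   `p`, sample sizes, `method`.
#' @export
mannwhitney_asymmetry <- function(records, greater_side = NULL) {
  sides <- sort(unique(records$side))
  if (length(sides) != 2) abort("need records on both sides of the pair")
  greater_side <- greater_side %||% sides[2]
  if (!greater_side %in% sides) abort("greater_side not among the record sides")
  xg <- records$foreign_fraction[records$side == greater_side]
  xo <- records$foreign_fraction[records$side != greater_side]
  n1 <- length(xo); n2 <- length(xg)
  r <- rank(c(xo, xg))  # midranks
  R2 <- sum(r[(n1 + 1):(n1 + n2)])
  U2 <- R2 - n2 * (n2 + 1) / 2   # pairs where the 'greater' side wins
  U1 <- n1 * n2 - U2
  ties <- table(r)
  all_tied <- length(ties) == 1
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - sum(ties^3 - ties) /
                            ((n1 + n2) * (n1 + n2 - 1)))
  has_ties <- any(ties > 1)
  if (all_tied) {
    return(tibble::tibble(test = "mann_whitney_one_tailed", U = min(U1, U2),
                          U_greater = U2, Z = 0, p = 1, n_1 = n1, n_2 = n2,
                          method = "degenerate_all_tied"))
  }
  if (!has_ties && n1 * n2 <= 400) {
    p <- exact_u_tail_p(n1, n2, U2)
    method <- "exact"
    Z <- (U2 - mu - 0.5) / sqrt(sig2)
  } else {
    Z <- (U2 - mu - 0.5) / sqrt(sig2)
    p <- pnorm(Z, lower.tail = FALSE)
    method <- "normal_tie_corrected"
  }
  tibble::tibble(test = "mann_whitney_one_tailed", U = min(U1, U2),
                 U_greater = U2, Z = Z, p = p, n_1 = n1, n_2 = n2,
                 method = method)
}

# P(U >= u) under the exact tie-free null, via the counting recursion
exact_u_tail_p <- function(n1, n2, u) {
  counts <- mw_counts(n1, n2)
  k <- ceiling(u - 1e-9)
  sum(counts[(k + 1):length(counts)]) / sum(counts)
}

# number of rank arrangements of (n, m) observations with U statistic u,
# u = 0..n*m, by the recursion N(u; n, m) = N(u - m; n - 1, m) + N(u; n, m - 1)
mw_counts <- function(n, m) {
  maxu <- n * m
  N <- lapply(0:n, function(i) c(1, rep(0, maxu)))  # j = 0 base case
  for (j in seq_len(m)) {
    Nn <- vector("list", n + 1)
    Nn[[1]] <- c(1, rep(0, maxu))                   # i = 0
    for (i in seq_len(n)) {
      v <- Nn[[i]]                                  # N(u; i - 1, j)
      shifted <- c(rep(0, j), v[seq_len(maxu + 1 - j)])
      Nn[[i + 1]] <- shifted + N[[i + 1]]           # + N(u; i, j - 1)
    }
    N <- Nn
  }
  N[[n + 1]]
}
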