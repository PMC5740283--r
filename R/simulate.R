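#' Scenario for simulating k diverged populations
#'
#' Biallelic genotypes under the Balding-Nichols model: an ancestral allele
#' frequency per locus is drawn from Uniform(0.1, 0.9) and each population's
#' frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), so F is the expected
#' Wright-style divergence among populations.
#'
#' @param k_true number of populations.
#' @param fst divergence parameter in (0, 1).
#' @param n_loci number of biallelic loci.
#' @param n_per_pop diploid individuals per population.
#' @param seed RNG seed.
#' @return list of class `structured_pop_scenario`.
#' @export
structured_pop_scenario <- function(k_true = 4L, fst = 0.3, n_loci = 50L,
                                    n_per_pop = 30L, seed = 1L) {
  if (fst <= 0 || fst >= 1) abort("fst must be in (0, 1)")
  if (k_true < 1) abort("k_true must be >= 1")
  if (k_true * n_per_pop == 0) abort("k_true * n_per_pop must be positive")
  structure(list(k_true = as.integer(k_true), fst = fst,
                 n_loci = as.integer(n_loci), n_per_pop = as.integer(n_per_pop),
                 seed = as.integer(seed)),
            class = "structured_pop_scenario")
}

#' Simulate genotypes for k diverged populations
#'
#' @param scn a [structured_pop_scenario()].
#' @return list with `genotypes` (a `genotype_tbl`), `truth`
#'   (tibble individual, population), and `freqs` (tibble locus, population,
#'   freq of allele "A").
#' @export
simulate_structured_populations <- function(scn) {
  stopifnot(inherits(scn, "structured_pop_scenario"))
  set.seed(scn$seed)
  L <- scn$n_loci; k <- scn$k_true; n <- scn$n_per_pop
  p_anc <- runif(L, 0.1, 0.9)
  f <- scn$fst
  freq <- matrix(rbeta(L * k,
                       rep(p_anc, k) * (1 - f) / f,
                       rep(1 - p_anc, k) * (1 - f) / f),
                 nrow = L, ncol = k)
  loci <- sprintf("L%03d", seq_len(L))
  pops <- sprintf("pop%d", seq_len(k))
  ids <- sprintf("%s_i%02d", rep(pops, each = n), rep(seq_len(n), k))
  # count of "A" alleles per individual x locus
  cnt <- matrix(0L, nrow = length(ids), ncol = L)
  for (j in seq_len(k)) {
    rows <- ((j - 1) * n + 1):(j * n)
    cnt[rows, ] <- matrix(rbinom(n * L, 2, rep(freq[, j], each = n)), nrow = n)
  }
  a1 <- ifelse(cnt >= 1, "A", "B")
  a2 <- ifelse(cnt == 2, "A", "B")
  g <- genotype_table(
    individual = rep(ids, times = L),
    locus = rep(loci, each = length(ids)),
    allele_1 = as.vector(a1),
    allele_2 = as.vector(a2)
  )
  list(
    genotypes = g,
    truth = tibble::tibble(individual = ids, population = rep(pops, each = n)),
    freqs = tibble::tibble(locus = rep(loci, k), population = rep(pops, each = L),
                           freq = as.vector(freq))
  )
}

#' Contact-zone scenario (stable or moving front)
#'
#' Defines the closed-form allele-frequency field of a two-species contact
#' zone on a planar window (km). The focal species occupies the high-x side;
#' the front now sits at `front` (= x1). Under `"moving"` the other species
#' advanced from `front_initial` (= x0 < x1), leaving a wake of focal alleles
#' `wake_amplitude * exp(-(x1 - x)/wake_length)` for x0 < x < x1, and an
#' enclave disc of pure focal ancestry persists behind the front. Under
#' `"stable"` the front never moved (x0 = x1, no wake); the enclave, if
#' present, represents long-distance colonization instead.
#'
#' @param scenario `"stable"` or `"moving"`.
#' @param front current front position x1 (km).
#' @param front_initial initial front x0; defaults to `front` (stable) or
#'   `front - 120` (moving).
#' @param width genetic cline width w (km); default 20 km, a few times the
#'   species' lifetime dispersal distance, as typical for tension zones in
#'   low-vagility amphibians.
#' @param wake_amplitude A in (0, 1]; ignored when stable.
#' @param wake_length lambda > 0 (km); with the default 60 km the wake is
#'   detectable across the whole invaded strip, matching a system where
#'   left-behind alleles reach deep into the invader's range.
#' @param enclave_centre length-2 (x, y) in km, or `NULL` for no enclave;
#'   default 83 km behind the front.
#' @param enclave_radius disc radius (km).
#' @param n_enclave_localities localities placed inside the enclave disc so
#'   the enclave is always sampled (0 when no enclave).
#' @param n_loci number of diagnostic biallelic loci.
#' @param n_localities number of sampled localities (reference and enclave
#'   localities are added on top).
#' @param window,window_y sampling window extents (km).
#' @param mt_lag mtDNA front offset: the mtDNA front sits at `front + mt_lag`.
#'   Defaults to -20 km under `"moving"` (the receding species' mtDNA
#'   protrudes into the invaded range) and 0 when stable.
#' @param focal,other species labels.
#' @param seed RNG seed.
#' @return list of class `zone_scenario`.
#' @export
zone_scenario <- function(scenario = c("moving", "stable"),
                          front = 0, front_initial = NULL, width = 20,
                          wake_amplitude = 0.4, wake_length = 60,
                          enclave_centre = c(front - 83, 0), enclave_radius = 10,
                          n_enclave_localities = 4L,
                          n_loci = 23L, n_localities = 100L,
                          window = c(-200, 200), window_y = c(-60, 60),
                          mt_lag = NULL, focal = "focal", other = "other",
                          seed = 1L) {
  scenario <- match.arg(scenario)
  front_initial <- front_initial %||% if (scenario == "stable") front else front - 120
  mt_lag <- mt_lag %||% if (scenario == "moving") -20 else 0
  if (wake_length <= 0) abort("wake_length must be > 0")
  if (scenario == "moving") {
    if (wake_amplitude <= 0 || wake_amplitude > 1) abort("wake_amplitude must be in (0, 1]")
    if (front_initial >= front) abort("moving scenario requires front_initial < front")
  } else {
    front_initial <- front
  }
  if (!is.null(enclave_centre)) {
    if (scenario == "moving" &&
        enclave_centre[1] + enclave_radius >= front) {
      abort("enclave overlaps the front: it must lie strictly behind it")
    }
  }
  if (is.null(enclave_centre)) n_enclave_localities <- 0L
  scn <- list(scenario = scenario, front = front, front_initial = front_initial,
              width = width, wake_amplitude = wake_amplitude,
              wake_length = wake_length, enclave_centre = enclave_centre,
              enclave_radius = enclave_radius,
              n_enclave_localities = as.integer(n_enclave_localities),
              n_loci = as.integer(n_loci),
              n_localities = as.integer(n_localities), window = window,
              window_y = window_y, mt_lag = mt_lag, focal = focal,
              other = other, seed = as.integer(seed))
  class(scn) <- "zone_scenario"
  scn
}

#' Closed-form focal-allele frequency field of a contact-zone scenario
#'
#' @param x,y coordinates (km); `y` recycled.
#' @param scn a [zone_scenario()].
#' @param what `"nuclear"` (allele-frequency field) or `"mtdna"`
#'   (probability of carrying focal mtDNA).
#' @return numeric vector of frequencies in `[0, 1]`.
#' @export
contact_zone_field <- function(x, y, scn, what = c("nuclear", "mtdna")) {
  what <- match.arg(what)
  centre <- if (what == "nuclear") scn$front else scn$front + scn$mt_lag
  p <- stats::plogis(4 * (x - centre) / scn$width)
  if (scn$scenario == "moving" && what == "nuclear") {
    wake <- scn$wake_amplitude * exp(-(scn$front - x) / scn$wake_length)
    in_wake <- x > scn$front_initial & x < scn$front
    p <- p + ifelse(in_wake, wake, 0)
  }
  p <- pmin(pmax(p, 0), 1)
  if (!is.null(scn$enclave_centre)) {
    d2 <- (x - scn$enclave_centre[1])^2 + (y - scn$enclave_centre[2])^2
    p[d2 <= scn$enclave_radius^2] <- 1  # focal-pure enclave
  }
  p
}

#' Simulate a sampled contact zone
#'
#' Localities are spread over the window (stratified in x with uniform
#' jitter, uniform in y), each with 1-3 diploid individuals (mean 2.645).
#' Per nuclear locus the focal-allele frequency at a locality is the
#' closed-form field of [contact_zone_field()] and genotypes are
#' Binomial(2, freq) draws. Reference localities (5 per species, 3
#' individuals each) are placed at least `3 * wake_length` beyond the front
#' on each pure side, outside the wake. mtDNA species labels are drawn from
#' the same sigmoid field with the front displaced by `mt_lag`.
#'
#' @param scn a [zone_scenario()].
#' @return list with `genotypes`, `localities` (a `locality_tbl`),
#'   `reference_panel`, `mtdna` (tibble individual, mt_species), `truth`
#'   (locality-level tibble with the generating frequencies) and `scenario`.
#' @export
simulate_contact_zone <- function(scn) {
  stopifnot(inherits(scn, "zone_scenario"))
  set.seed(scn$seed)
  # reference bands: clear of the wake (which is zero beyond the initial
  # front) and >= 3 cline widths beyond the nearer front on each side
  clearance <- 3 * scn$width
  ref_lo <- c(scn$window[1], min(scn$front, scn$front_initial) - clearance)
  ref_hi <- c(scn$front + clearance, scn$window[2])
  if (ref_lo[2] <= ref_lo[1] || ref_hi[2] <= ref_hi[1]) {
    abort("window too narrow to place reference localities beyond the contact zone")
  }
  # sampled localities: stratified x + jitter, uniform y
  n <- scn$n_localities
  bin <- diff(scn$window) / n
  xs <- scn$window[1] + (seq_len(n) - 1) * bin + runif(n, 0, bin)
  ys <- runif(n, scn$window_y[1], scn$window_y[2])
  loc_ids <- sprintf("loc%03d", seq_len(n))
  # enclave localities: uniform in the enclave disc
  ne <- scn$n_enclave_localities
  if (ne > 0) {
    r <- scn$enclave_radius * sqrt(runif(ne))
    ang <- runif(ne, 0, 2 * pi)
    xs <- c(xs, scn$enclave_centre[1] + r * cos(ang))
    ys <- c(ys, scn$enclave_centre[2] + r * sin(ang))
    loc_ids <- c(loc_ids, sprintf("enc%02d", seq_len(ne)))
  }
  # reference localities, 5 per species
  rx_o <- seq(ref_lo[1], ref_lo[2], length.out = 5)
  rx_f <- seq(ref_hi[1], ref_hi[2], length.out = 5)
  ry <- runif(10, scn$window_y[1], scn$window_y[2])
  # keep reference localities out of the enclave disc
  if (!is.null(scn$enclave_centre)) {
    rx <- c(rx_o, rx_f)
    inside <- (rx - scn$enclave_centre[1])^2 + (ry - scn$enclave_centre[2])^2 <=
      scn$enclave_radius^2
    ry[inside] <- scn$enclave_centre[2] + scn$enclave_radius + 5
  }
  ref_ids <- c(sprintf("ref_%s_%d", scn$other, 1:5), sprintf("ref_%s_%d", scn$focal, 1:5))
  all_loc <- tibble::tibble(
    locality = c(loc_ids, ref_ids),
    x = c(xs, rx_o, rx_f),
    y = c(ys, ry),
    is_reference = rep(c(FALSE, TRUE), c(n + ne, 10))
  )
  # 1-3 individuals per locality, mean 2.645; reference localities get 3
  n_ind <- ifelse(all_loc$is_reference, 3L,
                  sample(1:3, nrow(all_loc), replace = TRUE,
                         prob = c(0.100, 0.155, 0.745)))
  loc_long <- all_loc[rep(seq_len(nrow(all_loc)), n_ind), ]
  loc_long$individual <- paste0(loc_long$locality, "_i",
                                unlist(lapply(n_ind, seq_len)))
  p_nuc <- contact_zone_field(loc_long$x, loc_long$y, scn)
  p_mt <- contact_zone_field(loc_long$x, loc_long$y, scn, what = "mtdna")
  # reference individuals live in the pure field by construction
  loci <- sprintf("D%02d", seq_len(scn$n_loci))
  m <- nrow(loc_long)
  cnt <- matrix(rbinom(m * scn$n_loci, 2, rep(p_nuc, scn$n_loci)), nrow = m)
  a1 <- ifelse(cnt >= 1, "F", "O")   # F = focal allele, O = other allele
  a2 <- ifelse(cnt == 2, "F", "O")
  g <- genotype_table(
    individual = rep(loc_long$individual, times = scn$n_loci),
    locus = rep(loci, each = m),
    allele_1 = as.vector(a1),
    allele_2 = as.vector(a2)
  )
  species_hint <- ifelse(loc_long$is_reference,
                         ifelse(loc_long$x > scn$front, scn$focal, scn$other),
                         NA_character_)
  localities <- locality_table(loc_long$individual, loc_long$locality,
                               loc_long$x, loc_long$y,
                               species_hint = species_hint,
                               is_reference = loc_long$is_reference)
  panel <- reference_panel(loc_long$individual[loc_long$is_reference],
                           species_hint[loc_long$is_reference])
  mt <- tibble::tibble(
    individual = loc_long$individual,
    mt_species = ifelse(runif(m) < p_mt, scn$focal, scn$other)
  )
  truth <- loc_long |>
    dplyr::distinct(.data$locality, .data$x, .data$y, .data$is_reference) |>
    dplyr::mutate(
      true_freq = contact_zone_field(.data$x, .data$y, scn),
      p_mt_focal = contact_zone_field(.data$x, .data$y, scn, what = "mtdna"),
      in_enclave = if (is.null(scn$enclave_centre)) FALSE else
        (.data$x - scn$enclave_centre[1])^2 + (.data$y - scn$enclave_centre[2])^2 <=
        scn$enclave_radius^2,
      in_wake = scn$scenario == "moving" &
        .data$x > scn$front_initial & .data$x < scn$front
    )
  list(genotypes = g, localities = localities, reference_panel = panel,
       mtdna = mt, truth = truth, scenario = scn)
}

#' Simulate species-diagnostic mtDNA sequences for labelled individuals
#'
#' Two species haplotypes of the given length differ by a fixed substitution
#' every `diff_every` bp; each individual receives its species' haplotype.
#' This exercises the haplotype collapsing / assignment path with sequences
#' whose species signal is unambiguous.
#'
#' @param mt tibble (individual, mt_species) as returned by
#'   [simulate_contact_zone()].
#' @param length sequence length in bp (default 658).
#' @param diff_every put a fixed interspecific difference every this many bp.
#' @param seed RNG seed (base haplotype composition).
#' @return tibble (id, seq) usable with the sequence operations.
#' @export
simulate_mtdna_sequences <- function(mt, length = 658L, diff_every = 20L, seed = 1L) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  swap <- c(A = "G", C = "T", G = "A", T = "C")
  pos <- seq(diff_every, length, by = diff_every)
  hap2 <- base
  hap2[pos] <- swap[base[pos]]
  species <- sort(unique(mt$mt_species))
  haps <- list(paste0(base, collapse = ""), paste0(hap2, collapse = ""))
  names(haps) <- species[c(1, min(2, length(species)))]
  tibble::tibble(id = mt$individual,
                 seq = unlist(haps[mt$mt_species], use.names = FALSE))
}

#' Write a simulation bundle to plain-text files
#'
#' Writes `genotypes.csv` (wide dialect), `localities.csv`,
#' `reference_panel.csv`, `mtdna_labels.csv`, `truth.csv` and a
#' `manifest.json` recording the scenario and seed. Deterministic: two
#' bundles from the same simulation are byte-identical.
#'
#' @param sim output of [simulate_contact_zone()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    abort(paste("directory", dir, "is not empty (use force = TRUE)"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_table(sim$genotypes, file.path(dir, "genotypes.csv"))
  write_results_table(as.data.frame(sim$localities), file.path(dir, "localities.csv"),
                      sort_by = "individual")
  write_results_table(as.data.frame(sim$reference_panel),
                      file.path(dir, "reference_panel.csv"), sort_by = "individual")
  write_results_table(as.data.frame(sim$mtdna), file.path(dir, "mtdna_labels.csv"),
                      sort_by = "individual")
  write_results_table(as.data.frame(sim$truth), file.path(dir, "truth.csv"),
                      sort_by = "locality")
  scn <- sim$scenario
  manifest <- c(unclass(scn), list(class = class(scn)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}

#' Read or write a zone scenario as YAML
#'
#' Scenario files let a simulation design live beside the data it produced.
#'
#' @param scn a [zone_scenario()].
#' @param path YAML file path.
#' @return `write_zone_scenario()` returns `path` invisibly;
#'   `read_zone_scenario()` returns a validated `zone_scenario`.
#' @export
write_zone_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "zone_scenario"))
  yaml::write_yaml(unclass(scn), path)
  invisible(path)
}

#' @rdname write_zone_scenario
#' @export
read_zone_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$enclave_centre)) raw$enclave_centre <- unlist(raw$enclave_centre)
  if (!is.null(raw$window)) raw$window <- unlist(raw$window)
  if (!is.null(raw$window_y)) raw$window_y <- unlist(raw$window_y)
  do.call(zone_scenario, raw[intersect(names(raw), names(formals(zone_scenario)))])
}

#' Read back a fixture bundle
#' @param dir directory written by [write_fixture_bundle()].
#' @return list with `genotypes`, `localities`, `reference_panel`, `mtdna`,
#'   `truth`, `scenario`.
#' @export
read_fixture_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  man$class <- NULL
  if (!is.null(man$enclave_centre) && all(is.na(man$enclave_centre))) man$enclave_centre <- NULL
  scn <- do.call(zone_scenario, man[intersect(names(man), names(formals(zone_scenario)))])
  loc <- read_results_table(file.path(dir, "localities.csv"))
  list(
    genotypes = read_genotype_table(file.path(dir, "genotypes.csv"), "wide_csv"),
    localities = locality_table(loc$individual, loc$locality, loc$x, loc$y,
                                species_hint = loc$species_hint,
                                is_reference = as.logical(loc$is_reference)),
    reference_panel = (\(p) reference_panel(p$individual, p$species))(
      read_results_table(file.path(dir, "reference_panel.csv"))),
    mtdna = read_results_table(file.path(dir, "mtdna_labels.csv")),
    truth = read_results_table(file.path(dir, "truth.csv")),
    scenario = scn
  )
}
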