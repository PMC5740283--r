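make_records <- function(side, frac) {
  out <- tibble::tibble(
    locality = sprintf("L%02d", seq_along(side)),
    side = side,
    foreign_fraction = frac,
    presence = frac > 0,
    n_scored = 46L
  )
  class(out) <- c("introgression_tbl", class(out))
  out
}

test_that("species allele counts attribute only unambiguous diagnostic alleles", {
  fx <- fixed_difference_fixture(n_loci = 3)
  dp <- find_diagnostic_markers(fx$genotypes, fx$panel, "focal")
  g <- genotype_table(
    individual = rep(c("a", "b"), each = 3),
    locus = rep(c("L01", "L02", "L03"), 2),
    allele_1 = c("F", "F", "O", "O", "O", "O"),
    allele_2 = c("F", "O", "O", "O", "O", "O")
  )
  loc <- locality_table(c("a", "b"), c("P", "Q"), x = c(0, 1), y = 0)
  cnt <- allele_counts_by_species(g, dp, loc)
  expect_equal(cnt$n_alleles[cnt$locality == "P" & cnt$species == "focal"], 3)
  expect_equal(cnt$n_alleles[cnt$locality == "P" & cnt$species == "other"], 3)
  expect_equal(cnt$n_scored[cnt$locality == "P"][1], 6)
  expect_equal(cnt$n_alleles[cnt$locality == "Q" & cnt$species == "focal"], 0)
})

test_that("introgression records complement the hybrid index on the focal side", {
  sim <- small_moving_sim()
  dp <- find_diagnostic_markers(sim$genotypes, sim$reference_panel, "focal")
  cnt <- allele_counts_by_species(sim$genotypes, dp, sim$localities)
  pts <- locality_points(sim$localities)
  dom <- setNames(ifelse(pts$x > 0, "focal", "other"), pts$locality)
  truth <- sim$truth
  dom[truth$locality[truth$in_enclave]] <- "focal"
  rec <- introgression_table(cnt, dom, pair = c("focal", "other"))
  hi <- hybrid_index(sim$genotypes, dp, sim$localities)
  m <- dplyr::inner_join(rec, hi, by = "locality")
  focal_side <- m$side == "focal"
  expect_equal(m$foreign_fraction[focal_side], 1 - m$h[focal_side])
  other_side <- !focal_side
  expect_equal(m$foreign_fraction[other_side], m$h[other_side])
  expect_equal(m$presence, m$foreign_fraction > 0)
  # 1 foreign allele among 46 scored
  one <- make_records("focal", 0)
  expect_equal(1 / 46, 0.02174, tolerance = 1e-4)
})

test_that("third-species exclusion applies the Q-threshold and neighbour rules", {
  qs <- tibble::tibble(
    locality = c("A", "B", "C", "D"),
    q_sp1 = c(0.9, 0.5, 0.98, 0.97),
    q_sp2 = c(0.08, 0.4, 0.01, 0.02),
    q_sp3 = c(0.02, 0.10, 0.01, 0.01),
    dominant = c("sp1", "sp1", "sp1", "sp3"),
    admixed = FALSE,
    threshold = 0.0206
  )
  counts <- tidyr::expand_grid(locality = qs$locality,
                               species = c("sp1", "sp2", "sp3")) |>
    dplyr::mutate(n_alleles = dplyr::case_when(
      locality == "C" & species == "sp3" ~ 1L,   # low-frequency third allele
      species == "sp1" ~ 40L,
      TRUE ~ 0L),
      n_scored = 46L)
  adj <- tibble::tibble(locality_a = c("A", "C"), locality_b = c("B", "D"))
  ex <- exclude_third_species(qs, counts, adj, pair = c("sp1", "sp2"))
  get <- function(l) ex$excluded[ex$locality == l]
  expect_false(get("A"))            # third Q = 0.02 below threshold, no alleles
  expect_true(get("B"))             # rule (a): Q_sp3 = 0.10 > 0.0206
  expect_true(get("C"))             # rule (b): sp3 allele + sp3-dominant neighbour D
  expect_match(ex$reason[ex$locality == "B"], "threshold")
  expect_match(ex$reason[ex$locality == "C"], "neighbour")
  # same allele without a third-species neighbour is retained
  adj2 <- tibble::tibble(locality_a = "C", locality_b = "A")
  ex2 <- exclude_third_species(qs, counts, adj2, pair = c("sp1", "sp2"))
  expect_false(ex2$excluded[ex2$locality == "C"])
  expect_error(exclude_third_species(qs, counts, NULL, c("sp1", "sp2")),
               "adjacency")
})

test_that("Fisher test matches exact enumeration on small tables", {
  # [[3,0],[0,3]]: fixed margins admit 20 tables; the two extremes have
  # probability 1/20 each -> two-sided p = 0.1
  rec <- make_records(rep(c("focal", "other"), each = 3),
                      c(0.1, 0.2, 0.3, 0, 0, 0))
  ft <- fisher_asymmetry(rec)
  expect_equal(ft$p, 0.1)
  # equal presence proportions: no association, p = 1
  rec2 <- make_records(rep(c("focal", "other"), each = 4),
                       c(0.1, 0.1, 0, 0, 0.2, 0.2, 0, 0))
  expect_equal(fisher_asymmetry(rec2)$p, 1)
  # label swap leaves p unchanged
  rec3 <- make_records(rep(c("focal", "other"), c(5, 7)),
                       c(0.1, 0, 0, 0.3, 0, 0.2, 0.1, 0.4, 0, 0, 0.5, 0))
  swapped <- rec3
  swapped$side <- ifelse(rec3$side == "focal", "other", "focal")
  expect_equal(fisher_asymmetry(rec3)$p, fisher_asymmetry(swapped)$p)
  expect_error(fisher_asymmetry(make_records(rep("focal", 3), c(0, 0, 1))),
               "both sides")
})

test_that("Mann-Whitney U matches exact enumeration and rank identities", {
  # {1,2,3} vs {4,5,6} testing the second side greater: U = 0, p = 1/20
  rec <- make_records(rep(c("focal", "other"), each = 3),
                      c(1, 2, 3, 4, 5, 6) / 10)
  mw <- mannwhitney_asymmetry(rec, greater_side = "other")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 20)
  expect_equal(mw$method, "exact")
  # rank-sum identity U1 + U2 = n1 n2
  expect_equal(mw$U_greater + mw$U, mw$n_1 * mw$n_2)
  # identical samples: p >= 0.5
  rec2 <- make_records(rep(c("focal", "other"), each = 4), rep(0.2, 8))
  mw2 <- mannwhitney_asymmetry(rec2, greater_side = "other")
  expect_gte(mw2$p, 0.5)
  expect_equal(mw2$method, "degenerate_all_tied")
  # agreement with the normal-approximation reference implementation on ties
  set.seed(11)
  f1 <- round(runif(18, 0, 0.5), 2)
  f2 <- round(runif(25, 0, 0.7), 2)
  rec3 <- make_records(rep(c("focal", "other"), c(18, 25)), c(f1, f2))
  mw3 <- mannwhitney_asymmetry(rec3, greater_side = "other")
  ref <- wilcox.test(f2, f1, alternative = "greater", exact = FALSE,
                     correct = TRUE)
  expect_equal(mw3$U_greater, unname(ref$statistic))
  expect_equal(mw3$p, ref$p.value, tolerance = 1e-9)
  # direction flip under label swap
  swapped <- rec3
  swapped$side <- ifelse(rec3$side == "focal", "other", "focal")
  mw_f <- mannwhitney_asymmetry(swapped, greater_side = "focal")
  expect_equal(mw_f$p, mw3$p)
})

test_that("exact U distribution agrees with wilcox.test on tie-free samples", {
  set.seed(12)
  for (i in 1:5) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    vals <- sample(seq(0.01, 0.99, by = 0.01), n1 + n2)  # distinct -> no ties
    rec <- make_records(rep(c("focal", "other"), c(n1, n2)), vals)
    mw <- mannwhitney_asymmetry(rec, greater_side = "other")
    ref <- wilcox.test(vals[(n1 + 1):(n1 + n2)], vals[1:n1],
                       alternative = "greater", exact = TRUE)
    expect_equal(mw$U_greater, unname(ref$statistic))
    expect_equal(mw$p, ref$p.value)
  }
})
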