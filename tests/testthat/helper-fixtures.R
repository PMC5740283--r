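# shared fixtures, built in code at test time

# tiny hand-built genotype table: 3 individuals x 4 loci, alleles A/B
tiny_genotypes <- function() {
  genotype_table(
    individual = rep(c("i1", "i2", "i3"), each = 4),
    locus = rep(c("L1", "L2", "L3", "L4"), 3),
    allele_1 = c("A", "A", "B", "A",   "A", "A", "B", "A",   "B", "B", "B", NA),
    allele_2 = c("A", "B", "B", "A",   "A", "A", "B", "A",   "B", "B", "B", NA)
  )
}

# two-species reference set with fully fixed differences at n_loci markers
fixed_difference_fixture <- function(n_loci = 6, n_ref = 3) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  ids_f <- sprintf("f%d", seq_len(n_ref))
  ids_o <- sprintf("o%d", seq_len(n_ref))
  g <- genotype_table(
    individual = rep(c(ids_f, ids_o), each = n_loci),
    locus = rep(loci, 2 * n_ref),
    allele_1 = rep(c("F", "O"), each = n_loci * n_ref),
    allele_2 = rep(c("F", "O"), each = n_loci * n_ref)
  )
  panel <- reference_panel(c(ids_f, ids_o),
                           rep(c("focal", "other"), each = n_ref))
  list(genotypes = g, panel = panel, loci = loci)
}

# deterministic small contact-zone simulation (cached per session)
small_moving_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scn <- zone_scenario("moving", n_localities = 40L, seed = 11)
      cache <<- simulate_contact_zone(scn)
    }
    cache
  }
})

# reduced-size pipeline configuration used by seed-sweep tests
fast_config <- function(seed) {
  analysis_config(seed = seed, sweeps = 2000L, burnin = 500L,
                  grid_resolution = 120L, optimizer_restarts = 8L)
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}

mean_pairwise_frob <- function(mats) {
  pairs <- utils::combn(length(mats), 2)
  mean(apply(pairs, 2, function(ij)
    sqrt(sum((mats[[ij[1]]] - mats[[ij[2]]])^2))))
}

# brute-force nearest-site adjacency oracle: classify a dense grid by
# nearest locality; two localities are adjacent when 4-neighbouring grid
# cells belong to them
brute_force_adjacency <- function(pts, margin = 0.10, n_grid = 400) {
  rx <- range(pts$x); ry <- range(pts$y)
  mx <- margin * diff(rx); my <- margin * diff(ry)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = n_grid)
  gy <- seq(ry[1] - my, ry[2] + my, length.out = n_grid)
  grid <- expand.grid(x = gx, y = gy)
  d2 <- outer(grid$x, pts$x, `-`)^2 + outer(grid$y, pts$y, `-`)^2
  lab <- matrix(max.col(-d2), n_grid, n_grid)
  pairs <- unique(rbind(
    cbind(as.vector(lab[-1, ]), as.vector(lab[-n_grid, ])),
    cbind(as.vector(lab[, -1]), as.vector(lab[, -n_grid]))
  ))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  unique(tibble::tibble(
    locality_a = pts$locality[pmin(pairs[, 1], pairs[, 2])],
    locality_b = pts$locality[pmax(pairs[, 1], pairs[, 2])]
  )) |> dplyr::arrange(locality_a, locality_b)
}
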