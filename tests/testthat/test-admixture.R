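test_that("evidence estimator follows mean minus half variance", {
  expect_equal(estimate_evidence(c(-5, -5, -5)), -5)          # zero variance
  expect_equal(estimate_evidence(c(-10, -12)), -12)           # mean -11, var 2
  # white noise lowers the estimate through the variance penalty
  set.seed(1)
  base <- rep(-100, 200)
  expect_lt(estimate_evidence(base + rnorm(200)), estimate_evidence(base + 1e-9 * rnorm(200)))
  expect_error(estimate_evidence(-3), "at least 2")
})

test_that("Evanno delta-k reproduces hand-computed second differences", {
  # means {-100, -50, -48, -47} with replicate sd exactly 1
  mk <- function(k, m) tibble::tibble(k = k, replicate = 1:2,
                                      evidence = m + c(-1, 1) / sqrt(2))
  ev <- dplyr::bind_rows(mk(1, -100), mk(2, -50), mk(3, -48), mk(4, -47))
  tab <- evanno_delta_k(ev)
  expect_equal(tab$delta_k[tab$k == 2], 48)
  expect_equal(tab$delta_k[tab$k == 3], 1)
  expect_true(is.na(tab$delta_k[tab$k == 1]) && is.na(tab$delta_k[tab$k == 4]))
  expect_equal(attr(tab, "best_k"), 2)

  # linear evidence in k: all interior delta-k are zero
  lin <- dplyr::bind_rows(lapply(1:5, function(k) mk(k, -100 + 3 * k)))
  expect_true(all(evanno_delta_k(lin)$delta_k[2:4] == 0))

  # zero replicate variance at an interior k is an error
  degenerate <- dplyr::bind_rows(mk(1, -100),
                                 tibble::tibble(k = 2, replicate = 1:2, evidence = -50),
                                 mk(3, -48))
  expect_error(evanno_delta_k(degenerate), "zero replicate variance")
})

test_that("k = 1 gives a unit ancestry column and trivial simplex", {
  g <- tiny_genotypes()
  fit <- run_admixture_sampler(g, k = 1, sweeps = 200, burnin = 50, seed = 1)
  expect_true(all(fit$Q == 1))
  expect_equal(ncol(fit$Q), 1L)
})

test_that("Q rows sum to one and pure individuals concentrate at Fst 0.3", {
  scn <- structured_pop_scenario(k_true = 2, fst = 0.3, n_loci = 50,
                                 n_per_pop = 30, seed = 3)
  sim <- simulate_structured_populations(scn)
  fit <- run_admixture_sampler(sim$genotypes, k = 2, sweeps = 6000,
                               burnin = 1500, seed = 7)
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-9))
  expect_gte(mean(apply(fit$Q, 1, max) > 0.95), 0.95)
})

test_that("a synthetic F1 between the two populations gets Q near (0.5, 0.5)", {
  scn <- structured_pop_scenario(k_true = 2, fst = 0.5, n_loci = 60,
                                 n_per_pop = 20, seed = 5)
  sim <- simulate_structured_populations(scn)
  # one allele drawn from each population's frequency at every locus
  set.seed(8)
  f <- sim$freqs |> tidyr::pivot_wider(names_from = population, values_from = freq)
  hyb <- genotype_table(
    individual = "hybrid",
    locus = f$locus,
    allele_1 = ifelse(runif(nrow(f)) < f$pop1, "A", "B"),
    allele_2 = ifelse(runif(nrow(f)) < f$pop2, "A", "B")
  )
  g <- dplyr::bind_rows(sim$genotypes, hyb)
  class(g) <- class(sim$genotypes)
  fit <- run_admixture_sampler(g, k = 2, sweeps = 6000, burnin = 1500, seed = 9)
  expect_equal(unname(fit$Q["hybrid", 1]), 0.5, tolerance = 0.1)
})

test_that("supervised mode pins reference individuals and labels clusters", {
  fx <- fixed_difference_fixture(n_loci = 10)
  fit <- run_admixture_sampler(fx$genotypes, k = 2, sweeps = 1000,
                               burnin = 200, seed = 2, supervised = fx$panel)
  expect_equal(colnames(fit$Q), c("focal", "other"))
  expect_gt(min(fit$Q[paste0("f", 1:3), "focal"]), 0.9)
  expect_gt(min(fit$Q[paste0("o", 1:3), "other"]), 0.9)
})

test_that("sampler input validation catches degenerate requests", {
  g <- tiny_genotypes()
  expect_error(run_admixture_sampler(g, k = 10, sweeps = 100, burnin = 10),
               "exceeds")
  expect_error(run_admixture_sampler(g, k = 2, sweeps = 10, burnin = 10),
               "sweeps > burnin")
  # all-missing locus dropped with a warning
  gm <- dplyr::bind_rows(g, genotype_table(c("i1", "i2", "i3"), "L9",
                                           NA_character_, NA_character_))
  class(gm) <- class(g)
  expect_warning(run_admixture_sampler(gm, k = 1, sweeps = 100, burnin = 10),
                 "all-missing")
})

test_that("replicate alignment undoes label switching exactly", {
  scn <- structured_pop_scenario(k_true = 3, fst = 0.4, n_loci = 30,
                                 n_per_pop = 10, seed = 6)
  sim <- simulate_structured_populations(scn)
  fit <- run_admixture_sampler(sim$genotypes, k = 3, sweeps = 1500,
                               burnin = 300, seed = 4)
  swapped <- fit
  perm <- c(3, 1, 2)
  swapped$Q <- fit$Q[, perm]
  out <- align_replicates(list(fit, swapped))
  expect_equal(out$aligned[[2]]$Q, fit$Q, ignore_attr = TRUE)
  # identical replicates are unchanged
  out2 <- align_replicates(list(fit, fit))
  expect_equal(out2$aligned[[2]]$Q, fit$Q)

  # property: alignment never increases mean pairwise Frobenius distance
  set.seed(10)
  for (i in 1:5) {
    reps <- lapply(1:3, function(j) {
      f <- fit; f$Q <- fit$Q[, sample(3)]; f
    })
    pre <- mean_pairwise_frob(lapply(reps, function(f) f$Q))
    post <- mean_pairwise_frob(lapply(align_replicates(reps)$aligned,
                                      function(f) f$Q))
    expect_lte(post, pre + 1e-12)
  }
})

test_that("locality summaries apply the reference-minimum threshold rule", {
  # reference minimum Q = 0.9794 gives threshold 0.0206
  Q <- rbind(
    ref_a = c(0.9794, 0.0206), ref_b = c(0.01, 0.99),
    i1 = c(1, 0), i2 = c(0.6, 0.4), i3 = c(0.99, 0.01)
  )
  colnames(Q) <- c("c1", "c2")
  loc <- locality_table(rownames(Q), c("LA", "LB", "L1", "L2", "L3"),
                        x = 1:5, y = 0)
  panel <- reference_panel(c("ref_a", "ref_b"), c("spA", "spB"))
  s <- summarize_localities(Q, loc, panel)
  expect_equal(s$threshold[1], 1 - 0.9794)
  expect_equal(s$dominant[s$locality == "L1"], "spA")
  expect_false(s$admixed[s$locality == "L1"])   # mean Q (1, 0)
  expect_true(s$admixed[s$locality == "L2"])    # both species over threshold
  expect_false(s$admixed[s$locality == "L3"])   # 0.01 below 0.0206
  expect_error(summarize_localities(Q, loc, panel[0, ]), "empty reference")
})
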