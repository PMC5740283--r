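# hzfootprint

Tools for testing whether an **enclave** — a patch of one species' range
completely surrounded by a parapatric congener — arose by incomplete
species replacement. When a hybrid zone moves, theory predicts that the
receding species leaves a trail of selectively neutral alleles inside the
territory claimed by the invader. `hzfootprint` implements the inference
chain that turns co-dominant nuclear markers and locality coordinates into
a test of that prediction, for population geneticists and biogeographers
working on hybridizing species pairs.

## What it computes

Given diploid genotypes, locality coordinates, and per-species reference
panels, the pipeline runs:

1. **Admixture clustering** — a Gibbs sampler for the admixture model
   (independent allele frequencies, Dirichlet(α) ancestry prior with α
   sampled), model evidence `mean(lnL) − var(lnL)/2`, and Evanno's
   Δk = |L̄(k+1) − 2L̄(k) + L̄(k−1)| / sd(L(k)) for choosing the number of
   genepools; per-locality mean ancestries with the admixture threshold
   `1 − min(own-species reference Q)`.
2. **Diagnostic markers** — loci with fixed allelic differences between the
   focal species and every other species; locality hybrid index
   h = focal alleles / scored alleles; heterozygosity–ancestry triangle
   statistics (S, H) with the exact constraint H ≤ 2·min(S, 1−S).
3. **Spatial stages** — Thiessen (Voronoi) polygons and their adjacency,
   core/edge classification, piecewise-linear interpolation of h, the 0.5
   contour, and signed minimum distances to it (positive on the focal
   species' side).
4. **Geographic clines** — five variants (no tail / left / right / mirror /
   both) of the sigmoid cline p(x) = 1/(1+e^(−4(x−c)/w)) with exponential
   tails (δ, τ), binomial likelihood with n = genotypes per locality,
   multistart maximum likelihood, AICc model selection, and
   two-log-likelihood-unit support limits.
5. **Asymmetry tests** — third-species exclusions, per-locality foreign
   allele fractions, Fisher's exact test on presence/absence and a
   one-tailed Mann–Whitney U test (exact for small tie-free samples) on
   fractions, and a verdict: *footprint detected* iff Fisher p < 0.01 and
   the selected cline model has a tail on the invaded side.

A synthetic-data module (`zone_scenario()`, `simulate_contact_zone()`,
`simulate_structured_populations()`) generates stable and moving
contact-zone datasets — sigmoid front, exponential wake, focal-pure
enclave, lagging mtDNA cline — from a closed-form field that is also
returned, so every stage can be checked against ground truth.

## Worked example

```r
library(hzfootprint)

scn <- zone_scenario("moving", seed = 1)   # front moved 120 km, wake A = 0.4
sim <- simulate_contact_zone(scn)
res <- run_full_pipeline(sim, config = analysis_config(seed = 501,
                                                       sweeps = 2000, burnin = 500,
                                                       grid_resolution = 120,
                                                       optimizer_restarts = 8))
res
```

```
Hybrid-zone movement pipeline result
  pair: focal vs other
  Fisher p = 5.372e-05, Mann-Whitney one-tailed p = 1.189e-05
  best cline model: 'left' (tail on invaded side: TRUE)
  verdict: footprint DETECTED
```

The Fisher p says foreign-allele *presence* differs between the two sides
of the 0.5 contour far beyond chance; the Mann–Whitney p says the foreign
allele *fractions* on the invader's side are stochastically greater; and
the selected cline variant ('left') places an exponential introgression
tail on the invaded side of the transect — together, the genomic footprint
of a moving hybrid zone. The same call on a `"stable"` scenario returns
`footprint not detected` with a Fisher p near 1:

```r
res0 <- run_full_pipeline(simulate_contact_zone(zone_scenario("stable", seed = 1)),
                          config = analysis_config(seed = 501, sweeps = 2000,
                                                   burnin = 500,
                                                   grid_resolution = 120,
                                                   optimizer_restarts = 8))
res0$verdict[c("fisher_p", "best_cline", "footprint_detected")]
```

```
# A tibble: 1 × 3
  fisher_p best_cline footprint_detected
     <dbl> <chr>      <lgl>
1    0.779 none       FALSE
```

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; see `vignettes/hybrid-zone-footprint.Rmd` for the
models, their assumptions, and the design decisions.

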