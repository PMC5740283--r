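#' Structure-style admixture estimation by Gibbs sampling
#'
#' Estimates, for each individual, the fraction of ancestry Q derived from
#' each of `k` genepools under the admixture model with independent allele
#' frequencies: allele copies carry latent population origins, population
#' allele frequencies get a symmetric Dirichlet(1) prior, and individual
#' ancestries a symmetric Dirichlet(`alpha`) prior with `alpha` fixed.
#' Returns the posterior-mean Q and a thinned post-burnin trace of the data
#' log-likelihood, the input to [estimate_evidence()] and hence to the
#' Evanno k-selection.
#'
#' In supervised mode the allele origins of reference individuals are pinned
#' to their species, which both anchors cluster labels and sharpens the
#' frequency estimates.
#'
#' @param g a `genotype_tbl`.
#' @param k number of genepools (>= 1).
#' @param sweeps,burnin Gibbs sweep counts (`sweeps` > `burnin`). Defaults are
#'   desk-scale; raise for production runs.
#' @param seed RNG seed for this replicate.
#' @param supervised optional `reference_panel`; pins those individuals.
#' @param alpha Dirichlet concentration for the ancestry prior:
#'   `"sample"` (default) updates alpha by a Metropolis step each sweep, as
#'   the standard admixture samplers do (it shrinks well below 1 for
#'   strongly diverged genepools, concentrating Q for pure individuals); a
#'   numeric value keeps it fixed.
#' @param thin record the log-likelihood every `thin` sweeps.
#' @return object of class `admixture_fit`: list with `Q` (n x k matrix,
#'   rows summing to 1, rownames = individuals), `loglik` (post-burnin
#'   thinned trace), `k`, `seed`, and `cluster_labels` (species labels in
#'   supervised mode, else `NULL`).
#' @export
run_admixture_sampler <- function(g, k, sweeps = 20000L, burnin = 5000L,
                                  seed = 1L, supervised = NULL,
                                  alpha = "sample", thin = 10L) {
  validate_genotype_table(g)
  if (k < 1) abort("k must be >= 1")
  if (sweeps <= burnin || burnin < 0) abort("need sweeps > burnin >= 0")
  enc <- encode_genotypes(g)
  if (k > length(enc$individuals)) abort("k exceeds the number of individuals")
  fixed <- rep(-1L, length(enc$individuals))
  labels <- NULL
  if (!is.null(supervised)) {
    species <- sort(unique(supervised$species))
    if (length(species) > k) abort("more reference species than clusters k")
    labels <- c(species, if (k > length(species))
      sprintf("cluster%d", seq_len(k - length(species)) + length(species)))
    idx <- match(supervised$individual, enc$individuals)
    if (anyNA(idx)) abort("reference individuals absent from genotype table")
    fixed[idx] <- match(supervised$species, species) - 1L
  }
  sample_alpha <- identical(alpha, "sample")
  alpha0 <- if (sample_alpha) 1.0 else as.numeric(alpha)
  if (!sample_alpha && (!is.finite(alpha0) || alpha0 <= 0)) abort("alpha must be > 0")
  set.seed(seed)
  res <- admixture_gibbs_cpp(enc$a1, enc$a2, enc$n_alleles, as.integer(k),
                             as.integer(sweeps), as.integer(burnin),
                             as.integer(thin), alpha0, sample_alpha, fixed)
  Q <- res$Q
  rownames(Q) <- enc$individuals
  colnames(Q) <- labels %||% sprintf("cluster%d", seq_len(k))
  structure(list(Q = Q, loglik = as.numeric(res$loglik), k = as.integer(k),
                 seed = as.integer(seed), cluster_labels = labels,
                 alpha = res$alpha, sampled_alpha = sample_alpha,
                 dropped_loci = enc$dropped),
            class = "admixture_fit")
}

# integer-code a genotype table for the sampler; drops all-missing loci
encode_genotypes <- function(g) {
  individuals <- sort(unique(g$individual))
  loci <- sort(unique(g$locus))
  i <- match(g$individual, individuals)
  l <- match(g$locus, loci)
  n <- length(individuals); L <- length(loci)
  a1 <- matrix(-1L, n, L); a2 <- matrix(-1L, n, L)
  n_alleles <- integer(L)
  for (ll in seq_len(L)) {
    rows <- which(l == ll)
    sym <- sort(unique(stats::na.omit(c(g$allele_1[rows], g$allele_2[rows]))))
    n_alleles[ll] <- max(length(sym), 1L)
    c1 <- match(g$allele_1[rows], sym) - 1L
    c2 <- match(g$allele_2[rows], sym) - 1L
    a1[cbind(i[rows], ll)] <- ifelse(is.na(c1), -1L, c1)
    a2[cbind(i[rows], ll)] <- ifelse(is.na(c2), -1L, c2)
  }
  dropped <- loci[n_alleles == 1L & colSums(a1 >= 0) == 0]
  if (length(dropped)) {
    warn(paste("dropping all-missing loci:", paste(dropped, collapse = ", ")))
    keep <- !(loci %in% dropped)
    a1 <- a1[, keep, drop = FALSE]; a2 <- a2[, keep, drop = FALSE]
    n_alleles <- n_alleles[keep]; loci <- loci[keep]
  }
  list(a1 = a1, a2 = a2, n_alleles = n_alleles,
       individuals = individuals, loci = loci, dropped = dropped)
}

#' Model evidence from a log-likelihood trace
#'
#' The Structure-style estimator of ln P(data | k): the mean of the
#' post-burnin log-likelihood trace minus half its variance.
#'
#' @param trace numeric post-burnin log-likelihood values.
#' @return scalar evidence estimate.
#' @export
estimate_evidence <- function(trace) {
  if (length(trace) < 2) abort("trace must contain at least 2 values")
  mean(trace) - var(trace) / 2
}

#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  tibble::as_tibble(x$Q, rownames = "individual") |>
    tidyr::pivot_longer(-"individual", names_to = "cluster", values_to = "q")
}

#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$Q), seed = x$seed,
                 evidence = estimate_evidence(x$loglik),
                 mean_loglik = mean(x$loglik), sd_loglik = sd(x$loglik))
}

#' Evanno delta-k from per-k replicate evidences
#'
#' Delta-k at an interior k is `|mean L(k+1) - 2 mean L(k) + mean L(k-1)|`
#' divided by the standard deviation of L(k) over replicates; the k with the
#' largest delta-k is the selected number of genepools.
#'
#' @param evidence tibble with columns `k`, `replicate`, `evidence` (e.g.
#'   bound `glance()` rows over replicates and k values).
#' @return tibble of class `k_selection` with columns `k`, `mean_evidence`,
#'   `sd_evidence`, `delta_k` (NA at the end points); attribute `best_k`.
#' @export
evanno_delta_k <- function(evidence) {
  stopifnot(all(c("k", "replicate", "evidence") %in% names(evidence)))
  tab <- evidence |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_evidence = mean(.data$evidence),
                     sd_evidence = sd(.data$evidence),
                     n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$k)
  if (nrow(tab) < 3) abort("need evidences for at least 3 consecutive k values")
  if (any(diff(tab$k) != 1)) abort("k values must be consecutive")
  if (any(tab$n_replicates < 2)) abort("need >= 2 replicates per k")
  interior <- 2:(nrow(tab) - 1)
  if (any(tab$sd_evidence[interior] == 0)) {
    abort(paste("zero replicate variance at k =",
                paste(tab$k[interior][tab$sd_evidence[interior] == 0], collapse = ", "),
                "- delta-k is undefined; add replicates or jitter seeds"))
  }
  m <- tab$mean_evidence
  dk <- rep(NA_real_, nrow(tab))
  dk[interior] <- abs(m[interior + 1] - 2 * m[interior] + m[interior - 1]) /
    tab$sd_evidence[interior]
  tab$delta_k <- dk
  attr(tab, "best_k") <- tab$k[which.max(dk)]
  class(tab) <- c("k_selection", class(tab))
  tab
}

#' Undo label switching across sampler replicates
#'
#' Permutes each replicate's cluster columns to maximize the summed
#' column-wise dot product with the first replicate (exact assignment over
#' the k! permutations), then averages the aligned Q matrices.
#'
#' @param replicates list of `admixture_fit` objects over the same
#'   individuals and k.
#' @return list with `aligned` (the permuted fits) and `mean_q` (matrix).
#' @export
align_replicates <- function(replicates) {
  ks <- vapply(replicates, function(f) f$k, 1L)
  if (length(unique(ks)) != 1) abort("replicates have mismatched k")
  ref <- replicates[[1]]$Q
  ids <- rownames(ref)
  k <- ks[1]
  perms <- permutations_of(k)
  aligned <- lapply(replicates, function(f) {
    Q <- f$Q[ids, , drop = FALSE]
    score <- vapply(perms, function(pr) sum(ref * Q[, pr, drop = FALSE]), 0)
    best <- perms[[which.max(score)]]
    f$Q <- Q[, best, drop = FALSE]
    colnames(f$Q) <- colnames(ref)
    f
  })
  mean_q <- Reduce(`+`, lapply(aligned, function(f) f$Q)) / length(aligned)
  list(aligned = aligned, mean_q = mean_q)
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  if (k > 8) abort("alignment over permutations supported for k <= 8")
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (s in sub) {
    for (pos in seq_len(k)) {
      out[[idx]] <- as.integer(append(s, k, after = pos - 1L))
      idx <- idx + 1L
    }
  }
  out
}

#' Per-locality ancestry summaries with the admixture threshold rule
#'
#' Clusters are mapped to species via the reference panel (each species'
#' cluster is the argmax of its reference individuals' mean Q). The
#' admixture threshold is `1 - min` over reference individuals of their
#' own-species Q; a locality is genetically admixed when two or more species
#' exceed that threshold, and its dominant species is the argmax of mean Q.
#'
#' @param Q an `admixture_fit`, or a Q matrix with individual rownames.
#' @param localities a `locality_tbl`.
#' @param panel a `reference_panel`.
#' @param threshold override the reference-derived threshold with a fixed value.
#' @return tibble with columns `locality`, `q_<species>` ..., `dominant`,
#'   `admixed`, `threshold`.
#' @export
summarize_localities <- function(Q, localities, panel, threshold = NULL) {
  if (inherits(Q, "admixture_fit")) Q <- Q$Q
  if (nrow(panel) == 0) abort("empty reference panel: admixture threshold undefined")
  idx <- match(panel$individual, rownames(Q))
  if (anyNA(idx)) abort("reference individuals missing from Q")
  species <- sort(unique(panel$species))
  # map clusters to species by reference means
  ref_mean <- vapply(species, function(sp)
    colMeans(Q[idx[panel$species == sp], , drop = FALSE]), numeric(ncol(Q)))
  cluster_of <- apply(ref_mean, 2, which.max)
  if (anyDuplicated(cluster_of)) abort("two species map to the same cluster; clustering unresolved")
  own_q <- Q[cbind(idx, cluster_of[match(panel$species, species)])]
  t_used <- threshold %||% (1 - min(own_q))
  sq <- Q[, cluster_of, drop = FALSE]
  colnames(sq) <- species
  per_ind <- tibble::as_tibble(sq, rownames = "individual")
  out <- localities |>
    dplyr::inner_join(per_ind, by = "individual") |>
    dplyr::group_by(.data$locality) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(species), mean), .groups = "drop")
  qm <- as.matrix(out[species])
  out$dominant <- species[max.col(qm, ties.method = "first")]
  out$admixed <- rowSums(qm > t_used) >= 2
  out$threshold <- t_used
  names(out)[match(species, names(out))] <- paste0("q_", species)
  out
}
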