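#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the admixture model with independent allele frequencies.
//
// Data: two allele-code matrices (n x L), codes 0..(n_alleles[l]-1), -1 = missing.
// State: origin z of every allele copy; per-population allele frequencies p
// (symmetric Dirichlet(1) prior); per-individual ancestry q (symmetric
// Dirichlet(alpha) prior, alpha fixed). fixed_pop[i] >= 0 pins individual i's
// allele origins to that population (supervised mode).
//
// Returns the posterior-mean Q over post-burnin sweeps and the data
// log-likelihood trace, thinned, over post-burnin sweeps. Uses R's RNG.

static inline int sample_cat(const double *w, int k, double tot) {
  double u = unif_rand() * tot, acc = 0.0;
  for (int j = 0; j < k; ++j) {
    acc += w[j];
    if (u <= acc) return j;
  }
  return k - 1;
}

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix a1, IntegerMatrix a2,
                         IntegerVector n_alleles, int k, int sweeps,
                         int burnin, int thin, double alpha,
                         bool sample_alpha, IntegerVector fixed_pop) {
  const int n = a1.nrow(), L = a1.ncol();
  if (k < 1) stop("k must be >= 1");
  if (sweeps <= burnin) stop("sweeps must exceed burnin");

  // flattened frequency arrays: p[l][j*A_l + a]
  std::vector< std::vector<double> > p(L);
  std::vector<int> A(L);
  for (int l = 0; l < L; ++l) {
    A[l] = n_alleles[l];
    p[l].assign((size_t)k * A[l], 1.0 / A[l]);
  }
  // allele-origin assignments
  IntegerMatrix z1(n, L), z2(n, L);
  NumericMatrix q(n, k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) q(i, j) = 1.0 / k;
    for (int l = 0; l < L; ++l) {
      int init = (fixed_pop[i] >= 0) ? fixed_pop[i]
                                     : (int)std::floor(unif_rand() * k);
      if (init >= k) init = k - 1;
      z1(i, l) = init;
      z2(i, l) = init;
    }
  }

  NumericMatrix q_sum(n, k);
  std::vector<double> ll_trace;
  ll_trace.reserve((sweeps - burnin) / thin + 1);
  std::vector<double> w((size_t)k);
  std::vector<double> cnt_p;
  std::vector<double> cnt_q((size_t)k);

  for (int s = 0; s < sweeps; ++s) {
    // 1. resample allele origins z | p, q
    for (int i = 0; i < n; ++i) {
      if (fixed_pop[i] >= 0) continue;  // pinned
      for (int l = 0; l < L; ++l) {
        const double *pl = p[l].data();
        const int Al = A[l];
        int a = a1(i, l);
        if (a >= 0) {
          double tot = 0.0;
          for (int j = 0; j < k; ++j) { w[j] = q(i, j) * pl[j * Al + a]; tot += w[j]; }
          z1(i, l) = (tot > 0) ? sample_cat(w.data(), k, tot)
                               : (int)std::floor(unif_rand() * k);
        }
        a = a2(i, l);
        if (a >= 0) {
          double tot = 0.0;
          for (int j = 0; j < k; ++j) { w[j] = q(i, j) * pl[j * Al + a]; tot += w[j]; }
          z2(i, l) = (tot > 0) ? sample_cat(w.data(), k, tot)
                               : (int)std::floor(unif_rand() * k);
        }
      }
    }
    // 2. resample p | z  (Dirichlet(1 + counts))
    for (int l = 0; l < L; ++l) {
      const int Al = A[l];
      cnt_p.assign((size_t)k * Al, 1.0);  // Dirichlet(1) prior
      for (int i = 0; i < n; ++i) {
        int a = a1(i, l);
        if (a >= 0) cnt_p[z1(i, l) * Al + a] += 1.0;
        a = a2(i, l);
        if (a >= 0) cnt_p[z2(i, l) * Al + a] += 1.0;
      }
      for (int j = 0; j < k; ++j) {
        double tot = 0.0;
        for (int a = 0; a < Al; ++a) {
          double g = R::rgamma(cnt_p[j * Al + a], 1.0);
          p[l][j * Al + a] = g;
          tot += g;
        }
        for (int a = 0; a < Al; ++a) p[l][j * Al + a] /= tot;
      }
    }
    // 3. resample q | z  (Dirichlet(alpha + counts))
    for (int i = 0; i < n; ++i) {
      std::fill(cnt_q.begin(), cnt_q.end(), alpha);
      for (int l = 0; l < L; ++l) {
        if (a1(i, l) >= 0) cnt_q[z1(i, l)] += 1.0;
        if (a2(i, l) >= 0) cnt_q[z2(i, l)] += 1.0;
      }
      double tot = 0.0;
      for (int j = 0; j < k; ++j) {
        double g = R::rgamma(cnt_q[j], 1.0);
        q(i, j) = g;
        tot += g;
      }
      for (int j = 0; j < k; ++j) q(i, j) /= tot;
    }
    // 3b. Metropolis update of the ancestry concentration alpha
    // (uniform prior on (0, alpha_max]; Structure-style random-walk proposal)
    if (sample_alpha && k > 1) {
      const double alpha_max = 10.0, prop_sd = 0.05;
      double cand = alpha + norm_rand() * prop_sd;
      if (cand >= 0.001 && cand <= alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < k; ++j) slq += std::log(q(i, j));
        double lr = n * (R::lgammafn(k * cand) - k * R::lgammafn(cand)
                         - R::lgammafn(k * alpha) + k * R::lgammafn(alpha))
                    + (cand - alpha) * slq;
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) alpha = cand;
      }
    }
    // 4. accumulate
    if (s >= burnin) {
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < k; ++j) q_sum(i, j) += q(i, j);
      if ((s - burnin) % thin == 0) {
        double ll = 0.0;
        for (int i = 0; i < n; ++i) {
          for (int l = 0; l < L; ++l) {
            const double *pl = p[l].data();
            const int Al = A[l];
            int a = a1(i, l);
            if (a >= 0) {
              double m = 0.0;
              for (int j = 0; j < k; ++j) m += q(i, j) * pl[j * Al + a];
              ll += std::log(m);
            }
            a = a2(i, l);
            if (a >= 0) {
              double m = 0.0;
              for (int j = 0; j < k; ++j) m += q(i, j) * pl[j * Al + a];
              ll += std::log(m);
            }
          }
        }
        ll_trace.push_back(ll);
      }
    }
  }
  const double denom = sweeps - burnin;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) q_sum(i, j) /= denom;
  return List::create(_["Q"] = q_sum,
                      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["alpha"] = alpha);
}
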