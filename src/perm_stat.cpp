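// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Vertex-wise two-sample Mahalanobis/Hotelling statistic and the two-level
// permutation scheme (uncorrected vertex p-map + map-level p_feature
// correction).  X is an N x d x W cube of per-subject feature vectors on
// the template grid.  The inner kernel is hand-coded for small d (<= 8):
// pooled covariance accumulation, Cholesky solve, and diagonal shrinkage
// for ill-conditioned covariances.

namespace {

constexpr int DMAX = 8;

// Cholesky factorization of symmetric S (upper storage, d x d) in place.
// Returns false if not positive definite.  L is lower triangular.
bool chol_small(int d, const double* S, double* L) {
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double sum = S[i * DMAX + j];
      for (int k = 0; k < j; ++k) sum -= L[i * DMAX + k] * L[j * DMAX + k];
      if (i == j) {
        if (sum <= 0) return false;
        L[i * DMAX + i] = std::sqrt(sum);
      } else {
        L[i * DMAX + j] = sum / L[j * DMAX + j];
      }
    }
  }
  return true;
}

// solve S x = b given Cholesky L
void chol_solve(int d, const double* L, const double* b, double* x) {
  double y[DMAX];
  for (int i = 0; i < d; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * DMAX + k] * y[k];
    y[i] = s / L[i * DMAX + i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double s = y[i];
    for (int k = i + 1; k < d; ++k) s -= L[k * DMAX + i] * x[k];
    x[i] = s / L[i * DMAX + i];
  }
}

// Mahalanobis statistic at one vertex.  Xw: N x d column-major (leading
// dim N).  maskA[i] != 0 marks group A.  cond_max bounds a Cholesky-based
// conditioning surrogate (ratio of extreme squared pivots); covariances
// beyond it are shrunk toward their diagonal.
double maha_one(const double* Xw, int N, int d, const int* maskA,
                int nA, int nB, double cond_max, int w_report) {
  double mA[DMAX] = {0}, mB[DMAX] = {0};
  for (int i = 0; i < N; ++i) {
    const bool a = maskA[i] != 0;
    for (int c = 0; c < d; ++c)
      (a ? mA : mB)[c] += Xw[c * N + i];
  }
  for (int c = 0; c < d; ++c) { mA[c] /= nA; mB[c] /= nB; }
  double S[DMAX * DMAX] = {0};
  for (int i = 0; i < N; ++i) {
    const double* m = (maskA[i] != 0) ? mA : mB;
    double cvec[DMAX];
    for (int c = 0; c < d; ++c) cvec[c] = Xw[c * N + i] - m[c];
    for (int c = 0; c < d; ++c)
      for (int e = 0; e <= c; ++e)
        S[c * DMAX + e] += cvec[c] * cvec[e];
  }
  const double scale = 1.0 / (N - 2);
  for (int c = 0; c < d; ++c)
    for (int e = 0; e <= c; ++e) {
      S[c * DMAX + e] *= scale;
      S[e * DMAX + c] = S[c * DMAX + e];
    }
  double diff[DMAX];
  for (int c = 0; c < d; ++c) diff[c] = mA[c] - mB[c];

  double L[DMAX * DMAX];
  bool ok = false;
  for (int attempt = 0; attempt < 14 && !ok; ++attempt) {
    ok = chol_small(d, S, L);
    if (ok) {
      double pmin = L[0], pmax = L[0];
      for (int c = 1; c < d; ++c) {
        const double p = L[c * DMAX + c];
        pmin = std::min(pmin, p); pmax = std::max(pmax, p);
      }
      if ((pmax * pmax) / (pmin * pmin) > cond_max) ok = false;
    }
    if (!ok) {
      // shrink toward the diagonal; add a floor ridge on late attempts
      double tr = 0;
      for (int c = 0; c < d; ++c) tr += S[c * DMAX + c];
      const double ridge = (attempt >= 10) ? 1e-10 * (1.0 + tr) : 0.0;
      for (int c = 0; c < d; ++c)
        for (int e = 0; e < d; ++e)
          if (c != e) S[c * DMAX + e] *= 0.9;
      for (int c = 0; c < d; ++c) S[c * DMAX + c] += ridge;
    }
  }
  if (!ok)
    stop("singular pooled covariance after shrinkage at vertex %d", w_report);
  double sol[DMAX];
  chol_solve(d, L, diff, sol);
  double q = 0;
  for (int c = 0; c < d; ++c) q += diff[c] * sol[c];
  return (double)nA * nB / (nA + nB) * q;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_mahalanobis_map(NumericVector X, IntegerVector dims,
                                  IntegerVector maskA, double cond_max) {
  const int N = dims[0], d = dims[1];
  const R_xlen_t W = dims[2];
  if (d > DMAX) stop("feature dimension too large");
  int nA = 0;
  for (int i = 0; i < N; ++i) nA += (maskA[i] != 0);
  const int nB = N - nA;
  if (nA < 2 || nB < 2) stop("each group needs >= 2 subjects");
  NumericVector M(W);
  const double* x = X.begin();
  for (R_xlen_t w = 0; w < W; ++w)
    M[w] = maha_one(x + w * (R_xlen_t)N * d, N, d, maskA.begin(), nA, nB,
                    cond_max, (int)w + 1);
  return M;
}

// perm_masks: n_perm x N (row-major by R column-major convention: an
// IntegerMatrix), 1 where the subject falls in pseudo-group A.
// [[Rcpp::export]]
List cpp_perm_hotelling(NumericVector X, IntegerVector dims,
                        IntegerVector obs_mask, IntegerMatrix perm_masks,
                        double alpha, bool strict_ties, double cond_max) {
  const int N = dims[0], d = dims[1];
  const R_xlen_t W = dims[2];
  const int n_perm = perm_masks.nrow();
  if (d > DMAX) stop("feature dimension too large");
  int nA = 0;
  for (int i = 0; i < N; ++i) nA += (obs_mask[i] != 0);
  const int nB = N - nA;
  if (nA < 2 || nB < 2) stop("each group needs >= 2 subjects");

  const double* x = X.begin();
  NumericVector M_obs(W), p_unc(W);
  std::vector<int> pf_perm(n_perm, 0);
  std::vector<int> pmask(N);
  std::vector<double> col(n_perm);

  // permutation masks flattened per row for cache-friendly reuse
  std::vector<std::vector<int>> masks(n_perm, std::vector<int>(N));
  std::vector<int> nA_perm(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    int na = 0;
    for (int i = 0; i < N; ++i) {
      masks[p][i] = perm_masks(p, i);
      na += (masks[p][i] != 0);
    }
    nA_perm[p] = na;
    if (na < 2 || N - na < 2) stop("permutation with a group below 2");
  }

  int pf_obs = 0;
  for (R_xlen_t w = 0; w < W; ++w) {
    const double* Xw = x + w * (R_xlen_t)N * d;
    const double mobs = maha_one(Xw, N, d, &obs_mask[0], nA, nB, cond_max,
                                 (int)w + 1);
    M_obs[w] = mobs;
    for (int p = 0; p < n_perm; ++p)
      col[p] = maha_one(Xw, N, d, masks[p].data(), nA_perm[p],
                        N - nA_perm[p], cond_max, (int)w + 1);
    std::vector<double> sorted(col);
    std::sort(sorted.begin(), sorted.end());
    int ge;
    if (strict_ties)
      ge = n_perm - (int)(std::upper_bound(sorted.begin(), sorted.end(),
                                           mobs) - sorted.begin());
    else
      ge = n_perm - (int)(std::lower_bound(sorted.begin(), sorted.end(),
                                           mobs) - sorted.begin());
    p_unc[w] = (double)(ge + 1) / (n_perm + 1);
    if (p_unc[w] < alpha) ++pf_obs;
    // leave-self-in rank of each permutation in the common distribution
    for (int p = 0; p < n_perm; ++p) {
      const int gp = n_perm - (int)(std::lower_bound(sorted.begin(),
                                                     sorted.end(), col[p]) -
                                    sorted.begin());
      if ((double)gp / n_perm < alpha) ++pf_perm[p];
    }
  }

  int ge_feat = 0;
  for (int p = 0; p < n_perm; ++p)
    if (pf_perm[p] >= pf_obs) ++ge_feat;
  const double corrected = (double)(ge_feat + 1) / (n_perm + 1);

  return List::create(_["M"] = M_obs, _["p_uncorrected"] = p_unc,
                      _["p_feature"] = pf_obs,
                      _["p_feature_perm"] = IntegerVector(pf_perm.begin(),
                                                          pf_perm.end()),
                      _["corrected_p"] = corrected);
}
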