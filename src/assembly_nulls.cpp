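#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance for one sample pair.
// idxA/idxB: 0-based indices (into d) of OTUs present in each sample;
// wA/wB: within-sample relative abundances over present OTUs (sum to 1).
static double bmntd_kernel(const NumericMatrix& d,
                           const IntegerVector& idxA, const NumericVector& wA,
                           const IntegerVector& idxB, const NumericVector& wB) {
  const int nA = idxA.size(), nB = idxB.size();
  double acc = 0.0;
  for (int i = 0; i < nA; ++i) {
    const int a = idxA[i];
    double mn = R_PosInf;
    for (int j = 0; j < nB; ++j) {
      const double v = d(a, idxB[j]);
      if (v < mn) mn = v;
    }
    acc += wA[i] * mn;
  }
  double acc2 = 0.0;
  for (int j = 0; j < nB; ++j) {
    const int b = idxB[j];
    double mn = R_PosInf;
    for (int i = 0; i < nA; ++i) {
      const double v = d(b, idxA[i]);
      if (v < mn) mn = v;
    }
    acc2 += wB[j] * mn;
  }
  return 0.5 * (acc + acc2);
}

// [[Rcpp::export]]
double cpp_bmntd(const NumericMatrix& d,
                 const IntegerVector& idxA, const NumericVector& wA,
                 const IntegerVector& idxB, const NumericVector& wB) {
  return bmntd_kernel(d, idxA, wA, idxB, wB);
}

// betaMNTD under explicit tip-label permutations. perms is n_null x n_pool,
// 0-based: on null k the OTU originally at pool position i takes the tip
// (distance-matrix row/column) perms(k, i).
// [[Rcpp::export]]
NumericVector cpp_bmntd_perm_null(const NumericMatrix& d,
                                  const IntegerVector& idxA, const NumericVector& wA,
                                  const IntegerVector& idxB, const NumericVector& wB,
                                  const IntegerMatrix& perms) {
  const int n_null = perms.nrow();
  const int nA = idxA.size(), nB = idxB.size();
  NumericVector out(n_null);
  IntegerVector pA(nA), pB(nB);
  for (int k = 0; k < n_null; ++k) {
    for (int i = 0; i < nA; ++i) pA[i] = perms(k, idxA[i]);
    for (int j = 0; j < nB; ++j) pB[j] = perms(k, idxB[j]);
    out[k] = bmntd_kernel(d, pA, wA, pB, wB);
  }
  return out;
}

static double bray_curtis(const std::vector<double>& x, const std::vector<double>& y) {
  double num = 0.0, den = 0.0;
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    num += std::fabs(x[i] - y[i]);
    den += x[i] + y[i];
  }
  return den > 0 ? num / den : 0.0;
}

// Raup-Crick null Bray-Curtis draws. Each null reassembles both communities:
// draw the observed richness worth of OTUs without replacement with
// probability proportional to occupancy frequency, then allocate the observed
// read total among the drawn OTUs multinomially with probability proportional
// to pool mean relative abundance. Uses R's RNG (seed-reproducible from R).
// [[Rcpp::export]]
NumericVector cpp_rc_bray_null(const NumericVector& occ_freq,
                               const NumericVector& mean_relab,
                               const int richA, const int richB,
                               const int totA, const int totB,
                               const int n_null) {
  const int S = occ_freq.size();
  NumericVector out(n_null);
  IntegerVector pool = seq(0, S - 1);
  std::vector<double> xa(S), xb(S);
  std::vector<int> cnt(S);
  std::vector<double> prob(S);

  for (int k = 0; k < n_null; ++k) {
    std::fill(xa.begin(), xa.end(), 0.0);
    std::fill(xb.begin(), xb.end(), 0.0);
    for (int side = 0; side < 2; ++side) {
      const int rich = side == 0 ? richA : richB;
      const int tot  = side == 0 ? totA  : totB;
      std::vector<double>& x = side == 0 ? xa : xb;
      IntegerVector drawn = Rcpp::sample(pool, rich, false, occ_freq);
      double psum = 0.0;
      for (int i = 0; i < rich; ++i) psum += mean_relab[drawn[i]];
      std::vector<double> p(rich);
      for (int i = 0; i < rich; ++i)
        p[i] = psum > 0 ? mean_relab[drawn[i]] / psum : 1.0 / rich;
      std::vector<int> n(rich);
      ::Rf_rmultinom(tot, p.data(), rich, n.data());
      for (int i = 0; i < rich; ++i) x[drawn[i]] = n[i];
    }
    out[k] = bray_curtis(xa, xb);
  }
  return out;
}
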