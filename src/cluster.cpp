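#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Cluster-based permutation machinery on time x time maps: suprathreshold
// cells are clustered by 4-connectivity, each cluster scored by its mass
// (sum of t), and the null is the permutation distribution of the maximum
// absolute cluster mass over both signs (two-tailed family-wise control).

namespace {

// label positive (t > thr) and negative (t < -thr) clusters; returns masses
// and fills labels (positive clusters 1..k, negative -(1..m), else 0)
void label_clusters(const std::vector<double>& t, int nr, int nc, double thr,
                    std::vector<int>& labels,
                    std::vector<double>& pos_mass,
                    std::vector<double>& neg_mass) {
  labels.assign((size_t)nr * nc, 0);
  pos_mass.clear(); neg_mass.clear();
  std::vector<int> stack;
  for (int sgn = 1; sgn >= -1; sgn -= 2) {
    for (int c0 = 0; c0 < nc; ++c0) {
      for (int r0 = 0; r0 < nr; ++r0) {
        int idx0 = c0 * nr + r0;
        if (labels[idx0] != 0) continue;
        double v = t[idx0];
        bool supra = sgn > 0 ? (v > thr) : (v < -thr);
        if (!supra) continue;
        int lab = sgn > 0 ? (int)pos_mass.size() + 1
                          : -((int)neg_mass.size() + 1);
        double mass = 0.0;
        stack.clear();
        stack.push_back(idx0);
        labels[idx0] = lab;
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          mass += t[idx];
          int r = idx % nr, c = idx / nr;
          const int nb[4][2] = {{r - 1, c}, {r + 1, c}, {r, c - 1}, {r, c + 1}};
          for (auto& q : nb) {
            int rr = q[0], cc = q[1];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            int j = cc * nr + rr;
            if (labels[j] != 0) continue;
            double u = t[j];
            bool ok = sgn > 0 ? (u > thr) : (u < -thr);
            if (ok) { labels[j] = lab; stack.push_back(j); }
          }
        }
        if (sgn > 0) pos_mass.push_back(mass); else neg_mass.push_back(mass);
      }
    }
  }
}

double max_abs_mass(const std::vector<double>& t, int nr, int nc, double thr) {
  std::vector<int> labels;
  std::vector<double> pm, nm;
  label_clusters(t, nr, nc, thr, labels, pm, nm);
  double mx = 0.0;
  for (double m : pm) mx = std::max(mx, std::fabs(m));
  for (double m : nm) mx = std::max(mx, std::fabs(m));
  return mx;
}

// one-sample t statistics for given per-subject signs
void tmap_signed(const NumericMatrix& x, const std::vector<double>& sumsq,
                 const std::vector<int>& sgn, std::vector<double>& t) {
  const int n = x.nrow(), p = x.ncol();
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += sgn[i] * x(i, j);
    double m = s / n;
    double var = (sumsq[j] - n * m * m) / (n - 1);
    double se = std::sqrt(var / n);
    t[j] = se > 0 ? m / se : (m == 0 ? 0.0 : (m > 0 ? 1e12 : -1e12));
  }
}

// independent-samples pooled-variance t for a given group assignment
void tmap_two(const NumericMatrix& x, const std::vector<int>& inA,
              int nA, int nB, std::vector<double>& t) {
  const int n = x.nrow(), p = x.ncol();
  for (int j = 0; j < p; ++j) {
    double sA = 0.0, sB = 0.0, ssA = 0.0, ssB = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = x(i, j);
      if (inA[i]) { sA += v; ssA += v * v; }
      else { sB += v; ssB += v * v; }
    }
    double mA = sA / nA, mB = sB / nB;
    double sp2 = (ssA - nA * mA * mA + ssB - nB * mB * mB) / (nA + nB - 2);
    double se = std::sqrt(sp2 * (1.0 / nA + 1.0 / nB));
    double d = mA - mB;
    t[j] = se > 0 ? d / se : (d == 0 ? 0.0 : (d > 0 ? 1e12 : -1e12));
  }
}

}  // namespace

// One-sample sign-flip permutation cluster test on (maps - chance).
// x: subjects x cells matrix (cells = nr*nc, column-major map layout).
// Returns observed t map, cluster labels, masses, and the null max-|mass|
// sample. When exhaustive (2^n <= n_perm) all sign patterns are enumerated.
// [[Rcpp::export]]
List onesample_perm_cpp(NumericMatrix x, int nr, int nc, double tcrit,
                        int n_perm) {
  const int n = x.nrow(), p = x.ncol();
  if (p != nr * nc) stop("map dims do not match cell count");
  std::vector<double> sumsq(p, 0.0);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) sumsq[j] += x(i, j) * x(i, j);

  std::vector<int> sgn(n, 1);
  std::vector<double> t(p);
  tmap_signed(x, sumsq, sgn, t);
  std::vector<int> labels;
  std::vector<double> pos_mass, neg_mass;
  label_clusters(t, nr, nc, tcrit, labels, pos_mass, neg_mass);

  bool exhaustive = (n <= 30) && (std::pow(2.0, n) <= (double)n_perm);
  int n_eff = exhaustive ? (int)std::pow(2.0, n) : n_perm;
  NumericVector null_max(n_eff);
  for (int b = 0; b < n_eff; ++b) {
    if (exhaustive) {
      for (int i = 0; i < n; ++i) sgn[i] = ((b >> i) & 1) ? -1 : 1;
    } else {
      for (int i = 0; i < n; ++i) sgn[i] = unif_rand() < 0.5 ? -1 : 1;
    }
    tmap_signed(x, sumsq, sgn, t);
    null_max[b] = max_abs_mass(t, nr, nc, tcrit);
  }

  tmap_signed(x, sumsq, std::vector<int>(n, 1), t);
  return List::create(
    _["t_map"] = NumericMatrix(nr, nc, t.begin()),
    _["labels"] = IntegerMatrix(nr, nc, labels.begin()),
    _["pos_mass"] = NumericVector(pos_mass.begin(), pos_mass.end()),
    _["neg_mass"] = NumericVector(neg_mass.begin(), neg_mass.end()),
    _["null_max"] = null_max,
    _["exhaustive"] = exhaustive);
}

// Two-sample permutation cluster test (A - B); group labels are permuted
// preserving group sizes. xAB stacks A's rows then B's rows.
// [[Rcpp::export]]
List twosample_perm_cpp(NumericMatrix xAB, int nA, int nr, int nc,
                        double tcrit, int n_perm) {
  const int n = xAB.nrow(), p = xAB.ncol();
  const int nB = n - nA;
  if (p != nr * nc) stop("map dims do not match cell count");

  std::vector<int> inA(n, 0);
  for (int i = 0; i < nA; ++i) inA[i] = 1;
  std::vector<double> t(p);
  tmap_two(xAB, inA, nA, nB, t);
  std::vector<int> labels;
  std::vector<double> pos_mass, neg_mass;
  label_clusters(t, nr, nc, tcrit, labels, pos_mass, neg_mass);

  // exhaustive enumeration of group assignments when feasible
  double n_comb = 1.0;
  for (int i = 0; i < nA; ++i) n_comb *= (double)(n - i) / (i + 1);
  bool exhaustive = n_comb <= (double)n_perm;

  std::vector<int> assign(n, 0);
  NumericVector null_max;
  if (exhaustive) {
    std::vector<int> sel(n, 0);
    for (int i = 0; i < nA; ++i) sel[i] = 1;
    std::sort(sel.begin(), sel.end());  // start from lexicographically first
    std::vector<double> nm;
    do {
      tmap_two(xAB, sel, nA, nB, t);
      nm.push_back(max_abs_mass(t, nr, nc, tcrit));
    } while (std::next_permutation(sel.begin(), sel.end()));
    null_max = NumericVector(nm.begin(), nm.end());
  } else {
    null_max = NumericVector(n_perm);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int b = 0; b < n_perm; ++b) {
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(idx[i], idx[j]);
      }
      std::fill(assign.begin(), assign.end(), 0);
      for (int i = 0; i < nA; ++i) assign[idx[i]] = 1;
      tmap_two(xAB, assign, nA, nB, t);
      null_max[b] = max_abs_mass(t, nr, nc, tcrit);
    }
  }

  tmap_two(xAB, inA, nA, nB, t);
  return List::create(
    _["t_map"] = NumericMatrix(nr, nc, t.begin()),
    _["labels"] = IntegerMatrix(nr, nc, labels.begin()),
    _["pos_mass"] = NumericVector(pos_mass.begin(), pos_mass.end()),
    _["neg_mass"] = NumericVector(neg_mass.begin(), neg_mass.end()),
    _["null_max"] = null_max,
    _["exhaustive"] = exhaustive);
}
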