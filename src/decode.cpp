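#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Linear SVM (L2-regularized hinge loss) trained by dual coordinate descent
// (the LIBLINEAR algorithm), with per-feature z-scoring computed on the
// training set and applied to the test set, evaluated on a full
// train-time x test-time grid (temporal generalization). Feature vectors
// are the per-channel voltages at one time sample, plus a bias feature.

namespace {

struct Problem {
  int n, d;                    // examples, features (incl. bias)
  std::vector<double> X;       // n x d, row-major
  std::vector<double> y;       // +/-1
};

// dual coordinate descent for min 0.5 w'w + C sum max(0, 1 - y w'x)
void svm_train(const Problem& pb, double C, int max_epochs, double tol,
               std::vector<double>& w) {
  const int n = pb.n, d = pb.d;
  w.assign(d, 0.0);
  std::vector<double> alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double* xi = &pb.X[(size_t)i * d];
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qii[i] = s > 1e-12 ? s : 1e-12;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int ep = 0; ep < max_epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG (seeded from R)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      const double* xi = &pb.X[(size_t)i * d];
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * xi[j];
      g = g * pb.y[i] - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * pb.y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
        if (std::fabs(pg) > max_viol) max_viol = std::fabs(pg);
      }
    }
    if (max_viol < tol) break;
  }
}

inline double at3(const double* x, int n, int nch, int i, int ch, int t) {
  return x[(size_t)i + (size_t)n * ch + (size_t)n * nch * t];
}

}  // namespace

// Xtr, Xte: trials x channels x times arrays (column-major, as in R).
// ytr, yte: +1/-1 labels. train_idx, test_idx: 0-based time-sample indices
// of the decoding grid. Returns balanced accuracy, train times x test times.
// [[Rcpp::export]]
NumericMatrix decode_tg_cpp(NumericVector Xtr, IntegerVector ytr,
                            NumericVector Xte, IntegerVector yte,
                            IntegerVector train_idx, IntegerVector test_idx,
                            double C, int max_epochs, double tol) {
  IntegerVector dtr = Xtr.attr("dim");
  IntegerVector dte = Xte.attr("dim");
  const int ntr = dtr[0], nch = dtr[1];
  const int nte = dte[0];
  if (dte[1] != nch) stop("channel count mismatch between train and test");
  const int nT = train_idx.size(), nE = test_idx.size();
  NumericMatrix acc(nT, nE);
  const double* xtr = REAL(Xtr);
  const double* xte = REAL(Xte);

  Problem pb;
  pb.n = ntr; pb.d = nch + 1;
  pb.X.resize((size_t)ntr * (nch + 1));
  pb.y.resize(ntr);
  for (int i = 0; i < ntr; ++i) pb.y[i] = (double)ytr[i];

  std::vector<double> w, mu(nch), sdv(nch);
  std::vector<double> xte_t((size_t)nte * (nch + 1));

  for (int a = 0; a < nT; ++a) {
    int t = train_idx[a];
    // training-set z-scoring statistics at this sample
    for (int ch = 0; ch < nch; ++ch) {
      double s = 0.0, ss = 0.0;
      for (int i = 0; i < ntr; ++i) {
        double v = at3(xtr, ntr, nch, i, ch, t);
        s += v; ss += v * v;
      }
      double m = s / ntr;
      double var = ss / ntr - m * m;
      mu[ch] = m;
      sdv[ch] = var > 1e-20 ? std::sqrt(var) : 1.0;
    }
    for (int i = 0; i < ntr; ++i) {
      double* row = &pb.X[(size_t)i * (nch + 1)];
      for (int ch = 0; ch < nch; ++ch)
        row[ch] = (at3(xtr, ntr, nch, i, ch, t) - mu[ch]) / sdv[ch];
      row[nch] = 1.0;
    }
    svm_train(pb, C, max_epochs, tol, w);

    for (int b = 0; b < nE; ++b) {
      int te = test_idx[b];
      int nPos = 0, nNeg = 0, cPos = 0, cNeg = 0;
      for (int i = 0; i < nte; ++i) {
        double score = w[nch];
        for (int ch = 0; ch < nch; ++ch)
          score += w[ch] * ((at3(xte, nte, nch, i, ch, te) - mu[ch]) / sdv[ch]);
        int pred = score >= 0.0 ? 1 : -1;
        if (yte[i] > 0) { ++nPos; if (pred > 0) ++cPos; }
        else { ++nNeg; if (pred < 0) ++cNeg; }
      }
      double ba;
      if (nPos > 0 && nNeg > 0)
        ba = 0.5 * ((double)cPos / nPos + (double)cNeg / nNeg);
      else if (nPos > 0) ba = (double)cPos / nPos;
      else ba = (double)cNeg / nNeg;
      acc(a, b) = ba;
    }
  }
  return acc;
}
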