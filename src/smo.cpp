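// Sequential Minimal Optimization for a soft-margin RBF-kernel SVM,
// plus a leave-pair-out cross-validation driver that refits the SVM for
// every positive/negative pair with per-fold feature standardization.
//
// The solver is Platt-style SMO with an error cache and deterministic
// working-set heuristics (no RNG), so results are reproducible bit-for-bit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SMO {
  const std::vector<double>& K;   // n x n kernel, column-major
  const std::vector<double>& y;   // +1 / -1
  int n;
  double C, tol, eps;
  std::vector<double> alpha, err;
  double b;

  SMO(const std::vector<double>& K_, const std::vector<double>& y_, int n_,
      double C_, double tol_)
      : K(K_), y(y_), n(n_), C(C_), tol(tol_), eps(1e-12),
        alpha(n_, 0.0), err(n_), b(0.0) {
    for (int i = 0; i < n; ++i) err[i] = -y[i];  // f(x)=0 initially
  }

  inline double k(int i, int j) const { return K[i + (size_t)n * j]; }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2];
    double E1 = err[i1], E2 = err[i2];
    double s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    }
    if (H - L < eps) return false;
    double k11 = k(i1, i1), k12 = k(i1, i2), k22 = k(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > eps) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // degenerate kernel direction: evaluate objective at both ends
      double f1 = y1 * E1 - a1 * k11 - s * a2 * k12;
      double f2 = y2 * E2 - a2 * k22 - s * a1 * k12;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double objL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                    0.5 * L * L * k22 + s * L * L1 * k12;
      double objH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                    0.5 * H * H * k22 + s * H * H1 * k12;
      if (objL < objH - eps) a2new = L;
      else if (objL > objH + eps) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }

    double b1 = b - E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12;
    double b2 = b - E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22;
    double bnew;
    bool in1 = a1new > eps && a1new < C - eps;
    bool in2 = a2new > eps && a2new < C - eps;
    if (in1) bnew = b1;
    else if (in2) bnew = b2;
    else bnew = 0.5 * (b1 + b2);

    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2), db = bnew - b;
    for (int i = 0; i < n; ++i)
      err[i] += d1 * k(i1, i) + d2 * k(i2, i) + db;
    alpha[i1] = a1new; alpha[i2] = a2new; b = bnew;
    return true;
  }

  int examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2], E2 = err[i2];
    double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C - eps) || (r2 > tol && a2 > eps)) {
      // 2nd-choice heuristic: maximise |E1 - E2| over non-bound points
      int best = -1; double bestgap = -1.0;
      for (int i = 0; i < n; ++i) {
        if (alpha[i] > eps && alpha[i] < C - eps) {
          double gap = std::fabs(err[i] - E2);
          if (gap > bestgap) { bestgap = gap; best = i; }
        }
      }
      if (best >= 0 && take_step(best, i2)) return 1;
      for (int i = 0; i < n; ++i) {  // non-bound sweep, fixed order
        if (alpha[i] > eps && alpha[i] < C - eps && take_step(i, i2))
          return 1;
      }
      for (int i = 0; i < n; ++i)    // full sweep
        if (take_step(i, i2)) return 1;
    }
    return 0;
  }

  void solve(int max_passes) {
    int changed = 0;
    bool examine_all = true;
    int pass = 0;
    while ((changed > 0 || examine_all) && pass < max_passes) {
      ++pass;
      changed = 0;
      if (examine_all) {
        for (int i = 0; i < n; ++i) changed += examine(i);
      } else {
        for (int i = 0; i < n; ++i)
          if (alpha[i] > eps && alpha[i] < C - eps) changed += examine(i);
      }
      if (examine_all) examine_all = false;
      else if (changed == 0) examine_all = true;
    }
  }
};

void rbf_kernel(const std::vector<double>& X, int n, int d, double gamma,
                std::vector<double>& K) {
  K.assign((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    K[i + (size_t)n * i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double diff = X[i + (size_t)n * c] - X[j + (size_t)n * c];
        s += diff * diff;
      }
      double v = std::exp(-gamma * s);
      K[i + (size_t)n * j] = v;
      K[j + (size_t)n * i] = v;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".smo_fit")]]
List smo_fit_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol = 1e-3, int max_passes = 200) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> Xv(X.begin(), X.end());
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> K;
  rbf_kernel(Xv, n, d, gamma, K);
  SMO smo(K, yv, n, C, tol);
  smo.solve(max_passes);
  return List::create(_["alpha"] = NumericVector(smo.alpha.begin(), smo.alpha.end()),
                      _["b"] = smo.b);
}

// [[Rcpp::export(name = ".rbf_decision")]]
NumericVector rbf_decision_cpp(NumericMatrix Xtrain, NumericVector y,
                               NumericVector alpha, double b, double gamma,
                               NumericMatrix Xnew) {
  int n = Xtrain.nrow(), d = Xtrain.ncol(), m = Xnew.nrow();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    double f = b;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] <= 0) continue;
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double diff = Xtrain(i, c) - Xnew(t, c);
        s += diff * diff;
      }
      f += alpha[i] * y[i] * std::exp(-gamma * s);
    }
    out[t] = f;
  }
  return out;
}

// Leave-pair-out CV: for every (positive, negative) pair, fit the SVM on
// the remaining subjects (features z-scored on the training fold only) and
// record the decision values of the held-out pair.
// [[Rcpp::export(name = ".lpocv_rbf")]]
List lpocv_rbf_cpp(NumericMatrix X, IntegerVector y01, double C, double gamma,
                   double tol = 1e-3, int max_passes = 200) {
  int n = X.nrow(), d = X.ncol();
  std::vector<int> pos, neg;
  for (int i = 0; i < n; ++i) (y01[i] == 1 ? pos : neg).push_back(i);
  int nP = pos.size(), nN = neg.size();
  if (nP < 2 || nN < 2)
    stop("leave-pair-out CV needs at least 2 subjects per class");
  NumericMatrix cp(nP, nN), cn(nP, nN);

  int ntr = n - 2;
  std::vector<double> Xtr((size_t)ntr * d), ytr(ntr), K;
  std::vector<double> mu(d), sd(d), xp(d), xn(d);

  for (int a = 0; a < nP; ++a) {
    for (int bidx = 0; bidx < nN; ++bidx) {
      int ip = pos[a], in_ = neg[bidx];
      // training fold
      int r = 0;
      std::vector<int> rows(ntr);
      for (int i = 0; i < n; ++i) if (i != ip && i != in_) rows[r++] = i;
      // fold standardization
      for (int c = 0; c < d; ++c) {
        double m = 0;
        for (int i = 0; i < ntr; ++i) m += X(rows[i], c);
        m /= ntr;
        double v = 0;
        for (int i = 0; i < ntr; ++i) {
          double diff = X(rows[i], c) - m; v += diff * diff;
        }
        v = ntr > 1 ? v / (ntr - 1) : 0.0;
        mu[c] = m; sd[c] = v > 0 ? std::sqrt(v) : 1.0;
      }
      for (int c = 0; c < d; ++c) {
        for (int i = 0; i < ntr; ++i)
          Xtr[i + (size_t)ntr * c] = (X(rows[i], c) - mu[c]) / sd[c];
        xp[c] = (X(ip, c) - mu[c]) / sd[c];
        xn[c] = (X(in_, c) - mu[c]) / sd[c];
      }
      for (int i = 0; i < ntr; ++i) ytr[i] = y01[rows[i]] == 1 ? 1.0 : -1.0;

      rbf_kernel(Xtr, ntr, d, gamma, K);
      SMO smo(K, ytr, ntr, C, tol);
      smo.solve(max_passes);

      double fp = smo.b, fn = smo.b;
      for (int i = 0; i < ntr; ++i) {
        if (smo.alpha[i] <= 0) continue;
        double sp = 0, sn = 0;
        for (int c = 0; c < d; ++c) {
          double dp_ = Xtr[i + (size_t)ntr * c] - xp[c];
          double dn_ = Xtr[i + (size_t)ntr * c] - xn[c];
          sp += dp_ * dp_; sn += dn_ * dn_;
        }
        fp += smo.alpha[i] * ytr[i] * std::exp(-gamma * sp);
        fn += smo.alpha[i] * ytr[i] * std::exp(-gamma * sn);
      }
      cp(a, bidx) = fp;
      cn(a, bidx) = fn;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["cp"] = cp, _["cn"] = cn,
                      _["pos_index"] = IntegerVector(pos.begin(), pos.end()),
                      _["neg_index"] = IntegerVector(neg.begin(), neg.end()));
}
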