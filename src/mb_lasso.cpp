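#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lasso paths for Meinshausen-Buhlmann neighborhood selection.
//
// X must be column-standardised: each column has mean 0 and mean square 1,
// so the Gram matrix C = X'X / n has unit diagonal (zero-variance columns
// are allowed and simply attract no coefficients). For every target column
// j and every lambda on a descending path we solve
//
//   min_b  (1/2n) || x_j - X_{-j} b ||^2  +  lambda ||b||_1
//
// by cyclic coordinate descent on C (covariance updates), with warm starts
// along the path and an active-set strategy: active-set sweeps iterate to
// convergence, then one full sweep checks the KKT conditions and admits
// violators. The update for coordinate k is b_k <- S(z_k, lambda) / C_kk
// with z_k = C_kj - sum_{m != k} C_km b_m and S the soft threshold.

static inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// [[Rcpp::export]]
NumericVector mb_lasso_path_cpp(const NumericMatrix& X,
                                const NumericVector& lambdas,
                                double tol = 1e-5,
                                int max_sweeps = 1000) {
  const int n = X.nrow(), p = X.ncol();
  const int L = lambdas.size();

  // Gram matrix C = X'X / n (dense, column-major)
  std::vector<double> C((size_t)p * p);
  for (int a = 0; a < p; ++a) {
    const double* xa = &X(0, a);
    for (int b = a; b < p; ++b) {
      const double* xb = &X(0, b);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xa[i] * xb[i];
      s /= n;
      C[(size_t)a + (size_t)p * b] = s;
      C[(size_t)b + (size_t)p * a] = s;
    }
  }

  NumericVector out((R_xlen_t)p * p * L);  // B[k, j, l], zero-initialised
  std::vector<double> beta(p);
  std::vector<int> active;
  std::vector<char> in_active(p);
  active.reserve(p);

  for (int j = 0; j < p; ++j) {
    checkUserInterrupt();
    std::fill(beta.begin(), beta.end(), 0.0);
    std::fill(in_active.begin(), in_active.end(), 0);
    active.clear();
    const double* Cj = &C[(size_t)p * j];

    for (int l = 0; l < L; ++l) {
      const double lam = lambdas[l];
      int sweeps = 0;
      for (;;) {
        // active-set sweeps until stable
        double ad;
        do {
          ad = 0.0;
          for (size_t a = 0; a < active.size(); ++a) {
            const int k = active[a];
            const double ckk = C[(size_t)k + (size_t)p * k];
            if (ckk <= 0.0) continue;
            double z = Cj[k];
            const double* Ck = &C[(size_t)p * k];
            for (size_t b = 0; b < active.size(); ++b) {
              const int m = active[b];
              if (m != k) z -= Ck[m] * beta[m];
            }
            const double bnew = soft(z, lam) / ckk;
            const double d = std::fabs(bnew - beta[k]);
            if (d > 0.0) { beta[k] = bnew; if (d > ad) ad = d; }
          }
          ++sweeps;
        } while (ad >= tol && sweeps < max_sweeps);

        // full KKT sweep over inactive coordinates
        bool admitted = false;
        for (int k = 0; k < p; ++k) {
          if (k == j || in_active[k]) continue;
          const double ckk = C[(size_t)k + (size_t)p * k];
          if (ckk <= 0.0) continue;
          double z = Cj[k];
          const double* Ck = &C[(size_t)p * k];
          for (size_t a = 0; a < active.size(); ++a) {
            const int m = active[a];
            z -= Ck[m] * beta[m];
          }
          const double bnew = soft(z, lam) / ckk;
          if (bnew != 0.0) {
            beta[k] = bnew;
            active.push_back(k);
            in_active[k] = 1;
            admitted = true;
          }
        }
        ++sweeps;
        if (!admitted || sweeps >= max_sweeps) break;
      }

      // drop exact zeros from the active set before storing / next lambda
      std::vector<int> keep;
      keep.reserve(active.size());
      for (size_t a = 0; a < active.size(); ++a) {
        const int k = active[a];
        if (beta[k] != 0.0) keep.push_back(k);
        else in_active[k] = 0;
      }
      active.swap(keep);

      double* slab = &out[(R_xlen_t)p * j + (R_xlen_t)p * p * l];
      for (size_t a = 0; a < active.size(); ++a)
        slab[active[a]] = beta[active[a]];
    }
  }

  out.attr("dim") = IntegerVector::create(p, p, L);
  return out;
}
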