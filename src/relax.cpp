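#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spring relaxation of a bead chain: bonded neighbours at bond_dist,
// planted contact pairs pulled to contact_dist, all other pairs beyond the
// sequence-neighbour exclusion pushed out to repel_dist, near neighbours
// (2..exclude apart) kept above a soft floor. Gradient descent with a
// per-bead step cap; converges when every constraint has margin.
// [[Rcpp::export]]
NumericMatrix cpp_relax_chain(NumericMatrix centers_in,
                              IntegerVector ci, IntegerVector cj,
                              int max_steps, double contact_dist,
                              double repel_dist, double bond_dist,
                              int exclude, double lr, double max_move) {
  const int n = centers_in.nrow();
  NumericMatrix centers = clone(centers_in);
  const int m = ci.size();
  std::vector<bool> planted((size_t)n * n, false);
  for (int k = 0; k < m; ++k) {
    int a = ci[k] - 1, b = cj[k] - 1;
    planted[(size_t)a * n + b] = true;
    planted[(size_t)b * n + a] = true;
  }
  std::vector<double> fx(n), fy(n), fz(n);
  for (int step = 1; step <= max_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int a = 0; a < n - 1; ++a) {
      for (int b = a + 1; b < n; ++b) {
        double dx = centers(a, 0) - centers(b, 0);
        double dy = centers(a, 1) - centers(b, 1);
        double dz = centers(a, 2) - centers(b, 2);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < 1e-9) d = 1e-9;
        int sep = b - a;
        double coef = 0.0;
        if (sep == 1) {
          coef = (d - bond_dist) / d;
        } else if (planted[(size_t)a * n + b]) {
          coef = 1.5 * (d - contact_dist) / d;
        } else if (sep > exclude) {
          if (d < repel_dist) coef = 2.0 * (d - repel_dist) / d;
        } else {
          if (d < 3.0) coef = (d - 3.0) / d;
        }
        if (coef != 0.0) {
          fx[a] -= coef * dx; fy[a] -= coef * dy; fz[a] -= coef * dz;
          fx[b] += coef * dx; fy[b] += coef * dy; fz[b] += coef * dz;
        }
      }
    }
    for (int a = 0; a < n; ++a) {
      double mx = lr * fx[a], my = lr * fy[a], mz = lr * fz[a];
      double norm = std::sqrt(mx * mx + my * my + mz * mz);
      if (norm > max_move) {
        double s = max_move / norm;
        mx *= s; my *= s; mz *= s;
      }
      centers(a, 0) += mx; centers(a, 1) += my; centers(a, 2) += mz;
    }
    if (step % 100 == 0) {
      bool ok = true;
      for (int k = 0; k < m && ok; ++k) {
        int a = ci[k] - 1, b = cj[k] - 1;
        double dx = centers(a, 0) - centers(b, 0);
        double dy = centers(a, 1) - centers(b, 1);
        double dz = centers(a, 2) - centers(b, 2);
        if (std::sqrt(dx * dx + dy * dy + dz * dz) > contact_dist + 0.4)
          ok = false;
      }
      for (int a = 0; a < n - 1 && ok; ++a) {
        for (int b = a + 1; b < n && ok; ++b) {
          double dx = centers(a, 0) - centers(b, 0);
          double dy = centers(a, 1) - centers(b, 1);
          double dz = centers(a, 2) - centers(b, 2);
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          int sep = b - a;
          if (sep == 1) {
            if (std::fabs(d - bond_dist) > 0.6) ok = false;
          } else if (sep > exclude && !planted[(size_t)a * n + b]) {
            if (d < repel_dist - 0.3) ok = false;
          }
        }
      }
      if (ok) break;
    }
  }
  return centers;
}
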