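#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Explicit 5-point finite-difference diffusion with zero-flux (reflecting)
// boundaries and first-order decay. The macro step dt is internally split
// into the smallest number of sub-steps satisfying the stability bound
// D * dt_sub / h^2 <= 1/4; decay is applied per sub-step as exp(-decay*dt_sub)
// (the exact integral of dC/dt = -decay*C, unconditionally stable).
//
// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix conc, double D, double decay,
                          double h, double dt) {
  const int nr = conc.nrow(), nc = conc.ncol();
  if (!R_finite(D) || !R_finite(decay) || !R_finite(h) || !R_finite(dt))
    stop("non-finite diffusion inputs");
  if (D < 0 || decay < 0 || h <= 0)
    stop("D and decay must be >= 0, h > 0");
  NumericMatrix out = clone(conc);
  if (dt <= 0) return out;

  int nsub = 1;
  if (D > 0) {
    double dtmax = 0.25 * h * h / D;
    nsub = (int)std::ceil(dt / dtmax - 1e-12);
    if (nsub < 1) nsub = 1;
  }
  const double dts = dt / nsub;
  const double lam = (D > 0) ? D * dts / (h * h) : 0.0;
  const double dec = std::exp(-decay * dts);

  if (lam == 0.0) {
    // pure decay
    const double dtot = std::exp(-decay * dt);
    double *o = out.begin();
    for (int k = 0; k < nr * nc; ++k) o[k] *= dtot;
    return out;
  }

  std::vector<double> buf_a(out.begin(), out.end()), buf_b(nr * nc);
  double *cur = buf_a.data(), *nxt = buf_b.data();

  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < nc; ++j) {
      const double *c = cur + (size_t)j * nr;
      const double *cl = cur + (size_t)((j > 0) ? j - 1 : j) * nr;
      const double *cr = cur + (size_t)((j < nc - 1) ? j + 1 : j) * nr;
      double *o = nxt + (size_t)j * nr;
      // top edge (reflected row neighbor = self)
      {
        const int i = 0;
        const double up = c[i], dn = (nr > 1) ? c[i + 1] : c[i];
        o[i] = (c[i] + lam * (up + dn + cl[i] + cr[i] - 4.0 * c[i])) * dec;
      }
      for (int i = 1; i < nr - 1; ++i) {
        o[i] = (c[i] + lam * (c[i - 1] + c[i + 1] + cl[i] + cr[i]
                              - 4.0 * c[i])) * dec;
      }
      if (nr > 1) {
        const int i = nr - 1;
        const double up = c[i - 1], dn = c[i];
        o[i] = (c[i] + lam * (up + dn + cl[i] + cr[i] - 4.0 * c[i])) * dec;
      }
    }
    std::swap(cur, nxt);
  }
  std::copy(cur, cur + (size_t)nr * nc, out.begin());
  return out;
}

// Number of stability sub-steps cpp_diffuse will use (exposed for testing
// and for solver diagnostics).
//
// [[Rcpp::export]]
int cpp_diffusion_substeps(double D, double h, double dt) {
  if (D <= 0 || dt <= 0) return 1;
  double dtmax = 0.25 * h * h / D;
  int nsub = (int)std::ceil(dt / dtmax - 1e-12);
  return nsub < 1 ? 1 : nsub;
}

// Accumulate point-source increments onto a field (duplicate sites add).
//
// [[Rcpp::export]]
NumericMatrix cpp_add_at(NumericMatrix m, IntegerVector row, IntegerVector col,
                         NumericVector amount) {
  NumericMatrix out = clone(m);
  const int nr = out.nrow(), nc = out.ncol();
  for (int i = 0; i < row.size(); ++i) {
    int r = row[i] - 1, c = col[i] - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc) stop("source site out of bounds");
    out(r, c) += amount[i];
  }
  return out;
}
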