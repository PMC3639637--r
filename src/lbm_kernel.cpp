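#include <Rcpp.h>
using namespace Rcpp;

// Node classification codes (kept in sync with R/geometry.R)
static const int SOLID = 0;

// Equilibrium PDF for one node: w_i rho (1 + 3 e.u + 4.5 (e.u)^2 - 1.5 u.u)
static inline void equilibrium_node(const int q, const int d,
                                    const int *e, const double *w,
                                    const double rho, const double *u,
                                    double *feq) {
  double u2 = 0.0;
  for (int k = 0; k < d; ++k) u2 += u[k] * u[k];
  for (int i = 0; i < q; ++i) {
    double eu = 0.0;
    for (int k = 0; k < d; ++k) eu += e[i + k * q] * u[k];
    feq[i] = w[i] * rho * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * u2);
  }
}

// [[Rcpp::export]]
List lbm_moments_cpp(const NumericMatrix f, const IntegerMatrix e,
                     const IntegerVector cls) {
  const int q = f.nrow(), n = f.ncol(), d = e.ncol();
  NumericVector rho(n);
  NumericMatrix u(d, n);
  for (int j = 0; j < n; ++j) {
    if (cls[j] == SOLID) continue;
    double r = 0.0;
    double mom[3] = {0.0, 0.0, 0.0};
    for (int i = 0; i < q; ++i) {
      const double fi = f(i, j);
      r += fi;
      for (int k = 0; k < d; ++k) mom[k] += fi * e(i, k);
    }
    rho[j] = r;
    if (r > 0.0)
      for (int k = 0; k < d; ++k) u(k, j) = mom[k] / r;
  }
  return List::create(_["rho"] = rho, _["u"] = u);
}

// Fused BGK step kernel: nsteps of collide -> stream (with half-way
// bounce-back at fluid/solid links) -> inlet equilibrium -> outlet copy.
// All index vectors are 0-based. f is q x n (column-major over grid nodes).
// [[Rcpp::export]]
NumericMatrix lbm_run_chunk(NumericMatrix f, const IntegerVector cls,
                            const IntegerVector dims, const IntegerMatrix e,
                            const NumericVector w, const IntegerVector opp0,
                            const double tau,
                            const IntegerVector inlet_idx,
                            const NumericMatrix inlet_u,
                            const IntegerVector inlet_src,
                            const IntegerVector outlet_idx,
                            const IntegerVector outlet_src,
                            const int nsteps) {
  const int q = f.nrow(), n = f.ncol(), d = dims.size();
  const double omega = 1.0 / tau;

  std::vector<int> strides(d);
  strides[0] = 1;
  for (int k = 1; k < d; ++k) strides[k] = strides[k - 1] * dims[k - 1];

  std::vector<double> fa(f.begin(), f.end());
  std::vector<double> fb(fa.size());
  std::vector<double> feq(q), uloc(3);
  std::vector<int> ee(q * d);
  for (int i = 0; i < q; ++i)
    for (int k = 0; k < d; ++k) ee[i + k * q] = e(i, k);

  // active nodes (anything that collides and streams)
  std::vector<int> active;
  active.reserve(n);
  for (int j = 0; j < n; ++j)
    if (cls[j] != SOLID) active.push_back(j);

  for (int step = 0; step < nsteps; ++step) {
    // ---- collide (all non-solid nodes) ----
    for (size_t a = 0; a < active.size(); ++a) {
      const int j = active[a];
      double *fj = &fa[(size_t)j * q];
      double rho = 0.0;
      double mom[3] = {0.0, 0.0, 0.0};
      for (int i = 0; i < q; ++i) {
        rho += fj[i];
        for (int k = 0; k < d; ++k) mom[k] += fj[i] * ee[i + k * q];
      }
      for (int k = 0; k < d; ++k) uloc[k] = mom[k] / rho;
      equilibrium_node(q, d, ee.data(), &w[0], rho, uloc.data(), feq.data());
      // fold the equilibrium's rounding defect into the rest direction so
      // collision conserves nodal mass exactly
      double rdef = rho;
      for (int i = 0; i < q; ++i) rdef -= feq[i];
      feq[0] += rdef;
      for (int i = 0; i < q; ++i) fj[i] -= omega * (fj[i] - feq[i]);
    }

    // ---- stream with half-way bounce-back ----
    for (size_t a = 0; a < active.size(); ++a) {
      const int j = active[a];
      int c[3];
      int rem = j;
      for (int k = d - 1; k >= 0; --k) {
        c[k] = rem / strides[k];
        rem -= c[k] * strides[k];
      }
      const double *fj = &fa[(size_t)j * q];
      for (int i = 0; i < q; ++i) {
        int tgt = j;
        bool inb = true;
        for (int k = 0; k < d; ++k) {
          const int ck = c[k] + ee[i + k * q];
          if (ck < 0 || ck >= dims[k]) { inb = false; break; }
          tgt += ee[i + k * q] * strides[k];
        }
        if (inb && cls[tgt] != SOLID) {
          fb[(size_t)tgt * q + i] = fj[i];
        } else {
          fb[(size_t)j * q + opp0[i]] = fj[i]; // reflect at the wall link
        }
      }
    }
    std::swap(fa, fb);

    // ---- inlet: equilibrium at prescribed velocity, density from interior
    for (int m = 0; m < inlet_idx.size(); ++m) {
      const int j = inlet_idx[m], s = inlet_src[m];
      const double *fs = &fa[(size_t)s * q];
      double rho = 0.0;
      for (int i = 0; i < q; ++i) rho += fs[i];
      for (int k = 0; k < d; ++k) uloc[k] = inlet_u(k, m);
      equilibrium_node(q, d, ee.data(), &w[0], rho, uloc.data(), feq.data());
      double *fj = &fa[(size_t)j * q];
      for (int i = 0; i < q; ++i) fj[i] = feq[i];
    }

    // ---- outlet: zero-gradient velocity copy with the density pinned to
    // the reference value 1 (fixes the pressure level of the open system):
    // f_out = feq(1, u_nb) + (f_nb - feq(rho_nb, u_nb))
    for (int m = 0; m < outlet_idx.size(); ++m) {
      const int j = outlet_idx[m], s = outlet_src[m];
      double *fj = &fa[(size_t)j * q];
      const double *fs = &fa[(size_t)s * q];
      double rho = 0.0;
      double mom[3] = {0.0, 0.0, 0.0};
      for (int i = 0; i < q; ++i) {
        rho += fs[i];
        for (int k = 0; k < d; ++k) mom[k] += fs[i] * ee[i + k * q];
      }
      for (int k = 0; k < d; ++k) uloc[k] = mom[k] / rho;
      equilibrium_node(q, d, ee.data(), &w[0], rho, uloc.data(), feq.data());
      for (int i = 0; i < q; ++i) fj[i] = fs[i] - feq[i];
      equilibrium_node(q, d, ee.data(), &w[0], 1.0, uloc.data(), feq.data());
      for (int i = 0; i < q; ++i) fj[i] += feq[i];
    }
  }

  NumericMatrix out(q, n);
  std::copy(fa.begin(), fa.end(), out.begin());
  return out;
}
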