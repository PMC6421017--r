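#include <Rcpp.h>
using namespace Rcpp;

// Explicit finite-difference kernels for the 2-D Pennes bioheat equation
//
//   rho*Cp dT/dt = k Lap(T) + wb*rhob*cpb*(Ta - T) + Qm
//
// discretized with a 5-point Laplacian and a forward-Euler step (Jacobi
// sweep: the n+1 field is computed entirely from the n field).  Background
// pixels are Dirichlet nodes held at the boundary temperature; the caller
// guarantees that every brain pixel has four in-grid neighbours (all four
// grid borders are background).
//
// Per-pixel coefficient maps are prepared in R:
//   kmap  : thermal conductivity [W/(m C)]
//   rcmap : rho*Cp               [J/(m^3 C)]
//   pmap  : wb*rhob*cpb          [W/(m^3 C)]  (perfusion sink strength)
//   qmap  : Qm                   [W/m^3]
//
// conduct = 0 uses the centre pixel's conductivity for the whole stencil
// (matching the per-pixel indexing of the update equation); conduct = 1
// uses harmonic-mean face conductivities in flux form.

static inline double face_k(double ka, double kb) {
  double s = ka + kb;
  return (s > 0.0) ? 2.0 * ka * kb / s : 0.0;
}

static double sweep(const NumericMatrix& Tn, NumericMatrix& Tn1,
                    const IntegerMatrix& brain,
                    const NumericMatrix& kmap, const NumericMatrix& rcmap,
                    const NumericMatrix& pmap, const NumericMatrix& qmap,
                    double dt, double dx2, double Ta, int conduct) {
  int nr = Tn.nrow(), nc = Tn.ncol();
  const double* T = Tn.begin();
  double* U = Tn1.begin();
  const int* B = brain.begin();
  const double* K = kmap.begin();
  const double* RC = rcmap.begin();
  const double* P = pmap.begin();
  const double* Q = qmap.begin();
  double dmax = 0.0;
  for (int j = 1; j < nc - 1; ++j) {
    int col = j * nr;
    for (int i = 1; i < nr - 1; ++i) {
      int c = col + i;
      if (!B[c]) { U[c] = T[c]; continue; }
      double T0 = T[c];
      double lap;
      if (conduct == 0) {
        lap = K[c] * (T[c - 1] + T[c + 1] + T[c - nr] + T[c + nr] - 4.0 * T0);
      } else {
        lap  = face_k(K[c], K[c - 1])  * (T[c - 1]  - T0);
        lap += face_k(K[c], K[c + 1])  * (T[c + 1]  - T0);
        lap += face_k(K[c], K[c - nr]) * (T[c - nr] - T0);
        lap += face_k(K[c], K[c + nr]) * (T[c + nr] - T0);
      }
      double Tnew = T0 + dt / RC[c] * (lap / dx2 + P[c] * (Ta - T0) + Q[c]);
      U[c] = Tnew;
      double d = std::abs(Tnew - T0);
      if (d > dmax) dmax = d;
    }
  }
  return dmax;
}

// [[Rcpp::export(name = ".pennes_steady_cpp")]]
List pennes_steady_cpp(NumericMatrix T0, IntegerMatrix brain,
                       NumericMatrix kmap, NumericMatrix rcmap,
                       NumericMatrix pmap, NumericMatrix qmap,
                       double dt, double dx2, double Ta,
                       double tol, int max_iters, int conduct) {
  NumericMatrix Ta_buf = clone(T0), Tb_buf = clone(T0);
  double dmax = R_PosInf;
  int it = 0;
  bool converged = false;
  while (it < max_iters) {
    NumericMatrix& src = (it % 2 == 0) ? Ta_buf : Tb_buf;
    NumericMatrix& dst = (it % 2 == 0) ? Tb_buf : Ta_buf;
    dmax = sweep(src, dst, brain, kmap, rcmap, pmap, qmap, dt, dx2, Ta, conduct);
    ++it;
    if (!R_finite(dmax))
      stop("divergence: non-finite temperature at iteration %d", it);
    if (dmax < tol) { converged = true; break; }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix& fin = (it % 2 == 0) ? Ta_buf : Tb_buf;
  return List::create(_["values"] = fin, _["iterations"] = it,
                      _["converged"] = converged, _["last_change"] = dmax);
}

// [[Rcpp::export(name = ".pennes_transient_cpp")]]
List pennes_transient_cpp(NumericMatrix T0, IntegerMatrix brain,
                          NumericMatrix kmap, NumericMatrix rcmap,
                          NumericMatrix pmap, NumericMatrix qmap,
                          double dt, double dx2, double Ta,
                          IntegerVector sample_steps, int conduct) {
  NumericMatrix Ta_buf = clone(T0), Tb_buf = clone(T0);
  int nsamp = sample_steps.size();
  List out(nsamp);
  int it = 0, si = 0;
  while (si < nsamp && sample_steps[si] == 0) { out[si] = clone(Ta_buf); ++si; }
  int total = nsamp > 0 ? sample_steps[nsamp - 1] : 0;
  while (it < total) {
    NumericMatrix& src = (it % 2 == 0) ? Ta_buf : Tb_buf;
    NumericMatrix& dst = (it % 2 == 0) ? Tb_buf : Ta_buf;
    double dmax = sweep(src, dst, brain, kmap, rcmap, pmap, qmap,
                        dt, dx2, Ta, conduct);
    ++it;
    if (!R_finite(dmax))
      stop("divergence: non-finite temperature at step %d", it);
    while (si < nsamp && sample_steps[si] == it) {
      out[si] = clone(dst);
      ++si;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
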