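// Reaction-transport right-hand side on the lattice.
//
// First-order upwind differences for the advective terms, with replicated
// boundary values (zero one-sided gradient at the domain edge); the
// divergence terms arrive precomputed (central differences).  Reaction
// terms evaluate on values clamped at zero: adaptive sub-steps can
// transiently undershoot and C^n is undefined for C < 0 at fractional n.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {
// accumulate -(v . grad x) into out, v = coef * (dx, dy, dz), coef >= 0
void upwind_sub(NumericVector &out, const NumericVector &x,
                const NumericVector &dx, const NumericVector &dy,
                const NumericVector &dz, double coef, double h,
                int nx, int ny, int nz) {
  if (coef == 0.0) return;
  const double inv_h = coef / h;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const int base = (k * ny + j) * nx;
      for (int i = 0; i < nx; ++i) {
        const int q = base + i;
        double acc = 0.0;
        // x axis
        double v = dx[q];
        if (v > 0) acc += v * (x[q] - x[i > 0 ? q - 1 : q]);
        else if (v < 0) acc += v * (x[i < nx - 1 ? q + 1 : q] - x[q]);
        // y axis
        v = dy[q];
        if (v > 0) acc += v * (x[q] - x[j > 0 ? q - nx : q]);
        else if (v < 0) acc += v * (x[j < ny - 1 ? q + nx : q] - x[q]);
        // z axis
        v = dz[q];
        if (v > 0) acc += v * (x[q] - x[k > 0 ? q - nx * ny : q]);
        else if (v < 0) acc += v * (x[k < nz - 1 ? q + nx * ny : q] - x[q]);
        out[q] -= inv_h * acc;
      }
    }
  }
}
}  // namespace

// [[Rcpp::export]]
List cpp_species_rhs(IntegerVector shape, NumericVector B, NumericVector A,
                     NumericVector C, NumericVector dirx, NumericVector diry,
                     NumericVector dirz, NumericVector div_d,
                     NumericVector fux, NumericVector fuy, NumericVector fuz,
                     NumericVector div_fu, NumericVector basal,
                     NumericVector stim, List par, double nu_mp,
                     bool stimulus_on, double h) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const int n = nx * ny * nz;
  const double k_beta = par["k_beta"], k_A = par["k_A"], k_C = par["k_C"];
  const double I_beta = par["I_beta"], I_A = par["I_A"], I_C = par["I_C"];
  const double IS_beta = par["IS_beta"], IS_A = par["IS_A"],
               IS_C = par["IS_C"];
  const double k_nuc = par["k_nuc"], k_sev = par["k_sev"], k_n = par["k_n"];
  const double hill_n = par["n"], Psi0 = par["Psi0"], Psi1 = par["Psi1"];
  const double nu = par["nu"], xi = par["xi"], eta = par["eta"];

  NumericVector dB(n), dA(n), dC(n);

  // transport: polymerization advection of B along d, drift of B against
  // the repulsive force density, bulk flow of A and C along d
  upwind_sub(dB, B, dirx, diry, dirz, nu, h, nx, ny, nz);
  // velocity -eta*f_u: negate components via coef trick (coef stays >= 0)
  {
    NumericVector mfux(n), mfuy(n), mfuz(n);
    for (int q = 0; q < n; ++q) {
      mfux[q] = -fux[q]; mfuy[q] = -fuy[q]; mfuz[q] = -fuz[q];
    }
    upwind_sub(dB, B, mfux, mfuy, mfuz, eta, h, nx, ny, nz);
  }
  const double vbulk = xi * nu_mp;
  upwind_sub(dA, A, dirx, diry, dirz, vbulk, h, nx, ny, nz);
  upwind_sub(dC, C, dirx, diry, dirz, vbulk, h, nx, ny, nz);

  const double son = stimulus_on ? 1.0 : 0.0;
  for (int q = 0; q < n; ++q) {
    const double Bc = B[q] > 0 ? B[q] : 0.0;
    const double Ac = A[q] > 0 ? A[q] : 0.0;
    const double Cc = C[q] > 0 ? C[q] : 0.0;
    const double fnuc = k_nuc * Ac * Psi1 * Bc;
    const double cn = std::pow(Cc, hill_n);
    const double fsev = k_sev * cn / (k_n + cn) * Psi1 * Bc;
    dB[q] += -B[q] * nu * div_d[q] + eta * B[q] * div_fu[q] - k_beta * B[q] +
             Psi0 * (fnuc + fsev + I_beta * basal[q] +
                     IS_beta * son * stim[q]);
    dA[q] += -A[q] * vbulk * div_d[q] - k_A * A[q] - fnuc +
             I_A * basal[q] + IS_A * son * stim[q];
    dC[q] += -C[q] * vbulk * div_d[q] - k_C * C[q] - fsev +
             I_C * basal[q] + IS_C * son * stim[q];
  }
  return List::create(_["B"] = dB, _["A"] = dA, _["C"] = dC);
}
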