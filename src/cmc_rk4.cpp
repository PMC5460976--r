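#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of the canonical-microcircuit network.
//
// State: voltages V and currents I for four populations per source,
// stored as 4 x N matrices with row order SS, SP, II, DP.
// Each population follows damped second-order synaptic kinetics
//   dV/dt = I,  dI/dt = kappa * drive - 2 kappa I - kappa^2 V
// with population-specific drives assembled from the intrinsic coupling
// gains (gamma), the extrinsic forward/backward matrices (AF, AB) and the
// exogenous thalamic input C * u(t) arriving at spiny stellate cells.
//
// gamma row order (10 coupling pairs):
//  0 SS->SS, 1 SP->SS, 2 II->SS, 3 SS->II, 4 DP->II,
//  5 II->II, 6 SS->SP, 7 SP->SP, 8 DP->DP, 9 II->DP

static inline double sigm(double v, double r) {
  return 1.0 / (1.0 + std::exp(-r * v)) - 0.5;
}

static void cmc_deriv(const std::vector<double>& V, const std::vector<double>& I,
                      std::vector<double>& dV, std::vector<double>& dI,
                      const NumericMatrix& kappa, const NumericMatrix& gamma,
                      const NumericMatrix& AF, const NumericMatrix& AB,
                      const NumericVector& C, double r, double u, int N) {
  // population row indices
  const int SS = 0, SP = 1, II = 2, DP = 3;
  std::vector<double> sV(4 * N);
  for (int p = 0; p < 4; ++p)
    for (int i = 0; i < N; ++i)
      sV[p + 4 * i] = sigm(V[p + 4 * i], r);

  for (int i = 0; i < N; ++i) {
    double fwd = 0.0, bwd = 0.0;
    for (int j = 0; j < N; ++j) {
      fwd += AF(i, j) * sV[SP + 4 * j];
      bwd += AB(i, j) * sV[DP + 4 * j];
    }
    const double sss = sV[SS + 4 * i], ssp = sV[SP + 4 * i];
    const double sii = sV[II + 4 * i], sdp = sV[DP + 4 * i];

    double drive[4];
    drive[SS] = fwd - gamma(0, i) * sss - gamma(1, i) * ssp -
                gamma(2, i) * sii + C[i] * u;
    drive[II] = -bwd + gamma(3, i) * sss + gamma(4, i) * sdp -
                gamma(5, i) * sii;
    drive[SP] = -bwd + gamma(6, i) * sss - gamma(7, i) * ssp;
    drive[DP] = fwd - gamma(8, i) * sdp - gamma(9, i) * sii;

    for (int p = 0; p < 4; ++p) {
      const int k = p + 4 * i;
      const double kp = kappa(p, i);
      dV[k] = I[k];
      dI[k] = kp * drive[p] - 2.0 * kp * I[k] - kp * kp * V[k];
    }
  }
}

// [[Rcpp::export(name = ".cmc_rk4")]]
List cmc_rk4(NumericMatrix kappa, NumericMatrix gamma,
             NumericMatrix AF, NumericMatrix AB, NumericVector C,
             double r, NumericVector u_half, double dt, int nsteps,
             double vmax) {
  const int N = kappa.ncol();
  const int M = 4 * N;
  if (u_half.size() != 2 * nsteps + 1)
    stop("input samples must be given at half-step resolution");

  std::vector<double> V(M, 0.0), I(M, 0.0);
  std::vector<double> kV1(M), kI1(M), kV2(M), kI2(M), kV3(M), kI3(M),
      kV4(M), kI4(M), tV(M), tI(M);

  NumericVector out(M * (nsteps + 1));
  out.attr("dim") = IntegerVector::create(4, N, nsteps + 1);
  for (int k = 0; k < M; ++k) out[k] = 0.0;

  bool diverged = false;
  int div_step = -1;

  for (int s = 0; s < nsteps; ++s) {
    const double u0 = u_half[2 * s], um = u_half[2 * s + 1],
                 u1 = u_half[2 * s + 2];
    cmc_deriv(V, I, kV1, kI1, kappa, gamma, AF, AB, C, r, u0, N);
    for (int k = 0; k < M; ++k) {
      tV[k] = V[k] + 0.5 * dt * kV1[k];
      tI[k] = I[k] + 0.5 * dt * kI1[k];
    }
    cmc_deriv(tV, tI, kV2, kI2, kappa, gamma, AF, AB, C, r, um, N);
    for (int k = 0; k < M; ++k) {
      tV[k] = V[k] + 0.5 * dt * kV2[k];
      tI[k] = I[k] + 0.5 * dt * kI2[k];
    }
    cmc_deriv(tV, tI, kV3, kI3, kappa, gamma, AF, AB, C, r, um, N);
    for (int k = 0; k < M; ++k) {
      tV[k] = V[k] + dt * kV3[k];
      tI[k] = I[k] + dt * kI3[k];
    }
    cmc_deriv(tV, tI, kV4, kI4, kappa, gamma, AF, AB, C, r, u1, N);
    for (int k = 0; k < M; ++k) {
      V[k] += dt / 6.0 * (kV1[k] + 2.0 * kV2[k] + 2.0 * kV3[k] + kV4[k]);
      I[k] += dt / 6.0 * (kI1[k] + 2.0 * kI2[k] + 2.0 * kI3[k] + kI4[k]);
    }
    bool bad = false;
    for (int k = 0; k < M; ++k)
      if (!std::isfinite(V[k]) || std::fabs(V[k]) > vmax) { bad = true; break; }
    if (bad) { diverged = true; div_step = s + 1; break; }
    for (int k = 0; k < M; ++k) out[M * (s + 1) + k] = V[k];
  }

  return List::create(_["V"] = out, _["diverged"] = diverged,
                      _["step"] = div_step);
}
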