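#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-point-flux finite-volume diffusion on a triangle mesh.
// edges: interior edges as (i, j, w) with w = L_e / d_ij (shared-edge length
// over centroid distance); boundary edges carry no flux (zero-flux BC).
// rate_i = (D / area_i) * sum_e w_e (u_j - u_i)

static void fvm_rate(const double *u, double D, const int *ei, const int *ej,
                     const double *ew, int ne, const double *area, int nc,
                     double *rate) {
  for (int i = 0; i < nc; ++i) rate[i] = 0.0;
  if (D == 0.0) return;
  for (int e = 0; e < ne; ++e) {
    double f = ew[e] * (u[ej[e]] - u[ei[e]]);
    rate[ei[e]] += f;
    rate[ej[e]] -= f;
  }
  for (int i = 0; i < nc; ++i) rate[i] *= D / area[i];
}

// [[Rcpp::export]]
NumericVector cpp_fvm_rate(NumericVector u, double D, IntegerVector ei,
                           IntegerVector ej, NumericVector ew,
                           NumericVector area) {
  int nc = u.size(), ne = ei.size();
  NumericVector rate(nc);
  std::vector<int> i0(ne), j0(ne);
  for (int e = 0; e < ne; ++e) { i0[e] = ei[e] - 1; j0[e] = ej[e] - 1; }
  fvm_rate(u.begin(), D, i0.data(), j0.data(), ew.begin(), ne, area.begin(),
           nc, rate.begin());
  return rate;
}

// Linear BSW reaction rates with per-cell Fgf modulation:
//   dS = beta (k2 B - k3 W)
//   dB = beta (-k4eff S - k5 B + aB)
//   dW = beta (-k7eff S - k9 W + aW)
//   k4eff = k4 (1 - kF F),  k7eff = k7 / (1 - kF F)
static inline void bsw_reaction(double S, double B, double W, double F,
                                const double *p, double &dS, double &dB,
                                double &dW) {
  // p: beta k2 k3 k4 k5 k7 k9 aB aW kF
  double m = 1.0 - p[9] * F;
  double k4e = p[3] * m;
  double k7e = p[5] / m;
  dS = p[0] * (p[1] * B - p[2] * W);
  dB = p[0] * (-k4e * S - p[4] * B + p[7]);
  dW = p[0] * (-k7e * S - p[6] * W + p[8]);
}

// Heun (explicit trapezoidal) integration of the stochastic BSW system on a
// frozen mesh. Multiplicative Gaussian noise u <- u (1 + sd N(0,1)) applied
// per cell, per species, after each corrector step. Uses R's RNG stream so
// set.seed() makes runs reproducible. Snapshots of S/B/W are collected every
// `snap_every` steps (0 = only final state).
// [[Rcpp::export]]
List cpp_bsw_run(NumericVector S0, NumericVector B0, NumericVector W0,
                 NumericVector F, NumericVector params, double dt, int nsteps,
                 double noise_sd, bool clip_negative, int snap_every,
                 IntegerVector ei, IntegerVector ej, NumericVector ew,
                 NumericVector area, double DB, double DW) {
  int nc = S0.size(), ne = ei.size();
  std::vector<int> i0(ne), j0(ne);
  for (int e = 0; e < ne; ++e) { i0[e] = ei[e] - 1; j0[e] = ej[e] - 1; }
  std::vector<double> S(S0.begin(), S0.end()), B(B0.begin(), B0.end()),
      W(W0.begin(), W0.end());
  std::vector<double> dS1(nc), dB1(nc), dW1(nc), dS2(nc), dB2(nc), dW2(nc),
      Sp(nc), Bp(nc), Wp(nc), difB(nc), difW(nc);
  const double *p = params.begin();
  List snapsS, snapsB, snapsW;
  NumericVector snap_t;
  std::vector<double> tvec;
  RNGScope scope;
  long clip_events = 0;
  for (int step = 0; step < nsteps; ++step) {
    // predictor
    fvm_rate(B.data(), DB, i0.data(), j0.data(), ew.begin(), ne, area.begin(),
             nc, difB.data());
    fvm_rate(W.data(), DW, i0.data(), j0.data(), ew.begin(), ne, area.begin(),
             nc, difW.data());
    for (int i = 0; i < nc; ++i) {
      bsw_reaction(S[i], B[i], W[i], F[i], p, dS1[i], dB1[i], dW1[i]);
      dB1[i] += difB[i];
      dW1[i] += difW[i];
      Sp[i] = S[i] + dt * dS1[i];
      Bp[i] = B[i] + dt * dB1[i];
      Wp[i] = W[i] + dt * dW1[i];
    }
    // corrector
    fvm_rate(Bp.data(), DB, i0.data(), j0.data(), ew.begin(), ne, area.begin(),
             nc, difB.data());
    fvm_rate(Wp.data(), DW, i0.data(), j0.data(), ew.begin(), ne, area.begin(),
             nc, difW.data());
    for (int i = 0; i < nc; ++i) {
      bsw_reaction(Sp[i], Bp[i], Wp[i], F[i], p, dS2[i], dB2[i], dW2[i]);
      dB2[i] += difB[i];
      dW2[i] += difW[i];
      S[i] += 0.5 * dt * (dS1[i] + dS2[i]);
      B[i] += 0.5 * dt * (dB1[i] + dB2[i]);
      W[i] += 0.5 * dt * (dW1[i] + dW2[i]);
    }
    if (noise_sd > 0) {
      for (int i = 0; i < nc; ++i) {
        S[i] *= 1.0 + noise_sd * norm_rand();
        B[i] *= 1.0 + noise_sd * norm_rand();
        W[i] *= 1.0 + noise_sd * norm_rand();
      }
    }
    if (clip_negative) {
      for (int i = 0; i < nc; ++i) {
        if (S[i] < 0) { S[i] = 0; ++clip_events; }
        if (B[i] < 0) { B[i] = 0; ++clip_events; }
        if (W[i] < 0) { W[i] = 0; ++clip_events; }
      }
    }
    if ((snap_every > 0 && (step + 1) % snap_every == 0) ||
        step == nsteps - 1) {
      snapsS.push_back(NumericVector(S.begin(), S.end()));
      snapsB.push_back(NumericVector(B.begin(), B.end()));
      snapsW.push_back(NumericVector(W.begin(), W.end()));
      tvec.push_back((step + 1) * dt);
    }
  }
  // instability check
  bool finite = true;
  for (int i = 0; i < nc; ++i)
    if (!R_finite(S[i]) || !R_finite(B[i]) || !R_finite(W[i])) finite = false;
  return List::create(_["S"] = snapsS, _["B"] = snapsB, _["W"] = snapsW,
                      _["time"] = wrap(tvec), _["finite"] = finite,
                      _["clip_events"] = (double)clip_events);
}

// Pure single-species diffusion with Heun stepping (used for dye transport
// tests and the conservation suite).
// [[Rcpp::export]]
NumericVector cpp_diffuse(NumericVector u0, double D, double dt, int nsteps,
                          IntegerVector ei, IntegerVector ej, NumericVector ew,
                          NumericVector area) {
  int nc = u0.size(), ne = ei.size();
  std::vector<int> i0(ne), j0(ne);
  for (int e = 0; e < ne; ++e) { i0[e] = ei[e] - 1; j0[e] = ej[e] - 1; }
  std::vector<double> u(u0.begin(), u0.end()), r1(nc), r2(nc), up(nc);
  for (int s = 0; s < nsteps; ++s) {
    fvm_rate(u.data(), D, i0.data(), j0.data(), ew.begin(), ne, area.begin(),
             nc, r1.data());
    for (int i = 0; i < nc; ++i) up[i] = u[i] + dt * r1[i];
    fvm_rate(up.data(), D, i0.data(), j0.data(), ew.begin(), ne, area.begin(),
             nc, r2.data());
    for (int i = 0; i < nc; ++i) u[i] += 0.5 * dt * (r1[i] + r2[i]);
  }
  return NumericVector(u.begin(), u.end());
}
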