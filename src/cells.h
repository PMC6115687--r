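#ifndef ATRIASIM_CELLS_H
#define ATRIASIM_CELLS_H

#include <cmath>

// Detailed human atrial ionic model (Courtemanche-family formulation).
// State layout (21):
//  0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
// 10 d, 11 f, 12 fca, 13 u, 14 v, 15 w, 16 Nai, 17 Ki, 18 Cai, 19 Caup, 20 Carel
// Parameter layout (13):
//  0 gNa, 1 gK1, 2 gto, 3 gKr, 4 gKs, 5 gCaL, 6 gKurScale,
//  7 gbNa, 8 gbCa, 9 INaKmax, 10 INaCamax, 11 IpCamax, 12 Cm
#define ATRIA_N_STATE 21
#define ATRIA_N_PARAM 13

// Phenomenological two-variable excitable model (Mitchell-Schaeffer style),
// voltage mapped to mV. State layout (2): 0 V, 1 hgate.
// Parameter layout (7): 0 tauIn, 1 tauOut, 2 tauOpen, 3 tauClose,
//                       4 vGate, 5 Vrest, 6 Vamp
#define PHEN_N_STATE 2
#define PHEN_N_PARAM 7

namespace atriasim {

const double RGAS = 8.3143, TEMP = 310.0, FARADAY = 96.4867;
const double KO = 5.4, NAO = 140.0, CAO = 1.8;
const double VCELL_I = 13668.0, VUP = 1109.52, VREL = 96.48;
const double KREL = 30.0, IUP_MAX = 0.005, K_UP = 0.00092, CAUP_MAX = 15.0;
const double CMDN_MAX = 0.05, TRPN_MAX = 0.07, CSQN_MAX = 10.0;
const double KM_CMDN = 0.00238, KM_TRPN = 0.0005, KM_CSQN = 0.8;
const double KQ10 = 3.0;
const double KM_NAI = 10.0, KM_KO = 1.5;
const double KM_NA = 87.5, KM_CA = 1.38, K_SAT = 0.1, GAMMA_NCX = 0.35;
const double TAU_TR = 180.0, TAU_FCA = 2.0, TAU_U = 8.0;

inline double rl_update(double y, double yinf, double tau, double dt) {
  // Rush-Larsen exponential gate update
  return yinf - (yinf - y) * std::exp(-dt / tau);
}

inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

// One reaction step: advances `s` in place by dt with external current
// istim (pA/pF, depolarizing positive). Returns dV/dt (mV/ms).
inline double crn_step(double *s, const double *p, double istim, double dt) {
  const double V = s[0];
  const double FRT = FARADAY / (RGAS * TEMP);
  const double Cm = p[12];

  const double ENa = (1.0 / FRT) * std::log(NAO / s[16]);
  const double EK  = (1.0 / FRT) * std::log(KO / s[17]);
  const double ECa = (0.5 / FRT) * std::log(CAO / s[18]);

  // --- currents (pA/pF) ---
  const double INa  = p[0] * s[1] * s[1] * s[1] * s[2] * s[3] * (V - ENa);
  const double IK1  = p[1] * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  const double Ito  = p[2] * s[4] * s[4] * s[4] * s[5] * (V - EK);
  const double gKur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  const double IKur = p[6] * gKur * s[6] * s[6] * s[6] * s[7] * (V - EK);
  const double IKr  = p[3] * s[8] * (V - EK) / (1.0 + std::exp((V + 15.0) / 22.4));
  const double IKs  = p[4] * s[9] * s[9] * (V - EK);
  const double ICaL = p[5] * s[10] * s[11] * s[12] * (V - 65.0);

  const double sigma = (std::exp(NAO / 67.3) - 1.0) / 7.0;
  const double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * FRT) +
                             0.0365 * sigma * std::exp(-V * FRT));
  const double INaK = p[9] * fNaK / (1.0 + std::pow(KM_NAI / s[16], 1.5)) *
                      KO / (KO + KM_KO);

  const double expg  = std::exp(GAMMA_NCX * V * FRT);
  const double expg1 = std::exp((GAMMA_NCX - 1.0) * V * FRT);
  const double INaCa = p[10] *
      (expg * s[16] * s[16] * s[16] * CAO - expg1 * NAO * NAO * NAO * s[18]) /
      ((KM_NA * KM_NA * KM_NA + NAO * NAO * NAO) * (KM_CA + CAO) *
       (1.0 + K_SAT * expg1));

  const double IbNa = p[7] * (V - ENa);
  const double IbCa = p[8] * (V - ECa);
  const double IpCa = p[11] * s[18] / (0.0005 + s[18]);

  const double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa +
                      INaK + INaCa + IbNa + IbCa;

  // --- SR fluxes (mM/ms) ---
  const double Irel  = KREL * s[13] * s[13] * s[14] * s[15] * (s[20] - s[18]);
  const double Itr   = (s[19] - s[20]) / TAU_TR;
  const double Iup   = IUP_MAX / (1.0 + K_UP / s[18]);
  const double Ileak = IUP_MAX * s[19] / CAUP_MAX;

  // --- gate kinetics ---
  double am, bm, ah, bh, aj, bj;
  if (std::fabs(V + 47.13) < 1e-7) am = 3.2;
  else am = 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  bm = 0.08 * std::exp(-V / 11.0);
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  const double minf = am / (am + bm), taum = 1.0 / (am + bm);
  const double hinf = ah / (ah + bh), tauh = 1.0 / (ah + bh);
  const double jinf = aj / (aj + bj), tauj = 1.0 / (aj + bj);

  const double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  const double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  const double tauoa = 1.0 / ((aoa + boa) * KQ10);
  const double oainf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  const double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  const double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  const double tauoi = 1.0 / ((aoi + boi) * KQ10);
  const double oiinf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));

  const double aua = aoa, bua = boa;
  const double tauua = 1.0 / ((aua + bua) * KQ10);
  const double uainf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  const double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  const double bui = std::exp((V - 158.0) / 16.0);
  const double tauui = 1.0 / ((aui + bui) * KQ10);
  const double uiinf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));

  double axr, bxr;
  if (std::fabs(V + 14.1) < 1e-7) axr = 0.0015;
  else axr = 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  if (std::fabs(V - 3.3328) < 1e-7) bxr = 3.7836118e-4;
  else bxr = 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  const double tauxr = 1.0 / (axr + bxr);
  const double xrinf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));

  double axs, bxs;
  if (std::fabs(V - 19.9) < 1e-7) { axs = 6.8e-4; bxs = 3.15e-4; }
  else {
    axs = 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
    bxs = 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  }
  const double tauxs = 0.5 / (axs + bxs);
  const double xsinf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));

  double taud;
  if (std::fabs(V + 10.0) < 1e-7) taud = 2.289551;
  else {
    const double e = std::exp(-(V + 10.0) / 6.24);
    taud = (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
  }
  const double dinf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  const double tauf = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  const double finf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  const double fcainf = 1.0 / (1.0 + s[18] / 0.00035);

  // CICR trigger
  const double Fn = 1e-12 * VREL * Irel -
                    (5e-13 / FARADAY) * (0.5 * ICaL * Cm - 0.2 * INaCa * Cm);
  const double uinf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  const double tauv = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  const double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double tauw;
  if (std::fabs(V - 7.9) < 1e-7) tauw = 6.0 / 1.3;
  else {
    const double e = std::exp(-(V - 7.9) / 5.0);
    tauw = 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
  }
  const double winf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));

  // --- concentration derivatives (currents converted pA/pF -> pA via Cm) ---
  const double dNai = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * Cm / (FARADAY * VCELL_I);
  const double dKi  = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * Cm / (FARADAY * VCELL_I);
  const double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * Cm / (2.0 * FARADAY * VCELL_I) +
                    (VUP * (Ileak - Iup) + Irel * VREL) / VCELL_I;
  const double B2 = 1.0 + TRPN_MAX * KM_TRPN / ((s[18] + KM_TRPN) * (s[18] + KM_TRPN)) +
                    CMDN_MAX * KM_CMDN / ((s[18] + KM_CMDN) * (s[18] + KM_CMDN));
  const double dCaup  = Iup - Ileak - Itr * VREL / VUP;
  const double dCarel = (Itr - Irel) /
      (1.0 + CSQN_MAX * KM_CSQN / ((s[20] + KM_CSQN) * (s[20] + KM_CSQN)));

  const double dV = -Iion + istim;

  // --- advance ---
  s[0]  = V + dt * dV;
  s[1]  = clamp01(rl_update(s[1], minf, taum, dt));
  s[2]  = clamp01(rl_update(s[2], hinf, tauh, dt));
  s[3]  = clamp01(rl_update(s[3], jinf, tauj, dt));
  s[4]  = clamp01(rl_update(s[4], oainf, tauoa, dt));
  s[5]  = clamp01(rl_update(s[5], oiinf, tauoi, dt));
  s[6]  = clamp01(rl_update(s[6], uainf, tauua, dt));
  s[7]  = clamp01(rl_update(s[7], uiinf, tauui, dt));
  s[8]  = clamp01(rl_update(s[8], xrinf, tauxr, dt));
  s[9]  = clamp01(rl_update(s[9], xsinf, tauxs, dt));
  s[10] = clamp01(rl_update(s[10], dinf, taud, dt));
  s[11] = clamp01(rl_update(s[11], finf, tauf, dt));
  s[12] = clamp01(rl_update(s[12], fcainf, TAU_FCA, dt));
  s[13] = clamp01(rl_update(s[13], uinf, TAU_U, dt));
  s[14] = clamp01(rl_update(s[14], vinf, tauv, dt));
  s[15] = clamp01(rl_update(s[15], winf, tauw, dt));
  s[16] += dt * dNai;
  s[17] += dt * dKi;
  s[18] += dt * (B1 / B2);
  s[19] += dt * dCaup;
  s[20] += dt * dCarel;
  return dV;
}

// Phenomenological model step. istim in pA/pF is mapped onto the
// normalized activation variable via the voltage amplitude.
inline double phen_step(double *s, const double *p, double istim, double dt) {
  const double tauIn = p[0], tauOut = p[1], tauOpen = p[2], tauClose = p[3];
  const double vGate = p[4], Vrest = p[5], Vamp = p[6];
  double u = (s[0] - Vrest) / Vamp;
  if (u < 0.0) u = 0.0;
  const double du = s[1] * u * u * (1.0 - u) / tauIn - u / tauOut + istim / Vamp;
  const double hinf = (u < vGate) ? 1.0 : 0.0;
  const double tauh = (u < vGate) ? tauOpen : tauClose;
  s[1] = clamp01(rl_update(s[1], hinf, tauh, dt));
  const double dV = Vamp * du;
  s[0] += dt * dV;
  return dV;
}

inline int model_n_state(int modelId) { return modelId == 0 ? ATRIA_N_STATE : PHEN_N_STATE; }

inline double model_step(int modelId, double *s, const double *p, double istim, double dt) {
  return modelId == 0 ? crn_step(s, p, istim, dt) : phen_step(s, p, istim, dt);
}

} // namespace atriasim

#endif
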