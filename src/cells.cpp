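// Single-cell integration driver shared by tests, APD/ERP measurement and
// calibration utilities. Tissue coupling lives in solver.cpp.
#include <Rcpp.h>
#include "cells.h"
using namespace Rcpp;
using namespace atriasim;

static const char *CRN_STATE_NAMES[ATRIA_N_STATE] = {
  "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
  "d", "f", "fca", "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel"};
static const char *PHEN_STATE_NAMES[PHEN_N_STATE] = {"V", "hgate"};

// [[Rcpp::export(name = ".cellStateNames")]]
CharacterVector cell_state_names(int modelId) {
  int n = model_n_state(modelId);
  CharacterVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = modelId == 0 ? CRN_STATE_NAMES[i] : PHEN_STATE_NAMES[i];
  return out;
}

// Integrate a single cell from t0 for `duration` ms. Stimuli are rows of
// (onset, dur, amp) in ms / pA/pF. V is sampled every `sampleEvery` ms.
// [[Rcpp::export(name = ".cellRun")]]
List cell_run(int modelId, NumericVector params, NumericVector state0,
              double dt, double duration, double t0,
              NumericVector stimOnset, NumericVector stimDur, NumericVector stimAmp,
              double sampleEvery) {
  const int nState = model_n_state(modelId);
  if ((int)state0.size() != nState) stop("state vector has wrong length");
  std::vector<double> s(state0.begin(), state0.end());
  const int nStep = (int)std::llround(duration / dt);
  const int nStim = stimOnset.size();
  const int sampEvery = std::max(1, (int)std::llround(sampleEvery / dt));
  std::vector<double> times, vtrace;
  times.reserve(nStep / sampEvery + 2);
  vtrace.reserve(nStep / sampEvery + 2);
  double dvdtMax = -1e300, vMax = -1e300;
  times.push_back(t0); vtrace.push_back(s[0]);
  for (int k = 0; k < nStep; ++k) {
    const double t = t0 + k * dt;
    double istim = 0.0;
    for (int j = 0; j < nStim; ++j)
      if (t >= stimOnset[j] && t < stimOnset[j] + stimDur[j]) istim += stimAmp[j];
    const double dv = model_step(modelId, s.data(), REAL(params), istim, dt);
    if (!std::isfinite(s[0])) {
      int bad = 0;
      for (int i = 0; i < nState; ++i) if (!std::isfinite(s[i])) { bad = i; break; }
      stop("non-finite state variable '%s' at t = %.3f ms",
           modelId == 0 ? CRN_STATE_NAMES[bad] : PHEN_STATE_NAMES[bad], t);
    }
    if (dv > dvdtMax) dvdtMax = dv;
    if (s[0] > vMax) vMax = s[0];
    if ((k + 1) % sampEvery == 0) {
      times.push_back(t0 + (k + 1) * dt);
      vtrace.push_back(s[0]);
    }
  }
  return List::create(
    _["time"] = NumericVector(times.begin(), times.end()),
    _["V"] = NumericVector(vtrace.begin(), vtrace.end()),
    _["dVdtMax"] = dvdtMax,
    _["Vmax"] = vMax,
    _["finalState"] = NumericVector(s.begin(), s.end()),
    _["tEnd"] = t0 + nStep * dt);
}
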