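// Explicit operator-splitting monodomain stepper on an active-node list.
// Reaction substep: ionic model (Rush-Larsen gates + forward Euler).
// Diffusion substep: explicit finite differences of div(D grad V) with a
// 7-point face stencil plus centred cross-derivative terms; links to
// missing/inert neighbours are dropped, which realizes zero-flux boundaries.
#include <Rcpp.h>
#include "cells.h"
using namespace Rcpp;
using namespace atriasim;

// faceNb: nAct x 6 matrix of 0-based neighbour node indices (-1 if none),
// columns ordered (+x, -x, +y, -y, +z, -z).
// D6: nAct x 6 tensor components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), mm^2/ms.
// stimNodes: list parallel to stimOnset/... of 0-based node index vectors.
// [[Rcpp::export(name = ".monodomainRun")]]
List monodomain_run(IntegerMatrix faceNb, NumericMatrix D6,
                    IntegerVector typeIdx, List paramsList, int modelId,
                    NumericMatrix stateInit, double h, double dt,
                    double duration, double t0,
                    NumericVector stimOnset, NumericVector stimDur,
                    NumericVector stimAmp, List stimNodes,
                    double sampleEvery, double thresholdV) {
  const int nAct = faceNb.nrow();
  const int nState = model_n_state(modelId);
  if (stateInit.nrow() != nState || stateInit.ncol() != nAct)
    stop("state matrix must be nState x nActive");

  // copy state into contiguous working memory (node-major)
  std::vector<double> S((size_t)nAct * nState);
  for (int i = 0; i < nAct; ++i)
    for (int k = 0; k < nState; ++k) S[(size_t)i * nState + k] = stateInit(k, i);

  const int nPar = paramsList.size();
  std::vector<std::vector<double>> pars(nPar);
  for (int i = 0; i < nPar; ++i) {
    NumericVector pv = paramsList[i];
    pars[i] = std::vector<double>(pv.begin(), pv.end());
  }

  std::vector<int> nb((size_t)nAct * 6);
  for (int i = 0; i < nAct; ++i)
    for (int k = 0; k < 6; ++k) nb[(size_t)i * 6 + k] = faceNb(i, k);

  std::vector<double> D((size_t)nAct * 6);
  bool anyCross = false;
  for (int i = 0; i < nAct; ++i)
    for (int k = 0; k < 6; ++k) {
      D[(size_t)i * 6 + k] = D6(i, k);
      if (k >= 3 && std::fabs(D6(i, k)) > 1e-14) anyCross = true;
    }

  std::vector<double> V(nAct), Vnew(nAct), istim(nAct);
  for (int i = 0; i < nAct; ++i) V[i] = S[(size_t)i * nState];

  const int nStep = (int)std::llround(duration / dt);
  const int nStim = stimOnset.size();
  std::vector<std::vector<int>> stimIdx(nStim);
  for (int j = 0; j < nStim; ++j) {
    IntegerVector v = stimNodes[j];
    stimIdx[j] = std::vector<int>(v.begin(), v.end());
  }

  const int sampEvery = std::max(1, (int)std::llround(sampleEvery / dt));
  const int nSamp = nStep / sampEvery + 1;
  NumericMatrix Vsamp(nAct, nSamp);
  std::vector<double> sampTimes;
  sampTimes.reserve(nSamp);
  int sampCol = 0;
  for (int i = 0; i < nAct; ++i) Vsamp(i, 0) = V[i];
  sampTimes.push_back(t0);
  ++sampCol;

  std::vector<int> crossNode;
  std::vector<double> crossTime;
  std::vector<double> Vprev(V); // committed voltage at end of previous step
  const double inv_h2 = 1.0 / (h * h);

  for (int k = 0; k < nStep; ++k) {
    const double t = t0 + k * dt;

    // stimulus accumulation
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int j = 0; j < nStim; ++j)
      if (t >= stimOnset[j] && t < stimOnset[j] + stimDur[j])
        for (int idx : stimIdx[j]) istim[idx] += stimAmp[j];

    // reaction substep
    for (int i = 0; i < nAct; ++i) {
      double *s = &S[(size_t)i * nState];
      model_step(modelId, s, pars[typeIdx[i]].data(), istim[i], dt);
      V[i] = s[0];
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential at node %d, t = %.3f ms", i + 1, t);
    }

    // diffusion substep (explicit)
    for (int i = 0; i < nAct; ++i) {
      const int *nbi = &nb[(size_t)i * 6];
      const double *Di = &D[(size_t)i * 6];
      double lap = 0.0;
      const double Vi = V[i];
      for (int a = 0; a < 3; ++a) {
        const int np = nbi[2 * a], nm = nbi[2 * a + 1];
        if (np >= 0) lap += 0.5 * (Di[a] + D[(size_t)np * 6 + a]) * (V[np] - Vi) * inv_h2;
        if (nm >= 0) lap += 0.5 * (Di[a] + D[(size_t)nm * 6 + a]) * (V[nm] - Vi) * inv_h2;
      }
      if (anyCross) {
        // first derivative of V along axis b at node j: central where both
        // neighbours exist, one-sided at boundaries (narrow bundles would
        // otherwise lose most of their cross-term diffusion)
        const double inv_h = 1.0 / h, inv_2h = 0.5 / h;
        auto dVax = [&](int j, int b) -> double {
          const int *nbj = &nb[(size_t)j * 6];
          const int p = nbj[2 * b], m = nbj[2 * b + 1];
          if (p >= 0 && m >= 0) return (V[p] - V[m]) * inv_2h;
          if (p >= 0) return (V[p] - V[j]) * inv_h;
          if (m >= 0) return (V[j] - V[m]) * inv_h;
          return 0.0;
        };
        // pairs (axis a, axis b, component index c): (x,y,3) (x,z,4) (y,z,5)
        static const int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2}, pc[3] = {3, 4, 5};
        for (int q = 0; q < 3; ++q) {
          const int a = pa[q], b = pb[q], c = pc[q];
          // d/da ( Dab dV/db )
          {
            const int ap = nbi[2 * a], am = nbi[2 * a + 1];
            const double Fi = Di[c] * dVax(i, b);
            if (ap >= 0 && am >= 0)
              lap += (D[(size_t)ap * 6 + c] * dVax(ap, b) -
                      D[(size_t)am * 6 + c] * dVax(am, b)) * inv_2h;
            else if (ap >= 0)
              lap += (D[(size_t)ap * 6 + c] * dVax(ap, b) - Fi) * inv_h;
            else if (am >= 0)
              lap += (Fi - D[(size_t)am * 6 + c] * dVax(am, b)) * inv_h;
          }
          // d/db ( Dab dV/da )
          {
            const int bp = nbi[2 * b], bm = nbi[2 * b + 1];
            const double Fi = Di[c] * dVax(i, a);
            if (bp >= 0 && bm >= 0)
              lap += (D[(size_t)bp * 6 + c] * dVax(bp, a) -
                      D[(size_t)bm * 6 + c] * dVax(bm, a)) * inv_2h;
            else if (bp >= 0)
              lap += (D[(size_t)bp * 6 + c] * dVax(bp, a) - Fi) * inv_h;
            else if (bm >= 0)
              lap += (Fi - D[(size_t)bm * 6 + c] * dVax(bm, a)) * inv_h;
          }
        }
      }
      Vnew[i] = Vi + dt * lap;
    }

    // commit diffusion update, log upward threshold crossings
    const double tNew = t0 + (k + 1) * dt;
    for (int i = 0; i < nAct; ++i) {
      S[(size_t)i * nState] = Vnew[i];
      if (Vprev[i] < thresholdV && Vnew[i] >= thresholdV) {
        const double frac = (thresholdV - Vprev[i]) / (Vnew[i] - Vprev[i]);
        crossNode.push_back(i + 1);
        crossTime.push_back(tNew - dt + frac * dt);
      }
      Vprev[i] = Vnew[i];
      V[i] = Vnew[i];
    }

    if ((k + 1) % sampEvery == 0 && sampCol < nSamp) {
      for (int i = 0; i < nAct; ++i) Vsamp(i, sampCol) = V[i];
      sampTimes.push_back(tNew);
      ++sampCol;
    }
    if (k % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix finalState(nState, nAct);
  for (int i = 0; i < nAct; ++i)
    for (int kk = 0; kk < nState; ++kk) finalState(kk, i) = S[(size_t)i * nState + kk];

  if (sampCol < nSamp) Vsamp = Vsamp(_, Range(0, sampCol - 1));
  return List::create(
    _["times"] = NumericVector(sampTimes.begin(), sampTimes.end()),
    _["V"] = Vsamp,
    _["crossNode"] = IntegerVector(crossNode.begin(), crossNode.end()),
    _["crossTime"] = NumericVector(crossTime.begin(), crossTime.end()),
    _["finalState"] = finalState,
    _["tEnd"] = t0 + nStep * dt);
}
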