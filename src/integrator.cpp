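#include <Rcpp.h>
using namespace Rcpp;

// Adaptive leaky integrate-and-fire integrator with stylized AP templates.
//
// State: membrane voltage V [mV], adaptation current w [pA], spike-triggered
// AHP conductance gAhp [nS], Ih-like activation m (0..1) and A-type-K-like
// inactivation hA (0..1; de-inactivated by hyperpolarization, so it delays
// the first spike with a ramping depolarization and gives postinhibitory
// hypoexcitability).
// Units: conductances nS, currents pA, capacitance pF, time ms, voltage mV
// (nS * mV = pA; pA / pF = mV/ms).
//
// Between spikes V follows exponential Euler on
//   C dV/dt = gL (EL - V) + gAhp (EAhp - V) + gH m (EH - V)
//             + gA hA (EA - V) + Iext(t) - w.
// When V crosses vTh a raised-cosine AP template is pasted: rise from vTh to
// vTh + amp over riseMs, fall back to vTh over fallMs, where
//   amp = apAmp0 + droop * Iext(onset)   (droop <= 0, amplitude droop).
// After the template V restarts at vReset, w += bAdapt, gAhp += gAhpStep.
//
// [[Rcpp::export]]
List simulate_trace_cpp(NumericVector Iext, double dt, List par) {
  const int n = Iext.size();
  const double gL = par["gL"], C = par["C"], EL = par["EL"];
  const double vTh = par["vTh"], vReset = par["vReset"];
  const double aAdapt = par["aAdapt"], tauW = par["tauW"], bAdapt = par["bAdapt"];
  const double gAhpStep = par["gAhpStep"], tauAhp = par["tauAhp"], EAhp = par["EAhp"];
  const double gH = par["gH"], tauH = par["tauH"];
  const double vHalfH = par["vHalfH"], kH = par["kH"], EH = par["EH"];
  const double gA = par["gA"], tauA = par["tauA"];
  const double tauArec = par["tauArec"];
  const double vHalfA = par["vHalfA"], kA = par["kA"], EA = par["EA"];
  const double droop = par["droop"], apAmp0 = par["apAmp0"];
  const double riseMs = par["riseMs"], fallMs = par["fallMs"];
  const double v0 = par["v0"];

  const int nR = std::max(1, (int) std::lround(riseMs / dt));
  const int nF = std::max(1, (int) std::lround(fallMs / dt));
  const double decW = std::exp(-dt / tauW);
  const double decAhp = std::exp(-dt / tauAhp);
  // gating variables are slow (tau >= 15 ms); update them on a 1-ms cadence
  const int gateEvery = std::max(1, (int) std::lround(1.0 / dt));
  const double gdt = gateEvery * dt;
  const double decH = std::exp(-gdt / tauH);
  const double decA = std::exp(-gdt / tauA);        // inactivation (depol.)
  const double decArec = std::exp(-gdt / tauArec);  // recovery (hyperpol.)

  NumericVector V(n);
  std::vector<double> spikeT, spikeI, spikeAmp;

  double v = v0;
  double w = 0.0;
  double gAhp = 0.0;
  double m = 1.0 / (1.0 + std::exp((v0 - vHalfH) / kH));
  double hA = 1.0 / (1.0 + std::exp((v0 - vHalfA) / kA));

  int i = 0;
  while (i < n) {
    V[i] = v;
    if (v >= vTh) {
      // paste AP template; onset sample i carries the threshold voltage
      double amp = apAmp0 + droop * Iext[i];
      if (amp < 5.0) amp = 5.0;
      spikeT.push_back(i * dt);
      spikeI.push_back(Iext[i]);
      spikeAmp.push_back(amp);
      int j;
      for (j = 0; j <= nR && i + j < n; ++j)
        V[i + j] = vTh + amp * 0.5 * (1.0 - std::cos(M_PI * j / nR));
      for (j = 1; j <= nF && i + nR + j < n; ++j)
        V[i + nR + j] = vTh + amp * 0.5 * (1.0 + std::cos(M_PI * j / nF));
      int nTemp = nR + nF;
      // decay auxiliary states across the template duration
      w = w * std::exp(-nTemp * dt / tauW);
      gAhp = gAhp * std::exp(-nTemp * dt / tauAhp);
      m = m * std::exp(-nTemp * dt / tauH);
      hA = hA * std::exp(-nTemp * dt / tauA);
      w += bAdapt;
      gAhp += gAhpStep;
      v = vReset;
      i += nTemp + 1;
      continue;
    }
    // exponential Euler on V with frozen conductances over dt
    const double gHm = gH * m;
    const double gAh = gA * hA;
    const double gTot = gL + gAhp + gHm + gAh;
    const double vInf = (gL * EL + gAhp * EAhp + gHm * EH + gAh * EA +
                         Iext[i] - w) / gTot;
    const double x = dt * gTot / C;
    // x is tiny (< ~0.05); the quadratic Taylor expansion of exp(-x) is
    // accurate to x^3/6, far below estimator tolerances
    const double ex = x < 0.1 ? 1.0 - x + 0.5 * x * x : std::exp(-x);
    v = vInf + (v - vInf) * ex;
    // auxiliary states (exponential relaxation toward instantaneous targets)
    const double wInf = aAdapt * (v - EL);
    w = wInf + (w - wInf) * decW;
    gAhp *= decAhp;
    if (i % gateEvery == 0) {
      const double mInf = 1.0 / (1.0 + std::exp((v - vHalfH) / kH));
      m = mInf + (m - mInf) * decH;
      // A-type inactivation is fast on depolarization, slow to recover
      const double hInf = 1.0 / (1.0 + std::exp((v - vHalfA) / kA));
      hA = hInf + (hA - hInf) * (hInf < hA ? decA : decArec);
    }
    ++i;
  }

  return List::create(_["v"] = V,
                      _["spike_t"] = wrap(spikeT),
                      _["spike_i"] = wrap(spikeI),
                      _["spike_amp"] = wrap(spikeAmp));
}

// Sliding-window OLS slope over a uniformly sampled series.
// Returns slope [units of y per unit of t] for every window start position
// (window of `nw` samples). Used by the AHP end-of-event criterion.
// [[Rcpp::export]]
NumericVector sliding_ols_slope_cpp(NumericVector y, double dt, int nw) {
  const int n = y.size();
  const int nOut = n - nw + 1;
  if (nOut < 1) return NumericVector(0);
  NumericVector out(nOut);
  // x = 0, dt, ..., (nw-1)dt within each window
  const double sx = dt * nw * (nw - 1) / 2.0;
  const double sxx = dt * dt * (nw - 1) * nw * (2 * nw - 1) / 6.0;
  const double denom = nw * sxx - sx * sx;
  double sy = 0.0, sxy = 0.0;
  for (int i = 0; i < nw; ++i) {
    sy += y[i];
    sxy += dt * i * y[i];
  }
  out[0] = (nw * sxy - sx * sy) / denom;
  for (int j = 1; j < nOut; ++j) {
    // shift window right: subtract y[j-1], re-reference x to window start
    sxy -= dt * sy;             // x -> x - dt for all previous points
    sxy += dt * (nw - 1) * y[j + nw - 1];
    sy += y[j + nw - 1] - y[j - 1];
    // note sxy update order: after x-shift, the removed point has x = -dt
    sxy += dt * y[j - 1];       // remove contribution (-dt)*y[j-1]
    out[j] = (nw * sxy - sx * sy) / denom;
  }
  return out;
}
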