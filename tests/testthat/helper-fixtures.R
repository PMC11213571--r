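# fixtures built in code: template spikes spliced at known times, analytic
# RC epochs, and independent brute-force oracles

# raised-cosine spike template rising well above the 5 V/s onset criterion
spikeTemplate <- function(rate, riseMs = 0.8, fallMs = 1.5, amp = 85,
                          vBase = -55) {
  nR <- round(riseMs / 1000 * rate)
  nF <- round(fallMs / 1000 * rate)
  c(vBase + amp * (1 - cos(pi * seq_len(nR) / nR)) / 2,
    vBase + amp * (1 + cos(pi * seq_len(nF) / nF)) / 2)
}

# splice k template spikes into a flat trace at known onset times (s)
spliceSpikes <- function(onsets, duration = 2, rate = 20000, vBase = -55,
                         noise = 0, amp = 85, riseMs = 0.8, fallMs = 1.5,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * rate)
  v <- rep(vBase, n) + if (noise > 0) rnorm(n, 0, noise) else 0
  tpl <- spikeTemplate(rate, riseMs, fallMs, amp, vBase)
  for (on in onsets) {
    i <- round(on * rate) + 1L
    idx <- i:(i + length(tpl) - 1L)
    idx <- idx[idx <= n]
    v[idx] <- tpl[seq_along(idx)]
  }
  Sweep(v, current = 0, samplingRate = rate)
}

# independent spike-count oracle: upward crossings of a fixed voltage level
peakCountOracle <- function(sweep, level = -10) {
  v <- sweep@voltage
  sum(v[-1] >= level & v[-length(v)] < level)
}

# independent brute-force AHP end: OLS slope in every window position,
# computed directly from the normal equations
bruteForceAhpEnd <- function(v, dt, troughIdx, endIdx, windowMs = 50,
                             thresholdVs = 0.005) {
  nw <- round(windowMs / 1000 / dt)
  x <- (seq_len(nw) - 1) * dt
  sx <- sum(x); sxx <- sum(x^2)
  for (j in troughIdx:(endIdx - nw + 1)) {
    y <- v[j:(j + nw - 1)]
    slope <- (nw * sum(x * y) - sx * sum(y)) / (nw * sxx - sx^2)  # mV/s
    if (abs(slope) <= thresholdVs * 1000) return(j)
  }
  NA_integer_
}

# analytic RC step-family epoch (optionally noisy)
rcStepEpoch <- function(R = 200, C = 100, amps = c(-125, -100, -75, -50,
                                                   -25, 25),
                        rate = 20000, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tg <- seq(0, 1.75 - 1 / rate, by = 1 / rate)
  sweeps <- lapply(amps, function(I) {
    v <- analyticRCResponse(R, C, I, tg)
    if (noise > 0) v <- v + rnorm(length(v), 0, noise)
    Sweep(v, current = ifelse(tg >= 0.25 & tg < 1.25, I, 0),
          samplingRate = rate, time = tg)
  })
  ProtocolEpoch("step_family", sweeps, holdingPotential = -60,
                stepOnset = 0.25, stepOffset = 1.25, amplitudes = amps)
}

# analytic RC brief-pulse epoch
rcPulseEpoch <- function(R = 200, C = 100, I = -50, rate = 20000,
                         noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tg <- seq(0, 0.75 - 1 / rate, by = 1 / rate)
  v <- analyticRCResponse(R, C, I, tg, onset = 0.2, offset = 0.205)
  if (noise > 0) v <- v + rnorm(length(v), 0, noise)
  sw <- Sweep(v, current = ifelse(tg >= 0.2 & tg < 0.205, I, 0),
              samplingRate = rate, time = tg)
  ProtocolEpoch("brief_hyperpolarizing_pulse", list(sw),
                holdingPotential = -60, stepOnset = 0.2, stepOffset = 0.205,
                amplitudes = I)
}

# minimal bundle around given epochs
toyBundle <- function(..., cellId = "toy") {
  SweepBundle(cellId, list(...))
}

# closed-form tonic LIF firing period (s) with template-paste refractoriness
lifPeriod <- function(R, C, I, EL = -60, vTh = -45, vReset = -55,
                      riseMs = 0.8, fallMs = 1.4, rate = 20000) {
  tauS <- R * C / 1e6
  dVinf <- I * R / 1000
  tmpl <- (round(riseMs / 1000 * rate) + round(fallMs / 1000 * rate) + 1) /
    rate
  tmpl + tauS * log((dVinf - (vReset - EL)) / (dVinf - (vTh - EL)))
}
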