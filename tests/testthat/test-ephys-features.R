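test_that("AP detection finds spliced spikes and nothing else", {
  # flat trace: no events
  flat <- Sweep(rep(-60, 20000), samplingRate = 20000)
  expect_equal(nrow(detectAPs(flat)), 0)

  # k template spikes at known times: k events, onsets within 0.2 ms
  onsets <- c(0.2, 0.55, 0.9, 1.3, 1.72)
  sw <- spliceSpikes(onsets)
  ev <- detectAPs(sw)
  expect_equal(nrow(ev), length(onsets))
  expect_true(all(abs(ev$t_onset - onsets) < 2e-4))
  expect_true(all(ev$t_onset < ev$t_peak & ev$t_peak < ev$t_offset))
  expect_true(all(ev$amplitude > 0))

  # same with measurement noise
  swn <- spliceSpikes(onsets, noise = 0.2, seed = 5)
  expect_equal(nrow(detectAPs(swn)), length(onsets))

  # sub-threshold slope: triangle rising at 4 V/s to -20 mV never qualifies
  rate <- 20000
  up <- seq(-60, -20, by = 4 / rate * 1000)   # 4 V/s = 4 mV/ms
  tri <- Sweep(c(rep(-60, 100), up, rev(up), rep(-60, 100)),
               samplingRate = rate)
  expect_equal(nrow(detectAPs(tri)), 0)
})

test_that("AP detection count agrees with a level-crossing oracle", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(0:6, 1)
    onsets <- sort(runif(k, 0.05, 1.8))
    if (length(onsets) > 1) onsets <- onsets[c(TRUE, diff(onsets) > 0.03)]
    sw <- spliceSpikes(onsets, noise = 0.15)
    expect_equal(nrow(detectAPs(sw)), peakCountOracle(sw))
  }
})

test_that("AP metrics follow the onset/peak/offset definitions", {
  ev <- data.frame(t_onset = 0.1, v_onset = -45, t_peak = 0.101,
                   v_peak = 35, t_offset = 0.102, v_offset = -45,
                   amplitude = 80, duration = 2, max_rise_rate = 150,
                   truncated = FALSE)
  m <- apMetrics(ev)
  expect_equal(m$amplitude, 80)      # -45 -> +35 mV
  expect_equal(m$duration, 2)        # onset-to-offset, not half-width

  # symmetric triangular spike: 1 ms up + 1 ms down = 2 ms duration
  rate <- 20000
  up <- seq(-50, 30, length.out = rate / 1000 + 1)
  sw <- Sweep(c(rep(-50, 200), up, rev(up)[-1], rep(-50, 200)),
              samplingRate = rate)
  ev2 <- detectAPs(sw)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration, 2, tolerance = 0.1)

  # simulator spike with analytically known peak
  p <- phenotypeParams("passive", noiseSd = 1e-9)
  cell <- simulateNeuron(p, scaledProtocols(p), seed = 3)
  steps <- epochOfKind(cell@bundle, "step_family")
  ev3 <- detectAPs(steps@sweeps[[length(steps@sweeps)]])
  expect_gt(nrow(ev3), 0)
  expect_true(all(abs(ev3$amplitude[!ev3$truncated] - 85) < 0.5))
})

test_that("AHP metrics match an exhaustive brute-force window scan", {
  rate <- 20000
  dt <- 1 / rate
  # exponential recovery v = vEnd - A exp(-t/tau_ahp), A = 10, tau = 30 ms
  n <- round(0.6 * rate)
  t <- (seq_len(n) - 1) * dt
  v <- -50 - 10 * exp(-t / 0.03)
  sw <- Sweep(v, samplingRate = rate)
  a <- ahpMetrics(sw, data.frame(t_offset = 0, v_offset = -50))
  expect_false(a$unbounded)
  expect_equal(a$amplitude, 10, tolerance = 1e-6)
  trough <- which.min(v)
  jBF <- bruteForceAhpEnd(v, dt, trough, n)
  expect_equal(a$t_end, t[jBF], tolerance = dt / 2)

  # flat segment after offset: amplitude 0, end at the first window
  vf <- rep(-55, n)
  af <- ahpMetrics(Sweep(vf, samplingRate = rate),
                   data.frame(t_offset = 0))
  expect_false(af$unbounded)
  expect_equal(af$amplitude, 0)
  expect_equal(af$t_end, af$t_trough, tolerance = 2 * dt)

  # 20-ms ISI: less than one 50-ms window of data -> unbounded
  au <- ahpMetrics(sw, data.frame(t_offset = 0), segmentEnd = 0.02)
  expect_true(au$unbounded)
  expect_true(is.na(au$duration))
})

test_that("AHP sliding window equals brute force on varied recoveries", {
  rate <- 10000
  dt <- 1 / rate
  set.seed(7)
  for (i in 1:12) {
    n <- round(0.45 * rate)
    t <- (seq_len(n) - 1) * dt
    tau <- runif(1, 0.015, 0.08)
    A <- runif(1, 2, 15)
    v <- -52 - A * exp(-t / tau) + rnorm(n, 0, 0.1)
    sw <- Sweep(v, samplingRate = rate)
    a <- ahpMetrics(sw, data.frame(t_offset = 0))
    trough <- which.min(v)
    jBF <- bruteForceAhpEnd(v, dt, trough, n)
    if (is.na(jBF)) {
      expect_true(a$unbounded)
    } else {
      expect_equal(a$t_end, t[jBF], tolerance = dt / 2)
    }
  }
})

test_that("spontaneous activity is classified from the zero-current epoch", {
  rate <- 20000
  set.seed(11)
  silent <- Sweep(rep(-55, 10 * rate) + rnorm(10 * rate, 0, 1),
                  samplingRate = rate)
  sp <- classifySpontaneous(silent)
  expect_false(sp$spontaneous)
  expect_equal(sp$resting_vm, -55, tolerance = 0.1)
  expect_true(is.na(sp$spont_rate))

  onsets <- seq(0.4, 9.6, length.out = 12)
  active <- spliceSpikes(onsets, duration = 10, noise = 0.2, seed = 2)
  sp2 <- classifySpontaneous(active)
  expect_true(sp2$spontaneous)
  expect_equal(sp2$spont_rate, 1.2)

  one <- spliceSpikes(5, duration = 10)
  sp3 <- classifySpontaneous(one)
  expect_true(sp3$spontaneous)
  expect_equal(sp3$spont_rate, 0.1)
})

test_that("rheobase is the smallest spiking step amplitude", {
  rate <- 20000
  mkStep <- function(amp, spikes) {
    base <- rep(-60, round(1.75 * rate))
    sw <- Sweep(base, current = ifelse(
      (seq_along(base) - 1) / rate >= 0.25 &
        (seq_along(base) - 1) / rate < 1.25, amp, 0), samplingRate = rate)
    if (spikes > 0) {
      sp <- spliceSpikes(seq(0.4, 1.1, length.out = spikes), duration = 1.75,
                         rate = rate, vBase = -60)
      sw@voltage <- sp@voltage
      sw@current <- ifelse(sw@time >= 0.25 & sw@time < 1.25, amp, 0)
    }
    sw
  }
  ep <- ProtocolEpoch("step_family",
                      list(mkStep(25, 0), mkStep(50, 1), mkStep(75, 2)),
                      holdingPotential = -60, stepOnset = 0.25,
                      stepOffset = 1.25, amplitudes = c(25, 50, 75))
  rb <- rheobase(ep)
  expect_equal(rb$value, 50)
  expect_equal(rb$status, "ok")

  epAll <- ProtocolEpoch("step_family",
                         list(mkStep(25, 1), mkStep(50, 2)),
                         holdingPotential = -60, stepOnset = 0.25,
                         stepOffset = 1.25, amplitudes = c(25, 50))
  rbAll <- rheobase(epAll)
  expect_equal(rbAll$value, 25)
  expect_equal(rbAll$status, "lower_bound_only")

  epNone <- ProtocolEpoch("step_family", list(mkStep(25, 0)),
                          holdingPotential = -60, stepOnset = 0.25,
                          stepOffset = 1.25, amplitudes = 25)
  expect_equal(rheobase(epNone)$status, "unresolved")
})

test_that("simulated LIF rheobase matches the closed form g(theta - EL)", {
  p <- phenotypeParams("passive")
  cell <- simulateNeuron(p, scaledProtocols(p), seed = 4)
  pan <- extractPanel(cell@bundle)
  truth <- groundTruth(cell)[["rheobase"]]
  amps <- epochOfKind(cell@bundle, "step_family")@amplitudes
  inc <- min(diff(sort(amps[amps > 0])))
  expect_lte(abs(featureValues(pan)[["rheobase"]] - truth), inc + 1e-9)
})

test_that("AP drop rate is the amplitude-vs-current regression slope", {
  rate <- 20000
  dur <- 2.5
  onsets <- c(0.9, 1.2, 1.5)
  amps <- c(80, 78, 76)
  n <- round(dur * rate)
  v <- rep(-55, n)
  tpl0 <- function(a) spikeTemplate(rate, amp = a, vBase = -55)
  for (k in seq_along(onsets)) {
    i <- round(onsets[k] * rate) + 1
    tpl <- tpl0(amps[k])
    v[i:(i + length(tpl) - 1)] <- tpl
  }
  t <- (seq_len(n) - 1) / rate
  cur <- ifelse(t >= 0.25 & t < 2.25, (t - 0.25) / 2 * 300, 0)
  sw <- Sweep(v, current = cur, samplingRate = rate, time = t)
  dr <- dropRate(sw)
  expect_equal(dr$status, "ok")
  # currents at onsets: 97.5, 142.5, 187.5 -> slope -2 mV / 45 pA
  expect_equal(dr$value, -2 / 45, tolerance = 0.01)

  # constant amplitudes: slope 0
  v2 <- rep(-55, n)
  for (on in onsets) {
    i <- round(on * rate) + 1
    tpl <- tpl0(80)
    v2[i:(i + length(tpl) - 1)] <- tpl
  }
  dr2 <- dropRate(Sweep(v2, current = cur, samplingRate = rate, time = t))
  expect_equal(dr2$value, 0, tolerance = 1e-6)

  # fewer than three APs: unresolved
  dr3 <- dropRate(spliceSpikes(c(0.4, 0.8)))
  expect_equal(dr3$status, "unresolved")
})

test_that("drop rate on simulated ramps recovers the droop coefficient", {
  p <- phenotypeParams("DA", noiseSd = 1e-9)
  cell <- simulateNeuron(p, scaledProtocols(p), seed = 6, targetRate = 2)
  ramp <- epochOfKind(cell@bundle, "ramp_family")
  dr <- dropRate(ramp@sweeps[[1]])
  expect_equal(dr$status, "ok")
  expect_equal(dr$value, p[["droop"]], tolerance = abs(p[["droop"]]) * 0.1)
})

test_that("delay to first spike uses the rate-matched sweep", {
  rate <- 20000
  mk <- function(onsets) {
    sp <- spliceSpikes(onsets, duration = 1.75, rate = rate, vBase = -60)
    sp@current <- ifelse(sp@time >= 0.25 & sp@time < 1.25, 50, 0)
    sp
  }
  # one spike 180 ms after step onset -> rate 1 Hz, delay 0.180
  ep <- ProtocolEpoch("step_family", list(mk(0.43)),
                      holdingPotential = -60, stepOnset = 0.25,
                      stepOffset = 1.25, amplitudes = 50)
  d <- delayToFirstSpike(ep, targetRate = 1)
  expect_lt(abs(d$value - 0.18), 2e-4)

  # spike exactly at step onset -> 0
  ep0 <- ProtocolEpoch("step_family", list(mk(0.25)),
                       holdingPotential = -60, stepOnset = 0.25,
                       stepOffset = 1.25, amplitudes = 50)
  expect_lt(abs(delayToFirstSpike(ep0, targetRate = 1)$value), 2e-4)

  # no sweep within the rate window -> unresolved
  ep3 <- ProtocolEpoch("step_family", list(mk(c(0.3, 0.5, 0.7))),
                       holdingPotential = -60, stepOnset = 0.25,
                       stepOffset = 1.25, amplitudes = 50)
  expect_equal(delayToFirstSpike(ep3, targetRate = 1)$status, "unresolved")
})

test_that("DA-like delay decreases with step amplitude", {
  p <- phenotypeParams("DA", noiseSd = 1e-9)
  ep <- scaledProtocols(p)[[2]]
  amps <- ep$amplitudes[ep$amplitudes > 0]
  amps <- amps[c(5, 8, 11)]
  delays <- vapply(amps, function(a) {
    s <- IntrinsicEphys:::.simulateEpochSweep(p, ep, a)
    st <- s$spikeT[s$spikeT >= ep$stepOnset]
    if (length(st)) st[1] - ep$stepOnset else NA_real_
  }, numeric(1))
  expect_true(all(diff(delays) < 0))
})

test_that("steady-state voltage is the mean over the second half-second", {
  rate <- 20000
  ep <- rcStepEpoch(R = 150, C = 100, amps = -100, rate = rate)
  ss <- steadyStateVoltage(ep@sweeps[[1]], 0.25, 1.25)
  expect_equal(ss$value, -75, tolerance = 0.1)   # -60 - 100*0.15
  expect_false(ss$spikes)

  # linear drift: mean of the window is its midpoint
  t <- seq(0, 1.75 - 1 / rate, by = 1 / rate)
  drift <- Sweep(-80 + 10 * t, current = 0, samplingRate = rate, time = t)
  sd2 <- steadyStateVoltage(drift, 0.25, 1.25)
  expect_equal(sd2$value, -80 + 10 * 1, tolerance = 1e-3)  # midpoint t = 1

  # spiking sweep: value computed but flagged
  sp <- spliceSpikes(c(0.9, 1.1), duration = 1.75, vBase = -60)
  ssp <- steadyStateVoltage(sp, 0.25, 1.25)
  expect_true(ssp$spikes)
  expect_true(is.finite(ssp$value))
})

test_that("input resistance fits qualifying steps only", {
  # exact linear V(I) with R = 150 MOhm
  ep <- rcStepEpoch(R = 150, C = 100, amps = c(-150, -100, -50, 50))
  ir <- inputResistance(ep)
  expect_equal(ir$value, 150, tolerance = 1e-6)

  # steps settling at -95 and -40 mV are excluded from the fit
  epWide <- rcStepEpoch(R = 200, C = 100,
                        amps = c(-175, -100, -50, 100))
  # steady states: -95, -80, -70, -40; only the middle two qualify
  irW <- inputResistance(epWide)
  expect_equal(irW$n_steps, 2)
  expect_equal(irW$value, 200, tolerance = 1e-6)

  # fewer than two qualifying steps
  ir1 <- inputResistance(rcStepEpoch(R = 200, C = 100, amps = -175))
  expect_equal(ir1$status, "unresolved")

  # analytic oracle with noise
  ep2 <- rcStepEpoch(R = 200, C = 100, noise = 0.2, seed = 9)
  expect_equal(inputResistance(ep2)$value, 200, tolerance = 1)
})

test_that("sag amplitude is the steady-state-minus-peak of deep steps", {
  rate <- 20000
  t <- seq(0, 1.75 - 1 / rate, by = 1 / rate)
  # dip to -96 in the first half-second, settle at -90
  v <- rep(-60, length(t))
  inStep <- t >= 0.25 & t < 1.25
  v[inStep] <- -90 - 6 * exp(-(t[inStep] - 0.25) / 0.08) *
    (1 - exp(-(t[inStep] - 0.25) / 0.01)) / 0.63
  v[inStep][1:2000] <- pmax(v[inStep][1:2000], -96)
  v[t >= 1.25] <- -60
  dip <- Sweep(v, current = ifelse(inStep, -150, 0), samplingRate = rate,
               time = t)
  ep <- ProtocolEpoch("step_family", list(dip), holdingPotential = -60,
                      stepOnset = 0.25, stepOffset = 1.25,
                      amplitudes = -150)
  sg <- sagAmplitude(ep)
  expect_equal(sg$status, "ok")
  expect_equal(sg$value, abs(min(v) - mean(v[t >= 0.75 & t <= 1.25])),
               tolerance = 0.05)

  # pure RC: no sag beyond noise
  epRC <- rcStepEpoch(R = 200, C = 100, amps = -160, noise = 0.1, seed = 3)
  sgRC <- sagAmplitude(epRC)
  expect_equal(sgRC$status, "ok")
  expect_lt(sgRC$value, 0.5)   # extreme-value bias of the windowed minimum

  # no step reaching -90 +/- 5 mV
  expect_equal(sagAmplitude(rcStepEpoch(amps = -50))$status, "unresolved")
})

test_that("sag increases with the Ih-like conductance", {
  sags <- vapply(c(0, 1.5, 3), function(g) {
    p <- phenotypeParams("DA", gH = g, noiseSd = 1e-9)
    cell <- simulateNeuron(p, scaledProtocols(p), seed = 5, targetRate = 2,
                           keepBundle = FALSE)
    groundTruth(cell)[["sag_amplitude"]]
  }, numeric(1))
  expect_true(all(diff(sags) > 0))
})

test_that("tau fitting recovers the membrane time constant", {
  # noiseless analytic RC: tau = 20 ms exactly
  ft <- fitTau(rcPulseEpoch(R = 200, C = 100))
  expect_equal(ft$status, "ok")
  expect_equal(ft$tau, 20, tolerance = 0.2)
  expect_equal(ft$K0, -60, tolerance = 0.05)

  # flat recovery (no pulse deflection) is degenerate
  rate <- 20000
  flat <- Sweep(rep(-60, round(0.75 * rate)), samplingRate = rate)
  epF <- ProtocolEpoch("brief_hyperpolarizing_pulse", list(flat),
                       holdingPotential = -60, stepOnset = 0.2,
                       stepOffset = 0.205, amplitudes = -50)
  expect_equal(fitTau(epF)$status, "unresolved")
})

test_that("tau fitting stays within 5% under 0.3 mV noise", {
  taus <- vapply(1:30, function(s)
    fitTau(rcPulseEpoch(R = 200, C = 100, noise = 0.3, seed = s))$tau,
    numeric(1))
  expect_lt(abs(mean(taus, na.rm = TRUE) - 20) / 20, 0.05)
})

test_that("capacitance is exactly tau over resistance in pF", {
  expect_equal(capacitanceFromTau(10, 100), 100)
  expect_equal(capacitanceFromTau(0, 100), 0)
  expect_true(is.na(capacitanceFromTau(NA, 100)))
  for (tau in c(0.5, 5, 20, 80)) {
    for (R in c(50, 150, 400, 900)) {
      expect_identical(capacitanceFromTau(tau, R), 1000 * tau / R)
    }
  }
})

test_that("f-I slope is the rate-vs-current regression", {
  rate <- 20000
  mk <- function(nSpk, amp) {
    sp <- spliceSpikes(seq(0.3, 1.2, length.out = nSpk), duration = 1.75,
                       rate = rate, vBase = -60)
    sp@current <- ifelse(sp@time >= 0.25 & sp@time < 1.25, amp, 0)
    sp
  }
  ep <- ProtocolEpoch("step_family", list(mk(1, 50), mk(3, 100), mk(5, 150)),
                      holdingPotential = -60, stepOnset = 0.25,
                      stepOffset = 1.25, amplitudes = c(50, 100, 150))
  fi <- ifSlope(ep)
  expect_equal(fi$value, 0.04, tolerance = 1e-9)

  epEq <- ProtocolEpoch("step_family", list(mk(2, 50), mk(2, 100), mk(2, 150)),
                        holdingPotential = -60, stepOnset = 0.25,
                        stepOffset = 1.25, amplitudes = c(50, 100, 150))
  expect_equal(ifSlope(epEq)$value, 0)

  ep2 <- ProtocolEpoch("step_family", list(mk(1, 50), mk(3, 100)),
                       holdingPotential = -60, stepOnset = 0.25,
                       stepOffset = 1.25, amplitudes = c(50, 100))
  expect_equal(ifSlope(ep2)$status, "unresolved")
})

test_that("extractPanel composes estimators with presence flags", {
  cells <- makeCohort(1, "5HT", seed = 21)
  pan <- extractPanel(cells[[1]]@bundle, targetRate = 1)
  v <- featureValues(pan)
  fl <- featurePresent(pan)
  core <- c("rheobase", "input_resistance", "tau", "capacitance",
            "delay_first_spike", "ahp_duration", "ap_amplitude",
            "max_rise_rate", "ap_drop_rate", "if_slope", "baseline_vm")
  expect_true(all(fl[core]))
  expect_equal(unname(v["capacitance"]),
               unname(1000 * v["tau"] / v["input_resistance"]))
  # silent or active, never both fields
  expect_true(xor(fl["spont_rate"], fl["resting_vm"]))

  # missing ramp epoch: drop rate absent, all else unchanged
  b <- cells[[1]]@bundle
  b@epochs <- Filter(function(e) e@kind != "ramp_family", b@epochs)
  pan2 <- extractPanel(b, targetRate = 1)
  expect_false(featurePresent(pan2)["ap_drop_rate"])
  expect_true(all(featurePresent(pan2)[setdiff(core, "ap_drop_rate")]))
})

test_that("panels are deterministic given the same bundle", {
  cells <- makeCohort(1, "DA", seed = 31)
  p1 <- extractPanel(cells[[1]]@bundle, targetRate = 2)
  p2 <- extractPanel(cells[[1]]@bundle, targetRate = 2)
  expect_identical(featureValues(p1), featureValues(p2))
})

test_that("panel export writes flags as companion columns", {
  cells <- makeCohort(c(1, 1), c("5HT", "DA"), seed = 41)
  panels <- lapply(cells, function(cl)
    extractPanel(cl@bundle, targetRate = if (cl@label == "DA") 2 else 1))
  base <- file.path(tempdir(), "panels_test")
  df <- exportPanels(panels, base)
  expect_true(file.exists(paste0(base, ".tsv")))
  expect_true(file.exists(paste0(base, ".json")))
  expect_true("tau.present" %in% names(read.delim(paste0(base, ".tsv"))))
  unlink(paste0(base, c(".tsv", ".json")))
})
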