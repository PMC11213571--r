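## Synthetic recordings, cohorts, contours and trees with known ground truth.
##
## The simulator is an adaptive leaky integrate-and-fire model (exponential
## Euler, dt = 0.05 ms) with stylized raised-cosine AP templates pasted at
## threshold crossings, a spike-triggered AHP conductance, a
## sodium-inactivation-style amplitude droop on the injected current, an
## Ih-like sag conductance and a constant intrinsic pacemaker drive. Noise is
## additive Gaussian measurement noise on the recorded voltage, so the
## underlying deterministic trace doubles as the ground-truth reference.

.PARAM_NAMES <- c("R", "C", "EL", "vTh", "vReset", "aAdapt", "tauW",
                  "bAdapt", "gAhpStep", "tauAhp", "EAhp", "gH", "tauH",
                  "vHalfH", "kH", "EH", "gA", "tauA", "tauArec", "vHalfA", "kA", "EA",
                  "droop", "apAmp0", "riseMs", "fallMs", "drive", "noiseSd",
                  "samplingRate")

.PHENOTYPES <- list(
  # 5-HT-like: large capacitance, fast AP rise, long AHP, short spike delay,
  # near-constant AP amplitude on ramps, little sag
  "5HT" = c(R = 250, C = 120, EL = -60, vTh = -45, vReset = -52,
            aAdapt = 0, tauW = 9000, bAdapt = 25, gAhpStep = 3.5,
            tauAhp = 120, EAhp = -90, gH = 0.3, tauH = 100, vHalfH = -80,
            kH = 6, EH = -30, gA = 0, tauA = 150, tauArec = 2500, vHalfA = -70, kA = 8,
            EA = -85, droop = -0.003, apAmp0 = 88, riseMs = 0.75,
            fallMs = 1.5, drive = 50, noiseSd = 0.2, samplingRate = 20000),
  # DA-like: small capacitance, slow rise, long ramping spike delay
  # (A-type-K-like inactivating conductance), amplitude droop on ramps,
  # sag, rebound and postinhibitory hypoexcitability
  "DA" = c(R = 500, C = 40, EL = -60, vTh = -42, vReset = -50,
           aAdapt = 0, tauW = 9000, bAdapt = 26, gAhpStep = 3,
           tauAhp = 30, EAhp = -90, gH = 0.3, tauH = 300, vHalfH = -80,
           kH = 6, EH = -30, gA = 8, tauA = 250, tauArec = 12000,
           vHalfA = -70, kA = 8, EA = -90, droop = -0.05, apAmp0 = 75,
           riseMs = 1.3, fallMs = 2.2, drive = 50, noiseSd = 0.2,
           samplingRate = 20000),
  # rebound-spiking, fast interneuron-like profile
  "interneuron" = c(R = 400, C = 25, EL = -60, vTh = -47, vReset = -54,
                    aAdapt = 0, tauW = 5000, bAdapt = 18, gAhpStep = 4,
                    tauAhp = 15, EAhp = -85, gH = 2, tauH = 80,
                    vHalfH = -75, kH = 6, EH = -25, gA = 0, tauA = 150, tauArec = 2500,
                    vHalfA = -70, kA = 8, EA = -85, droop = -0.01,
                    apAmp0 = 80, riseMs = 0.5, fallMs = 0.9, drive = 30,
                    noiseSd = 0.2, samplingRate = 20000),
  # slow regular-firing non-5-HT-like profile
  "slow_regular" = c(R = 300, C = 55, EL = -60, vTh = -44, vReset = -51,
                     aAdapt = 0, tauW = 5000, bAdapt = 20, gAhpStep = 2.5,
                     tauAhp = 70, EAhp = -90, gH = 0.8, tauH = 100,
                     vHalfH = -80, kH = 6, EH = -30, gA = 0, tauA = 150, tauArec = 2500,
                     vHalfA = -70, kA = 8, EA = -85, droop = -0.015,
                     apAmp0 = 82, riseMs = 1, fallMs = 1.8, drive = 55,
                     noiseSd = 0.2, samplingRate = 20000),
  # passive membrane + plain LIF spiking: closed-form ground truth
  "passive" = c(R = 200, C = 100, EL = -60, vTh = -45, vReset = -55,
                aAdapt = 0, tauW = 200, bAdapt = 0, gAhpStep = 0,
                tauAhp = 50, EAhp = -90, gH = 0, tauH = 100, vHalfH = -80,
                kH = 6, EH = -30, gA = 0, tauA = 150, tauArec = 2500, vHalfA = -70, kA = 8,
                EA = -85, droop = 0, apAmp0 = 85, riseMs = 0.8,
                fallMs = 1.4, drive = 0, noiseSd = 0.2,
                samplingRate = 20000))

# steady-state current (pA) required to hold the membrane at V, with all
# gates at their steady-state values
.steadyCurrent <- function(p, V) {
  gL <- 1000 / p[["R"]]
  mInf <- 1 / (1 + exp((V - p[["vHalfH"]]) / p[["kH"]]))
  hInf <- 1 / (1 + exp((V - p[["vHalfA"]]) / p[["kA"]]))
  gL * (V - p[["EL"]]) - p[["gH"]] * mInf * (p[["EH"]] - V) -
    p[["gA"]] * hInf * (p[["EA"]] - V) + p[["aAdapt"]] * (V - p[["EL"]])
}

#' Simulator parameter sets for the built-in phenotypes
#'
#' Parameter names and units: \code{R} MOhm, \code{C} pF (so tau = R*C),
#' \code{EL}/\code{vTh}/\code{vReset}/\code{EAhp}/\code{EH}/\code{vHalfH} mV,
#' \code{aAdapt}/\code{gAhpStep}/\code{gH} nS, \code{tauW}/\code{tauAhp}/
#' \code{tauH}/\code{riseMs}/\code{fallMs} ms, \code{bAdapt}/\code{drive} pA,
#' \code{droop} mV/pA, \code{apAmp0} mV, \code{kH} mV, \code{noiseSd} mV,
#' \code{samplingRate} Hz.
#'
#' @param type one of "5HT", "DA", "interneuron", "slow_regular", "passive".
#' @param ... named overrides of individual parameters.
#' @return A \linkS4class{PhenotypeParams}.
#' @export
phenotypeParams <- function(type = c("5HT", "DA", "interneuron",
                                     "slow_regular", "passive"), ...) {
  type <- match.arg(type)
  v <- .PHENOTYPES[[type]]
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), .PARAM_NAMES)
    if (length(bad)) .stopf("unknown parameter(s): %s",
                            paste(bad, collapse = ", "))
    v[names(ov)] <- ov
  }
  obj <- new("PhenotypeParams", values = v, label = type)
  validObject(obj)
  obj
}

#' @rdname phenotypeParams
#' @param x a PhenotypeParams.
#' @param name parameter name.
#' @export
setMethod("[[", "PhenotypeParams", function(x, i, ...) x@values[[i]])

setMethod("show", "PhenotypeParams", function(object) {
  cat("PhenotypeParams '", object@label, "' (tau = ",
      round(object@values["R"] * object@values["C"] / 1000, 1), " ms)\n",
      sep = "")
  print(round(object@values, 4))
})

#' Build the acquisition protocol set
#'
#' Four epochs mirroring the acquisition protocol: a 10-s zero-current
#' recording; a family of 1-s current steps from a -60 mV holding potential;
#' a current ramp; and a 5-ms hyperpolarizing pulse.
#'
#' @param stepAmplitudes pA, default seq(-100, 150, by = 25).
#' @param rampPeak pA (ramp runs 0 to \code{rampPeak}).
#' @param rampDuration s.
#' @param pulseAmplitude pA.
#' @param holdingPotential mV.
#' @param samplingRate Hz.
#' @return list of protocol-epoch descriptors consumed by
#'   \code{\link{simulateNeuron}}.
#' @export
makeProtocols <- function(stepAmplitudes = seq(-100, 150, by = 25),
                          rampPeak = 300, rampDuration = 2,
                          pulseAmplitude = -50, holdingPotential = -60,
                          samplingRate = 20000) {
  list(
    list(kind = "zero_current_10s", duration = 10,
         stepOnset = NA_real_, stepOffset = NA_real_,
         amplitudes = 0, holding = NA_real_,
         samplingRate = samplingRate),
    list(kind = "step_family", duration = 1.75, stepOnset = 0.25,
         stepOffset = 1.25, amplitudes = stepAmplitudes,
         holding = holdingPotential, samplingRate = samplingRate),
    list(kind = "ramp_family", duration = rampDuration + 0.5,
         stepOnset = 0.25, stepOffset = 0.25 + rampDuration,
         amplitudes = rampPeak, holding = holdingPotential,
         samplingRate = samplingRate),
    list(kind = "brief_hyperpolarizing_pulse", duration = 0.75,
         stepOnset = 0.2, stepOffset = 0.205, amplitudes = pulseAmplitude,
         holding = holdingPotential, samplingRate = samplingRate))
}

#' Protocols with step amplitudes scaled to the cell
#'
#' Mimics the acquisition practice of scaling step amplitudes to a test
#' pulse evoking one to two APs: depolarizing steps are multiples of the
#' cell's effective rheobase estimate, hyperpolarizing steps target
#' steady-state deflections reaching about -90 mV.
#'
#' @param params \linkS4class{PhenotypeParams}.
#' @param ... passed to \code{\link{makeProtocols}}.
#' @return protocol list.
#' @export
scaledProtocols <- function(params, ...) {
  p <- params@values
  vHold <- -60
  gL <- 1000 / p[["R"]]
  h0 <- 1 / (1 + exp((vHold - p[["vHalfA"]]) / p[["kA"]]))
  # steady-state threshold current, or the onset (dynamic) one when a
  # standing A-type conductance initially brakes the depolarization
  iRheo <- max(.steadyCurrent(p, p[["vTh"]]) - .steadyCurrent(p, vHold),
               (p[["vTh"]] - vHold) * (gL + p[["gA"]] * h0))
  dep <- iRheo * c(0.35, 0.5, 0.65, 0.8, 0.95, 1.02, 1.08, 1.15, 1.3,
                   1.5, 1.7, 1.9, 2.2, 2.6, 3)
  # hyperpolarizing targets with the A-type gate frozen at its holding
  # value: its recovery is far slower than the 1-s step
  frozen <- function(V) {
    mInf <- 1 / (1 + exp((V - p[["vHalfH"]]) / p[["kH"]]))
    gL * (V - p[["EL"]]) - p[["gH"]] * mInf * (p[["EH"]] - V) -
      p[["gA"]] * h0 * (p[["EA"]] - V)
  }
  hyp <- vapply(c(-92, -88, -81, -74, -67), function(v)
    frozen(v) - frozen(vHold), numeric(1))
  makeProtocols(stepAmplitudes = c(hyp, dep),
                samplingRate = params[["samplingRate"]], ...)
}

#' Closed-form RC membrane response to a current step
#'
#' V(t) = EL + I R (1 - exp(-(t - onset)/tau)) during the step and a
#' symmetric exponential decay back to EL afterwards; tau = R C.
#'
#' @param R MOhm; @param C pF; @param I pA.
#' @param tGrid time grid, s.
#' @param onset,offset step window, s.
#' @param EL resting potential, mV.
#' @return voltage trace, mV.
#' @export
analyticRCResponse <- function(R, C, I, tGrid, onset = 0.25,
                               offset = 1.25, EL = -60) {
  tau <- R * C / 1e6            # seconds (MOhm * pF = us)
  dV <- I * R / 1000            # mV
  v <- rep(EL, length(tGrid))
  during <- tGrid >= onset & tGrid < offset
  v[during] <- EL + dV * (1 - exp(-(tGrid[during] - onset) / tau))
  vEnd <- EL + dV * (1 - exp(-(offset - onset) / tau))
  after <- tGrid >= offset
  v[after] <- EL + (vEnd - EL) * exp(-(tGrid[after] - offset) / tau)
  v
}

# command waveform (pA) for one epoch descriptor at the fine grid
.commandWave <- function(ep, tFine) {
  I <- numeric(length(tFine))
  if (ep$kind == "ramp_family") {
    during <- tFine >= ep$stepOnset & tFine < ep$stepOffset
    I[during] <- ep$amplitude * (tFine[during] - ep$stepOnset) /
      (ep$stepOffset - ep$stepOnset)
  } else if (!is.na(ep$stepOnset)) {
    I[tFine >= ep$stepOnset & tFine < ep$stepOffset] <- ep$amplitude
  }
  I
}

.FINE_DT_MS <- 0.05

.simulateEpochSweep <- function(params, ep, amplitude) {
  p <- params@values
  dtS <- .FINE_DT_MS / 1000
  n <- round(ep$duration / dtS)
  tFine <- (seq_len(n) - 1L) * dtS
  epi <- list(kind = ep$kind, stepOnset = ep$stepOnset,
              stepOffset = ep$stepOffset, amplitude = amplitude)
  gL <- 1000 / p[["R"]]
  wave <- .commandWave(epi, tFine)
  if (ep$kind == "zero_current_10s") {
    Iext <- rep(p[["drive"]], n)
    v0 <- min(p[["EL"]] + p[["drive"]] / gL, p[["vTh"]] - 0.5)
  } else {
    hold <- .steadyCurrent(p, ep$holding) - p[["drive"]]
    Iext <- hold + p[["drive"]] + wave
    v0 <- ep$holding
  }
  cpar <- list(gL = gL, C = p[["C"]], EL = p[["EL"]], vTh = p[["vTh"]],
               vReset = p[["vReset"]], aAdapt = p[["aAdapt"]],
               tauW = p[["tauW"]], bAdapt = p[["bAdapt"]],
               gAhpStep = p[["gAhpStep"]], tauAhp = p[["tauAhp"]],
               EAhp = p[["EAhp"]], gH = p[["gH"]], tauH = p[["tauH"]],
               vHalfH = p[["vHalfH"]], kH = p[["kH"]], EH = p[["EH"]],
               gA = p[["gA"]], tauA = p[["tauA"]], tauArec = p[["tauArec"]],
               vHalfA = p[["vHalfA"]], kA = p[["kA"]], EA = p[["EA"]],
               droop = p[["droop"]], apAmp0 = p[["apAmp0"]],
               riseMs = p[["riseMs"]], fallMs = p[["fallMs"]], v0 = v0)
  res <- simulate_trace_cpp(Iext, .FINE_DT_MS, cpar)
  if (!is.finite(sum(res$v)))
    .stopf("numerical blow-up in simulation (R=%g, C=%g, amplitude=%g)",
           p[["R"]], p[["C"]], amplitude)
  f <- max(1L, round(20000 / ep$samplingRate))
  keep <- seq(1L, n, by = f)
  list(time = tFine[keep], v = res$v[keep],
       command = wave[keep],
       spikeT = res$spike_t / 1000, spikeI = res$spike_i,
       spikeAmp = res$spike_amp)
}

# ground-truth features from the noise-free reference traces
.groundTruth <- function(params, ref, protocols, targetRate) {
  p <- params@values
  gL <- 1000 / p[["R"]]
  gt <- c(R = unname(p[["R"]]), C = unname(p[["C"]]),
          tau = unname(p[["R"]] * p[["C"]] / 1000),
          capacitance = unname(p[["C"]]),
          rheobase = unname(.steadyCurrent(p, p[["vTh"]]) -
                              .steadyCurrent(p, -60)),
          ap_drop_rate = unname(p[["droop"]]),
          spont_rate = NA, delay_first_spike = NA, ahp_duration = NA,
          ahp_amplitude = NA, ap_amplitude = NA,
          ap_duration = unname(p[["riseMs"]] + p[["fallMs"]]),
          max_rise_rate = NA, sag_amplitude = NA)
  kinds <- vapply(protocols, `[[`, character(1), "kind")
  iz <- which(kinds == "zero_current_10s")[1]
  if (!is.na(iz))
    gt["spont_rate"] <- length(ref[[iz]][[1]]$spikeT) /
      protocols[[iz]]$duration
  is <- which(kinds == "step_family")[1]
  if (!is.na(is)) {
    ep <- protocols[[is]]
    sws <- ref[[is]]
    counts <- vapply(sws, function(s)
      sum(s$spikeT >= ep$stepOnset & s$spikeT <= ep$stepOffset), numeric(1))
    rates <- counts / (ep$stepOffset - ep$stepOnset)
    ok <- which(abs(rates - targetRate) <= 0.3 & rates > 0)
    cand <- if (length(ok)) ok[order(abs(rates[ok] - targetRate))]
            else if (any(counts > 0)) which(counts > 0)[1] else integer()
    # reference AHP landmarks exist on whichever rate-matched sweep bounds
    # them; prefer the best rate match, then lower current
    sel <- if (length(cand)) cand[1] else NA_integer_
    if (length(cand) > 1) {
      for (cc in cand) {
        s <- sws[[cc]]
        inStep <- s$spikeT >= ep$stepOnset & s$spikeT <= ep$stepOffset
        sw <- Sweep(s$v, current = s$command,
                    samplingRate = ep$samplingRate, time = s$time)
        tOff <- s$spikeT[inStep] + (p[["riseMs"]] + p[["fallMs"]]) / 1000
        nxt <- c(s$spikeT[inStep][-1], ep$stepOffset)
        bounded <- any(vapply(seq_along(tOff), function(i) {
          if (tOff[i] >= nxt[i]) return(FALSE)
          !ahpMetrics(sw, data.frame(t_offset = tOff[i]),
                      segmentEnd = min(nxt[i], ep$stepOffset))$unbounded
        }, logical(1)))
        if (bounded) { sel <- cc; break }
      }
    }
    if (!is.na(sel)) {
      s <- sws[[sel]]
      inStep <- s$spikeT >= ep$stepOnset & s$spikeT <= ep$stepOffset
      gt["delay_first_spike"] <- s$spikeT[inStep][1] - ep$stepOnset
      gt["ap_amplitude"] <- mean(s$spikeAmp[inStep])
      gt["max_rise_rate"] <- mean(s$spikeAmp[inStep]) * pi /
        (2 * p[["riseMs"]])
      # AHP landmarks on the noise-free reference trace
      sw <- Sweep(s$v, current = s$command,
                  samplingRate = ep$samplingRate, time = s$time)
      tOff <- s$spikeT[inStep] + (p[["riseMs"]] + p[["fallMs"]]) / 1000
      nxt <- c(s$spikeT[inStep][-1], ep$stepOffset)
      ah <- lapply(seq_along(tOff), function(i) {
        if (tOff[i] >= nxt[i]) return(NULL)
        ahpMetrics(sw, data.frame(t_offset = tOff[i]),
                   segmentEnd = min(nxt[i], ep$stepOffset))
      })
      ah <- ah[!vapply(ah, is.null, logical(1))]
      amp <- vapply(ah, `[[`, numeric(1), "amplitude")
      bounded <- !vapply(ah, `[[`, logical(1), "unbounded")
      if (any(!is.na(amp))) gt["ahp_amplitude"] <- mean(amp, na.rm = TRUE)
      if (any(bounded))
        gt["ahp_duration"] <- mean(vapply(ah, `[[`, numeric(1),
                                          "duration")[bounded])
    }
    # sag from noise-free hyperpolarizing sweeps
    ssWin <- function(s) mean(s$v[s$time >= ep$stepOnset + 0.5 &
                                    s$time <= ep$stepOffset])
    pk <- function(s) min(s$v[s$time >= ep$stepOnset &
                                s$time <= ep$stepOnset + 0.5])
    ss <- vapply(sws, ssWin, numeric(1))
    okSag <- ss >= -95 & ss <= -85
    if (any(okSag))
      gt["sag_amplitude"] <- mean(pmax(0, ss[okSag] -
                                         vapply(sws[okSag], pk, numeric(1))))
  }
  gt
}

#' Simulate one synthetic neuron
#'
#' Integrates the adaptive LIF model over every protocol epoch at a fine
#' 0.05-ms grid, decimates to the declared sampling rate, and adds Gaussian
#' measurement noise to the recorded sweeps. The underlying noise-free
#' traces provide the attached ground truth (analytic where closed forms
#' exist, fine-grid reference simulation otherwise).
#'
#' @param params \linkS4class{PhenotypeParams}.
#' @param protocols from \code{\link{makeProtocols}} or
#'   \code{\link{scaledProtocols}}.
#' @param seed integer; all randomness (the measurement noise) flows from it
#'   and it is recorded in the bundle metadata.
#' @param cellId cell identifier.
#' @param targetRate Hz, rate-matched sweep target for ground-truth AP/AHP
#'   landmarks.
#' @param keepBundle FALSE to skip building the (memory-heavy) noisy bundle
#'   and return ground truth only.
#' @return A \linkS4class{SyntheticCell}.
#' @export
simulateNeuron <- function(params, protocols = scaledProtocols(params),
                           seed = 1, cellId = "cell", targetRate = 1,
                           keepBundle = TRUE) {
  validObject(params)
  set.seed(seed)
  ref <- lapply(protocols, function(ep)
    lapply(ep$amplitudes, function(a) .simulateEpochSweep(params, ep, a)))
  gt <- .groundTruth(params, ref, protocols, targetRate)
  bundle <- NULL
  if (keepBundle) {
    noiseSd <- params@values[["noiseSd"]]
    epochs <- lapply(seq_along(protocols), function(i) {
      ep <- protocols[[i]]
      sweeps <- lapply(ref[[i]], function(s)
        Sweep(s$v + rnorm(length(s$v), 0, noiseSd), current = s$command,
              samplingRate = ep$samplingRate, time = s$time))
      ProtocolEpoch(kind = ep$kind, sweeps = sweeps,
                    holdingPotential = ep$holding,
                    stepOnset = ep$stepOnset, stepOffset = ep$stepOffset,
                    amplitudes = ep$amplitudes)
    })
    bundle <- SweepBundle(cellId, epochs)
    bundle@metadata$seed <- seed
  }
  new("SyntheticCell", params = params, bundle = bundle,
      groundTruth = gt, label = params@label)
}

#' @rdname simulateNeuron
#' @param cell a \linkS4class{SyntheticCell}.
#' @export
groundTruth <- function(cell) cell@groundTruth

setMethod("show", "SyntheticCell", function(object) {
  cat("SyntheticCell (", object@label, "), ground truth:\n", sep = "")
  print(round(object@groundTruth, 3))
})

.VARY_LOGNORMAL <- c("R", "C", "gAhpStep", "tauAhp", "gH", "apAmp0", "drive")

#' Generate a labeled cohort of synthetic cells
#'
#' Draws cells from one or more phenotypes with between-cell lognormal
#' variability (sdlog \code{cv}) on conductance/size parameters and additive
#' jitter on the spike threshold; optional multiplicative group effects
#' emulate lesion-shifted cohorts (e.g. a shorter tau via a capacitance
#' factor, a higher spontaneously-active fraction via a drive factor).
#'
#' @param nPerGroup integer vector, cells per group.
#' @param types phenotype per group (recycled).
#' @param effects list (one element per group) of named multiplicative
#'   factors applied to the phenotype parameters, or NULL.
#' @param labels group labels (default: types, made unique).
#' @param seed integer master seed; cell i of group g derives its own seed.
#' @param cv between-cell lognormal sdlog, default 0.15.
#' @param keepBundle build full sweep bundles (FALSE: ground truth only).
#' @param targetRates Hz per group for rate-matched ground truth (default
#'   1 for 5-HT-like/others, 2 for DA-like).
#' @param protocolKinds optional epoch kinds to simulate (e.g. only
#'   \code{"step_family"} when just step-derived ground truth is needed);
#'   default: the full protocol set.
#' @return list of \linkS4class{SyntheticCell} with group labels.
#' @export
makeCohort <- function(nPerGroup, types = "5HT", effects = NULL,
                       labels = NULL, seed = 1, cv = 0.15,
                       keepBundle = TRUE, targetRates = NULL,
                       protocolKinds = NULL) {
  nG <- max(length(nPerGroup), length(types))
  nPerGroup <- rep_len(nPerGroup, nG)
  types <- rep_len(types, nG)
  labels <- labels %||% make.unique(types)
  targetRates <- targetRates %||% ifelse(types == "DA", 2, 1)
  if (sum(nPerGroup) == 0) return(list())
  cells <- list()
  idx <- 0L
  for (g in seq_len(nG)) {
    base <- .PHENOTYPES[[types[g]]]
    eff <- if (!is.null(effects) && length(effects) >= g) effects[[g]]
           else NULL
    for (i in seq_len(nPerGroup[g])) {
      idx <- idx + 1L
      cellSeed <- (seed * 10000L + idx) %% .Machine$integer.max
      set.seed(cellSeed)
      v <- base
      if (!is.null(eff)) v[names(eff)] <- v[names(eff)] * unlist(eff)
      v[.VARY_LOGNORMAL] <- v[.VARY_LOGNORMAL] *
        exp(rnorm(length(.VARY_LOGNORMAL), 0, cv))
      v["vTh"] <- v["vTh"] + rnorm(1, 0, 1)
      if (v["vReset"] >= v["vTh"]) v["vReset"] <- v["vTh"] - 3
      pp <- new("PhenotypeParams", values = v, label = types[g])
      prot <- scaledProtocols(pp)
      if (!is.null(protocolKinds))
        prot <- prot[vapply(prot, `[[`, character(1), "kind") %in%
                       protocolKinds]
      cell <- simulateNeuron(pp, prot, seed = cellSeed,
                             cellId = sprintf("%s_%03d", labels[g], idx),
                             targetRate = targetRates[g],
                             keepBundle = keepBundle)
      cell@label <- labels[g]
      if (!is.null(cell@bundle)) {
        cell@bundle@metadata$group <-
          if (labels[g] %in% c("Sham", "6-OHDA", "DMI+6-OHDA"))
            labels[g] else "none"
        cell@bundle@metadata$putativeType <- types[g]
      }
      cells[[idx]] <- cell
    }
  }
  cells
}

#' Ground-truth feature panels of a cohort
#'
#' Assembles the simulated cells' ground-truth values into FeaturePanel
#' objects (for classification tests against known labels without running
#' the estimators).
#'
#' @param cells list of \linkS4class{SyntheticCell}.
#' @return list of \linkS4class{FeaturePanel}.
#' @export
cohortTruthPanels <- function(cells) {
  lapply(seq_along(cells), function(i) {
    gt <- cells[[i]]@groundTruth
    keep <- c("spont_rate", "rheobase", "ap_amplitude", "ap_duration",
              "ahp_amplitude", "ahp_duration", "ap_drop_rate",
              "delay_first_spike", "sag_amplitude", "tau", "capacitance",
              "max_rise_rate")
    vals <- setNames(rep(NA_real_, length(.PANEL_NAMES)), .PANEL_NAMES)
    vals[keep] <- gt[keep]
    vals["input_resistance"] <- gt[["R"]]
    vals["capacitance"] <- 1000 * vals["tau"] / vals["input_resistance"]
    new("FeaturePanel",
        cellId = sprintf("%s_%03d", cells[[i]]@label, i),
        values = vals, present = !is.na(vals),
        meta = list(group = cells[[i]]@label, putativeType = cells[[i]]@label,
                    spontaneous = isTRUE(gt[["spont_rate"]] > 0)))
  })
}

## ---- morphology fixtures ----------------------------------------------------

#' Generate a soma polygon with a target circularity
#'
#' Builds a smoothly perturbed ellipse and solves its axis ratio so that the
#' measured circularity (4*pi*area/perimeter^2) matches \code{target} to
#' high precision; targets above the perturbed circle's own circularity
#' simply return the near-circle.
#'
#' @param target circularity in (0.2, 1].
#' @param scale mean radius, um.
#' @param seed integer.
#' @param nVertices polygon resolution.
#' @return A \linkS4class{SomaContour}.
#' @export
makeSomaPolygon <- function(target, scale = 8, seed = 1, nVertices = 240) {
  if (target > 1) .stopf("circularity target > 1 is unreachable")
  if (target <= 0.2) .stopf("circularity target must exceed 0.2")
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = nVertices + 1)[-(nVertices + 1)]
  amp <- runif(3, 0, 0.015)
  ph <- runif(3, 0, 2 * pi)
  bump <- 1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) +
    amp[3] * cos(5 * th + ph[3])
  rot <- runif(1, 0, pi)
  shape <- function(ratio) {
    x <- bump * cos(th)
    y <- bump * sin(th) * ratio
    m <- cbind(cos(rot) * x - sin(rot) * y, sin(rot) * x + cos(rot) * y)
    SomaContour(m * scale)
  }
  circ <- function(ratio) somaMetrics(shape(ratio))@circularity
  if (circ(1) <= target) return(shape(1))
  ratio <- stats::uniroot(function(r) circ(r) - target,
                          lower = 0.02, upper = 1, tol = 1e-9)$root
  shape(ratio)
}

#' Generate a random dendritic tree with exact topology counts
#'
#' Starts \code{nStems} primary dendrites from a soma root and adds
#' \code{nBifurcations} by splitting randomly chosen terminal branches, so
#' the generated tree has exactly nStems stems, nBifurcations bifurcations
#' and nBifurcations + nStems terminations. Branches are 3-D polylines with
#' random drifting directions. The accumulated segment length is attached as
#' attribute \code{totalLength}.
#'
#' @param nStems number of primary dendrites (>= 1).
#' @param nBifurcations number of bifurcations (>= 0).
#' @param seed integer.
#' @param segmentsPerBranch polyline nodes per branch.
#' @param branchLength mean branch length, um.
#' @return A \linkS4class{DendriteTree} with attribute \code{totalLength}.
#' @export
makeTree <- function(nStems, nBifurcations = 0, seed = 1,
                     segmentsPerBranch = 4, branchLength = 60) {
  stopifnot(nStems >= 1, nBifurcations >= 0)
  set.seed(seed)
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 5, parent = -1L)
  nextId <- 2L
  total <- 0
  leaves <- integer()     # tip node ids of unbranched branch ends
  growBranch <- function(fromId) {
    from <- nodes[nodes$id == fromId, ]
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    pos <- c(from$x, from$y, from$z)
    parent <- fromId
    len <- branchLength * exp(rnorm(1, 0, 0.3))
    for (s in seq_len(segmentsPerBranch)) {
      dir <- dir + rnorm(3, 0, 0.25)
      dir <- dir / sqrt(sum(dir^2))
      step <- len / segmentsPerBranch
      pos <- pos + dir * step
      total <<- total + step
      nodes[nrow(nodes) + 1L, ] <<- list(nextId, 3L, pos[1], pos[2],
                                         pos[3], 0.8, parent)
      parent <- nextId
      nextId <<- nextId + 1L
    }
    parent        # tip id
  }
  for (s in seq_len(nStems)) leaves <- c(leaves, growBranch(1L))
  for (b in seq_len(nBifurcations)) {
    if (!length(leaves)) break
    pick <- sample(length(leaves), 1)
    tip <- leaves[pick]
    leaves <- leaves[-pick]
    leaves <- c(leaves, growBranch(tip), growBranch(tip))
  }
  tree <- new("DendriteTree", nodes = nodes)
  validObject(tree)
  attr(tree, "totalLength") <- total
  tree
}
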