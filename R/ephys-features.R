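## Estimators for intrinsic electrophysiological properties.
##
## Conventions: voltages mV, currents pA, times s on sweeps; reported features
## use ms / MOhm / pF / Hz / V/s / mV/pA (the scales used throughout the
## figures). Unresolvable features are returned with status != "ok" and NA
## values; they are never silently zero.

.dvdt <- function(v, dt) {
  # centered finite differences on the raw grid, V/s (= mV/ms)
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt) / 1000
  d[1] <- (v[2] - v[1]) / dt / 1000
  d[n] <- (v[n] - v[n - 1]) / dt / 1000
  d
}

#' Detect action potentials in a sweep
#'
#' An AP onset is the first sample, ahead of a voltage peak, where the
#' centered-difference dV/dt reaches \code{onsetSlopeThreshold}; the offset is
#' the first sample after the peak where the voltage has repolarized back to
#' the onset voltage. Candidate peaks are local maxima at or above
#' \code{peakFloor} (the floor keeps noise peaks from seeding events; the
#' slope criterion alone defines the onset). Events are time-ordered and
#' non-overlapping; an event whose offset is not reached before the sweep
#' ends is flagged truncated.
#'
#' @param sweep a \linkS4class{Sweep}.
#' @param onsetSlopeThreshold V/s, default 5.
#' @param peakFloor mV, default -20.
#' @return data.frame with one row per AP: t_onset, v_onset, t_peak, v_peak,
#'   t_offset, v_offset, amplitude (mV), duration (ms), max_rise_rate (V/s),
#'   truncated.
#' @export
detectAPs <- function(sweep, onsetSlopeThreshold = 5, peakFloor = -20) {
  v <- sweep@voltage
  t <- sweep@time
  n <- length(v)
  empty <- data.frame(t_onset = numeric(), v_onset = numeric(),
                      t_peak = numeric(), v_peak = numeric(),
                      t_offset = numeric(), v_offset = numeric(),
                      amplitude = numeric(), duration = numeric(),
                      max_rise_rate = numeric(), truncated = logical())
  if (n < 3 || max(v) < peakFloor) return(empty)
  dt <- 1 / sweep@samplingRate
  slope <- .dvdt(v, dt)
  isPeak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n],
              FALSE) & v >= peakFloor
  peaks <- which(isPeak)
  rows <- vector("list", length(peaks))
  nEvents <- 0L
  lastEnd <- 0L
  for (p in peaks) {
    if (p <= lastEnd) next
    lo <- lastEnd + 1L
    # walk back from the peak to the contiguous fast-rise run feeding it;
    # its first sample is the AP onset
    j <- p
    while (j > lo && slope[j] < onsetSlopeThreshold) j <- j - 1L
    if (slope[j] < onsetSlopeThreshold) next  # sub-threshold rising slope
    while (j > lo && slope[j - 1L] >= onsetSlopeThreshold) j <- j - 1L
    onset <- j
    vOn <- v[onset]
    after <- if (p < n) which(v[(p + 1):n] <= vOn) else integer()
    if (length(after)) {
      off <- p + after[1]
      truncated <- FALSE
    } else {
      off <- n
      truncated <- TRUE
    }
    nEvents <- nEvents + 1L
    rows[[nEvents]] <- data.frame(
      t_onset = t[onset], v_onset = vOn, t_peak = t[p], v_peak = v[p],
      t_offset = t[off], v_offset = v[off],
      amplitude = v[p] - vOn, duration = (t[off] - t[onset]) * 1000,
      max_rise_rate = max(slope[onset:p]), truncated = truncated)
    lastEnd <- off
  }
  if (!nEvents) return(empty)
  do.call(rbind, rows[seq_len(nEvents)])
}

#' AP metrics from detected events
#'
#' Amplitude is the onset-to-peak voltage difference; duration the
#' onset-to-offset time (not a half-width). Truncated events are excluded.
#'
#' @param events data.frame from \code{\link{detectAPs}}.
#' @return data.frame with amplitude (mV), duration (ms), max_rise_rate (V/s).
#' @export
apMetrics <- function(events) {
  ev <- events[!events$truncated, , drop = FALSE]
  data.frame(amplitude = ev$v_peak - ev$v_onset,
             duration = (ev$t_offset - ev$t_onset) * 1000,
             max_rise_rate = ev$max_rise_rate)
}

#' Afterhyperpolarization metrics for one AP
#'
#' The AHP starts at the AP offset; its amplitude is the voltage difference
#' between the AP offset and the subsequent local minimum (trough). Its end
#' is found by sliding a window of \code{windowMs} sample-by-sample from the
#' trough and taking the left edge of the first window whose OLS slope
#' magnitude is at most \code{endSlopeThreshold}. If the criterion is never
#' met before the next AP (or the segment is shorter than one window) the
#' AHP is flagged unbounded.
#'
#' @param sweep a \linkS4class{Sweep}.
#' @param event one-row data.frame from \code{\link{detectAPs}}.
#' @param segmentEnd latest time (s) the AHP may extend to (next AP onset,
#'   stimulus offset, or sweep end). Default: sweep end.
#' @param windowMs sliding-window length, ms (default 50).
#' @param endSlopeThreshold V/s, default 0.005.
#' @return list with t_start, t_trough, t_end (s), amplitude (mV),
#'   duration (ms), unbounded (logical).
#' @export
ahpMetrics <- function(sweep, event, segmentEnd = NULL, windowMs = 50,
                       endSlopeThreshold = 0.005) {
  t <- sweep@time
  v <- sweep@voltage
  dt <- 1 / sweep@samplingRate
  i0 <- which.min(abs(t - event$t_offset))
  i1 <- if (is.null(segmentEnd)) length(t) else
    max(i0, which.min(abs(t - segmentEnd)))
  out <- list(t_start = event$t_offset, t_trough = NA_real_,
              t_end = NA_real_, amplitude = NA_real_, duration = NA_real_,
              unbounded = TRUE)
  nw <- max(2L, round(windowMs / 1000 / dt))
  if (i1 - i0 + 1 < nw) return(out)
  seg <- v[i0:i1]
  trough <- i0 + which.min(seg) - 1L
  out$t_trough <- t[trough]
  # amplitude relative to the AP end voltage (event's v_offset when known)
  vEnd <- if (!is.null(event$v_offset)) event$v_offset else v[i0]
  out$amplitude <- vEnd - v[trough]
  if (i1 - trough + 1 < nw) return(out)
  slopes <- sliding_ols_slope_cpp(v[trough:i1], dt, nw)  # mV/s
  hit <- which(abs(slopes) <= endSlopeThreshold * 1000)
  if (!length(hit)) return(out)
  out$t_end <- t[trough + hit[1] - 1L]
  out$duration <- (out$t_end - out$t_start) * 1000
  out$unbounded <- FALSE
  out
}

#' Spontaneous-activity classification from the zero-current epoch
#'
#' A cell is spontaneously active iff at least one AP is detected in the
#' 10-s zero-current recording; its rate is count/duration. Silent cells get
#' a resting membrane potential (mean voltage over the epoch) instead.
#'
#' @param epoch the zero-current \linkS4class{ProtocolEpoch} (or a
#'   \linkS4class{Sweep}).
#' @param ... passed to \code{\link{detectAPs}}.
#' @return list(spontaneous, spont_rate (Hz) or NA, resting_vm (mV) or NA,
#'   n_aps).
#' @export
classifySpontaneous <- function(epoch, ...) {
  sweep <- if (is(epoch, "ProtocolEpoch")) epoch@sweeps[[1]] else epoch
  dur <- diff(range(sweep@time)) + 1 / sweep@samplingRate
  ev <- detectAPs(sweep, ...)
  if (nrow(ev) >= 1)
    list(spontaneous = TRUE, spont_rate = nrow(ev) / dur,
         resting_vm = NA_real_, n_aps = nrow(ev))
  else
    list(spontaneous = FALSE, spont_rate = NA_real_,
         resting_vm = mean(sweep@voltage), n_aps = 0L)
}

.stepWindowCounts <- function(epoch, ...) {
  vapply(epoch@sweeps, function(s) {
    ev <- detectAPs(s, ...)
    slack <- 2 / s@samplingRate   # onset lands within a sample of the edge
    sum(ev$t_onset >= epoch@stepOnset - slack &
          ev$t_onset <= epoch@stepOffset + slack)
  }, numeric(1))
}

#' Rheobase from a step family
#'
#' Minimum step amplitude among sweeps evoking at least one AP during the
#' step. With no spiking sweep the result is unresolved; if even the smallest
#' depolarizing step spikes, the value is only a lower bound and flagged so.
#'
#' @param epoch a step-family \linkS4class{ProtocolEpoch}.
#' @param ... passed to \code{\link{detectAPs}}.
#' @return list(value (pA), status one of "ok", "unresolved",
#'   "lower_bound_only").
#' @export
rheobase <- function(epoch, ...) {
  counts <- .stepWindowCounts(epoch, ...)
  amps <- epoch@amplitudes
  spiking <- counts >= 1
  if (!any(spiking)) return(list(value = NA_real_, status = "unresolved"))
  val <- min(amps[spiking])
  status <- if (any(!spiking & amps > 0 & amps < val)) "ok"
            else "lower_bound_only"
  list(value = val, status = status)
}

#' AP amplitude drop rate from a ramp sweep
#'
#' During a current ramp, each AP's amplitude is paired with the instantaneous
#' injected current at its onset; the OLS slope of amplitude vs current is
#' the drop rate (mV/pA, typically <= 0 when amplitudes droop).
#'
#' @param sweep the ramp \linkS4class{Sweep}.
#' @param ... passed to \code{\link{detectAPs}}.
#' @return list(value (mV/pA), status, n_aps).
#' @export
dropRate <- function(sweep, ...) {
  ev <- detectAPs(sweep, ...)
  ev <- ev[!ev$truncated, , drop = FALSE]
  if (nrow(ev) < 3)
    return(list(value = NA_real_, status = "unresolved", n_aps = nrow(ev)))
  idx <- vapply(ev$t_onset, function(tt) which.min(abs(sweep@time - tt)),
                integer(1))
  cur <- sweep@current[idx]
  if (diff(range(cur)) < 1e-9)
    return(list(value = 0, status = "ok", n_aps = nrow(ev)))
  fit <- lm(ev$amplitude ~ cur)
  list(value = unname(coef(fit)[2]), status = "ok", n_aps = nrow(ev))
}

#' Select the rate-matched sweep of a step family
#'
#' The sweep whose evoked rate (spike count over the 1-s step) is closest to
#' \code{targetRate} and within \code{tol}; ties break toward lower current.
#'
#' @param epoch step-family epoch.
#' @param targetRate Hz (1 for 5-HT-like, 2 for DA-like cells).
#' @param tol Hz, default 0.3.
#' @param ... passed to \code{\link{detectAPs}}.
#' @return list(index or NA, rate, status).
#' @export
rateMatchedSweep <- function(epoch, targetRate = 1, tol = 0.3, ...) {
  dur <- epoch@stepOffset - epoch@stepOnset
  rates <- .stepWindowCounts(epoch, ...) / dur
  ok <- which(abs(rates - targetRate) <= tol + 1e-9 & rates > 0)
  if (!length(ok))
    return(list(index = NA_integer_, rate = NA_real_, status = "unresolved"))
  d <- abs(rates[ok] - targetRate)
  cand <- ok[d == min(d)]
  sel <- cand[which.min(epoch@amplitudes[cand])]
  list(index = sel, rate = rates[sel], status = "ok")
}

#' Delay to the first spike
#'
#' Time between step onset and the onset of the first AP, measured on the
#' rate-matched sweep (see \code{\link{rateMatchedSweep}}).
#'
#' @inheritParams rateMatchedSweep
#' @return list(value (s), status, sweep_index).
#' @export
delayToFirstSpike <- function(epoch, targetRate = 1, tol = 0.3, ...) {
  sel <- rateMatchedSweep(epoch, targetRate, tol, ...)
  if (sel$status != "ok")
    return(list(value = NA_real_, status = "unresolved",
                sweep_index = NA_integer_))
  s <- epoch@sweeps[[sel$index]]
  ev <- detectAPs(s, ...)
  ev <- ev[ev$t_onset >= epoch@stepOnset - 2 / s@samplingRate, ,
           drop = FALSE]
  list(value = max(0, ev$t_onset[1] - epoch@stepOnset), status = "ok",
       sweep_index = sel$index)
}

#' Steady-state voltage of a step sweep
#'
#' Mean voltage from 0.5 s after step onset to the step offset. If APs occur
#' in that window the value is still computed but flagged.
#'
#' @param sweep a \linkS4class{Sweep}.
#' @param stepOnset,stepOffset s.
#' @param ... passed to \code{\link{detectAPs}}.
#' @return list(value (mV), spikes (logical)).
#' @export
steadyStateVoltage <- function(sweep, stepOnset, stepOffset, ...) {
  t <- sweep@time
  win <- t >= stepOnset + 0.5 - 1e-9 & t <= stepOffset + 1e-9
  ev <- detectAPs(sweep, ...)
  spikes <- any(ev$t_onset >= stepOnset + 0.5 - 1e-9 &
                  ev$t_onset <= stepOffset + 1e-9)
  list(value = mean(sweep@voltage[win]), spikes = spikes)
}

#' Input resistance from a step family
#'
#' OLS slope of the steady-state voltage vs injected current over steps whose
#' steady-state voltage lies within [-90, -50] mV (R = dV/dI). Sweeps with
#' any AP during the step are excluded: once a cell has spiked, its
#' spike-triggered conductances contaminate the apparent steady state.
#'
#' @param epoch step-family epoch.
#' @param range qualifying steady-state window, mV.
#' @param ... passed to \code{\link{steadyStateVoltage}} /
#'   \code{\link{detectAPs}}.
#' @return list(value (MOhm), status, n_steps).
#' @export
inputResistance <- function(epoch, range = c(-90, -50), ...) {
  v <- vapply(epoch@sweeps, function(s)
    steadyStateVoltage(s, epoch@stepOnset, epoch@stepOffset, ...)$value,
    numeric(1))
  spk <- .stepWindowCounts(epoch, ...) > 0
  ok <- v >= range[1] & v <= range[2] & !spk
  if (sum(ok) < 2)
    return(list(value = NA_real_, status = "unresolved", n_steps = sum(ok)))
  fit <- lm(v[ok] ~ epoch@amplitudes[ok])
  list(value = unname(coef(fit)[2]) * 1000, status = "ok", n_steps = sum(ok))
}

#' Sag amplitude from hyperpolarizing steps
#'
#' Over steps hyperpolarizing the cell to -90 +/- 5 mV (steady state), sag is
#' the steady-state voltage minus the peak (minimum) voltage of the first
#' 0.5 s of the step, averaged across qualifying steps; clamped at 0 for
#' monotone responses.
#'
#' @param epoch step-family epoch.
#' @param range qualifying steady-state window, mV (default [-95, -85]).
#' @param ... passed to \code{\link{steadyStateVoltage}}.
#' @return list(value (mV), status, n_steps).
#' @export
sagAmplitude <- function(epoch, range = c(-95, -85), ...) {
  t0 <- epoch@stepOnset
  res <- vapply(epoch@sweeps, function(s) {
    ss <- steadyStateVoltage(s, t0, epoch@stepOffset, ...)$value
    peak <- min(s@voltage[s@time >= t0 - 1e-9 & s@time <= t0 + 0.5 + 1e-9])
    c(ss, peak)
  }, numeric(2))
  ok <- res[1, ] >= range[1] & res[1, ] <= range[2]
  if (!any(ok))
    return(list(value = NA_real_, status = "unresolved", n_steps = 0L))
  list(value = mean(pmax(0, res[1, ok] - res[2, ok])), status = "ok",
       n_steps = sum(ok))
}

#' Membrane time constant from a brief hyperpolarizing pulse
#'
#' Fits the offset exponential y = K0 + K1*exp(-(t - t0)/K2) to the voltage
#' recovery after a 5-ms hyperpolarizing pulse. The fit window starts 1 ms
#' after the negative voltage peak and ends when the membrane potential has
#' returned to the mean pre-pulse baseline (or at sweep end if it never
#' crosses). Tau is K2 in ms.
#'
#' @param epoch a brief-pulse \linkS4class{ProtocolEpoch} (or a
#'   \linkS4class{Sweep} with \code{stepOnset}/\code{stepOffset} supplied).
#' @param stepOnset,stepOffset pulse window, s (taken from the epoch when
#'   omitted).
#' @param tauBounds admissible tau range, ms; fits outside are unresolved.
#' @return list(K0 (mV), K1 (mV), tau (ms), status).
#' @export
fitTau <- function(epoch, stepOnset = NULL, stepOffset = NULL,
                   tauBounds = c(0.1, 500)) {
  if (is(epoch, "ProtocolEpoch")) {
    sweep <- epoch@sweeps[[1]]
    stepOnset <- stepOnset %||% epoch@stepOnset
    stepOffset <- stepOffset %||% epoch@stepOffset
  } else sweep <- epoch
  t <- sweep@time
  v <- sweep@voltage
  unresolved <- list(K0 = NA_real_, K1 = NA_real_, tau = NA_real_,
                     status = "unresolved")
  base <- mean(v[t < stepOnset - 1e-9])
  searchWin <- t >= stepOnset - 1e-9 & t <= stepOffset + 0.002
  peakIdx <- which(searchWin)[which.min(v[searchWin])]
  if (v[peakIdx] >= base - 0.05) return(unresolved)  # no identifiable peak
  start <- peakIdx + round(0.001 * sweep@samplingRate)
  if (start >= length(t)) return(unresolved)
  # baseline return detected on a 2-ms running mean: a single noise
  # excursion above baseline does not end the fit window
  nsm <- max(1L, round(0.002 * sweep@samplingRate))
  vs <- as.numeric(stats::filter(v, rep(1 / nsm, nsm), sides = 2))
  back <- which(!is.na(vs[start:length(vs)]) & vs[start:length(vs)] >= base)
  end <- if (length(back)) start + back[1] - 1L else length(t)
  if (end - start < 10) return(unresolved)
  x <- t[start:end] - t[start]
  y <- v[start:end]
  k1 <- y[1] - base
  if (abs(k1) < 0.05) return(unresolved)            # flat recovery
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ K0 + K1 * exp(-x / K2),
                      start = list(K0 = base, K1 = k1, K2 = 0.02),
                      lower = c(-Inf, -Inf, 1e-5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(unresolved)
  cf <- coef(fit)
  tau <- unname(cf["K2"]) * 1000
  if (!is.finite(tau) || tau <= tauBounds[1] || tau >= tauBounds[2])
    return(unresolved)
  list(K0 = unname(cf["K0"]), K1 = unname(cf["K1"]), tau = tau,
       status = "ok")
}

#' Membrane capacitance from tau and input resistance
#'
#' C = tau / R; with tau in ms and R in MOhm, tau/R is in nF, reported in pF.
#'
#' @param tau ms.
#' @param inputResistance MOhm.
#' @return pF (NA propagates from either missing input).
#' @export
capacitanceFromTau <- function(tau, inputResistance) {
  ifelse(is.na(tau) | is.na(inputResistance), NA_real_,
         1000 * tau / inputResistance)
}

#' Frequency-current (f-I) slope
#'
#' OLS slope of evoked mean rate (spike count over the 1-s step) vs step
#' amplitude over suprathreshold steps.
#'
#' @param epoch step-family epoch.
#' @param ... passed to \code{\link{detectAPs}}.
#' @return list(value (Hz/pA), status, n_steps).
#' @export
ifSlope <- function(epoch, ...) {
  dur <- epoch@stepOffset - epoch@stepOnset
  rates <- .stepWindowCounts(epoch, ...) / dur
  ok <- rates > 0
  if (sum(ok) < 3)
    return(list(value = NA_real_, status = "unresolved", n_steps = sum(ok)))
  if (diff(range(rates[ok])) < 1e-12)
    return(list(value = 0, status = "ok", n_steps = sum(ok)))
  fit <- lm(rates[ok] ~ epoch@amplitudes[ok])
  list(value = unname(coef(fit)[2]), status = "ok", n_steps = sum(ok))
}

## ---- panel assembly ---------------------------------------------------------

#' Feature names of the five- and twenty-parameter panels
#'
#' \code{fiveFeatureNames}: the five properties that separate 5-HT-like from
#' DA-like cells (delay to first spike, AP drop rate, AP max rise rate, AHP
#' duration, capacitance). \code{twentyFeatureNames}: the extended
#' standardized panel used for four-type clustering.
#'
#' @export
fiveFeatureNames <- c("delay_first_spike", "ap_drop_rate", "max_rise_rate",
                      "ahp_duration", "capacitance")

#' @rdname fiveFeatureNames
#' @export
twentyFeatureNames <- c(
  "spontaneous", "baseline_vm", "rheobase", "ap_amplitude", "ap_duration",
  "ap_v_onset", "ap_v_peak", "max_rise_rate", "ap_max_fall_rate",
  "ahp_amplitude", "ahp_duration", "ahp_trough_vm", "ap_drop_rate",
  "delay_first_spike", "input_resistance", "sag_amplitude", "tau",
  "capacitance", "if_slope", "rebound_spiking")

.PANEL_NAMES <- unique(c(
  "spont_rate", "resting_vm", twentyFeatureNames))

#' Extract the full feature panel of one cell
#'
#' Runs every estimator on the bundle and assembles a
#' \linkS4class{FeaturePanel}. AP/AHP metrics are per-cell averages over the
#' non-truncated (and, for AHP, bounded) events of the rate-matched step
#' sweep. Every unresolved feature is flagged absent; missing epochs degrade
#' the panel feature-by-feature, never silently.
#'
#' @param bundle a \linkS4class{SweepBundle}.
#' @param targetRate Hz; rate window for AP-metric sweep selection
#'   (1 for 5-HT-like, 2 for DA-like cells).
#' @param reboundWindow s after step offset in which a spike counts as
#'   rebound spiking.
#' @param ... passed to \code{\link{detectAPs}}.
#' @return A \linkS4class{FeaturePanel}.
#' @export
extractPanel <- function(bundle, targetRate = 1, reboundWindow = 0.3, ...) {
  validObject(bundle)
  vals <- setNames(rep(NA_real_, length(.PANEL_NAMES)), .PANEL_NAMES)
  meta <- list(group = bundle@metadata$group,
               putativeType = bundle@metadata$putativeType,
               spontaneous = NA, targetRate = targetRate,
               rateMatchedIndex = NA_integer_)

  zero <- epochOfKind(bundle, "zero_current_10s")
  if (!is.null(zero)) {
    sp <- classifySpontaneous(zero, ...)
    meta$spontaneous <- sp$spontaneous
    vals["spontaneous"] <- as.numeric(sp$spontaneous)
    if (sp$spontaneous) vals["spont_rate"] <- sp$spont_rate
    else vals["resting_vm"] <- sp$resting_vm
    vals["baseline_vm"] <- mean(zero@sweeps[[1]]@voltage)
  }

  steps <- epochOfKind(bundle, "step_family")
  if (!is.null(steps)) {
    rb <- rheobase(steps, ...)
    if (rb$status %in% c("ok", "lower_bound_only")) vals["rheobase"] <- rb$value
    meta$rheobaseStatus <- rb$status
    ir <- inputResistance(steps, ...)
    if (ir$status == "ok") vals["input_resistance"] <- ir$value
    sg <- sagAmplitude(steps, ...)
    if (sg$status == "ok") vals["sag_amplitude"] <- sg$value
    fi <- ifSlope(steps, ...)
    if (fi$status == "ok") vals["if_slope"] <- fi$value

    sel <- rateMatchedSweep(steps, targetRate, ...)
    if (sel$status == "ok") {
      meta$rateMatchedIndex <- sel$index
      s <- steps@sweeps[[sel$index]]
      ev <- detectAPs(s, ...)
      slack <- 2 / s@samplingRate
      ev <- ev[ev$t_onset >= steps@stepOnset - slack &
                 ev$t_onset <= steps@stepOffset + slack, , drop = FALSE]
      vals["delay_first_spike"] <- max(0, ev$t_onset[1] - steps@stepOnset)
      good <- !ev$truncated
      if (any(good)) {
        m <- apMetrics(ev)
        vals["ap_amplitude"] <- mean(m$amplitude)
        vals["ap_duration"] <- mean(m$duration)
        vals["max_rise_rate"] <- mean(m$max_rise_rate)
        vals["ap_v_onset"] <- mean(ev$v_onset[good])
        vals["ap_v_peak"] <- mean(ev$v_peak[good])
        dt <- 1 / s@samplingRate
        fall <- vapply(which(good), function(i) {
          i0 <- which.min(abs(s@time - ev$t_peak[i]))
          i1 <- which.min(abs(s@time - ev$t_offset[i]))
          if (i1 <= i0) NA_real_ else min(.dvdt(s@voltage, dt)[i0:i1])
        }, numeric(1))
        vals["ap_max_fall_rate"] <- mean(abs(fall), na.rm = TRUE)
        ahps <- lapply(which(good), function(i) {
          nxt <- if (i < nrow(ev)) ev$t_onset[i + 1] else steps@stepOffset
          ahpMetrics(s, ev[i, ], segmentEnd = min(nxt, steps@stepOffset))
        })
        amp <- vapply(ahps, `[[`, numeric(1), "amplitude")
        dur <- vapply(ahps, `[[`, numeric(1), "duration")
        tr <- vapply(ahps, function(a) {
          if (is.na(a$t_trough)) NA_real_
          else s@voltage[which.min(abs(s@time - a$t_trough))]
        }, numeric(1))
        bounded <- !vapply(ahps, `[[`, logical(1), "unbounded")
        if (any(!is.na(amp))) vals["ahp_amplitude"] <- mean(amp, na.rm = TRUE)
        if (any(bounded)) vals["ahp_duration"] <- mean(dur[bounded])
        if (any(!is.na(tr))) vals["ahp_trough_vm"] <- mean(tr, na.rm = TRUE)
      }
    }
    hyp <- which(steps@amplitudes < 0)
    if (length(hyp)) {
      reb <- any(vapply(hyp, function(i) {
        ev <- detectAPs(steps@sweeps[[i]], ...)
        any(ev$t_onset > steps@stepOffset &
              ev$t_onset <= steps@stepOffset + reboundWindow)
      }, logical(1)))
      vals["rebound_spiking"] <- as.numeric(reb)
    }
  }

  ramp <- epochOfKind(bundle, "ramp_family")
  if (!is.null(ramp) && length(ramp@sweeps)) {
    dr <- dropRate(ramp@sweeps[[1]], ...)
    if (dr$status == "ok") vals["ap_drop_rate"] <- dr$value
  }

  pulse <- epochOfKind(bundle, "brief_hyperpolarizing_pulse")
  if (!is.null(pulse)) {
    ft <- fitTau(pulse)
    if (ft$status == "ok") vals["tau"] <- ft$tau
  }

  vals["capacitance"] <- capacitanceFromTau(vals["tau"],
                                            vals["input_resistance"])
  new("FeaturePanel", cellId = bundle@cellId, values = vals,
      present = !is.na(vals), meta = meta)
}

#' @describeIn extractPanel Accessors for feature values and presence flags.
#' @param panel a \linkS4class{FeaturePanel}.
#' @export
featureValues <- function(panel) panel@values

#' @rdname extractPanel
#' @export
featurePresent <- function(panel) panel@present

setMethod("show", "FeaturePanel", function(object) {
  cat("FeaturePanel '", object@cellId, "': ",
      sum(object@present), "/", length(object@values),
      " features present\n", sep = "")
  v <- object@values[object@present]
  print(round(v, 4))
})

#' Export panels to a per-cell table
#'
#' One row per cell; presence flags exported as companion boolean columns
#' suffixed \code{.present}. Columns are versioned via the
#' \code{panel_format} attribute written into the JSON export.
#'
#' @param panels list of \linkS4class{FeaturePanel}.
#' @param path optional base path; writes \code{<path>.tsv} and
#'   \code{<path>.json} when supplied.
#' @return data.frame, invisibly when \code{path} given.
#' @export
exportPanels <- function(panels, path = NULL) {
  df <- do.call(rbind, lapply(panels, function(p) {
    row <- as.data.frame(as.list(p@values))
    flags <- as.data.frame(as.list(p@present))
    names(flags) <- paste0(names(flags), ".present")
    cbind(data.frame(cell_id = p@cellId,
                     group = p@meta$group %||% "none",
                     putative_type = as.character(p@meta$putativeType %||%
                                                    NA_character_),
                     spontaneous = p@meta$spontaneous), row, flags)
  }))
  if (!is.null(path)) {
    write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(panel_format = 1L, cells = df),
                         paste0(path, ".json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(df))
  }
  df
}
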