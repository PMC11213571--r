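---
title: "Intrinsic-property extraction, neuron-type classification and morphometrics: methods"
author: "IntrinsicEphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic-property extraction, neuron-type classification and morphometrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IntrinsicEphys)
```

# Scope

IntrinsicEphys turns whole-cell current-clamp recordings into a per-cell
panel of intrinsic electrophysiological properties, classifies cells into
putative types by standardized PCA followed by Ward hierarchical
clustering, and computes soma and dendritic-tree morphometrics from 2-D
contours and SWC reconstructions. Because raw recordings of this kind are
rarely deposited, the package ships a synthetic-data module that generates
current-clamp sweep bundles with known ground truth, so every estimator is
testable end to end.

# The recording protocol

A cell's `SweepBundle` is organized by protocol epoch, mirroring a standard
slice-physiology session:

* a 10-s recording at zero injected current (spontaneous activity or
  resting potential);
* a family of 1-s de- and hyperpolarizing current steps from a holding
  potential of -60 mV;
* a current ramp (default 0 to 300 pA over 2 s);
* a brief 5-ms hyperpolarizing pulse (default -50 pA) for the
  membrane-time-constant fit.

Canonical units are mV, pA and seconds on disk and in `Sweep` objects;
reported features use ms, MOhm, pF, Hz, V/s and mV/pA, the scales on which
these quantities are conventionally printed. Sweeps containing NaN samples
are rejected outright: silent interpolation would corrupt the
slope-threshold criteria below.

# Feature definitions and estimators

**AP detection.** An action potential's onset is the first sample, ahead of
a voltage peak, at which the centered-difference dV/dt reaches 5 V/s; its
end is the return to the onset voltage; amplitude is onset-to-peak and
duration onset-to-offset (not a half-width). dV/dt is computed on the raw
grid with no smoothing by default — the criterion is defined on raw slope —
with candidate peaks restricted to local maxima above a -20 mV floor so
that baseline noise cannot seed events. The floor is a detection guard, not
part of the onset definition, and is configurable.

**AHP.** The afterhyperpolarization starts at the AP offset; its amplitude
is the offset-to-trough voltage difference. Its end is found by sliding a
50-ms window sample-by-sample from the trough and taking the left edge of
the first window whose OLS slope magnitude falls to 0.005 V/s or less. We
apply the criterion to the slope magnitude rather than the signed slope, so
that a noise-induced sign flip near zero cannot defer the end. If the
criterion is never met before the next AP (or before the stimulus ends) the
AHP is flagged unbounded and excluded from per-cell averages.

**Rate-matched sweep.** AP and AHP shape metrics are averaged over the
spikes of the step sweep whose evoked rate is within ±0.3 Hz of a
type-specific target (1 Hz for 5-HT-like, 2 Hz for DA-like cells, i.e.
close to their typical spontaneous rates); ties break toward lower current.
With 1-s steps the evoked rate is a count, so the window effectively
selects the sweep with exactly one (or two) spikes.

**Passive properties.** Steady-state voltage is the mean over the last
half-second of a step. Input resistance is the OLS slope of steady-state
voltage against injected current over steps settling between -90 and
-50 mV; sweeps with any AP during the step are excluded because
spike-triggered conductances contaminate the apparent steady state (this
disambiguates an "all current-voltage steps" convention that presumes
subthreshold responses). Sag is the mean, over steps settling at -90 ± 5 mV, of the
steady-state voltage minus the most negative voltage of the first 0.5 s,
clamped at zero for monotone responses. The membrane time constant comes
from the offset exponential y = K0 + K1·exp(-(t - t0)/K2) fitted to the
recovery after the 5-ms pulse, from 1 ms after the negative peak until the
membrane potential has returned to the pre-pulse baseline; tau is K2 in
time units — the only dimensionally consistent reading of the fit, since a
rate constant in the exponent could not itself be a time constant.
Baseline return is detected on a 2-ms running mean so that a single noise
excursion cannot truncate the fit window; on noiseless traces this changes
nothing. Capacitance is C = tau/R, and with tau in ms and R in MOhm the
ratio is in nF, reported in pF.

**Excitability.** Rheobase is the smallest step amplitude evoking at least
one AP (flagged as a lower bound if even the smallest depolarizing step
spikes). The f-I slope is the OLS slope of evoked rate against amplitude
over suprathreshold steps. The AP drop rate is the OLS slope of AP
amplitude against the instantaneous ramp current at each AP's *onset* —
the paper-style "amplitude vs injected current" plot leaves onset vs peak
open, and we fix it at the onset where the threshold crossing occurs. The
delay to the first spike is measured on the rate-matched sweep.

Every feature carries a presence flag. An estimator that cannot resolve its
quantity (no rate-matched sweep, no qualifying hyperpolarizing step,
non-convergent fit, tau outside (0.1, 500) ms) reports an absent value,
never a silent zero, and absent features propagate into downstream
complete-case filtering.

# Classification

`classifyTwoTypes()` standardizes the five properties that separate
5-HT-like from DA-like cells — delay to first spike, AP drop rate, maximal
AP rise rate, AHP duration and capacitance — runs a PCA, and applies
agglomerative clustering with Ward's criterion on Euclidean distances over
the first two PC scores, cut at k = 2. `classifyFourTypes()` does the same
on a twenty-parameter standardized panel with the first three components
and k = 4. The twenty-feature list (`twentyFeatureNames`) extends the core
panel with always-defined descriptors (baseline membrane potential of the
zero-current epoch, AP onset/peak voltages, maximal fall rate, AHP trough
voltage, a rebound-spiking indicator); the descriptors that are only
defined for one activity state (spontaneous rate vs resting potential) are
deliberately excluded so that silent and active cells share a complete
panel.

Numerical conventions: standardization uses the sample SD and errors on
zero-variance columns (naming the column); PCA keeps complete-case cells
only and reports which cells were dropped; each loading's
largest-magnitude element is made positive so results are deterministic
across platforms; `hclust(method = "ward.D2")` implements Ward linkage on
unsquared Euclidean distances. `clusterPurity()` scores a labeling against
known types under the best one-to-one cluster-to-type assignment.

# Morphometrics

Soma contours are simple 2-D polygons (traced cell-body outlines). Area
comes from the shoelace formula, perimeter from the closed polygon length,
and the major/minor axes from the moments-equivalent ellipse — the ellipse
with the same area and second central moments, the standard image-analysis
"fit ellipse" — rather than Feret diameters. Circularity is
4·pi·area/perimeter², which is 1 exactly for a circle and smaller for
elongated or complex outlines; a ratio printed the other way up
(perimeter²/4·pi·area) is simply its reciprocal and cannot lie in (0, 1],
so the bounded form is the operative definition here.

Dendritic trees are analyzed in 3-D SWC coordinates: primary dendrites are
the children of the soma root, bifurcations are non-soma nodes with at
least two children (a node with c > 2 children counts as c - 1
bifurcations, with a message), terminations are non-soma leaves, and
lengths are summed Euclidean segment lengths, reported both in total and
per primary dendrite — total length and the per-dendrite distribution
answer different questions, so both are emitted. For binary trees the
identity n_terminations = n_bifurcations + n_stems holds and is enforced in
the test suite.

# The synthetic-data generator

`simulateNeuron()` integrates an adaptive leaky integrate-and-fire model
with exponential Euler at dt = 0.05 ms, decimates to the declared sampling
rate (10-20 kHz), and adds Gaussian measurement noise (default
SD 0.2 mV) to the recorded sweeps. Because the noise is additive on the
recording, the underlying deterministic trace doubles as the ground-truth
reference: capacitance, time constant, droop coefficient and template
shape are known analytically, while delay, AHP landmarks and sag are read
off the noise-free fine-grid trace.

Mechanisms, all optional per phenotype:

* stylized raised-cosine AP templates pasted at threshold crossings, whose
  amplitude shrinks linearly with the injected current at onset (the
  sodium-inactivation-style amplitude droop that produces the AP drop rate
  on ramps); template parameters give exact ground truth for AP amplitude,
  duration and maximal rise rate at negligible cost compared to
  Hodgkin-Huxley-style spikes;
* a spike-triggered AHP conductance with exponential decay (reversal
  near -90 mV), setting AHP amplitude and duration;
* a slow spike-triggered adaptation current whose decay is much longer
  than the 1-s step, which makes the spike count a staircase function of
  the step amplitude — this is what guarantees that a sweep evoking
  exactly one (or two) spikes exists for essentially every cell, so the
  rate-matched metrics are defined;
* an Ih-like conductance activating on hyperpolarization (sag, rebound);
* an A-type-potassium-like conductance with fast inactivation and much
  slower recovery. Standing at -60 mV, it brakes depolarization until it
  inactivates, producing the long ramping delay to the first spike of
  DA-like cells; because recovery is slower than the step, it stays out of
  the inter-spike dynamics, so the AHP-end slope criterion remains
  attainable. Its slow recovery also yields postinhibitory
  hypoexcitability after hyperpolarizing steps.

The four built-in phenotypes encode the qualitative profiles the package
is designed to separate: 5-HT-like (tau = 30 ms, C = 120 pF, fast AP rise
~184 V/s, AHP duration ~0.5 s, short spike delay ~0.1 s, near-zero droop);
DA-like (C = 40 pF, slow rise ~87 V/s, delay ~0.2 s with ramping
depolarization, droop -0.05 mV/pA, sag, brief AHP ~0.2 s); a
rebound-spiking interneuron-like profile; and a slow-regular non-5-HT-like
profile. A fifth "passive" phenotype is a plain LIF cell with closed-form
rheobase and firing rate, used as the oracle for the passive-property
estimators. Between-cell variability is lognormal (sdlog 0.15) on size and
conductance parameters with 1-mV Gaussian jitter on the spike threshold —
a dispersion typical of within-type variability in slice data. Lesion-like
cohorts are built by multiplicative `effects` on the parameters (e.g. a
0.7 capacitance factor for a 30% shorter tau).

Per-cell step amplitudes are scaled to the cell (multiples of its
threshold-current estimate, hyperpolarizing steps targeting steady states
near -90 mV), mirroring the acquisition practice of scaling steps to a
test pulse that evokes one to two APs; a fixed pA grid remains available
in `makeProtocols()`. For strongly rectifying cells the hyperpolarizing
targets are computed against the holding-state (frozen) A-conductance,
since its recovery is slower than the step.

Spontaneous activity is driven by a constant pacemaker current drawn per
cell; a cell is spontaneously active iff at least one AP occurs in the
10-s zero-current epoch (the active/silent dichotomy needs no minimum
rate). The drive medians were chosen so that roughly a third of 5-HT-like
and over half of DA-like cells are active, matching the reported
proportions in control tissue.

What the generator does *not* emulate: channel noise in the dynamics
(noise is measurement-only, so detection operates on clean spikes plus
additive noise), biophysically detailed AP waveforms, synaptic input,
electrode artifacts, and realistic slow pacemaking — with the long
adaptation time constants, simulated spontaneous rates sit below the
1-2 Hz typical of real cells even though the active fractions are
realistic. Passing tests therefore demonstrate correctness of the
estimators under the stated definitions and robustness to additive
recording noise, not performance on every pathology of real recordings.

# Group statistics

`compareGroups()` reproduces a common slice-physiology workflow: a
Kolmogorov-Smirnov normality gate at alpha = 0.05 on every group (with
parameters estimated from the sample, as acquisition software commonly
does; this makes the gate conservative as a normality test, which we log
as a caveat), then an unpaired t-test or Mann-Whitney U for two groups and
one-way ANOVA or Kruskal-Wallis for three or more. Groups with fewer than
three values fail the gate with a warning. No multiple-testing correction
is applied; every comparison is reported so users can apply their own.
Exact vs asymptotic Mann-Whitney p-values are selectable (`exact`
argument); the default follows `wilcox.test`'s small-sample rule.
`percentActive()` rounds halves away from zero, the convention under which
11 of 30 prints as 37%.

Under null simulations the gated two-group test holds its nominal type-I
error (measured near 0.04 at alpha = 0.05 over 1000 replicates in the
acceptance suite).

# Problem sizes and reproducibility

The test and acceptance suites use: 100 noise seeds for the RC-recovery
checks, 50 traces for the AHP brute-force equivalence, 20 parameter draws
for the LIF rheobase identity, 50 cohort seeds of 30 + 40 cells for
two-type classification (ground-truth panels), 2 full simulate-and-extract
cohorts of 4 × 10 cells for four-type classification, 1000 replicates for
the type-I-error check, and 100 random trees for the termination identity.
These sizes keep each property estimate stable while the whole suite runs
in minutes on a single core. All randomness flows from one seed
(`--seed` in `scripts/acceptance.R`); the per-cell seed is recorded in the
bundle manifest, and identical seeds reproduce bit-identical bundles.

# Known limitations

* The estimators assume the protocol structure above; bundles missing
  epochs degrade feature-by-feature via presence flags.
* AHP duration is only defined when the post-spike trajectory flattens
  below 0.005 V/s before the next spike; cells firing fast at every tested
  amplitude report it absent, exactly as the criterion dictates.
* Measured input resistance and time constant reflect the total standing
  conductance near the holding potential; for strongly rectifying model
  cells they deviate from the nominal leak parameters, as they would in a
  real cell.
* The twenty-parameter panel is one reasonable extended feature set; the
  exact composition of such panels varies between laboratories, so it is
  exposed as `twentyFeatureNames` rather than hard-wired.
* Cluster number is fixed by the caller (k = 2 or 4); no model selection
  is attempted.
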