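#' @import methods
#' @importFrom stats coef cor cutree dist hclust kruskal.test ks.test lm
#'   na.omit prcomp rnorm runif sd t.test wilcox.test aov anova setNames
#'   nls.control rlnorm
#' @importFrom utils read.delim write.table head tail
#' @useDynLib IntrinsicEphys, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

EPOCH_KINDS <- c("zero_current_10s", "step_family", "ramp_family",
                 "brief_hyperpolarizing_pulse")

#' Sweep: one current-clamp recording
#'
#' A single voltage recording on a uniform time grid with its current-command
#' waveform. Canonical units are seconds, millivolts and picoamperes.
#'
#' @slot time numeric, seconds, strictly increasing uniform grid.
#' @slot voltage numeric, millivolts.
#' @slot current numeric, picoamperes (command waveform).
#' @slot samplingRate numeric scalar, hertz.
#' @exportClass Sweep
setClass("Sweep",
  representation(time = "numeric", voltage = "numeric", current = "numeric",
                 samplingRate = "numeric"))

setValidity("Sweep", function(object) {
  msgs <- character()
  n <- length(object@time)
  if (length(object@voltage) != n || length(object@current) != n)
    msgs <- c(msgs, "time, voltage and current must have equal length")
  if (n >= 2) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msgs <- c(msgs, "time must be strictly increasing")
    else if (diff(range(dt)) > 1e-6 * mean(dt))
      msgs <- c(msgs, "time grid must be uniform")
  }
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a positive scalar")
  if (anyNA(object@voltage) || anyNA(object@current))
    msgs <- c(msgs, "NaN/NA samples are rejected (no silent interpolation)")
  if (length(msgs)) msgs else TRUE
})

#' ProtocolEpoch: one protocol segment with its sweeps
#'
#' @slot kind character, one of zero_current_10s, step_family, ramp_family,
#'   brief_hyperpolarizing_pulse.
#' @slot holdingPotential numeric, mV (NA for the zero-current epoch).
#' @slot stepOnset,stepOffset numeric, seconds (stimulus window within sweeps).
#' @slot amplitudes numeric, pA, one per sweep (peak ramp current for ramps).
#' @slot sweeps list of \linkS4class{Sweep}.
#' @exportClass ProtocolEpoch
setClass("ProtocolEpoch",
  representation(kind = "character", holdingPotential = "numeric",
                 stepOnset = "numeric", stepOffset = "numeric",
                 amplitudes = "numeric", sweeps = "list"))

setValidity("ProtocolEpoch", function(object) {
  msgs <- character()
  if (!object@kind %in% EPOCH_KINDS)
    msgs <- c(msgs, paste0("unknown epoch kind '", object@kind, "'"))
  if (!all(vapply(object@sweeps, is, logical(1), "Sweep")))
    msgs <- c(msgs, "sweeps must all be Sweep objects")
  if (length(object@amplitudes) != length(object@sweeps))
    msgs <- c(msgs, "one amplitude per sweep required")
  dur <- object@stepOffset - object@stepOnset
  if (object@kind == "step_family" && length(dur) == 1L &&
      abs(dur - 1) > 1e-6)
    msgs <- c(msgs, "step_family steps must last 1 s")
  if (object@kind == "brief_hyperpolarizing_pulse" && length(dur) == 1L &&
      abs(dur - 0.005) > 1e-9)
    msgs <- c(msgs, "brief pulse must last 5 ms")
  if (object@kind == "zero_current_10s") {
    ok <- vapply(object@sweeps, function(s)
      length(s@time) / s@samplingRate >= 10 - 1e-6 && all(s@current == 0),
      logical(1))
    if (length(ok) && !all(ok))
      msgs <- c(msgs, "zero_current epoch requires >= 10 s at exactly 0 pA")
  }
  if (length(msgs)) msgs else TRUE
})

#' SweepBundle: all recordings for one cell
#'
#' @slot cellId character scalar.
#' @slot epochs list of \linkS4class{ProtocolEpoch}.
#' @slot metadata list; recognised entries: \code{group} (one of
#'   "Sham", "6-OHDA", "DMI+6-OHDA", "none"), \code{putativeType}.
#' @exportClass SweepBundle
setClass("SweepBundle",
  representation(cellId = "character", epochs = "list", metadata = "list"))

setValidity("SweepBundle", function(object) {
  msgs <- character()
  if (length(object@cellId) != 1L || !nzchar(object@cellId))
    msgs <- c(msgs, "cellId must be a non-empty string")
  if (!all(vapply(object@epochs, is, logical(1), "ProtocolEpoch")))
    msgs <- c(msgs, "epochs must all be ProtocolEpoch objects")
  grp <- object@metadata$group
  if (!is.null(grp) && !grp %in% c("Sham", "6-OHDA", "DMI+6-OHDA", "none"))
    msgs <- c(msgs, "metadata$group must be Sham, 6-OHDA, DMI+6-OHDA or none")
  if (length(msgs)) msgs else TRUE
})

#' FeaturePanel: the per-cell vector of intrinsic properties
#'
#' Every numeric feature carries a presence flag; features an estimator could
#' not resolve are NA with flag FALSE, never silently zero.
#'
#' @slot cellId character scalar.
#' @slot values named numeric vector of feature values (canonical report
#'   units: pA, mV, ms, MOhm, pF, Hz, V/s, mV/pA, s).
#' @slot present named logical vector, same names as \code{values}.
#' @slot meta list (e.g. group label, rate-matched sweep index).
#' @exportClass FeaturePanel
setClass("FeaturePanel",
  representation(cellId = "character", values = "numeric",
                 present = "logical", meta = "list"))

setValidity("FeaturePanel", function(object) {
  msgs <- character()
  if (!identical(names(object@values), names(object@present)))
    msgs <- c(msgs, "values and present must share names")
  if (any(!object@present & !is.na(object@values)) ||
      any(object@present & is.na(object@values)))
    msgs <- c(msgs, "present flags must match non-NA values")
  if (all(c("tau", "input_resistance", "capacitance") %in%
          names(object@values))) {
    v <- object@values
    if (!is.na(v["tau"]) && !is.na(v["input_resistance"]) &&
        !is.na(v["capacitance"]) && v["input_resistance"] > 0 &&
        abs(v["capacitance"] - 1000 * v["tau"] / v["input_resistance"]) >
          1e-6 * max(1, abs(v["capacitance"])))
      msgs <- c(msgs, "capacitance must equal tau/input_resistance")
  }
  if (length(msgs)) msgs else TRUE
})

#' ClusterResult: PCA + Ward clustering output
#'
#' @slot linkage the \code{hclust} object (Ward linkage, Euclidean distance).
#' @slot labels integer cluster labels in 1..k, named by cell id.
#' @slot scores matrix of PC scores (cells x components).
#' @slot loadings matrix of PC loadings (features x components), orthonormal.
#' @slot explainedVariance numeric fractions, decreasing, sum <= 1.
#' @slot nComponents,k integer parameters of the clustering.
#' @slot confusion table or NULL; labels vs known types when supplied.
#' @slot dropped character, cell ids excluded as incomplete cases.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(linkage = "ANY", labels = "integer", scores = "matrix",
                 loadings = "matrix", explainedVariance = "numeric",
                 nComponents = "integer", k = "integer", confusion = "ANY",
                 dropped = "character"))

setValidity("ClusterResult", function(object) {
  msgs <- character()
  h <- object@linkage$height
  if (!is.null(h) && any(diff(h) < -1e-8 * max(abs(h), 1)))
    msgs <- c(msgs, "Ward merge heights must be non-decreasing")
  if (length(object@labels) &&
      !all(object@labels %in% seq_len(object@k)))
    msgs <- c(msgs, "labels must lie in 1..k")
  if (sum(object@explainedVariance) > 1 + 1e-8)
    msgs <- c(msgs, "explained-variance fractions must sum to <= 1")
  if (length(msgs)) msgs else TRUE
})

#' SomaContour: traced cell-body outline
#'
#' @slot vertices numeric matrix (n x 2), micrometers, ordered; the polygon is
#'   closed implicitly (last vertex connects to the first).
#' @exportClass SomaContour
setClass("SomaContour", representation(vertices = "matrix"))

setValidity("SomaContour", function(object) {
  msgs <- character()
  v <- object@vertices
  if (ncol(v) != 2 || nrow(v) < 3)
    msgs <- c(msgs, "contour needs >= 3 two-dimensional vertices")
  else {
    if (abs(.shoelace(v)) <= 0) msgs <- c(msgs, "polygon area must be positive")
    if (!.isSimplePolygon(v)) msgs <- c(msgs, "polygon must be simple (non-self-intersecting)")
  }
  if (length(msgs)) msgs else TRUE
})

#' SomaMetrics: soma shape descriptors
#'
#' @slot area um^2; @slot perimeter um; @slot majorAxis,minorAxis um (axes of
#'   the moments-equivalent ellipse); @slot circularity 4*pi*area/perimeter^2.
#' @exportClass SomaMetrics
setClass("SomaMetrics",
  representation(area = "numeric", perimeter = "numeric",
                 majorAxis = "numeric", minorAxis = "numeric",
                 circularity = "numeric"))

setValidity("SomaMetrics", function(object) {
  msgs <- character()
  if (object@majorAxis < object@minorAxis - 1e-9)
    msgs <- c(msgs, "majorAxis must be >= minorAxis")
  if (object@circularity <= 0 || object@circularity > 1 + 1e-9)
    msgs <- c(msgs, "circularity must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' DendriteTree: SWC-derived reconstruction
#'
#' @slot nodes data.frame with SWC columns: id, type, x, y, z, radius, parent.
#'   Exactly one root (parent -1) of soma type; connected and acyclic.
#' @exportClass DendriteTree
setClass("DendriteTree", representation(nodes = "data.frame"))

setValidity("DendriteTree", function(object) {
  .validateSWCNodes(object@nodes)
})

#' TreeMetrics: dendritic-tree statistics
#'
#' @slot nStems,nBifurcations,nTerminations integer counts.
#' @slot totalLength um; @slot stemLengths um per primary dendrite.
#' @exportClass TreeMetrics
setClass("TreeMetrics",
  representation(nStems = "integer", nBifurcations = "integer",
                 nTerminations = "integer", totalLength = "numeric",
                 stemLengths = "numeric"))

#' PhenotypeParams: simulator parameter set
#'
#' Named-vector backed parameter set of the adaptive leaky integrate-and-fire
#' simulator. See \code{\link{phenotypeParams}} for names, units and defaults.
#'
#' @slot values named numeric vector.
#' @slot label character scalar (phenotype name).
#' @exportClass PhenotypeParams
setClass("PhenotypeParams",
  representation(values = "numeric", label = "character"))

setValidity("PhenotypeParams", function(object) {
  need <- .PARAM_NAMES
  miss <- setdiff(need, names(object@values))
  if (length(miss))
    return(paste("missing parameters:", paste(miss, collapse = ", ")))
  pos <- c("R", "C", "tauW", "tauAhp", "tauH", "kH", "riseMs", "fallMs",
           "apAmp0", "noiseSd", "samplingRate")
  bad <- pos[object@values[pos] <= 0]
  if (length(bad))
    return(paste("parameters must be positive:", paste(bad, collapse = ", ")))
  if (object@values["vReset"] >= object@values["vTh"])
    return("vReset must lie below vTh")
  TRUE
})

#' SyntheticCell: simulated cell with ground truth
#'
#' @slot params \linkS4class{PhenotypeParams} actually used (after
#'   between-cell variability).
#' @slot bundle \linkS4class{SweepBundle} or NULL when only ground truth was
#'   requested.
#' @slot groundTruth named numeric vector of true property values.
#' @slot label character phenotype/group label.
#' @exportClass SyntheticCell
setClass("SyntheticCell",
  representation(params = "PhenotypeParams", bundle = "ANY",
                 groundTruth = "numeric", label = "character"))
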