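#' Construct a Sweep
#'
#' Builds a \linkS4class{Sweep} on a uniform time grid. Either supply
#' \code{time} explicitly (it must be uniform) or let it be derived from
#' \code{samplingRate} and \code{t0}.
#'
#' @param voltage numeric, mV.
#' @param current numeric, pA; a scalar is recycled.
#' @param samplingRate scalar, Hz. Acquisition convention is 10--20 kHz;
#'   rates outside that range trigger a warning, not an error.
#' @param time optional numeric, s.
#' @param t0 start time, s, when \code{time} is derived.
#' @return A \linkS4class{Sweep}.
#' @export
Sweep <- function(voltage, current = 0, samplingRate = 20000,
                  time = NULL, t0 = 0) {
  n <- length(voltage)
  if (length(current) == 1L) current <- rep(current, n)
  if (is.null(time)) time <- t0 + (seq_len(n) - 1L) / samplingRate
  if (samplingRate < 10000 || samplingRate > 20000)
    warning("samplingRate outside the usual 10-20 kHz acquisition range")
  new("Sweep", time = as.numeric(time), voltage = as.numeric(voltage),
      current = as.numeric(current), samplingRate = samplingRate)
}

#' Construct a ProtocolEpoch
#'
#' @param kind epoch kind; see \linkS4class{ProtocolEpoch}.
#' @param sweeps list of \linkS4class{Sweep}.
#' @param holdingPotential mV (NA for the zero-current epoch).
#' @param stepOnset,stepOffset stimulus window, s.
#' @param amplitudes pA per sweep (peak current for ramps).
#' @return A \linkS4class{ProtocolEpoch}.
#' @export
ProtocolEpoch <- function(kind, sweeps, holdingPotential = NA_real_,
                          stepOnset = NA_real_, stepOffset = NA_real_,
                          amplitudes = numeric()) {
  if (length(amplitudes) == 0L && kind == "zero_current_10s")
    amplitudes <- rep(0, length(sweeps))
  new("ProtocolEpoch", kind = kind, holdingPotential = holdingPotential,
      stepOnset = stepOnset, stepOffset = stepOffset,
      amplitudes = as.numeric(amplitudes), sweeps = sweeps)
}

#' Construct a SweepBundle
#'
#' A bundle needs at least one zero-current epoch and one step family for a
#' complete feature panel; bundles missing epochs are legal and the missing
#' features are flagged absent downstream (see \code{\link{missingEpochs}}).
#'
#' @param cellId cell identifier.
#' @param epochs list of \linkS4class{ProtocolEpoch}.
#' @param group experimental group label.
#' @param putativeType optional known type label.
#' @return A \linkS4class{SweepBundle}.
#' @export
SweepBundle <- function(cellId, epochs, group = "none",
                        putativeType = NA_character_) {
  new("SweepBundle", cellId = cellId, epochs = epochs,
      metadata = list(group = group, putativeType = putativeType))
}

#' @rdname SweepBundle
#' @param x,object a SweepBundle.
#' @export
cellId <- function(x) x@cellId

#' Retrieve epochs of a given kind
#'
#' @param x a \linkS4class{SweepBundle}.
#' @param kind epoch kind.
#' @return \code{epochOfKind}: the first matching
#'   \linkS4class{ProtocolEpoch} or NULL; \code{hasEpoch}: logical;
#'   \code{missingEpochs}: kinds required for a full panel but absent.
#' @export
epochOfKind <- function(x, kind) {
  i <- which(vapply(x@epochs, function(e) e@kind, character(1)) == kind)
  if (length(i)) x@epochs[[i[1]]] else NULL
}

#' @rdname epochOfKind
#' @export
hasEpoch <- function(x, kind) !is.null(epochOfKind(x, kind))

#' @rdname epochOfKind
#' @export
missingEpochs <- function(x) {
  setdiff(EPOCH_KINDS, vapply(x@epochs, function(e) e@kind, character(1)))
}

setMethod("show", "SweepBundle", function(object) {
  kinds <- vapply(object@epochs, function(e) e@kind, character(1))
  ns <- vapply(object@epochs, function(e) length(e@sweeps), integer(1))
  cat("SweepBundle '", object@cellId, "' (group: ",
      object@metadata$group %||% "none", ")\n", sep = "")
  for (i in seq_along(kinds))
    cat("  ", kinds[i], ": ", ns[i], " sweep(s)\n", sep = "")
  mi <- missingEpochs(object)
  if (length(mi)) cat("  absent:", paste(mi, collapse = ", "), "\n")
})

setMethod("show", "Sweep", function(object) {
  cat(sprintf("Sweep: %d samples @ %g kHz, %.3f s, V in [%.1f, %.1f] mV\n",
              length(object@time), object@samplingRate / 1000,
              diff(range(object@time)), min(object@voltage),
              max(object@voltage)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- bundle I/O: JSON manifest + one TSV per sweep --------------------------

.UNIT_FACTORS <- list(
  time = c(s = 1, ms = 1e-3),
  voltage = c(mV = 1, V = 1000),
  current = c(pA = 1, nA = 1000, A = 1e12))

.toCanonical <- function(x, quantity, unit) {
  f <- .UNIT_FACTORS[[quantity]][unit]
  if (is.na(f)) .stopf("unsupported %s unit '%s'", quantity, unit)
  x * unname(f)
}

#' Write a sweep bundle to disk
#'
#' Writes one \code{manifest.json} plus one TSV table (columns time, voltage,
#' current; canonical units s/mV/pA) per sweep into \code{path}. Numeric
#' values are preserved to at least 8 significant digits.
#'
#' @param bundle a valid \linkS4class{SweepBundle}.
#' @param path directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
writeBundle <- function(bundle, path) {
  validObject(bundle)
  if (length(bundle@epochs) == 0L)
    .stopf("refusing to write bundle '%s' with no epochs", bundle@cellId)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) .stopf("cannot create directory '%s'", path)
  k <- 0L
  epochs <- lapply(bundle@epochs, function(e) {
    sw <- lapply(seq_along(e@sweeps), function(i) {
      k <<- k + 1L
      fn <- sprintf("sweep_%03d.tsv", k)
      s <- e@sweeps[[i]]
      df <- data.frame(time = sprintf("%.10g", s@time),
                       voltage = sprintf("%.8g", s@voltage),
                       current = sprintf("%.8g", s@current))
      write.table(df, file.path(path, fn), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      list(file = fn, amplitude = e@amplitudes[i],
           sampling_rate = s@samplingRate)
    })
    list(kind = e@kind, holding_potential = e@holdingPotential,
         step_onset = e@stepOnset, step_offset = e@stepOffset, sweeps = sw)
  })
  manifest <- list(
    format_version = 1L,
    cell_id = bundle@cellId,
    metadata = list(group = bundle@metadata$group %||% "none",
                    putative_type = bundle@metadata$putativeType),
    units = list(time = "s", voltage = "mV", current = "pA"),
    epochs = epochs)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a sweep bundle from disk
#'
#' Reads a directory written by \code{\link{writeBundle}} (or conforming to
#' the same manifest schema). Units declared in the manifest are normalized
#' to s/mV/pA. Missing protocol epochs load fine and are reported by
#' \code{\link{missingEpochs}}; a missing manifest or a sweep on a
#' non-uniform time grid is an error.
#'
#' @param path bundle directory.
#' @return A \linkS4class{SweepBundle}.
#' @export
readBundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    .stopf("format error: no manifest.json in '%s'", path)
  m <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (is.null(m$format_version) || m$format_version != 1L)
    .stopf("format error: unsupported format_version in '%s'", mf)
  units <- list(time = m$units$time %||% "s",
                voltage = m$units$voltage %||% "mV",
                current = m$units$current %||% "pA")
  epochs <- lapply(m$epochs, function(e) {
    sweeps <- lapply(e$sweeps, function(sw) {
      tab <- read.delim(file.path(path, sw$file))
      tm <- .toCanonical(tab$time, "time", units$time)
      if (length(tm) >= 2) {
        dt <- diff(tm)
        if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
          .stopf("data error: non-uniform time grid in sweep '%s'", sw$file)
      }
      rate <- sw$sampling_rate %||% (1 / stats::median(diff(tm)))
      Sweep(voltage = .toCanonical(tab$voltage, "voltage", units$voltage),
            current = .toCanonical(tab$current, "current", units$current),
            samplingRate = rate, time = tm)
    })
    ProtocolEpoch(kind = e$kind, sweeps = sweeps,
      holdingPotential = as.numeric(e$holding_potential %||% NA),
      stepOnset = as.numeric(e$step_onset %||% NA),
      stepOffset = as.numeric(e$step_offset %||% NA),
      amplitudes = vapply(e$sweeps, function(sw)
        as.numeric(sw$amplitude %||% NA), numeric(1)))
  })
  b <- SweepBundle(cellId = m$cell_id, epochs = epochs,
                   group = m$metadata$group %||% "none",
                   putativeType = as.character(m$metadata$putative_type %||%
                                                 NA_character_))
  validObject(b)
  b
}

## ---- SWC I/O ----------------------------------------------------------------

#' Read an SWC reconstruction
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent). Requires a
#' single root of soma type; cycles, orphan parents and self-parenting are
#' structure errors.
#'
#' @param path SWC file.
#' @return A \linkS4class{DendriteTree}.
#' @export
readSWC <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) .stopf("structure error: empty SWC file '%s'", path)
  fields <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(fields) != 7)
    .stopf("structure error: SWC must have 7 columns ('%s')", path)
  nodes <- data.frame(id = as.integer(fields[, 1]),
                      type = as.integer(fields[, 2]),
                      x = fields[, 3], y = fields[, 4], z = fields[, 5],
                      radius = fields[, 6],
                      parent = as.integer(fields[, 7]))
  ok <- .validateSWCNodes(nodes)
  if (!isTRUE(ok)) .stopf("structure error in '%s': %s", path, ok[1])
  new("DendriteTree", nodes = nodes)
}

#' Write an SWC reconstruction
#'
#' @param tree a \linkS4class{DendriteTree}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSWC <- function(tree, path) {
  validObject(tree)
  n <- tree@nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %.8g %.8g %.8g %.8g %d",
                     n$id, n$type, n$x, n$y, n$z, n$radius, n$parent), con)
  invisible(path)
}

#' Canonical topology fingerprint of a tree
#'
#' Hash-friendly canonical string of the rooted tree topology (invariant to
#' node renumbering and child order), used in round-trip tests.
#'
#' @param tree a \linkS4class{DendriteTree}.
#' @return character scalar.
#' @export
topologyHash <- function(tree) {
  n <- tree@nodes
  kids <- split(n$id, factor(n$parent, levels = n$id))
  canon <- function(id) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || !length(ch)) return("()")
    paste0("(", paste(sort(vapply(ch, canon, character(1))), collapse = ""),
           ")")
  }
  canon(n$id[n$parent == -1])
}

setMethod("show", "DendriteTree", function(object) {
  cat(sprintf("DendriteTree: %d nodes\n", nrow(object@nodes)))
})
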