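## Group-comparison layer: Kolmogorov-Smirnov normality gate, then
## t-test / Mann-Whitney U (two groups) or ANOVA / Kruskal-Wallis (three or
## more). No multiple-testing correction is applied; every comparison is
## reported so users can apply their own.

#' Kolmogorov-Smirnov normality gate
#'
#' TRUE iff every group passes a KS test against a normal distribution with
#' parameters estimated from the sample (alpha = 0.05). Groups with fewer
#' than 3 values fail the gate with a warning. Note that using estimated
#' parameters makes the KS test conservative as a normality test; this
#' mirrors common practice in acquisition software.
#'
#' @param groups list of numeric vectors.
#' @param alpha significance level, default 0.05.
#' @return logical scalar.
#' @export
normalityGate <- function(groups, alpha = 0.05) {
  for (g in groups) {
    g <- g[!is.na(g)]
    if (length(g) < 3) {
      warning("group with n < 3: insufficient data for a normality test")
      return(FALSE)
    }
    if (sd(g) == 0) return(FALSE)
    p <- suppressWarnings(
      ks.test(g, "pnorm", mean = mean(g), sd = sd(g))$p.value)
    if (p < alpha) return(FALSE)
  }
  TRUE
}

#' Compare a feature across groups
#'
#' Two groups: unpaired t-test if the normality gate passes, Mann-Whitney U
#' otherwise. Three or more groups: one-way ANOVA or Kruskal-Wallis. Reports
#' per-group mean +/- SEM and n.
#'
#' @param values numeric vector of feature values.
#' @param group group labels, same length.
#' @param feature feature name for the report.
#' @param exact logical or NA; passed to \code{wilcox.test} (NA = its
#'   default rule: exact for small untied samples, asymptotic otherwise).
#' @param alpha gate significance level.
#' @return data.frame (one row): feature, test, statistic, p_value, normal,
#'   plus per-group mean/sem/n list-columns in attributes \code{groups}.
#' @export
compareGroups <- function(values, group, feature = "feature", exact = NA,
                          alpha = 0.05) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- factor(as.character(group[keep]))
  gs <- split(values, group)
  if (length(gs) < 2) .stopf("need at least 2 groups")
  if (any(vapply(gs, length, integer(1)) < 2))
    .stopf("empty or singleton group in comparison of '%s'", feature)
  normal <- normalityGate(gs, alpha = alpha)
  if (length(gs) == 2) {
    if (normal) {
      ht <- t.test(gs[[1]], gs[[2]], var.equal = TRUE)
      test <- "t"
    } else {
      ht <- suppressWarnings(
        if (is.na(exact)) wilcox.test(gs[[1]], gs[[2]])
        else wilcox.test(gs[[1]], gs[[2]], exact = exact))
      test <- "Mann-Whitney"
    }
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    if (normal) {
      fit <- aov(values ~ group)
      tab <- anova(fit)
      stat <- tab$`F value`[1]
      p <- tab$`Pr(>F)`[1]
      test <- "ANOVA"
    } else {
      ht <- kruskal.test(values, group)
      stat <- unname(ht$statistic)
      p <- ht$p.value
    test <- "Kruskal-Wallis"
    }
  }
  out <- data.frame(feature = feature, test = test, statistic = stat,
                    p_value = p, normal = normal)
  attr(out, "groups") <- data.frame(
    group = names(gs),
    n = vapply(gs, length, integer(1)),
    mean = vapply(gs, mean, numeric(1)),
    sem = vapply(gs, function(x) sd(x) / sqrt(length(x)), numeric(1)))
  out
}

#' Percentage of spontaneously active cells
#'
#' round(100 * nActive / nTotal) to the nearest integer, rounding halves
#' away from zero (the printed-percentage convention: 11 of 30 gives 37).
#'
#' @param nActive,nTotal counts, 0 <= nActive <= nTotal, nTotal > 0.
#' @return integer percent.
#' @export
percentActive <- function(nActive, nTotal) {
  if (any(nTotal <= 0)) .stopf("nTotal must be positive")
  if (any(nActive < 0 | nActive > nTotal))
    .stopf("need 0 <= nActive <= nTotal")
  as.integer(.roundHalfAway(100 * nActive / nTotal))
}

#' Run the full synthetic-cohort pipeline
#'
#' Generate-or-load bundles, extract feature panels, classify, compute
#' morphometrics and group statistics, and write a TSV/JSON report plus a
#' log carrying the seed and configuration. The default configuration
#' simulates a two-group 5-HT-like cohort (Sham vs a capacitance-and-AHP
#' reduced lesion-like group).
#'
#' @param config list; recognised entries (with defaults):
#'   \code{nPerGroup} (12), \code{types} (c("5HT","5HT")),
#'   \code{labels} (c("Sham","6-OHDA")), \code{effects}
#'   (list(NULL, list(C = 0.7, tauAhp = 0.7, apAmp0 = 0.9))),
#'   \code{targetRates}, \code{features} to test, \code{classify} (TRUE),
#'   \code{morphometrics} (TRUE), \code{exact} (NA). Alternatively a path
#'   to a JSON file with those entries.
#' @param seed integer.
#' @param outDir output directory.
#' @return list with panels data.frame, comparisons, cluster result and
#'   morphometrics table; report files written to \code{outDir}.
#' @export
runPipeline <- function(config = list(), seed = 1, outDir = tempfile()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (!is.list(config)) .stopf("config must be a list or a JSON file path")
  known <- c("nPerGroup", "types", "labels", "effects", "targetRates",
             "features", "classify", "morphometrics", "exact", "cv")
  bad <- setdiff(names(config), known)
  if (length(bad)) .stopf("unknown config entries: %s",
                          paste(bad, collapse = ", "))
  cfg <- list(
    nPerGroup = config$nPerGroup %||% 12,
    types = config$types %||% c("5HT", "5HT"),
    labels = config$labels %||% c("Sham", "6-OHDA"),
    effects = config$effects %||%
      list(NULL, list(C = 0.7, tauAhp = 0.7, apAmp0 = 0.9)),
    targetRates = config$targetRates,
    features = config$features %||%
      c("rheobase", "ap_amplitude", "ahp_duration", "tau", "capacitance",
        "input_resistance", "delay_first_spike"),
    classify = config$classify %||% TRUE,
    morphometrics = config$morphometrics %||% TRUE,
    exact = config$exact %||% NA,
    cv = config$cv %||% 0.15)
  if (isTRUE(cfg$classify) && sum(rep_len(cfg$nPerGroup,
                                          length(cfg$types))) < 4)
    .stopf("classification requires at least 4 cells")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "pipeline.log")
  logLine <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    message(msg)
  }
  logLine("seed: %d", seed)
  logLine("package version: %s",
          as.character(utils::packageVersion("IntrinsicEphys")))
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null")
  logLine("config: %s", cfgJson)
  logLine("config md5: %s", tools::md5sum(
    {f <- tempfile(); writeLines(cfgJson, f); f}))

  logLine("simulating cohort ...")
  cells <- makeCohort(cfg$nPerGroup, cfg$types, effects = cfg$effects,
                      labels = cfg$labels, seed = seed, cv = cfg$cv,
                      targetRates = cfg$targetRates)
  logLine("extracting feature panels for %d cells ...", length(cells))
  panels <- lapply(cells, function(cell)
    extractPanel(cell@bundle,
                 targetRate = if (cell@params@label == "DA") 2 else 1))
  for (i in seq_along(panels)) panels[[i]]@meta$group <- cells[[i]]@label
  df <- exportPanels(panels, file.path(outDir, "panels"))

  groups <- vapply(cells, function(cell) cell@label, character(1))
  comparisons <- do.call(rbind, lapply(cfg$features, function(f)
    tryCatch(compareGroups(df[[f]], groups, feature = f, exact = cfg$exact),
             error = function(e) data.frame(
               feature = f, test = NA_character_, statistic = NA_real_,
               p_value = NA_real_, normal = NA))))
  write.table(comparisons, file.path(outDir, "comparisons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cluster <- NULL
  if (isTRUE(cfg$classify)) {
    logLine("classifying ...")
    cluster <- tryCatch(
      classifyTwoTypes(panels, knownLabels = groups),
      error = function(e) {
        logLine("classification skipped: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(cluster))
      exportClusterResult(cluster, file.path(outDir, "cluster"))
  }

  morpho <- NULL
  if (isTRUE(cfg$morphometrics)) {
    logLine("morphometrics on synthetic contours/trees ...")
    morpho <- do.call(rbind, lapply(seq_along(cells), function(i) {
      circ <- if (groups[i] == cfg$labels[1]) 0.75 else 0.85
      sm <- somaMetrics(makeSomaPolygon(circ, scale = 8, seed = seed + i))
      tr <- makeTree(3, 4, seed = seed + i)
      tm <- treeMetrics(tr)
      data.frame(cell_id = df$cell_id[i], group = groups[i],
                 soma_area = sm@area, soma_perimeter = sm@perimeter,
                 soma_major = sm@majorAxis, soma_minor = sm@minorAxis,
                 circularity = sm@circularity, n_stems = tm@nStems,
                 n_bifurcations = tm@nBifurcations,
                 n_terminations = tm@nTerminations,
                 dendritic_length = tm@totalLength)
    }))
    write.table(morpho, file.path(outDir, "morphometrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  nAct <- vapply(split(df$spontaneous, groups), function(x)
    sum(x, na.rm = TRUE), numeric(1))
  nTot <- table(groups)[names(nAct)]
  summary <- list(
    seed = seed, n_cells = length(cells),
    percent_active = as.list(setNames(
      percentActive(nAct, as.numeric(nTot)), names(nAct))),
    cluster_purity = if (!is.null(cluster))
      clusterPurity(cluster@labels,
                    groups[match(names(cluster@labels), df$cell_id)])
      else NULL)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logLine("done; report in %s", outDir)
  invisible(list(panels = df, comparisons = comparisons, cluster = cluster,
                 morphometrics = morpho, summary = summary))
}
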