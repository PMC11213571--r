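## Cell-type classification: standardize -> PCA -> Ward/Euclidean clustering.

#' Collect feature panels into a SummarizedExperiment
#'
#' Features are rows, cells are columns. Assay \code{values} holds the
#' feature matrix (NA for absent features), assay \code{present} the flags;
#' \code{colData} carries group and known-type labels.
#'
#' @param panels list of \linkS4class{FeaturePanel}.
#' @param features feature names to keep (default: all panel features).
#' @return A \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
panelExperiment <- function(panels, features = NULL) {
  features <- features %||% names(panels[[1]]@values)
  vals <- vapply(panels, function(p) p@values[features],
                 numeric(length(features)))
  pres <- vapply(panels, function(p) p@present[features],
                 logical(length(features)))
  ids <- vapply(panels, function(p) p@cellId, character(1))
  dimnames(vals) <- dimnames(pres) <- list(features, ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(values = vals, present = pres),
    colData = S4Vectors::DataFrame(
      group = vapply(panels, function(p) p@meta$group %||% "none",
                     character(1)),
      putativeType = vapply(panels, function(p)
        as.character(p@meta$putativeType %||% NA_character_), character(1)),
      row.names = ids))
}

# coerce panels / SE / matrix to a cells x features matrix
.featureMatrix <- function(x, features = NULL) {
  if (is.list(x) && length(x) && is(x[[1]], "FeaturePanel"))
    x <- panelExperiment(x, features)
  if (is(x, "SummarizedExperiment")) {
    m <- t(SummarizedExperiment::assay(x, "values"))
    if (!is.null(features)) m <- m[, features, drop = FALSE]
    return(m)
  }
  m <- as.matrix(x)
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  m
}

#' Standardize a feature matrix
#'
#' Column-wise z-scores over non-missing entries (sample SD); missing entries
#' stay missing. A zero-variance column is an error naming the column.
#'
#' @param x cells x features matrix (or SummarizedExperiment / list of
#'   panels; coerced).
#' @return matrix of the same shape.
#' @export
standardizeFeatures <- function(x) {
  m <- .featureMatrix(x)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2)
      .stopf("feature '%s' has fewer than 2 non-missing values",
             colnames(m)[j] %||% as.character(j))
    s <- sd(v[ok])
    if (s == 0)
      .stopf("feature '%s' has zero variance", colnames(m)[j] %||%
               as.character(j))
    m[, j] <- (v - mean(v[ok])) / s
  }
  m
}

#' Principal component analysis of a standardized feature matrix
#'
#' Complete-case cells only (cells with any missing feature are dropped and
#' reported). Loadings are orthonormal; the sign convention makes each
#' loading's largest-magnitude element positive so results are deterministic
#' across platforms.
#'
#' @param x standardized cells x features matrix.
#' @return list(scores, loadings, explainedVariance, kept, dropped).
#' @export
pcaFeatures <- function(x) {
  m <- .featureMatrix(x)
  cc <- stats::complete.cases(m)
  if (sum(cc) < 2) .stopf("PCA needs at least 2 complete-case cells")
  mm <- m[cc, , drop = FALSE]
  p <- prcomp(mm, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  loadings <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       explainedVariance = p$sdev^2 / sum(p$sdev^2),
       kept = rownames(mm) %||% which(cc),
       dropped = (rownames(m) %||% as.character(seq_len(nrow(m))))[!cc])
}

#' Ward hierarchical clustering of PC scores
#'
#' Agglomerative clustering with Ward's criterion on Euclidean distances over
#' the first \code{nComponents} score columns (\code{hclust} method
#' \code{ward.D2}); flat labels by cutting the tree at \code{k} clusters.
#'
#' @param scores cells x components score matrix.
#' @param nComponents number of leading components to use (2 or 3).
#' @param k number of flat clusters.
#' @param pca optional list from \code{\link{pcaFeatures}} to embed in the
#'   result.
#' @param knownLabels optional vector of known types (same order as rows of
#'   \code{scores}); a confusion table is attached.
#' @return A \linkS4class{ClusterResult}.
#' @export
wardCluster <- function(scores, nComponents = 2, k = 2, pca = NULL,
                        knownLabels = NULL) {
  stopifnot(nComponents >= 1)
  if (k > nrow(scores))
    .stopf("k = %d exceeds the number of cells (%d)", k, nrow(scores))
  use <- scores[, seq_len(min(nComponents, ncol(scores))), drop = FALSE]
  hc <- hclust(dist(use, method = "euclidean"), method = "ward.D2")
  labels <- cutree(hc, k = k)
  conf <- if (!is.null(knownLabels)) table(cluster = labels,
                                           type = knownLabels) else NULL
  new("ClusterResult", linkage = hc, labels = as.integer(labels),
      scores = scores,
      loadings = pca$loadings %||% matrix(numeric(), 0, 0),
      explainedVariance = pca$explainedVariance %||% numeric(),
      nComponents = as.integer(nComponents), k = as.integer(k),
      confusion = conf,
      dropped = as.character(pca$dropped %||% character()))
}

.classifyPipeline <- function(x, features, nComponents, k,
                              knownLabels = NULL) {
  m <- .featureMatrix(x, features)
  cc <- stats::complete.cases(m)
  if (sum(cc) < 2 * k)
    .stopf("classification needs at least %d complete-case cells (have %d)",
           2 * k, sum(cc))
  z <- standardizeFeatures(m[cc, , drop = FALSE])
  pc <- pcaFeatures(z)
  if (!is.null(knownLabels)) knownLabels <- knownLabels[cc]
  res <- wardCluster(pc$scores, nComponents = nComponents, k = k, pca = pc,
                     knownLabels = knownLabels)
  res@dropped <- (rownames(m) %||% as.character(seq_len(nrow(m))))[!cc]
  names(res@labels) <- rownames(pc$scores)
  res
}

#' Two-type classification on the five-parameter panel
#'
#' Standardizes the five separating properties (delay to first spike, AP
#' drop rate, AP max rise rate, AHP duration, capacitance), runs PCA, and
#' Ward-clusters the first two PC scores into k = 2 groups.
#'
#' @param x list of \linkS4class{FeaturePanel}, a SummarizedExperiment from
#'   \code{\link{panelExperiment}}, or a cells x features matrix.
#' @param knownLabels optional known types for a confusion table.
#' @return A \linkS4class{ClusterResult}.
#' @export
classifyTwoTypes <- function(x, knownLabels = NULL) {
  .classifyPipeline(x, fiveFeatureNames, nComponents = 2, k = 2,
                    knownLabels = knownLabels)
}

#' Four-type classification on the twenty-parameter panel
#'
#' Standardizes the extended panel (\code{twentyFeatureNames}), runs PCA and
#' Ward-clusters the first three PC scores into k = 4 groups.
#'
#' @inheritParams classifyTwoTypes
#' @return A \linkS4class{ClusterResult}.
#' @export
classifyFourTypes <- function(x, knownLabels = NULL) {
  .classifyPipeline(x, twentyFeatureNames, nComponents = 3, k = 4,
                    knownLabels = knownLabels)
}

#' Cluster purity against known labels
#'
#' Fraction of cells whose cluster maps to their true type under the best
#' one-to-one cluster-to-type assignment (all permutations; k is small).
#'
#' @param labels integer cluster labels.
#' @param truth known type labels, same length.
#' @return purity in [0, 1].
#' @export
clusterPurity <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  tab <- table(labels, truth)
  k <- nrow(tab)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  cols <- seq_len(ncol(tab))
  best <- 0
  for (p in perms(cols)) {
    hit <- sum(vapply(seq_len(min(k, length(cols))), function(i)
      tab[i, p[i]], numeric(1)))
    best <- max(best, hit)
  }
  best / length(labels)
}

#' Export a clustering result
#'
#' Writes the 4-column merge table (\code{merge} pairs, height, size), flat
#' labels and PC scores as TSV files.
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param path base path; writes \code{<path>_linkage.tsv},
#'   \code{<path>_labels.tsv}, \code{<path>_scores.tsv}.
#' @return \code{path}, invisibly.
#' @export
exportClusterResult <- function(result, path) {
  hc <- result@linkage
  # standard 4-column linkage: left, right, height, merged cluster size
  size <- integer(length(hc$height))
  csize <- function(m) if (m < 0) 1L else size[m]
  for (i in seq_along(hc$height))
    size[i] <- csize(hc$merge[i, 1]) + csize(hc$merge[i, 2])
  link <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                     height = hc$height, size = size)
  write.table(link, paste0(path, "_linkage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = names(result@labels),
                         cluster = result@labels),
              paste0(path, "_labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(cell_id = rownames(result@scores),
                         result@scores),
              paste0(path, "_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d cells, k = %d on %d PC(s)\n",
              length(object@labels), object@k, object@nComponents))
  if (length(object@explainedVariance))
    cat("  explained variance:",
        paste0(sprintf("%.1f%%", 100 * head(object@explainedVariance, 4)),
               collapse = ", "), "\n")
  cat("  cluster sizes:", paste(table(object@labels), collapse = ", "), "\n")
  if (!is.null(object@confusion)) {
    cat("  confusion (cluster x type):\n")
    print(object@confusion)
  }
  if (length(object@dropped))
    cat("  dropped (incomplete cases):", length(object@dropped), "\n")
})
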