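## Soma-contour shape descriptors and dendritic-tree statistics.

#' Construct a SomaContour
#'
#' @param vertices n x 2 numeric matrix of ordered polygon vertices (um).
#'   The polygon is closed implicitly and must be simple.
#' @return A \linkS4class{SomaContour}.
#' @export
SomaContour <- function(vertices) {
  v <- as.matrix(vertices)
  colnames(v) <- c("x", "y")
  obj <- new("SomaContour", vertices = v)
  validObject(obj)
  obj
}

# exact area moments of a simple polygon (second central moments per unit
# area), via the standard shoelace-type contour integrals
.polygonMoments <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- x * yn - xn * y
  A <- sum(a) / 2
  cx <- sum((x + xn) * a) / (6 * A)
  cy <- sum((y + yn) * a) / (6 * A)
  Ixx <- sum((y^2 + y * yn + yn^2) * a) / 12
  Iyy <- sum((x^2 + x * xn + xn^2) * a) / 12
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * a) / 24
  s <- sign(A)
  A <- abs(A)
  # central second moments per unit area (covariance of the uniform lamina)
  list(area = A, cx = cx, cy = cy,
       mxx = s * Iyy / A - cx^2,   # var of x
       myy = s * Ixx / A - cy^2,   # var of y
       mxy = s * Ixy / A - cx * cy)
}

#' Soma shape metrics
#'
#' Area by the shoelace formula; perimeter as the closed polygon length;
#' major/minor axis from the moments-equivalent best-fit ellipse (the ellipse
#' with the same area and second moments, the usual image-analysis "fit
#' ellipse"); circularity = 4*pi*area/perimeter^2, which is 1 for a circle
#' and < 1 for elongated or complex shapes.
#'
#' @param contour a \linkS4class{SomaContour} (or vertex matrix).
#' @return A \linkS4class{SomaMetrics}.
#' @export
somaMetrics <- function(contour) {
  if (!is(contour, "SomaContour")) contour <- SomaContour(contour)
  validObject(contour)
  v <- contour@vertices
  A <- abs(.shoelace(v))
  d <- rbind(diff(v), v[1, ] - v[nrow(v), ])
  P <- sum(sqrt(rowSums(d^2)))
  m <- .polygonMoments(v)
  cov <- matrix(c(m$mxx, m$mxy, m$mxy, m$myy), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  ev[ev < 0] <- 0
  new("SomaMetrics", area = A, perimeter = P,
      majorAxis = 4 * sqrt(ev[1]), minorAxis = 4 * sqrt(ev[2]),
      circularity = min(1, 4 * pi * A / P^2))
}

setMethod("show", "SomaMetrics", function(object) {
  cat(sprintf(paste0("SomaMetrics: area %.2f um^2, perimeter %.2f um,\n",
                     "  major axis %.2f um, minor axis %.2f um, ",
                     "circularity %.4f\n"),
              object@area, object@perimeter, object@majorAxis,
              object@minorAxis, object@circularity))
})

#' Dendritic-tree statistics
#'
#' Primary dendrites are children of the soma root; bifurcations are
#' non-soma nodes with at least two children (a node with c > 2 children
#' counts as c - 1 bifurcations, with a message); terminations are non-soma
#' leaves. Lengths are summed 3-D Euclidean segment lengths; per-stem
#' lengths cover each primary dendrite's subtree.
#'
#' @param tree a \linkS4class{DendriteTree}.
#' @return A \linkS4class{TreeMetrics}.
#' @export
treeMetrics <- function(tree) {
  validObject(tree)
  n <- tree@nodes
  rootId <- n$id[n$parent == -1]
  pidx <- match(n$parent, n$id)
  nKids <- tabulate(pidx[!is.na(pidx)], nbins = nrow(n))
  isSoma <- n$type == 1L
  stems <- which(!isSoma & n$parent %in% n$id[isSoma])
  bifNodes <- which(!isSoma & nKids >= 2)
  over <- nKids[bifNodes] > 2
  if (any(over))
    message(sum(over), " node(s) with > 2 children counted as multiple ",
            "bifurcations")
  nBif <- sum(pmax(0L, nKids[bifNodes] - 1L))
  terms <- which(!isSoma & nKids == 0)
  segLen <- numeric(nrow(n))
  hasPar <- !is.na(pidx) & !isSoma
  segLen[hasPar] <- sqrt((n$x[hasPar] - n$x[pidx[hasPar]])^2 +
                           (n$y[hasPar] - n$y[pidx[hasPar]])^2 +
                           (n$z[hasPar] - n$z[pidx[hasPar]])^2)
  # assign each node to its stem by walking up the parent chain
  stemOf <- integer(nrow(n))
  for (i in which(!isSoma)) {
    j <- i
    while (!is.na(pidx[j]) && !isSoma[pidx[j]]) j <- pidx[j]
    stemOf[i] <- j
  }
  stemLengths <- vapply(stems, function(s)
    sum(segLen[stemOf == s]), numeric(1))
  new("TreeMetrics", nStems = length(stems), nBifurcations = as.integer(nBif),
      nTerminations = length(terms), totalLength = sum(segLen),
      stemLengths = stemLengths)
}

setMethod("show", "TreeMetrics", function(object) {
  cat(sprintf(paste0("TreeMetrics: %d primary dendrite(s), %d bifurcation(s),",
                     " %d termination(s),\n  total length %.1f um\n"),
              object@nStems, object@nBifurcations, object@nTerminations,
              object@totalLength))
})

#' Read a soma contour from a CSV vertex list
#'
#' @param path CSV with columns x, y (um).
#' @return A \linkS4class{SomaContour}.
#' @export
readContour <- function(path) {
  df <- utils::read.csv(path)
  SomaContour(as.matrix(df[, c("x", "y")]))
}

#' @rdname readContour
#' @param contour a \linkS4class{SomaContour}.
#' @export
writeContour <- function(contour, path) {
  utils::write.csv(data.frame(x = contour@vertices[, 1],
                              y = contour@vertices[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
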