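# internal helpers shared across modules

.shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# segment-intersection test for simple-polygon validation; vectorized over
# all non-adjacent edge pairs (contours have at most a few hundred vertices)
.isSimplePolygon <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- pairs[, 2] - pairs[, 1] >= 2 &
    !(pairs[, 1] == 1 & pairs[, 2] == n)
  i <- pairs[keep, 1]
  j <- pairs[keep, 2]
  if (!length(i)) return(TRUE)
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  !any(((d1 > 0) != (d2 > 0)) & ((d3 > 0) != (d4 > 0)))
}

.validateSWCNodes <- function(nodes) {
  msgs <- character()
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    return(paste("SWC table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nodes$id)) msgs <- c(msgs, "duplicate node ids")
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L)
    msgs <- c(msgs, "exactly one root (parent = -1) required")
  else if (nodes$type[roots] != 1L)
    msgs <- c(msgs, "root must be of soma type (type 1)")
  if (any(nodes$parent == nodes$id))
    msgs <- c(msgs, "node cannot be its own parent")
  known <- nodes$parent %in% c(-1, nodes$id)
  if (!all(known)) msgs <- c(msgs, "orphan nodes: parent id not in table")
  if (!length(msgs)) {
    # connectivity/acyclicity: walk each node to the root
    idx <- match(nodes$parent, nodes$id)
    n <- nrow(nodes)
    for (i in seq_len(n)) {
      seen <- logical(n)
      j <- i
      while (!is.na(idx[j])) {
        if (seen[j]) return("cycle detected in SWC parent links")
        seen[j] <- TRUE
        j <- idx[j]
      }
      if (nodes$parent[j] != -1) return("disconnected node (no path to root)")
    }
  }
  if (length(msgs)) msgs else TRUE
}

# rounding half away from zero (printed-percentage convention)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
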