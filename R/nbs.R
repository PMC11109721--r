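# upper-triangle edge indexing helpers shared across the NBS stage
.upperTriIndex <- function(n) which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)

# stack a list of ConnectivityMatrix (or matrices) into subjects x edges
.edgeMatrix <- function(matrices) {
  vals <- lapply(matrices, function(m)
    if (is(m, "ConnectivityMatrix")) m@values else as.matrix(m))
  n <- nrow(vals[[1]])
  ut <- upper.tri(vals[[1]])
  E <- t(vapply(vals, function(v) v[ut], numeric(sum(ut))))
  rownames(E) <- names(matrices)
  attr(E, "nNodes") <- n
  E
}

#' One-sample edge mask for sparse connectomes
#'
#' For every inter-node connection, a one-sample t-test of the edge values
#' against zero is run across the supplied matrices; edges whose two-sided p
#' is not below \code{alpha} are zeroed in every matrix. Zero-variance edges
#' are retained when their common value is nonzero (a perfectly consistent
#' signal) and masked out when it is zero.
#'
#' @param matrices named list of \linkS4class{ConnectivityMatrix} (at least
#'   3) sharing a node set.
#' @param alpha two-sided significance level for edge retention.
#' @return a \linkS4class{SparseConnectomeSet}.
#' @export
oneSampleEdgeMask <- function(matrices, alpha = 0.05) {
  if (length(matrices) < 3) stop("need at least 3 matrices for the edge test")
  E <- .edgeMatrix(matrices)
  n <- attr(E, "nNodes")
  S <- nrow(E)
  mu <- colMeans(E)
  sdv <- sqrt(colSums(sweep(E, 2, mu)^2) / (S - 1))
  t <- mu / (sdv / sqrt(S))
  p <- 2 * stats::pt(-abs(t), df = S - 1)
  keep <- ifelse(sdv < 1e-14, abs(mu) > 1e-14, p < alpha)
  mask <- matrix(FALSE, n, n)
  mask[upper.tri(mask)] <- keep
  mask <- mask | t(mask)
  masked <- lapply(matrices, function(m) {
    v <- m@values
    v[!mask] <- 0
    diag(v) <- 0
    initialize(m, values = v)
  })
  new("SparseConnectomeSet", matrices = masked, mask = mask,
      maskingAlpha = alpha)
}

#' Edge-wise GLM contrast statistics
#'
#' Applies the Freedman-Lane contrast t statistic of the permutation GLM to
#' every retained edge of a masked connectome set, under one design shared
#' across edges. Masked edges carry \code{NA}.
#'
#' @param sparseSet a \linkS4class{SparseConnectomeSet}; its matrices must
#'   be ordered to match the rows of \code{design@X}.
#' @param design a \linkS4class{DesignSpec}.
#' @return symmetric node x node matrix of t statistics (\code{NA} on
#'   masked edges and the diagonal).
#' @export
edgewiseStats <- function(sparseSet, design) {
  validObject(design)
  E <- .edgeMatrix(sparseSet@matrices)
  n <- attr(E, "nNodes")
  keep <- sparseSet@mask[upper.tri(sparseSet@mask)]
  t <- rep(NA_real_, length(keep))
  if (any(keep))
    t[keep] <- .tStats(E[, keep, drop = FALSE], design@X, design@contrast)
  out <- matrix(NA_real_, n, n)
  out[upper.tri(out)] <- t
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Connected components of supra-threshold edges
#'
#' Builds the graph of edges whose t statistic exceeds the primary
#' threshold in the requested direction (\code{t > thr},
#' \code{t < -thr}, or \code{|t| > thr}) and returns its maximal connected
#' components, ordered by edge count (descending), ties broken by the
#' lexicographic node list.
#'
#' @param edgeT symmetric t matrix (NA = masked).
#' @param primaryThreshold positive cluster-forming threshold.
#' @param direction \code{"positive"}, \code{"negative"} or
#'   \code{"two.sided"}.
#' @return list of components, each with \code{edges} (two-column matrix of
#'   node indices), \code{nodes}, and \code{size} (edge count).
#' @export
supraThresholdComponents <- function(edgeT, primaryThreshold,
                                     direction = c("positive", "negative",
                                                   "two.sided")) {
  direction <- match.arg(direction)
  A <- .supraAdjacency(edgeT, primaryThreshold, direction)
  if (!any(A)) return(list())
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  ut <- which(A & upper.tri(A), arr.ind = TRUE)
  comps <- lapply(split(seq_len(nrow(ut)), memb[ut[, 1]]), function(ix) {
    edges <- ut[ix, , drop = FALSE]
    nodes <- sort(unique(as.vector(edges)))
    list(edges = unname(edges), nodes = nodes, size = nrow(edges))
  })
  ord <- order(-vapply(comps, `[[`, 0L, "size"),
               vapply(comps, function(co) paste(co$nodes, collapse = ","), ""))
  unname(comps[ord])
}

.supraAdjacency <- function(edgeT, thr, direction) {
  A <- switch(direction,
    positive = edgeT > thr,
    negative = edgeT < -thr,
    two.sided = abs(edgeT) > thr)
  A[is.na(A)] <- FALSE
  A
}

#' Network-based statistics with component-level FWE control
#'
#' Edge-level permutation inference: every retained edge is tested with the
#' design's contrast, edges beyond the primary threshold are clustered into
#' connected components, and each observed component's family-wise-error
#' corrected p-value is the proportion of the permutation distribution of
#' the MAXIMAL component size (in edges; identity permutation included)
#' that reaches the observed size. Permutations use the same Freedman-Lane
#' scheme as the scalar permutation GLM, synchronized across edges.
#'
#' @param sparseSet a \linkS4class{SparseConnectomeSet}, ordered to match
#'   \code{design@X}.
#' @param design a \linkS4class{DesignSpec}.
#' @param primaryThreshold positive cluster-forming t threshold.
#' @param direction component direction, see
#'   \code{\link{supraThresholdComponents}}.
#' @return an \linkS4class{NBSResult}.
#' @export
nbsFwe <- function(sparseSet, design, primaryThreshold = 3.0,
                   direction = c("positive", "negative", "two.sided")) {
  direction <- match.arg(direction)
  validObject(design)
  E <- .edgeMatrix(sparseSet@matrices)
  n <- attr(E, "nNodes")
  keep <- sparseSet@mask[upper.tri(sparseSet@mask)]
  utIdx <- .upperTriIndex(n)[keep, , drop = FALSE]
  if (!any(keep)) {
    empty <- matrix(NA_real_, n, n)
    return(new("NBSResult", edgeT = empty,
               primaryThreshold = primaryThreshold, direction = direction,
               components = list(), nullMaxSize = 0L,
               nPermUsed = 1L, seed = design@seed))
  }
  T <- .flStats(E[, keep, drop = FALSE], design@X, design@contrast,
                design@exchangeability, design@nPermutations, design@seed)
  R <- nrow(T)
  # max component size (edges) per permutation
  maxSize <- integer(R)
  for (r in seq_len(R))
    maxSize[r] <- .maxComponentSize(T[r, ], utIdx, n, primaryThreshold,
                                    direction)
  edgeT <- matrix(NA_real_, n, n)
  tvec <- rep(NA_real_, length(keep)); tvec[keep] <- T[1, ]
  edgeT[upper.tri(edgeT)] <- tvec
  edgeT[lower.tri(edgeT)] <- t(edgeT)[lower.tri(edgeT)]
  comps <- supraThresholdComponents(edgeT, primaryThreshold, direction)
  comps <- lapply(comps, function(co) {
    co$pFWE <- sum(maxSize >= co$size) / R
    co
  })
  new("NBSResult", edgeT = edgeT, primaryThreshold = primaryThreshold,
      direction = direction, components = comps,
      nullMaxSize = maxSize, nPermUsed = as.integer(R), seed = design@seed)
}

.maxComponentSize <- function(tvec, utIdx, n, thr, direction) {
  sel <- switch(direction,
    positive = tvec > thr,
    negative = tvec < -thr,
    two.sided = abs(tvec) > thr)
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) return(0L)
  edges <- utIdx[sel, , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- igraph::components(g)$membership
  max(tabulate(memb[edges[, 1]]))
}
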