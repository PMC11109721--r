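.asWeightMatrix <- function(W) {
  if (is(W, "ConnectivityMatrix")) W <- W@values
  W <- as.matrix(W)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-8)
    stop("weight matrix must be square and symmetric")
  diag(W) <- 0
  W
}

#' Split a signed network into positive and negative parts
#'
#' @param W symmetric signed weight matrix (or
#'   \linkS4class{ConnectivityMatrix}) with zero diagonal.
#' @return list with nonnegative matrices \code{positive} and
#'   \code{negative} (magnitudes); \code{positive - negative} reconstructs
#'   \code{W} exactly.
#' @rdname splitSigns
#' @export
setMethod("splitSigns", "ANY", function(W) {
  W <- .asWeightMatrix(W)
  list(positive = pmax(W, 0), negative = pmax(-W, 0))
})

# Onnela-type weighted clustering on one nonnegative part: weights are
# max-normalized, per-node clustering is the geometric-mean triangle
# intensity over k(k-1), nodes with degree < 2 contribute 0, and the total
# is the mean over all nodes.
.clusteringPart <- function(A) {
  mx <- max(A)
  if (mx <= 0) return(0)
  M <- (A / mx)^(1 / 3)
  k <- rowSums(A > 0)
  tri <- diag(M %*% M %*% M)          # 2 x sum of triangle intensities
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Signed total clustering coefficients
#'
#' The total clustering coefficient — the mean over nodes of the weighted
#' clustering coefficient, a measure of network segregation — computed
#' separately on the positive weights and on the magnitudes of the negative
#' weights. Each sign part is normalized by its maximum weight, so the
#' values lie in [0, 1] and are invariant to a global rescaling of that
#' part. The weighted per-node coefficient is the Onnela geometric-mean
#' form: the sum over triangles of the cube-root weight product, divided by
#' k(k-1) for node degree k (nodes of degree < 2 contribute 0).
#'
#' @param W symmetric signed weight matrix or
#'   \linkS4class{ConnectivityMatrix}.
#' @param variant \code{"onnela"} (geometric-mean triangle weights, the
#'   default) or \code{"zhang"} (Zhang-Horvath: triangle weight products
#'   over the maximal possible products).
#' @param ... unused.
#' @return named numeric vector \code{c(positive = ..., negative = ...)}.
#' @rdname totalClustering
#' @export
setMethod("totalClustering", "ANY", function(W, variant = c("onnela", "zhang"),
                                             ...) {
  variant <- match.arg(variant)
  parts <- splitSigns(W)
  f <- if (variant == "onnela") .clusteringPart else .clusteringZhang
  c(positive = f(parts$positive), negative = f(parts$negative))
})

.clusteringZhang <- function(A) {
  mx <- max(A)
  if (mx <= 0) return(0)
  M <- A / mx
  num <- diag(M %*% M %*% M)
  sr <- rowSums(M)
  den <- sr^2 - rowSums(M^2)
  ci <- ifelse(den > 0, num / den, 0)
  mean(ci)
}

#' Weighted global efficiency
#'
#' Global efficiency — the mean over ordered node pairs of the inverse
#' weighted shortest-path length, a measure of network integration — is
#' computed on the positive part of the network only: each positive edge
#' has connection length \eqn{1/w_{ij}}, path lengths are exact shortest
#' paths over those lengths, and unreachable pairs contribute 0.
#'
#' @param W symmetric signed weight matrix or
#'   \linkS4class{ConnectivityMatrix}.
#' @return nonnegative scalar; 0 for an edgeless graph.
#' @rdname globalEfficiency
#' @export
setMethod("globalEfficiency", "ANY", function(W) {
  A <- splitSigns(W)$positive
  n <- nrow(A)
  if (n < 2 || all(A == 0)) return(0)
  L <- ifelse(A > 0, 1 / A, 0)
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
})

#' Weighted node strength
#'
#' Per-node sum of absolute edge weights.
#'
#' @param W symmetric signed weight matrix or
#'   \linkS4class{ConnectivityMatrix}.
#' @return numeric vector, one entry per node.
#' @rdname nodeStrength
#' @export
setMethod("nodeStrength", "ANY", function(W) {
  W <- .asWeightMatrix(W)
  rowSums(abs(W))
})

#' Whole-network summary metrics for a set of connectomes
#'
#' Computes positive and negative total clustering and global efficiency for
#' each connectome and returns them in long format.
#'
#' @param connectomes named list of \linkS4class{ConnectivityMatrix} (keys
#'   \code{"<subject_id>_<session>"}).
#' @param variant clustering variant, see \code{\link{totalClustering}}.
#' @return data.frame with columns \code{subject_id}, \code{session},
#'   \code{metric} (\code{clustering_pos}, \code{clustering_neg},
#'   \code{efficiency}) and \code{value}.
#' @export
graphMetrics <- function(connectomes, variant = "onnela") {
  rows <- lapply(names(connectomes), function(key) {
    cm <- connectomes[[key]]
    cl <- totalClustering(cm, variant = variant)
    data.frame(subject_id = cm@subjectId, session = cm@session,
               metric = c("clustering_pos", "clustering_neg", "efficiency"),
               value = c(cl[["positive"]], cl[["negative"]],
                         globalEfficiency(cm)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
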