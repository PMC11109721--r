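#' Node labels of a connectivity matrix
#'
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return character vector of node identifiers.
#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "ConnectivityMatrix", function(x) x@nodeLabels)

#' @export
setMethod("dim", "ConnectivityMatrix", function(x) dim(x@values))

#' Extract the numeric matrix from a ConnectivityMatrix
#'
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "ConnectivityMatrix", function(x, ...) {
  v <- x@values
  dimnames(v) <- list(x@nodeLabels, x@nodeLabels)
  v
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix: %d nodes, rho = %g, subject %s, session %s\n",
              nrow(object@values), object@rho,
              object@subjectId, object@session))
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("  edge weights: range [%.3f, %.3f], mean %.3f\n",
              min(off), max(off), mean(off)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d HC (1 session), %d PD (ON/OFF; %d MADD / %d non-MADD)\n",
    object@nHC, object@nPD, object@nMADD, object@nPD - object@nMADD))
  cat(sprintf("  %d nodes x %d time points, %d communities, ar = %g, seed %d\n",
              object@nNodes, object@nTimepoints, object@nCommunities,
              object@arCoefficient, object@seed))
  cat(sprintf("  effects (delta on planted edges): session %+g (%d edges), interaction %+g (%d edges), baseline %+g (%d edges)\n",
              object@sessionEffect@delta, nrow(object@sessionEffect@edges),
              object@interactionEffect@delta, nrow(object@interactionEffect@edges),
              object@baselineEffect@delta, nrow(object@baselineEffect@edges)))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d subject-sessions (%d HC, %d PD)\n",
              nrow(object@manifest),
              sum(object@manifest$group == "HC"),
              sum(object@manifest$group == "PD")))
  cat(sprintf("  series: %d x %d each\n",
              nrow(object@series[[1]]), ncol(object@series[[1]])))
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("InferenceResult (%s)\n", object@method))
  cat(sprintf("  stat = %.4f, p = %.4g (%d permutations)",
              object@observedStat, object@pUncorrected, object@nPermUsed))
  if (!is.na(object@pFDR)) cat(sprintf(", p_FDR = %.4g", object@pFDR))
  cat("\n")
  if (length(object@partialP))
    cat("  partial p:", paste(signif(object@partialP, 4), collapse = ", "), "\n")
})

setMethod("show", "NBSResult", function(object) {
  cat(sprintf("NBSResult: direction %s, |t| threshold %g, %d permutations\n",
              object@direction, object@primaryThreshold, object@nPermUsed))
  if (!length(object@components)) {
    cat("  no supra-threshold components\n")
  } else {
    for (i in seq_along(object@components)) {
      comp <- object@components[[i]]
      cat(sprintf("  component %d: %d edges, %d nodes, p_FWE = %.4g\n",
                  i, comp$size, length(comp$nodes), comp$pFWE))
    }
  }
})

setMethod("show", "SparseConnectomeSet", function(object) {
  n <- nrow(object@mask)
  cat(sprintf("SparseConnectomeSet: %d matrices, %d/%d edges retained (alpha = %g)\n",
              length(object@matrices), sum(object@mask[upper.tri(object@mask)]),
              n * (n - 1) / 2, object@maskingAlpha))
})
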