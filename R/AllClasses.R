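#' @import methods
NULL

#' Planted connectivity effect
#'
#' An \code{EffectSpec} names a set of edges (pairs of node indices) and an
#' additive change \code{delta} applied to the partial correlation implied by
#' the generating precision matrix on those edges, in the condition where the
#' effect is active.
#'
#' @slot edges integer matrix with two columns, one row per edge (1-based node
#'   indices, i < j).
#' @slot delta numeric scalar; additive change on the partial-correlation
#'   scale.
#' @export
setClass("EffectSpec",
  representation(edges = "matrix", delta = "numeric"),
  prototype(edges = matrix(integer(0), ncol = 2L), delta = 0))

setValidity("EffectSpec", function(object) {
  msg <- character(0)
  if (ncol(object@edges) != 2L)
    msg <- c(msg, "edges must have two columns")
  if (nrow(object@edges) > 0 &&
      (any(object@edges < 1) || any(object@edges[, 1] == object@edges[, 2])))
    msg <- c(msg, "edges must be pairs of distinct positive node indices")
  if (length(object@delta) != 1L || !is.finite(object@delta))
    msg <- c(msg, "delta must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Describes the design of a synthetic resting-state cohort: group sizes
#' (healthy controls with one session; patients with a stimulation-ON and a
#' stimulation-OFF session, split into a psychiatric subgroup), the
#' community-structured sparse precision matrix generating the node signals,
#' planted connectivity effects, temporal autocorrelation, and the nuisance
#' covariate model. Defaults mirror a cohort of 20 controls and 81 patients
#' (42 of them in the psychiatric subgroup) with 230 nodes and 200 time
#' points per run.
#'
#' @slot nHC,nPD,nMADD integer group sizes; \code{nMADD <= nPD}.
#' @slot nNodes,nTimepoints integer dimensions of each run.
#' @slot nCommunities integer; number of communities in the base precision.
#' @slot withinPC numeric; within-community partial-correlation magnitude of
#'   the base precision.
#' @slot sparsity numeric in (0,1]; probability that a within-community edge
#'   is present.
#' @slot sessionEffect \linkS4class{EffectSpec} applied to the ON-session
#'   precision of every patient.
#' @slot interactionEffect \linkS4class{EffectSpec} applied additionally to
#'   the ON-session precision of patients outside the psychiatric subgroup.
#' @slot baselineEffect \linkS4class{EffectSpec} applied to both sessions of
#'   every patient (disease-related degradation relative to controls).
#' @slot arCoefficient numeric in [0,1); lag-1 autoregressive coefficient of
#'   the temporal mixing.
#' @slot covariateModel named list of covariate descriptors (see
#'   \code{\link{defaultCovariateModel}}).
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec",
  representation(nHC = "integer", nPD = "integer", nMADD = "integer",
    nNodes = "integer", nTimepoints = "integer",
    nCommunities = "integer", withinPC = "numeric", sparsity = "numeric",
    sessionEffect = "EffectSpec", interactionEffect = "EffectSpec",
    baselineEffect = "EffectSpec",
    arCoefficient = "numeric", covariateModel = "list", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nHC < 1L || object@nPD < 1L)
    msg <- c(msg, "nHC and nPD must be >= 1")
  if (object@nMADD < 0L || object@nMADD > object@nPD)
    msg <- c(msg, "nMADD must satisfy 0 <= nMADD <= nPD")
  if (object@nNodes < 2L) msg <- c(msg, "nNodes must be >= 2")
  if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
  if (object@arCoefficient < 0 || object@arCoefficient >= 1)
    msg <- c(msg, "arCoefficient must lie in [0, 1)")
  if (object@sparsity <= 0 || object@sparsity > 1)
    msg <- c(msg, "sparsity must lie in (0, 1]")
  for (eff in list(object@sessionEffect, object@interactionEffect,
                   object@baselineEffect)) {
    if (nrow(eff@edges) > 0 && any(eff@edges > object@nNodes))
      msg <- c(msg, "effect edges reference node indices beyond nNodes")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort container
#'
#' Holds the generated per-subject-per-session time-series matrices (rows =
#' time points, columns = nodes) together with the cohort manifest (one row
#' per subject-session; group, subgroup, session, covariates) and the
#' generating \linkS4class{CohortSpec}. Manifest rows and time-series list
#' entries are keyed identically by \code{"<subject_id>_<session>"}.
#'
#' @slot series named list of numeric matrices.
#' @slot manifest data.frame with columns \code{subject_id}, \code{group},
#'   \code{madd_status}, \code{session} and covariate columns (NA = missing).
#' @slot spec the generating \linkS4class{CohortSpec}.
#' @export
setClass("Cohort",
  representation(series = "list", manifest = "data.frame",
                 spec = "CohortSpec"))

setValidity("Cohort", function(object) {
  keys <- paste(object@manifest$subject_id, object@manifest$session, sep = "_")
  if (!identical(sort(keys), sort(names(object@series))))
    return("manifest rows and series keys are not in bijection")
  TRUE
})

#' Regularized partial-correlation network
#'
#' A symmetric signed node-by-node matrix of ridge-regularized partial
#' correlations for one subject-session. The diagonal is fixed to zero by
#' convention so that graph-metric stages never count self-loops.
#'
#' @slot values numeric node x node matrix.
#' @slot nodeLabels character vector of node identifiers.
#' @slot rho ridge penalty used in estimation (>= 0).
#' @slot subjectId,session labels.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", nodeLabels = "character",
    rho = "numeric", subjectId = "character", session = "character"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (length(object@nodeLabels) != nrow(v))
    msg <- c(msg, "nodeLabels length must equal matrix dimension")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
  if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (any(abs(v) > 1 + 1e-6)) msg <- c(msg, "off-diagonals must lie in [-1, 1]")
  if (object@rho < 0) msg <- c(msg, "rho must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Masked connectome collection
#'
#' A set of \linkS4class{ConnectivityMatrix} objects sharing a node set, with
#' an edge mask derived from one-sample t-tests of each edge against zero:
#' edges not significant across the sample are exactly zero in every matrix.
#'
#' @slot matrices named list of \linkS4class{ConnectivityMatrix}.
#' @slot mask logical node x node symmetric matrix; TRUE = edge retained.
#' @slot maskingAlpha the two-sided alpha used for the edge tests.
#' @export
setClass("SparseConnectomeSet",
  representation(matrices = "list", mask = "matrix", maskingAlpha = "numeric"))

setValidity("SparseConnectomeSet", function(object) {
  m <- object@mask
  msg <- character(0)
  if (!is.logical(m) || nrow(m) != ncol(m))
    msg <- c(msg, "mask must be a square logical matrix")
  if (!identical(m, t(m))) msg <- c(msg, "mask must be symmetric")
  if (any(diag(m))) msg <- c(msg, "mask diagonal must be FALSE")
  if (length(msg)) msg else TRUE
})

#' Permutation design
#'
#' Bundles the design matrix, the contrast of interest, the exchangeability
#' scheme and the permutation budget for a permutation GLM. Columns of
#' \code{X} with zero contrast weight are treated as nuisance and handled by
#' Freedman-Lane residualization.
#'
#' @slot X numeric design matrix (rows = observations).
#' @slot contrast numeric contrast weights, one per column of \code{X}.
#' @slot exchangeability \code{"group_shuffle"} (permute rows) or
#'   \code{"paired_sign_flip"} (flip signs of rows; for designs whose rows are
#'   within-subject session differences).
#' @slot nPermutations requested number of random permutations; the full
#'   space is enumerated instead whenever it is no larger.
#' @slot seed integer RNG seed.
#' @export
setClass("DesignSpec",
  representation(X = "matrix", contrast = "numeric",
    exchangeability = "character", nPermutations = "integer",
    seed = "integer"))

setValidity("DesignSpec", function(object) {
  msg <- character(0)
  if (length(object@contrast) != ncol(object@X))
    msg <- c(msg, "contrast length must equal ncol(X)")
  if (all(object@contrast == 0))
    msg <- c(msg, "contrast must be nonzero on at least one column")
  if (!object@exchangeability %in% c("group_shuffle", "paired_sign_flip"))
    msg <- c(msg, "unknown exchangeability scheme")
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Permutation inference result
#'
#' @slot observedStat observed t statistic (or Fisher combining statistic).
#' @slot pUncorrected permutation p-value, in [1/nPermUsed, 1].
#' @slot pFDR FDR-adjusted p (NA until a family correction is applied).
#' @slot nPermUsed number of permutations in the reference distribution,
#'   including the identity.
#' @slot partialP observed partial p-values per modality when non-parametric
#'   combination was applied (empty otherwise).
#' @slot method short description of the test.
#' @export
setClass("InferenceResult",
  representation(observedStat = "numeric", pUncorrected = "numeric",
    pFDR = "numeric", nPermUsed = "integer", partialP = "numeric",
    method = "character"),
  prototype(pFDR = NA_real_, partialP = numeric(0), method = ""))

setValidity("InferenceResult", function(object) {
  p <- object@pUncorrected
  if (p < 1 / object@nPermUsed - 1e-12 || p > 1 + 1e-12)
    return("pUncorrected must lie in [1/nPermUsed, 1]")
  if (!is.na(object@pFDR) && object@pFDR < p - 1e-12)
    return("pFDR must be >= pUncorrected")
  TRUE
})

#' Network-based statistics result
#'
#' Edge-level t statistics, the supra-threshold components in the requested
#' direction, and their family-wise-error-corrected p-values from the
#' permutation null distribution of the maximal component size (component
#' size is measured in edges).
#'
#' @slot edgeT symmetric node x node matrix of edge t statistics (NA on
#'   masked edges).
#' @slot primaryThreshold primary cluster-forming threshold on t.
#' @slot direction \code{"positive"}, \code{"negative"} or
#'   \code{"two.sided"}.
#' @slot components list of components, each a list with elements
#'   \code{edges} (matrix of node index pairs), \code{nodes}, \code{size}
#'   (edge count) and \code{pFWE}.
#' @slot nullMaxSize integer vector of maximal component sizes across the
#'   permutation distribution (first entry = observed).
#' @slot nPermUsed,seed permutation bookkeeping.
#' @export
setClass("NBSResult",
  representation(edgeT = "matrix", primaryThreshold = "numeric",
    direction = "character", components = "list",
    nullMaxSize = "integer", nPermUsed = "integer", seed = "integer"))
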