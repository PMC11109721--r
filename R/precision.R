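#' Construct an EffectSpec
#'
#' @param edges two-column matrix (or data.frame) of 1-based node index
#'   pairs, or NULL for an empty effect.
#' @param delta additive change applied to the implied partial correlation on
#'   those edges in the condition where the effect is active.
#' @return an \linkS4class{EffectSpec}.
#' @examples
#' effectSpec(cbind(1:3, 2:4), delta = 0.2)
#' @export
effectSpec <- function(edges = NULL, delta = 0) {
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  # canonical orientation i < j
  flip <- edges[, 1] > edges[, 2]
  edges[flip, ] <- edges[flip, 2:1]
  new("EffectSpec", edges = edges, delta = as.numeric(delta))
}

#' Default covariate model
#'
#' Per-covariate generating distributions and missingness probabilities for
#' the synthetic manifest. Parameters are plausibility anchors loosely
#' matched to a typical chronically stimulated Parkinson cohort (ages around
#' 60, roughly one third female, two to three years since implantation,
#' about 35\% motor improvement, low and slightly improving depression
#' scores, about a third using antidepressants); they are not estimates of
#' any particular study's effects.
#'
#' Each element is a list with a \code{draw(n)} function and a
#' \code{missing} probability. The raw pre/post clinical scores are drawn so
#' that derived covariates (\code{\link{clinicalMotorImprovement}},
#' \code{\link{madrsChange}}) have realistic distributions.
#'
#' @return named list of covariate descriptors.
#' @export
defaultCovariateModel <- function() {
  list(
    age = list(draw = function(n) round(stats::rnorm(n, 59, 8), 1),
               missing = 0),
    sex = list(draw = function(n) stats::rbinom(n, 1, 0.32), missing = 0),
    months_since_implant = list(
      draw = function(n) round(stats::rlnorm(n, log(24), 0.6), 1),
      missing = 0),
    updrs_pre = list(draw = function(n) pmax(stats::rnorm(n, 40, 8), 5),
                     missing = 0.02),
    updrs_post = NULL,   # derived below from updrs_pre and improvement
    madrs_pre = list(draw = function(n) pmax(round(stats::rnorm(n, 4.7, 3.5)), 0),
                     missing = 0.02),
    madrs_post = NULL,   # derived below from madrs_pre and change
    motor_improvement_frac = list(
      draw = function(n) stats::rnorm(n, 0.35, 0.15), missing = NA),
    madrs_change_raw = list(
      draw = function(n) round(stats::rnorm(n, -1.2, 5)), missing = NA),
    antidepressant = list(draw = function(n) stats::rbinom(n, 1, 0.36),
                          missing = 0),
    vta_overlap = list(draw = function(n) round(abs(stats::rnorm(n, 0, 5)), 2),
                       missing = 0.02),
    # post scores carry the bulk of the cohort's missingness (late follow-up)
    post_missing = list(updrs_post = 0.03, madrs_post = 0.2)
  )
}

#' Construct a CohortSpec
#'
#' @param nHC,nPD,nMADD group sizes (controls; patients; patients in the
#'   psychiatric subgroup).
#' @param nNodes,nTimepoints dimensions of each parcellated run.
#' @param nCommunities,withinPC,sparsity base precision model: nodes are
#'   split into \code{nCommunities} blocks; each within-block edge is present
#'   with probability \code{sparsity} and carries an implied partial
#'   correlation of magnitude \code{withinPC}.
#' @param sessionEffect,interactionEffect,baselineEffect
#'   \linkS4class{EffectSpec}s; see \linkS4class{CohortSpec}.
#' @param arCoefficient lag-1 autoregressive coefficient in [0,1).
#' @param covariateModel see \code{\link{defaultCovariateModel}}.
#' @param seed master RNG seed.
#' @return a validated \linkS4class{CohortSpec}.
#' @examples
#' cohortSpec(nHC = 4, nPD = 6, nMADD = 3, nNodes = 20, nTimepoints = 100)
#' @export
cohortSpec <- function(nHC = 20L, nPD = 81L, nMADD = 42L,
                       nNodes = 230L, nTimepoints = 200L,
                       nCommunities = 5L, withinPC = 0.15, sparsity = 0.6,
                       sessionEffect = effectSpec(),
                       interactionEffect = effectSpec(),
                       baselineEffect = effectSpec(),
                       arCoefficient = 0.3,
                       covariateModel = defaultCovariateModel(),
                       seed = 1L) {
  new("CohortSpec", nHC = as.integer(nHC), nPD = as.integer(nPD),
      nMADD = as.integer(nMADD), nNodes = as.integer(nNodes),
      nTimepoints = as.integer(nTimepoints),
      nCommunities = as.integer(nCommunities),
      withinPC = withinPC, sparsity = sparsity,
      sessionEffect = sessionEffect, interactionEffect = interactionEffect,
      baselineEffect = baselineEffect,
      arCoefficient = arCoefficient, covariateModel = covariateModel,
      seed = as.integer(seed))
}

# Set precision entries so that the implied partial correlation on the given
# edges is r (precision off-diagonal -r*sqrt(Theta_ii*Theta_jj)).
.setPartial <- function(theta, edges, r) {
  if (nrow(edges) == 0) return(theta)
  d <- diag(theta)
  v <- -r * sqrt(d[edges[, 1]] * d[edges[, 2]])
  theta[edges] <- v
  theta[edges[, 2:1, drop = FALSE]] <- v
  theta
}

#' Partial correlations implied by a precision matrix
#'
#' For a precision matrix \eqn{\Theta}, the partial correlation between
#' nodes i and j given all others is
#' \eqn{-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}}. The diagonal of the
#' returned matrix is zero by convention.
#'
#' @param theta symmetric positive definite precision matrix.
#' @return node x node partial-correlation matrix with zero diagonal.
#' @export
impliedPartialCorrelation <- function(theta) {
  s <- 1 / sqrt(diag(theta))
  r <- -theta * tcrossprod(s)
  diag(r) <- 0
  r
}

#' Build the generating precision matrix for one condition
#'
#' Constructs the community-structured sparse base precision of a
#' \linkS4class{CohortSpec} and applies the planted effects active in the
#' requested condition. Effects add \code{delta} to the implied partial
#' correlation on their edges. Positive definiteness is enforced: if a
#' perturbation drives the minimum eigenvalue below a small floor, the
#' perturbed off-diagonals are shrunk toward feasibility (with a warning);
#' if even a heavily shrunk matrix is not positive definite an error names
#' the offending delta.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param condition one of \code{"HC"} (base), \code{"PD_OFF"} (base +
#'   baseline effect), \code{"PD_ON"} (+ session effect) or
#'   \code{"PD_ON_nonMADD"} (+ session + interaction effects).
#' @return symmetric positive definite precision matrix.
#' @export
buildPrecision <- function(spec,
                           condition = c("HC", "PD_OFF", "PD_ON",
                                         "PD_ON_nonMADD")) {
  condition <- match.arg(condition)
  p <- spec@nNodes
  set.seed(.subSeed(spec@seed, 104729L))
  comm <- sort(rep_len(seq_len(spec@nCommunities), p))
  theta <- diag(p)
  ut <- which(upper.tri(theta), arr.ind = TRUE)
  within <- comm[ut[, 1]] == comm[ut[, 2]]
  keep <- within & stats::runif(nrow(ut)) < spec@sparsity
  baseEdges <- ut[keep, , drop = FALSE]
  sgn <- sample(c(-1, 1), nrow(baseEdges), replace = TRUE, prob = c(0.3, 0.7))
  theta <- .setPartial(theta, baseEdges, sgn * spec@withinPC)
  theta <- .repairSPD(theta, what = "base precision model")

  effects <- switch(condition,
    HC = list(),
    PD_OFF = list(spec@baselineEffect),
    PD_ON = list(spec@baselineEffect, spec@sessionEffect),
    PD_ON_nonMADD = list(spec@baselineEffect, spec@sessionEffect,
                         spec@interactionEffect))
  mineig <- function(m) min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  for (eff in effects) {
    if (nrow(eff@edges) == 0 || eff@delta == 0) next
    r0 <- impliedPartialCorrelation(theta)[eff@edges]
    target <- function(s) pmin(pmax(r0 + s * eff@delta, -0.95), 0.95)
    shrink <- 1
    cand <- .setPartial(theta, eff@edges, target(shrink))
    while (mineig(cand) < 1e-6) {
      shrink <- shrink * 0.8
      if (shrink < 0.05)
        stop(sprintf("effect delta %g destroys positive definiteness and cannot be repaired",
                     eff@delta))
      cand <- .setPartial(theta, eff@edges, target(shrink))
    }
    if (shrink < 1)
      warning(sprintf("effect delta %g rescaled by %.2f to keep the precision positive definite",
                      eff@delta, shrink))
    theta <- cand
  }
  theta
}

# Rescale off-diagonals until SPD; used for the random base structure.
.repairSPD <- function(theta, what, floor = 1e-4) {
  d <- diag(theta)
  for (k in 0:40) {
    ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= floor) return(theta)
    off <- theta - diag(d)
    theta <- diag(d) + 0.9 * off
  }
  stop(sprintf("could not make the %s positive definite", what))
}

# deterministic sub-seed derivation, kept inside 32-bit range
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483647)
}
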