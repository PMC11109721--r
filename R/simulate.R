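#' Simulate a parcellated time-series matrix from a precision matrix
#'
#' Draws a multivariate Gaussian signal whose stationary cross-sectional
#' covariance equals the inverse of \code{precision}, with AR(1) temporal
#' mixing: innovations \eqn{\epsilon_t \sim N(0, \Theta^{-1})} are combined
#' as \eqn{s_t = \phi s_{t-1} + \sqrt{1-\phi^2}\,\epsilon_t}, which leaves
#' the cross-sectional covariance exactly \eqn{\Theta^{-1}} at every lag-0
#' cross-section while giving each column lag-1 autocorrelation \eqn{\phi}.
#' A burn-in of 50 samples is discarded; the chain is started from its
#' stationary distribution so the output is stationary throughout.
#'
#' @param precision symmetric positive definite node x node matrix.
#' @param nTimepoints number of rows to return.
#' @param arCoefficient \eqn{\phi \in [0,1)}.
#' @param seed integer RNG seed; the same seed yields bit-identical output.
#' @return numeric matrix, \code{nTimepoints} x \code{nNodes}, columns named
#'   \code{node001, node002, ...}.
#' @examples
#' ts <- simulateTimeseries(diag(4), 100, 0, seed = 7)
#' dim(ts)
#' @export
simulateTimeseries <- function(precision, nTimepoints, arCoefficient = 0,
                               seed = 1L) {
  p <- nrow(precision)
  if (!isTRUE(all.equal(precision, t(precision), tolerance = 1e-8)))
    stop("precision must be symmetric")
  ch <- tryCatch(chol(precision), error = function(e)
    stop("precision must be positive definite"))
  if (nTimepoints < p)
    warning(sprintf("nTimepoints (%d) < nNodes (%d); the sample covariance will be singular",
                    nTimepoints, p))
  set.seed(seed)
  burn <- 50L
  total <- nTimepoints + burn
  # innovations with covariance solve(precision): z %*% solve(t(chol)) has
  # covariance (R'R)^{-1} for R = chol(precision)
  z <- matrix(stats::rnorm(total * p), total, p)
  eps <- z %*% t(backsolve(ch, diag(p)))
  phi <- arCoefficient
  if (phi > 0) {
    out <- eps
    out[1, ] <- eps[1, ]   # stationary start: var = Sigma
    sc <- sqrt(1 - phi^2)
    for (t in 2:total) out[t, ] <- phi * out[t - 1, ] + sc * eps[t, ]
    eps <- out
  }
  res <- eps[(burn + 1):total, , drop = FALSE]
  colnames(res) <- sprintf("node%03d", seq_len(p))
  res
}

#' Generate a synthetic cohort
#'
#' Simulates one run per control subject and an ON and an OFF run per
#' patient, from condition-specific precision matrices: controls use the
#' base precision; patient OFF runs add the baseline effect; patient ON runs
#' add the session effect; ON runs of patients outside the psychiatric
#' subgroup additionally receive the interaction effect. Covariates are
#' drawn per \code{spec@covariateModel} with missingness injected at the
#' stated probabilities (controls carry age and sex only; patient-only
#' clinical fields are structurally absent, not "missing", for controls).
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return a \linkS4class{Cohort}; the manifest has
#'   \code{nHC + 2 * nPD} rows.
#' @examples
#' coh <- generateCohort(cohortSpec(nHC = 2, nPD = 2, nMADD = 1,
#'                                  nNodes = 10, nTimepoints = 50))
#' nrow(coh@manifest)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  thetaHC  <- buildPrecision(spec, "HC")
  thetaOFF <- buildPrecision(spec, "PD_OFF")
  thetaON  <- buildPrecision(spec, "PD_ON")
  thetaONn <- buildPrecision(spec, "PD_ON_nonMADD")

  hcIds <- sprintf("HC%03d", seq_len(spec@nHC))
  pdIds <- sprintf("PD%03d", seq_len(spec@nPD))
  # deterministic subgroup assignment: first nMADD patients are MADD
  madd <- c(rep(TRUE, spec@nMADD), rep(FALSE, spec@nPD - spec@nMADD))

  series <- list()
  rows <- list()
  k <- 0L
  addRun <- function(theta, id, group, maddStatus, session) {
    k <<- k + 1L
    ts <- simulateTimeseries(theta, spec@nTimepoints, spec@arCoefficient,
                             seed = .subSeed(spec@seed, k))
    series[[paste(id, session, sep = "_")]] <<- ts
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = id, group = group, madd_status = maddStatus,
      session = session, stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec@nHC))
    addRun(thetaHC, hcIds[i], "HC", NA_character_, "REST")
  for (i in seq_len(spec@nPD)) {
    st <- if (madd[i]) "MADD" else "nonMADD"
    addRun(thetaOFF, pdIds[i], "PD", st, "OFF")
    addRun(if (madd[i]) thetaON else thetaONn, pdIds[i], "PD", st, "ON")
  }
  manifest <- do.call(rbind, rows)
  manifest <- .attachCovariates(manifest, spec)
  new("Cohort", series = series, manifest = manifest, spec = spec)
}

# Draw subject-level covariates and replicate them across sessions.
.attachCovariates <- function(manifest, spec) {
  cm <- spec@covariateModel
  subj <- unique(manifest[, c("subject_id", "group", "madd_status")])
  n <- nrow(subj)
  set.seed(.subSeed(spec@seed, 999983L))
  cov <- data.frame(subject_id = subj$subject_id)
  cov$age <- cm$age$draw(n)
  cov$sex <- cm$sex$draw(n)
  isPD <- subj$group == "PD"
  nPD <- sum(isPD)
  pdcol <- function(x) { v <- rep(NA_real_, n); v[isPD] <- x; v }
  cov$months_since_implant <- pdcol(cm$months_since_implant$draw(nPD))
  updrsPre <- cm$updrs_pre$draw(nPD)
  improve <- pmin(pmax(cm$motor_improvement_frac$draw(nPD), -0.5), 0.95)
  cov$updrs_pre <- pdcol(updrsPre)
  cov$updrs_post <- pdcol(round(updrsPre * (1 - improve), 1))
  madrsPre <- cm$madrs_pre$draw(nPD)
  cov$madrs_pre <- pdcol(madrsPre)
  cov$madrs_post <- pdcol(pmax(madrsPre + cm$madrs_change_raw$draw(nPD), 0))
  cov$antidepressant <- pdcol(cm$antidepressant$draw(nPD))
  cov$vta_overlap <- pdcol(cm$vta_overlap$draw(nPD))
  # missingness, PD-only fields
  miss <- c(months_since_implant = cm$months_since_implant$missing,
            updrs_pre = cm$updrs_pre$missing,
            updrs_post = cm$post_missing$updrs_post,
            madrs_pre = cm$madrs_pre$missing,
            madrs_post = cm$post_missing$madrs_post,
            antidepressant = cm$antidepressant$missing,
            vta_overlap = cm$vta_overlap$missing)
  for (nm in names(miss)) {
    if (miss[[nm]] <= 0) next
    drop <- isPD & stats::runif(n) < miss[[nm]]
    cov[[nm]][drop] <- NA_real_
  }
  merge(manifest, cov, by = "subject_id", sort = FALSE)
}

#' Write a cohort to disk
#'
#' Writes one tab-separated time-series file per subject-session
#' (\code{<subject_id>_<session>.tsv}; rows = time points, header = node
#' labels), the manifest as \code{manifest.csv} (empty cell = missing) and a
#' \code{cohort_spec.yaml} echo of the generating configuration.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort@series))
    utils::write.table(cohort@series[[key]],
                       file.path(dir, paste0(key, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort@manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  spec <- cohort@spec
  echo <- list(
    n_hc = spec@nHC, n_pd = spec@nPD, n_madd = spec@nMADD,
    n_nodes = spec@nNodes, n_timepoints = spec@nTimepoints,
    n_communities = spec@nCommunities, within_pc = spec@withinPC,
    sparsity = spec@sparsity, ar_coefficient = spec@arCoefficient,
    seed = spec@seed,
    session_effect = list(delta = spec@sessionEffect@delta,
                          n_edges = nrow(spec@sessionEffect@edges)),
    interaction_effect = list(delta = spec@interactionEffect@delta,
                              n_edges = nrow(spec@interactionEffect@edges)),
    baseline_effect = list(delta = spec@baselineEffect@delta,
                           n_edges = nrow(spec@baselineEffect@edges)))
  yaml::write_yaml(echo, file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by \code{writeCohort}
#'
#' @param dir directory containing \code{manifest.csv} and one
#'   \code{<subject_id>_<session>.tsv} per run.
#' @return a list with elements \code{series} (named list of matrices) and
#'   \code{manifest} (data.frame).
#' @export
readCohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  keys <- paste(manifest$subject_id, manifest$session, sep = "_")
  series <- lapply(keys, function(k)
    as.matrix(utils::read.delim(file.path(dir, paste0(k, ".tsv")))))
  names(series) <- keys
  list(series = series, manifest = manifest)
}
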