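#' Column-standardize a time-series matrix
#'
#' Centers each node's signal to mean zero and scales it to unit (sample)
#' variance. Constant columns cannot be scaled; they are left at zero and
#' flagged with a warning.
#'
#' @param ts numeric matrix, time points x nodes; must contain no NaN/NA.
#' @return matrix of the same dimension with standardized columns.
#' @export
standardizeTimeseries <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("need at least 2 time points")
  if (any(!is.finite(ts)))
    stop("time series contains non-finite values; clean the input upstream")
  mu <- colMeans(ts)
  ts <- sweep(ts, 2, mu)
  sdv <- sqrt(colSums(ts^2) / (nrow(ts) - 1))
  const <- sdv < .Machine$double.eps^0.5
  if (any(const)) {
    warning(sprintf("%d constant column(s) left at zero", sum(const)))
    sdv[const] <- 1
  }
  sweep(ts, 2, sdv, "/")
}

#' Ridge-regularized partial-correlation network
#'
#' Estimates the partial-correlation matrix of a parcellated run by
#' L2-regularized inversion of the sample covariance: with sample covariance
#' \eqn{S}, the regularized precision is
#' \eqn{P = (S + \rho\,\bar{s}\,I)^{-1}} where \eqn{\bar{s}} is the mean
#' diagonal variance, and the edge weights are
#' \eqn{r_{ij} = -P_{ij}/\sqrt{P_{ii} P_{jj}}}. The diagonal is set to zero.
#' With \eqn{\rho = 0} this is the textbook partial correlation from the
#' unregularized inverse covariance; a positive \eqn{\rho} stabilizes the
#' inverse when time points are few relative to nodes.
#'
#' @param ts time points x nodes matrix (standardized internally).
#' @param rho ridge penalty, >= 0.
#' @param nodeLabels optional node identifiers (defaults to column names).
#' @param subjectId,session labels carried into the result.
#' @return a \linkS4class{ConnectivityMatrix}.
#' @examples
#' ts <- simulateTimeseries(diag(5), 200, 0, seed = 2)
#' ridgePartialCorrelation(ts, rho = 0.1)
#' @export
ridgePartialCorrelation <- function(ts, rho = 0.1, nodeLabels = NULL,
                                    subjectId = "", session = "") {
  if (rho < 0) stop("rho must be >= 0")
  ts <- as.matrix(ts)
  if (is.null(nodeLabels))
    nodeLabels <- colnames(ts)
  if (is.null(nodeLabels))
    nodeLabels <- sprintf("node%03d", seq_len(ncol(ts)))
  z <- suppressWarnings(standardizeTimeseries(ts))
  S <- crossprod(z) / (nrow(z) - 1)
  Sreg <- S + rho * mean(diag(S)) * diag(ncol(S))
  P <- tryCatch(solve(Sreg), error = function(e)
    stop("covariance is singular at rho = 0; use a positive ridge penalty rho"))
  s <- 1 / sqrt(diag(P))
  r <- -P * tcrossprod(s)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  r <- pmin(pmax(r, -1), 1)
  new("ConnectivityMatrix", values = r, nodeLabels = as.character(nodeLabels),
      rho = rho, subjectId = as.character(subjectId),
      session = as.character(session))
}

#' Estimate connectomes for every run of a cohort
#'
#' @param cohort a \linkS4class{Cohort} or a list with \code{series} and
#'   \code{manifest} (as returned by \code{\link{readCohort}}).
#' @param rho ridge penalty passed to \code{\link{ridgePartialCorrelation}}.
#' @return named list of \linkS4class{ConnectivityMatrix}, keyed like the
#'   series.
#' @export
computeConnectomes <- function(cohort, rho = 0.1) {
  if (is(cohort, "Cohort"))
    cohort <- list(series = cohort@series, manifest = cohort@manifest)
  manifest <- cohort$manifest
  keys <- paste(manifest$subject_id, manifest$session, sep = "_")
  out <- lapply(seq_along(keys), function(i)
    ridgePartialCorrelation(cohort$series[[keys[i]]], rho = rho,
                            subjectId = manifest$subject_id[i],
                            session = manifest$session[i]))
  names(out) <- keys
  out
}

#' Write connectome matrices as TSV files
#'
#' One square tab-separated matrix per subject-session, with node labels as
#' header row and first column.
#'
#' @param connectomes named list of \linkS4class{ConnectivityMatrix}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeConnectomes <- function(connectomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(connectomes)) {
    m <- as.matrix(connectomes[[key]])
    utils::write.table(m, file.path(dir, paste0(key, "_connectome.tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}
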