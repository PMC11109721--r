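#' Clinical motor improvement of stimulation
#'
#' Relative improvement of the motor score: the difference between the
#' pre-implantation score and the post-implantation (stimulation active)
#' score, as a ratio of the pre-implantation score, so that positive values
#' correspond to clinical improvement.
#'
#' @param pre,post motor scale scores (part III) before implantation and at
#'   follow-up; \code{pre} must be positive. NA propagates.
#' @return \code{(pre - post) / pre}.
#' @examples
#' clinicalMotorImprovement(40, 26)  # 0.35
#' @export
clinicalMotorImprovement <- function(pre, post) {
  if (any(!is.na(pre) & pre <= 0))
    stop("pre-implantation score must be positive")
  (pre - post) / pre
}

#' Depression score change
#'
#' Simple numerical difference between the depression score at the imaging
#' session and the pre-implantation score; negative values correspond to
#' improvement.
#'
#' @param pre,post depression scale scores (both >= 0). NA propagates.
#' @return \code{post - pre}.
#' @examples
#' madrsChange(6, 4)  # -2
#' @export
madrsChange <- function(pre, post) {
  if (any(stats::na.omit(c(pre, post)) < 0))
    stop("depression scores must be >= 0")
  post - pre
}

#' Select report-worthy nodes of a component edge list
#'
#' For figure labelling, only nodes whose summed incident |t| exceeds a
#' threshold are kept (default 10).
#'
#' @param edgeList data.frame with columns \code{node1}, \code{node2},
#'   \code{t}.
#' @param minTSum threshold on the per-node sum of |t| over incident edges.
#' @return data.frame with columns \code{node} and \code{t_sum}, restricted
#'   to nodes above the threshold, ordered by decreasing \code{t_sum}.
#' @export
labelReportNodes <- function(edgeList, minTSum = 10) {
  nodes <- c(edgeList$node1, edgeList$node2)
  tsum <- tapply(rep(abs(edgeList$t), 2), nodes, sum)
  keep <- tsum > minTSum
  out <- data.frame(node = names(tsum)[keep], t_sum = unname(tsum[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$t_sum), , drop = FALSE]
}
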