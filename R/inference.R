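# ---- permutation engine ------------------------------------------------

# Enumerate or sample the permutation space. Returns a list with:
#   type: "sign_flip" or "shuffle"
#   mat:  R x n matrix of sign vectors (+-1) or row indices; row 1 = identity
#   exhaustive: TRUE when the whole space is enumerated
.permScheme <- function(n, scheme, nPerm, seed) {
  if (scheme == "paired_sign_flip") {
    size <- 2^n
    if (size <= 1) stop("permutation space has size 1; nothing to permute")
    if (size <= nPerm) {
      mat <- matrix(1, size, n)
      for (j in seq_len(n))
        mat[, j] <- ifelse(bitwAnd(seq_len(size) - 1L, bitwShiftL(1L, j - 1L)) > 0,
                           -1, 1)
      # ensure identity first (it is: i = 0 row has all +1)
      return(list(type = "sign_flip", mat = mat, exhaustive = TRUE))
    }
    set.seed(seed)
    mat <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
    mat <- rbind(rep(1, n), mat)
    return(list(type = "sign_flip", mat = mat, exhaustive = FALSE))
  }
  # group_shuffle
  sizeLog <- lfactorial(n)
  if (n <= 1) stop("permutation space has size 1; nothing to permute")
  if (sizeLog <= log(nPerm) + 1e-9) {
    mat <- .allPermutations(n)
    idx <- which(apply(mat, 1, function(r) all(r == seq_len(n))))
    mat <- rbind(mat[idx, ], mat[-idx, , drop = FALSE])
    return(list(type = "shuffle", mat = mat, exhaustive = TRUE))
  }
  set.seed(seed)
  mat <- t(replicate(nPerm, sample.int(n)))
  mat <- rbind(seq_len(n), mat)
  list(type = "shuffle", mat = mat, exhaustive = FALSE)
}

.allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(block)
    r <- r + nrow(sub)
  }
  storage.mode(out) <- "integer"
  out
}

# t statistics for every column of Y under OLS with common design X.
.tStats <- function(Y, X, contrast, qrX = qr(X), cXc = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    if (is.null(bad)) bad <- qrX$pivot[(qrX$rank + 1):p]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(cXc)) cXc <- drop(crossprod(contrast, solve(crossprod(X), contrast)))
  B <- qr.coef(qrX, Y)
  cB <- drop(crossprod(contrast, B))
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  # zero residual variance: the statistic is undefined; define it as 0 so a
  # constant response ties with every permutation (maximal p), never as a
  # spurious detection
  tiny <- sigma2 < 1e-24
  t <- cB / sqrt(cXc * pmax(sigma2, 1e-24))
  t[tiny] <- 0
  t
}

# Freedman-Lane permutation distribution of contrast t statistics.
# Y: n x m (m responses tested marginally under synchronized permutations).
# Returns R x m matrix of t statistics; row 1 = observed.
.flStats <- function(Y, X, contrast, exchangeability, nPermutations, seed) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(nrow(X) == n, length(contrast) == ncol(X))
  scheme <- .permScheme(n, exchangeability, nPermutations, seed)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    if (is.null(bad)) bad <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  cXc <- drop(crossprod(contrast, solve(crossprod(X), contrast)))
  nuis <- which(contrast == 0)
  if (length(nuis)) {
    Z <- X[, nuis, drop = FALSE]
    G <- qr.coef(qr(Z), Y)
    fitted <- Z %*% G
    E <- Y - fitted
  } else {
    fitted <- matrix(0, n, ncol(Y))
    E <- Y
  }
  R <- nrow(scheme$mat)
  out <- matrix(NA_real_, R, ncol(Y))
  out[1, ] <- .tStats(Y, X, contrast, qrX, cXc)
  for (r in 2:R) {
    Ystar <- if (scheme$type == "sign_flip")
      fitted + scheme$mat[r, ] * E
    else
      fitted + E[scheme$mat[r, ], , drop = FALSE]
    out[r, ] <- .tStats(Ystar, X, contrast, qrX, cXc)
  }
  attr(out, "exhaustive") <- scheme$exhaustive
  out
}

# per-permutation partial p-values from a stat matrix (two-sided):
# p_r = #( |t_s| >= |t_r| ) / R, computed per column.
.partialPMatrix <- function(T) {
  apply(abs(T), 2, function(a) {
    R <- length(a)
    (R - rank(a, ties.method = "min") + 1) / R
  })
}

# ---- user-facing operations -------------------------------------------

#' Group-mean imputation of a covariate
#'
#' Replaces missing values of a numeric covariate by the mean of the
#' observed values in the same group, computed over unique subjects (so
#' repeated sessions of one subject are not double-counted). A provenance
#' column \code{<covariate>_imputed} records which rows were filled.
#'
#' @param manifest data.frame with \code{subject_id} and the grouping
#'   column.
#' @param covariate name of the numeric covariate column.
#' @param by name of the grouping column (default \code{"group"}).
#' @return the completed manifest.
#' @export
imputeGroupMean <- function(manifest, covariate, by = "group") {
  x <- manifest[[covariate]]
  if (!is.numeric(x)) stop("covariate must be numeric")
  g <- manifest[[by]]
  flag <- is.na(x)
  for (lev in unique(g[flag])) {
    inGrp <- !is.na(g) & g == lev
    subj <- manifest$subject_id[inGrp & !is.na(x)]
    vals <- x[inGrp & !is.na(x)]
    obs <- tapply(vals, subj, mean)
    if (length(obs) == 0)
      stop(sprintf("group '%s' has no observed values for '%s'", lev, covariate))
    x[inGrp & is.na(x)] <- mean(obs)
  }
  manifest[[covariate]] <- x
  manifest[[paste0(covariate, "_imputed")]] <- flag
  manifest
}

#' Contrast t statistic from an ordinary least-squares fit
#'
#' Fits \code{Y ~ X} by OLS and returns
#' \eqn{t = c^\top\hat\beta / \mathrm{se}(c^\top\hat\beta)} with the
#' residual-variance standard error on \code{n - p} degrees of freedom.
#'
#' @param Y numeric response vector.
#' @param X design matrix (include an intercept column explicitly).
#' @param contrast numeric contrast weights, one per column of \code{X}.
#' @return scalar t statistic.
#' @export
glmContrastStat <- function(Y, X, contrast) {
  X <- as.matrix(X)
  drop(.tStats(matrix(Y, ncol = 1), X, contrast))
}

#' Permutation p-value for a GLM contrast
#'
#' Freedman-Lane permutation inference: the response is residualized
#' against the nuisance columns (those with zero contrast weight), the
#' residuals are permuted (\code{group_shuffle}) or sign-flipped
#' (\code{paired_sign_flip}, for designs whose rows are within-subject
#' differences), the full model is refit and the contrast t recomputed. The
#' two-sided p-value is the proportion of the reference distribution
#' (identity included) with \eqn{|t| \ge |t_{obs}|}. When the permutation
#' space is no larger than \code{nPermutations} it is enumerated
#' exhaustively.
#'
#' @param Y response vector.
#' @param X design matrix.
#' @param contrast contrast weights.
#' @param exchangeability \code{"group_shuffle"} or
#'   \code{"paired_sign_flip"}.
#' @param nPermutations requested number of random permutations.
#' @param seed RNG seed.
#' @return an \linkS4class{InferenceResult}.
#' @export
permutationP <- function(Y, X, contrast,
                         exchangeability = c("group_shuffle",
                                             "paired_sign_flip"),
                         nPermutations = 10000L, seed = 1L) {
  exchangeability <- match.arg(exchangeability)
  T <- .flStats(matrix(Y, ncol = 1), as.matrix(X), contrast,
                exchangeability, nPermutations, seed)
  R <- nrow(T)
  p <- sum(abs(T[, 1]) >= abs(T[1, 1]) - 1e-12) / R
  new("InferenceResult", observedStat = T[1, 1], pUncorrected = p,
      nPermUsed = as.integer(R),
      method = sprintf("permutation GLM (%s%s)", exchangeability,
                       if (attr(T, "exhaustive")) ", exhaustive" else ""))
}

#' Non-parametric combination by Fisher's method
#'
#' Joint inference over several modalities tested under synchronized
#' permutations. The input is the matrix of per-permutation partial
#' p-values (rows = permutations, row 1 = observed; columns = modalities).
#' The combining statistic for each row is \eqn{-2\sum_m \ln p_m} and the
#' joint p-value is the proportion of rows whose statistic reaches the
#' observed one. Zero partial p-values are clamped to 1/R with a warning.
#'
#' @param partialP numeric matrix of partial p-values, permutations x
#'   modalities, row 1 observed.
#' @return an \linkS4class{InferenceResult} with the Fisher statistic as
#'   \code{observedStat} and the observed partial p-values in
#'   \code{partialP}.
#' @export
npcFisher <- function(partialP) {
  partialP <- as.matrix(partialP)
  R <- nrow(partialP)
  if (any(partialP <= 0)) {
    warning("zero partial p-values clamped to 1/nPerm before log")
    partialP[partialP <= 0] <- 1 / R
  }
  stat <- -2 * rowSums(log(partialP))
  p <- sum(stat >= stat[1] - 1e-12) / R
  new("InferenceResult", observedStat = stat[1], pUncorrected = p,
      nPermUsed = as.integer(R), partialP = partialP[1, ],
      method = "non-parametric combination (Fisher)")
}

#' Joint NPC test of several responses under one design
#'
#' Runs the Freedman-Lane permutation GLM for each response column under
#' one synchronized set of permutations, converts each column's statistics
#' to per-permutation partial p-values, and combines them with
#' \code{\link{npcFisher}}.
#'
#' @inheritParams permutationP
#' @param Y matrix of responses (columns = modalities, e.g. positive and
#'   negative total clustering).
#' @return an \linkS4class{InferenceResult}.
#' @export
npcJointTest <- function(Y, X, contrast,
                         exchangeability = c("group_shuffle",
                                             "paired_sign_flip"),
                         nPermutations = 10000L, seed = 1L) {
  exchangeability <- match.arg(exchangeability)
  T <- .flStats(as.matrix(Y), as.matrix(X), contrast, exchangeability,
                nPermutations, seed)
  npcFisher(.partialPMatrix(T))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR control at level \code{q}; a thin wrapper around
#' \code{stats::p.adjust(method = "BH")} returning both the rejection flags
#' and the adjusted p-values.
#'
#' @param p vector of p-values.
#' @param q FDR level.
#' @return list with \code{reject} (logical) and \code{adjusted}
#'   (numeric), both in the input order; empty input gives empty output.
#' @export
fdrBH <- function(p, q = 0.05) {
  if (length(p) == 0) return(list(reject = logical(0), adjusted = numeric(0)))
  adj <- stats::p.adjust(p, method = "BH")
  list(reject = !is.na(adj) & adj <= q, adjusted = adj)
}
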