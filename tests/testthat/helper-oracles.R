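# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized/igraph-backed code paths.

# random symmetric signed weight matrix with zero diagonal
randomSignedGraph <- function(n, density = 0.6) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  k <- sum(ut)
  w <- ifelse(runif(k) < density, runif(k, -1, 1), 0)
  W[ut] <- w
  W + t(W)
}

# Onnela signed total clustering by exhaustive triple enumeration
bruteClustering <- function(W) {
  onePart <- function(A) {
    mx <- max(A)
    if (mx <= 0) return(0)
    A <- A / mx
    n <- nrow(A)
    ci <- numeric(n)
    for (i in 1:n) {
      k <- sum(A[i, ] > 0)
      if (k < 2) next
      s <- 0
      for (j in 1:n) for (h in 1:n) {
        if (j == i || h == i || j == h) next
        s <- s + (A[i, j] * A[j, h] * A[h, i])^(1 / 3)
      }
      ci[i] <- s / (k * (k - 1))
    }
    mean(ci)
  }
  c(positive = onePart(pmax(W, 0)), negative = onePart(pmax(-W, 0)))
}

# global efficiency via Floyd-Warshall over inverse-weight lengths
bruteEfficiency <- function(W) {
  A <- pmax(W, 0)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1 / A[A > 0]
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# connected components of an edge list by union-find
unionFindComponents <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 1L)
}

# exhaustive paired sign-flip p-value for a one-sample t on differences,
# with Freedman-Lane handling of nuisance columns
bruteSignFlipP <- function(y, Z = NULL) {
  n <- length(y)
  X <- matrix(1, n, 1)
  if (!is.null(Z)) X <- cbind(X, Z)
  tStat <- function(yy) {
    fit <- lm.fit(X, yy)
    se <- sqrt(sum(fit$residuals^2) / (n - ncol(X)) *
                 solve(crossprod(X))[1, 1])
    fit$coefficients[1] / se
  }
  if (is.null(Z)) { E <- y; fitted <- rep(0, n) }
  else { g <- lm.fit(Z, y); E <- g$residuals; fitted <- g$fitted.values }
  tobs <- tStat(y)
  stats <- numeric(2^n)
  for (i in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(i, bitwShiftL(1L, 0:(n - 1))) > 0, -1, 1)
    stats[i + 1] <- tStat(fitted + s * E)
  }
  mean(abs(stats) >= abs(tobs) - 1e-12)
}

# textbook partial correlation from the unregularized inverse covariance
brutePartialCorrelation <- function(ts) {
  P <- solve(cov(ts))
  s <- 1 / sqrt(diag(P))
  r <- -P * tcrossprod(s)
  diag(r) <- 0
  r
}

# small helper: ConnectivityMatrix from a plain symmetric matrix
asCM <- function(W, id = "s", ses = "x") {
  new("ConnectivityMatrix", values = W,
      nodeLabels = sprintf("n%02d", seq_len(nrow(W))),
      rho = 0, subjectId = id, session = ses)
}
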