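test_that("zero-effect spec yields identical condition precisions", {
  spec <- cohortSpec(nHC = 2, nPD = 2, nMADD = 1, nNodes = 10,
                     nTimepoints = 50, seed = 11)
  expect_identical(buildPrecision(spec, "HC"), buildPrecision(spec, "PD_OFF"))
  expect_identical(buildPrecision(spec, "PD_ON"),
                   buildPrecision(spec, "PD_ON_nonMADD"))
  expect_identical(buildPrecision(spec, "HC"), buildPrecision(spec, "PD_ON"))
})

test_that("chain precision implies zero partial correlation on the absent edge", {
  theta <- diag(3)
  theta[1, 2] <- theta[2, 1] <- -0.4
  theta[2, 3] <- theta[3, 2] <- -0.3
  r <- impliedPartialCorrelation(theta)
  expect_equal(r[1, 3], 0)
  expect_equal(r[1, 2], 0.4)
  # yet the marginal correlation 1-3 is nonzero (connected through node 2)
  expect_gt(abs(cov2cor(solve(theta))[1, 3]), 0.05)
})

test_that("community precisions match direct inversion on planted edges", {
  spec <- cohortSpec(nHC = 2, nPD = 2, nMADD = 1, nNodes = 20,
                     nTimepoints = 50, nCommunities = 4, withinPC = 0.2,
                     sparsity = 1, seed = 3)
  theta <- buildPrecision(spec, "HC")
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # implied partial correlation from the definition vs from the numerical
  # inverse of the inverse covariance (independent route)
  S <- solve(theta)
  Pnum <- solve(S)
  rNum <- -Pnum / sqrt(tcrossprod(diag(Pnum)))
  diag(rNum) <- 0
  expect_equal(impliedPartialCorrelation(theta), rNum, tolerance = 1e-10)
  # within-community edges carry magnitude withinPC where planted
  offdiag <- abs(impliedPartialCorrelation(theta))
  vals <- offdiag[upper.tri(offdiag)]
  expect_true(all(abs(vals[vals > 1e-9] - 0.2) < 1e-9))
})

test_that("simulated series reproduce the generating covariance structure", {
  ts <- simulateTimeseries(diag(6), 5000, arCoefficient = 0, seed = 21)
  offd <- cor(ts)[upper.tri(diag(6))]
  expect_lt(max(abs(offd)), 4 / sqrt(5000))
  # determinism
  expect_identical(ts, simulateTimeseries(diag(6), 5000, 0, seed = 21))
  # AR(1) coefficient shows up as lag-1 autocorrelation
  ar <- simulateTimeseries(diag(3), 20000, arCoefficient = 0.9, seed = 4)
  lag1 <- vapply(1:3, function(j)
    cor(ar[-1, j], ar[-nrow(ar), j]), numeric(1))
  expect_equal(lag1, rep(0.9, 3), tolerance = 0.03)
  expect_error(simulateTimeseries(matrix(c(1, 2, 2, 1), 2), 10, 0, 1),
               "positive definite")
  expect_warning(simulateTimeseries(diag(5), 3, 0, 1), "singular")
})

test_that("cohort layout matches the design and keys are in bijection", {
  spec <- cohortSpec(nHC = 2, nPD = 2, nMADD = 1, nNodes = 8,
                     nTimepoints = 30, seed = 7)
  coh <- generateCohort(spec)
  expect_equal(nrow(coh@manifest), 2 + 2 * 2)
  expect_true(validObject(coh))
  expect_setequal(coh@manifest$session[coh@manifest$group == "HC"], "REST")
  expect_setequal(coh@manifest$session[coh@manifest$group == "PD"],
                  c("ON", "OFF"))
  # same seed regenerates the identical cohort
  coh2 <- generateCohort(spec)
  expect_identical(coh@series, coh2@series)
  expect_identical(coh@manifest, coh2@manifest)
})

test_that("planted session effect moves estimated ON-OFF differences to the implied value", {
  edges <- cbind(1:6, 2:7)
  spec <- cohortSpec(nHC = 2, nPD = 40, nMADD = 20, nNodes = 20,
                     nTimepoints = 200, sessionEffect = effectSpec(edges, 0.1),
                     arCoefficient = 0, seed = 31)
  implied <- impliedPartialCorrelation(buildPrecision(spec, "PD_ON"))[edges] -
    impliedPartialCorrelation(buildPrecision(spec, "PD_OFF"))[edges]
  expect_equal(unname(implied), rep(0.1, 6), tolerance = 1e-8)
  coh <- generateCohort(spec)
  conn <- computeConnectomes(coh, rho = 0)
  ids <- sprintf("PD%03d", 1:40)
  d <- vapply(ids, function(id)
    mean(conn[[paste0(id, "_ON")]]@values[edges] -
         conn[[paste0(id, "_OFF")]]@values[edges]), numeric(1))
  expect_gt(mean(d), 0)
  # bootstrap CI of the mean difference contains the implied difference
  set.seed(1)
  bs <- replicate(2000, mean(sample(d, replace = TRUE)))
  expect_gt(0.1, quantile(bs, 0.005))
  expect_lt(0.1, quantile(bs, 0.995))
})

test_that("covariate missingness behaves as specified", {
  cm <- defaultCovariateModel()
  cm$post_missing$madrs_post <- 0
  cm$post_missing$updrs_post <- 0
  for (nm in c("updrs_pre", "madrs_pre", "vta_overlap")) cm[[nm]]$missing <- 0
  spec <- cohortSpec(nHC = 2, nPD = 20, nMADD = 10, nNodes = 6,
                     nTimepoints = 20, covariateModel = cm, seed = 5)
  m <- generateCohort(spec)@manifest
  pd <- m[m$group == "PD", ]
  expect_false(anyNA(pd[, c("updrs_pre", "updrs_post", "madrs_pre",
                            "madrs_post", "vta_overlap")]))
  # with nonzero probabilities, missingness appears (PD fields only)
  spec2 <- cohortSpec(nHC = 2, nPD = 60, nMADD = 30, nNodes = 6,
                      nTimepoints = 20, seed = 5)
  m2 <- generateCohort(spec2)@manifest
  expect_gt(sum(is.na(m2$madrs_post[m2$group == "PD"])), 0)
  expect_false(anyNA(m2$age))
})

test_that("cohort round-trips through the on-disk layout", {
  spec <- cohortSpec(nHC = 2, nPD = 2, nMADD = 1, nNodes = 5,
                     nTimepoints = 12, seed = 13)
  coh <- generateCohort(spec)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "cohort_spec.yaml")))
  back <- readCohort(dir)
  expect_equal(nrow(back$manifest), nrow(coh@manifest))
  key <- names(coh@series)[[3]]
  expect_equal(unname(back$series[[key]]), unname(coh@series[[key]]),
               tolerance = 1e-9)
})

test_that("non-repairable effect deltas raise an informative error", {
  # delta pushing every edge of a dense node set far beyond feasibility
  edges <- t(combn(1:6, 2))
  spec <- cohortSpec(nHC = 2, nPD = 2, nMADD = 1, nNodes = 6,
                     nTimepoints = 20, nCommunities = 1, withinPC = 0.3,
                     sparsity = 1, sessionEffect = effectSpec(edges, 1.9),
                     seed = 2)
  expect_error(suppressWarnings(buildPrecision(spec, "PD_ON")), "delta")
})
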