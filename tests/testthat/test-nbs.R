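makeCMSet <- function(n, S, f) {
  out <- lapply(seq_len(S), function(s) asCM(f(s), sprintf("s%02d", s), "x"))
  names(out) <- sprintf("s%02d", seq_len(S))
  out
}

test_that("one-sample edge mask matches per-edge textbook t-tests", {
  set.seed(61)
  n <- 7; S <- 10
  mats <- makeCMSet(n, S, function(s) randomSignedGraph(n, density = 0.9))
  sp <- oneSampleEdgeMask(mats, alpha = 0.05)
  # independent edgewise t-tests
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    v <- vapply(mats, function(m) m@values[i, j], numeric(1))
    keepOracle <- if (sd(v) < 1e-14) abs(mean(v)) > 1e-14
                  else t.test(v)$p.value < 0.05
    expect_identical(sp@mask[i, j], keepOracle)
    if (!keepOracle)
      expect_true(all(vapply(sp@matrices, function(m) m@values[i, j],
                             numeric(1)) == 0))
  }
})

test_that("degenerate edges follow the stated conventions", {
  n <- 4
  base <- matrix(0, n, n)
  consistent <- base; consistent[1, 2] <- consistent[2, 1] <- 0.5
  mats <- makeCMSet(n, 5, function(s) consistent)
  sp <- oneSampleEdgeMask(mats, 0.05)
  expect_true(sp@mask[1, 2])            # zero variance, nonzero mean: kept
  expect_false(sp@mask[3, 4])           # exactly zero everywhere: masked
  expect_error(oneSampleEdgeMask(mats[1:2], 0.05), "at least 3")
})

test_that("edgewise statistics align with the scalar GLM and carry sentinels", {
  set.seed(71)
  n <- 6; S <- 12
  mats <- makeCMSet(n, S, function(s) randomSignedGraph(n, density = 1))
  sp <- oneSampleEdgeMask(mats, alpha = 0.9)  # retain nearly everything
  g <- rep(0:1, each = S / 2)
  des <- designSpec(cbind(1, g), c(0, 1), "group_shuffle", 10, 1)
  et <- edgewiseStats(sp, des)
  expect_true(is.na(et[1, 1]))
  i <- 2; j <- 5
  if (sp@mask[i, j]) {
    v <- vapply(mats, function(m) m@values[i, j], numeric(1))
    expect_equal(et[i, j], glmContrastStat(v, cbind(1, g), c(0, 1)),
                 tolerance = 1e-12)
  }
  expect_equal(et[i, j], et[j, i])
  # identical conditions: all retained t near 0
  mats2 <- makeCMSet(n, S, function(s) if (s <= 6) mats[[1]]@values
                                       else mats[[1]]@values)
  sp2 <- oneSampleEdgeMask(mats2, alpha = 0.9)
  et2 <- edgewiseStats(sp2, des)
  expect_lt(max(abs(et2), na.rm = TRUE), 1e-6)
})

test_that("supra-threshold components match a union-find oracle", {
  # triangle of supra-threshold edges: one component of 3 edges
  t1 <- matrix(0, 5, 5)
  t1[1, 2] <- t1[2, 3] <- t1[1, 3] <- 4
  t1 <- t1 + t(t1)
  comps <- supraThresholdComponents(t1, 3, "positive")
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size, 3)
  # two disjoint edges: two components of size 1
  t2 <- matrix(0, 6, 6)
  t2[1, 2] <- t2[4, 5] <- 4
  t2 <- t2 + t(t2)
  comps2 <- supraThresholdComponents(t2, 3, "positive")
  expect_length(comps2, 2)
  expect_true(all(vapply(comps2, `[[`, 0L, "size") == 1))
  # random matrices vs union-find
  set.seed(91)
  for (rep in 1:10) {
    n <- 10
    tm <- randomSignedGraph(n) * 6
    comps3 <- supraThresholdComponents(tm, 3, "two.sided")
    edges <- which(abs(tm) > 3 & upper.tri(tm), arr.ind = TRUE)
    if (nrow(edges) == 0) { expect_length(comps3, 0); next }
    memb <- unionFindComponents(edges, n)
    sizes <- sort(tabulate(memb[edges[, 1]]))
    sizes <- sizes[sizes > 0]
    expect_equal(sort(vapply(comps3, `[[`, 0L, "size")), sizes)
  }
})

test_that("raising the primary threshold never grows a component", {
  set.seed(13)
  tm <- randomSignedGraph(12) * 6
  for (dir in c("positive", "two.sided")) {
    sizes <- vapply(c(1, 2, 3, 4), function(th) {
      cs <- supraThresholdComponents(tm, th, dir)
      if (length(cs)) max(vapply(cs, `[[`, 0L, "size")) else 0L
    }, integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("NBS FWE control: planted effects are found, null components are not", {
  set.seed(300)
  n <- 10; S <- 24
  g <- rep(0:1, each = S / 2)
  planted <- cbind(1:4, 2:5)
  mats <- makeCMSet(n, S, function(s) {
    W <- randomSignedGraph(n, density = 1) * 0.2
    if (g[s] == 1) {
      W[planted] <- W[planted] + 0.8
      W[planted[, 2:1]] <- W[planted]
    }
    W
  })
  sp <- oneSampleEdgeMask(mats, alpha = 0.9)
  des <- designSpec(cbind(1, g), c(0, 1), "group_shuffle", 500, 5)
  res <- nbsFwe(sp, des, primaryThreshold = 3, direction = "positive")
  expect_gt(length(res@components), 0)
  top <- res@components[[1]]
  expect_lte(top$pFWE, 0.05)
  # planted edges dominate the recovered component
  plantedKeys <- paste(planted[, 1], planted[, 2])
  compKeys <- paste(top$edges[, 1], top$edges[, 2])
  expect_gte(mean(plantedKeys %in% compKeys), 0.75)
  # observed statistic is part of its own null: minimum attainable p
  expect_gte(min(vapply(res@components, `[[`, 0, "pFWE")),
             1 / res@nPermUsed)
  # threshold above the largest |t|: no components, not an error
  resHigh <- nbsFwe(sp, des, primaryThreshold = max(abs(res@edgeT),
                                                    na.rm = TRUE) + 1,
                    direction = "positive")
  expect_length(resHigh@components, 0)
})

test_that("component sizes are measured in edges, not nodes", {
  # a 4-node star has 3 edges and 4 nodes; its size must report 3
  tm <- matrix(0, 6, 6)
  tm[1, 2] <- tm[1, 3] <- tm[1, 4] <- 5
  tm <- tm + t(tm)
  comps <- supraThresholdComponents(tm, 3, "positive")
  expect_equal(comps[[1]]$size, 3L)
  expect_length(comps[[1]]$nodes, 4)
})
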