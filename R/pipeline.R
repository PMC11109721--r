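#' Construct a DesignSpec
#'
#' @param X design matrix.
#' @param contrast contrast weights (zero-weight columns are nuisance).
#' @param exchangeability \code{"group_shuffle"} or
#'   \code{"paired_sign_flip"}.
#' @param nPermutations permutation budget.
#' @param seed RNG seed.
#' @return a validated \linkS4class{DesignSpec}.
#' @export
designSpec <- function(X, contrast,
                       exchangeability = c("group_shuffle",
                                           "paired_sign_flip"),
                       nPermutations = 10000L, seed = 1L) {
  exchangeability <- match.arg(exchangeability)
  new("DesignSpec", X = as.matrix(X), contrast = as.numeric(contrast),
      exchangeability = exchangeability,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline. All constants the analysis needs
#' beyond the data live here: the ridge penalty, the clustering variant,
#' the NBS primary threshold, the permutation budget, the FDR level and the
#' edge-masking alpha.
#'
#' @param rho ridge penalty for partial-correlation estimation.
#' @param clusteringVariant \code{"onnela"} or \code{"zhang"}.
#' @param nbsPrimaryThreshold primary cluster-forming |t| threshold.
#' @param nPermutations permutation budget for every permutation test.
#' @param seed master seed; per-test seeds are derived deterministically.
#' @param fdrQ FDR level for each comparison family.
#' @param maskingAlpha alpha of the one-sample edge mask.
#' @return a list with class \code{"netpermConfig"}.
#' @export
analysisConfig <- function(rho = 0.1, clusteringVariant = "onnela",
                           nbsPrimaryThreshold = 3.0,
                           nPermutations = 10000L, seed = 1L,
                           fdrQ = 0.05, maskingAlpha = 0.05) {
  stopifnot(rho >= 0, fdrQ > 0, fdrQ < 1, nPermutations >= 1,
            nbsPrimaryThreshold > 0, maskingAlpha > 0, maskingAlpha < 1)
  structure(list(rho = rho, clusteringVariant = clusteringVariant,
                 nbsPrimaryThreshold = nbsPrimaryThreshold,
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed), fdrQ = fdrQ,
                 maskingAlpha = maskingAlpha),
            class = "netpermConfig")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file with any subset of the \code{\link{analysisConfig}}
#'   fields; unspecified fields keep their defaults.
#' @return a \code{"netpermConfig"} list.
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysisConfig, y[intersect(names(y), names(formals(analysisConfig)))])
}

# ---- cohort preparation ------------------------------------------------

# Derive the clinical covariates from raw pre/post scores and impute
# missing nuisance covariates by group mean (within patients, by subgroup).
# Raw pre/post score columns are left untouched so complete-case analyses
# can still see their missingness.
.prepareManifest <- function(manifest) {
  m <- manifest
  m$motor_improvement <- clinicalMotorImprovement(m$updrs_pre, m$updrs_post)
  m$psych_improvement <- madrsChange(m$madrs_pre, m$madrs_post)
  m$.impgroup <- ifelse(m$group == "HC", "HC", m$madd_status)
  pd <- m$group == "PD"
  for (cv in c("months_since_implant", "motor_improvement",
               "psych_improvement", "antidepressant", "vta_overlap")) {
    if (!cv %in% names(m)) next
    flagCol <- paste0(cv, "_imputed")
    m[[flagCol]] <- FALSE
    if (!any(is.na(m[[cv]][pd]))) next
    sub <- imputeGroupMean(m[pd, , drop = FALSE], cv, by = ".impgroup")
    m[[cv]][pd] <- sub[[cv]]
    m[[flagCol]][pd] <- sub[[flagCol]]
  }
  m
}

# wide per-run metric table keyed by "<subject>_<session>"
.metricsWide <- function(metricsDf) {
  key <- paste(metricsDf$subject_id, metricsDf$session, sep = "_")
  out <- unique(data.frame(key = key,
                           subject_id = metricsDf$subject_id,
                           session = metricsDf$session,
                           stringsAsFactors = FALSE))
  for (met in unique(metricsDf$metric)) {
    sel <- metricsDf$metric == met
    out[[met]] <- metricsDf$value[sel][match(out$key, key[sel])]
  }
  out
}

# one row per PD subject (covariates are subject-level)
.pdSubjects <- function(manifest) {
  pd <- manifest[manifest$group == "PD" & manifest$session == "OFF", ,
                 drop = FALSE]
  pd[order(pd$subject_id), , drop = FALSE]
}

.center <- function(X) sweep(X, 2, colMeans(X))

# per-PD-subject ON - OFF differences of metrics and of masked connectomes
.pairedDeltas <- function(wide, sparseSet, pdIds) {
  onKeys <- paste0(pdIds, "_ON"); offKeys <- paste0(pdIds, "_OFF")
  mOn <- wide[match(onKeys, wide$key), ]
  mOff <- wide[match(offKeys, wide$key), ]
  metricDelta <- cbind(clustering_pos = mOn$clustering_pos - mOff$clustering_pos,
                       clustering_neg = mOn$clustering_neg - mOff$clustering_neg,
                       efficiency = mOn$efficiency - mOff$efficiency)
  rownames(metricDelta) <- pdIds
  edgeDelta <- lapply(pdIds, function(id)
    sparseSet@matrices[[paste0(id, "_ON")]]@values -
      sparseSet@matrices[[paste0(id, "_OFF")]]@values)
  names(edgeDelta) <- pdIds
  list(metric = metricDelta, edges = edgeDelta)
}

.resultRow <- function(aim, comparison, test, direction, stat, res,
                       nPerm, seed, size = NA_integer_) {
  data.frame(aim = aim, comparison = comparison, test = test,
             direction = direction, statistic = stat,
             component_size = size,
             p_uncorrected = res, n_perm = nPerm, seed = seed,
             stringsAsFactors = FALSE)
}

# run clustering NPC + efficiency t + directional NBS for one comparison
.runComparison <- function(aim, comparison, Ymetrics, X, contrast,
                           exchangeability, sparseForNBS, nbsMatrices,
                           config, seedBase, log) {
  rows <- list(); nbs <- list()
  npc <- npcJointTest(Ymetrics[, c("clustering_pos", "clustering_neg"),
                               drop = FALSE],
                      X, contrast, exchangeability,
                      config$nPermutations, .subSeed(seedBase, 1L))
  rows[[1]] <- .resultRow(aim, comparison, "clustering_npc", "two.sided",
                          npc@observedStat, npc@pUncorrected,
                          npc@nPermUsed, .subSeed(seedBase, 1L))
  eff <- permutationP(Ymetrics[, "efficiency"], X, contrast,
                      exchangeability, config$nPermutations,
                      .subSeed(seedBase, 2L))
  rows[[2]] <- .resultRow(aim, comparison, "efficiency_t", "two.sided",
                          eff@observedStat, eff@pUncorrected,
                          eff@nPermUsed, .subSeed(seedBase, 2L))
  nbsSet <- new("SparseConnectomeSet", matrices = nbsMatrices,
                mask = sparseForNBS@mask,
                maskingAlpha = sparseForNBS@maskingAlpha)
  for (dir in c("positive", "negative")) {
    sd <- .subSeed(seedBase, if (dir == "positive") 3L else 4L)
    des <- designSpec(X, contrast, exchangeability,
                      config$nPermutations, sd)
    res <- nbsFwe(nbsSet, des, config$nbsPrimaryThreshold, dir)
    nbs[[dir]] <- res
    for (i in seq_along(res@components)) {
      co <- res@components[[i]]
      rows[[length(rows) + 1L]] <-
        .resultRow(aim, comparison, sprintf("nbs_component_%d", i), dir,
                   NA_real_, co$pFWE, res@nPermUsed, sd, size = co$size)
    }
  }
  log(sprintf("[%s/%s] mask retains %d edges; NBS components: +%d / -%d",
              aim, comparison,
              sum(sparseForNBS@mask[upper.tri(sparseForNBS@mask)]),
              length(nbs$positive@components),
              length(nbs$negative@components)))
  list(rows = do.call(rbind, rows), nbs = nbs)
}

# ---- aim runners -------------------------------------------------------

#' Run the Aim 1 analysis: stimulation effect versus healthy controls
#'
#' Executes the six-GLM structure of the primary analysis: three
#' comparisons (patient ON vs OFF paired; HC vs patient ON; HC vs patient
#' OFF), each tested on (i) the whole-network metrics — joint NPC over
#' positive/negative total clustering and a t test of global efficiency —
#' and (ii) the sparse connectomes via directional network-based
#' statistics. The paired comparison adjusts for sex, age, months since
#' implantation, clinical motor and psychiatric improvement and VTA
#' overlap; the control comparisons adjust for sex and age only. One FDR
#' correction is applied over the whole Aim 1 family.
#'
#' @param cohort a \linkS4class{Cohort} (or \code{\link{readCohort}} list).
#' @param config an \code{\link{analysisConfig}}.
#' @param outDir optional directory for the report bundle (CSV tables, edge
#'   lists, config echo, log). Outputs are byte-deterministic given
#'   config + seed.
#' @return list with \code{inference} (data.frame incl. \code{p_fdr}),
#'   \code{metrics}, \code{summary}, per-comparison \code{nbs} results and
#'   the \code{config}.
#' @export
runAim1 <- function(cohort, config = analysisConfig(), outDir = NULL) {
  prep <- .prepareAll(cohort, config)
  logLines <- character(0)
  log <- function(s) logLines <<- c(logLines, s)
  pdIds <- prep$pdTab$subject_id
  out <- list()

  # paired ON vs OFF, patients only
  pairedMask <- oneSampleEdgeMask(
    prep$connectomes[c(paste0(pdIds, "_ON"), paste0(pdIds, "_OFF"))],
    config$maskingAlpha)
  deltas <- .pairedDeltas(prep$wide, pairedMask, pdIds)
  Z <- .center(as.matrix(prep$pdTab[, c("sex", "age", "months_since_implant",
                                        "motor_improvement",
                                        "psych_improvement", "vta_overlap")]))
  X <- cbind(session = 1, Z)
  out$ON_vs_OFF <- .runComparison("aim1", "ON_vs_OFF", deltas$metric, X,
                                  c(1, rep(0, ncol(Z))), "paired_sign_flip",
                                  pairedMask, deltas$edges, config,
                                  .subSeed(config$seed, 11L), log)

  # HC vs each patient session
  hcIds <- sort(unique(prep$manifest$subject_id[prep$manifest$group == "HC"]))
  hcKeys <- paste0(hcIds, "_REST")
  for (ses in c("ON", "OFF")) {
    keys <- c(hcKeys, paste0(pdIds, "_", ses))
    cmp <- paste0("HC_vs_", ses)
    mask <- oneSampleEdgeMask(prep$connectomes[keys], config$maskingAlpha)
    rows <- match(keys, paste(prep$manifest$subject_id,
                              prep$manifest$session, sep = "_"))
    X <- cbind(intercept = 1,
               groupPD = as.numeric(prep$manifest$group[rows] == "PD"),
               sex = prep$manifest$sex[rows], age = prep$manifest$age[rows])
    Ym <- as.matrix(prep$wide[match(keys, prep$wide$key),
                              c("clustering_pos", "clustering_neg",
                                "efficiency")])
    out[[cmp]] <- .runComparison("aim1", cmp, Ym, X, c(0, 1, 0, 0),
                                 "group_shuffle", mask,
                                 lapply(mask@matrices[keys],
                                        function(m) m@values),
                                 config,
                                 .subSeed(config$seed,
                                          if (ses == "ON") 21L else 31L), log)
  }

  inference <- do.call(rbind, lapply(out, `[[`, "rows"))
  adj <- fdrBH(inference$p_uncorrected, config$fdrQ)
  inference$p_fdr <- adj$adjusted
  inference$significant <- adj$reject
  inference$fdr_family <- "aim1"
  rownames(inference) <- NULL
  bundle <- list(inference = inference, metrics = prep$metrics,
                 summary = .metricSummary(prep$wide, prep$manifest),
                 nbs = lapply(out, `[[`, "nbs"), config = config,
                 log = logLines)
  if (!is.null(outDir)) .writeReport(bundle, outDir, "aim1", prep)
  bundle
}

#' Run the Aim 2 analysis: psychiatric subgroup by stimulation interaction
#'
#' Tests whether the stimulation response (per-subject ON minus OFF
#' difference) differs between patients outside and inside the psychiatric
#' subgroup: joint NPC over the clustering deltas and a t test of the
#' efficiency delta, directional network-based statistics on the delta
#' connectomes, and a clinical GLM (motor and depression score pre-to-post
#' changes by subgroup) run on the complete-case subset. Nuisance
#' covariates: sex, age, months since implantation, clinical motor
#' improvement, antidepressant use and VTA overlap (the clinical GLM omits
#' motor improvement, which is derived from its own dependent variable).
#' One FDR correction is applied over the whole Aim 2 family.
#'
#' @inheritParams runAim1
#' @return list as in \code{\link{runAim1}}, plus \code{clinicalN} (size of
#'   the complete-case subset).
#' @export
runAim2 <- function(cohort, config = analysisConfig(), outDir = NULL) {
  prep <- .prepareAll(cohort, config)
  logLines <- character(0)
  log <- function(s) logLines <<- c(logLines, s)
  pdTab <- prep$pdTab
  if (length(unique(stats::na.omit(pdTab$madd_status))) < 2)
    stop("both psychiatric subgroups (MADD and nonMADD) must be present")
  pdIds <- pdTab$subject_id

  pairedMask <- oneSampleEdgeMask(
    prep$connectomes[c(paste0(pdIds, "_ON"), paste0(pdIds, "_OFF"))],
    config$maskingAlpha)
  deltas <- .pairedDeltas(prep$wide, pairedMask, pdIds)
  Z <- .center(as.matrix(pdTab[, c("sex", "age", "months_since_implant",
                                   "motor_improvement", "antidepressant",
                                   "vta_overlap")]))
  X <- cbind(intercept = 1,
             nonMADD = as.numeric(pdTab$madd_status == "nonMADD"), Z)
  contrast <- c(0, 1, rep(0, ncol(Z)))
  out <- list(interaction = .runComparison("aim2", "interaction",
                                           deltas$metric, X, contrast,
                                           "group_shuffle", pairedMask,
                                           deltas$edges, config,
                                           .subSeed(config$seed, 41L), log))

  # clinical GLM on the complete-case subset
  cc <- !is.na(pdTab$updrs_pre) & !is.na(pdTab$updrs_post) &
        !is.na(pdTab$madrs_pre) & !is.na(pdTab$madrs_post)
  ccTab <- pdTab[cc, , drop = FALSE]
  log(sprintf("[aim2/clinical] complete-case subset: %d of %d patients",
              nrow(ccTab), nrow(pdTab)))
  clinRows <- list()
  if (nrow(ccTab) >= 4) {
    Zc <- .center(as.matrix(ccTab[, c("sex", "age", "months_since_implant",
                                      "antidepressant", "vta_overlap")]))
    Xc <- cbind(intercept = 1,
                nonMADD = as.numeric(ccTab$madd_status == "nonMADD"), Zc)
    con <- c(0, 1, rep(0, ncol(Zc)))
    resps <- list(clinical_updrs_change = ccTab$updrs_post - ccTab$updrs_pre,
                  clinical_madrs_change =
                    madrsChange(ccTab$madrs_pre, ccTab$madrs_post))
    for (i in seq_along(resps)) {
      sd <- .subSeed(config$seed, 50L + i)
      r <- permutationP(resps[[i]], Xc, con, "group_shuffle",
                        config$nPermutations, sd)
      clinRows[[i]] <- .resultRow("aim2", "clinical", names(resps)[i],
                                  "two.sided", r@observedStat,
                                  r@pUncorrected, r@nPermUsed, sd)
    }
  }
  inference <- rbind(out$interaction$rows, do.call(rbind, clinRows))
  adj <- fdrBH(inference$p_uncorrected, config$fdrQ)
  inference$p_fdr <- adj$adjusted
  inference$significant <- adj$reject
  inference$fdr_family <- "aim2"
  rownames(inference) <- NULL
  bundle <- list(inference = inference, metrics = prep$metrics,
                 summary = .metricSummary(prep$wide, prep$manifest),
                 nbs = lapply(out, `[[`, "nbs"), config = config,
                 clinicalN = sum(cc), log = logLines)
  if (!is.null(outDir)) .writeReport(bundle, outDir, "aim2", prep)
  bundle
}

# shared preparation: connectomes, metrics, manifest with derived/imputed
# covariates, PD subject table
.prepareAll <- function(cohort, config) {
  if (is(cohort, "Cohort"))
    cohort <- list(series = cohort@series, manifest = cohort@manifest)
  manifest <- .prepareManifest(cohort$manifest)
  connectomes <- computeConnectomes(cohort, rho = config$rho)
  metrics <- graphMetrics(connectomes, variant = config$clusteringVariant)
  wide <- .metricsWide(metrics)
  list(manifest = manifest, connectomes = connectomes, metrics = metrics,
       wide = wide, pdTab = .pdSubjects(manifest))
}

.metricSummary <- function(wide, manifest) {
  grp <- ifelse(wide$session == "REST", "HC",
                paste0("PD_", wide$session))
  rows <- list()
  for (g in unique(grp)) for (met in c("clustering_pos", "clustering_neg",
                                       "efficiency")) {
    v <- wide[[met]][grp == g]
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, metric = met, mean = mean(v), sd = stats::sd(v),
      n = length(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.writeReport <- function(bundle, outDir, aim, prep) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(outDir, name), row.names = FALSE)
  wr(bundle$inference, paste0(aim, "_inference.csv"))
  wr(bundle$metrics, "metrics.csv")
  wr(bundle$summary, "metrics_summary.csv")
  for (cmp in names(bundle$nbs)) {
    res0 <- bundle$nbs[[cmp]][[1]]
    et <- res0@edgeT
    lab <- sprintf("node%03d", seq_len(nrow(et)))
    dimnames(et) <- list(lab, lab)
    utils::write.table(round(et, 6),
      file.path(outDir, sprintf("%s_%s_edge_t.tsv", aim, cmp)),
      sep = "\t", quote = FALSE, col.names = NA)
    for (dir in names(bundle$nbs[[cmp]])) {
      res <- bundle$nbs[[cmp]][[dir]]
      for (i in seq_along(res@components)) {
        co <- res@components[[i]]
        el <- data.frame(node1 = lab[co$edges[, 1]],
                         node2 = lab[co$edges[, 2]],
                         t = res@edgeT[co$edges])
        utils::write.table(el,
          file.path(outDir, sprintf("%s_%s_%s_component%d.tsv",
                                    aim, cmp, dir, i)),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  cfg <- bundle$config
  yaml::write_yaml(unclass(cfg), file.path(outDir, "config_echo.yaml"))
  writeLines(bundle$log, file.path(outDir, paste0(aim, "_log.txt")))
  invisible(outDir)
}
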