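#' @include syntheticCohort.R jackknife.R fcDynamics.R groupNBS.R networkMaps.R crossPhase.R ccaClinical.R
NULL

#' Atlas table for an arbitrary region count
#'
#' Assigns \code{nRegions} regions to the 8 canonical networks in contiguous
#' blocks of near-equal size — the bookkeeping needed to exercise
#' network-level summaries on reduced synthetic parcellations.
#'
#' @param nRegions number of regions.
#' @return atlas data.frame (\code{region_id}, \code{label}, \code{network}).
#' @export
syntheticAtlas <- function(nRegions) {
  nets <- canonicalNetworks()
  nw <- nets[ceiling(seq_len(nRegions) / (nRegions / length(nets)))]
  nw[is.na(nw)] <- nets[length(nets)]
  data.frame(region_id = seq_len(nRegions),
             label = sprintf("%s_%03d", nw, seq_len(nRegions)),
             network = nw, stringsAsFactors = FALSE)
}

#' Assemble a pipeline configuration
#'
#' Merges user settings over the pipeline defaults. \code{cohort} entries are
#' passed to [cohortConfig()]; remaining blocks parameterise the stages.
#' A YAML file with the same structure can be given instead of a list.
#'
#' @param config named list or path to a YAML file.
#' @return validated config list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(
    seed = 1L,
    cohort = list(nPerGroup = c(HC = 30, AX = 30), nRegions = 60L,
                  includeRecallEdgeFC = TRUE),
    fc = list(method = "jackknife_zflip", fisherTransform = TRUE, pool = "all"),
    blocks = list(nBlocks = 4L),
    nbs = list(thresholdP = 0.001, nPerm = 1000L, direction = "greater",
               comparisons = list(c("HC", "AX"))),
    crossphase = list(nPerm = 1000L),
    cca = list(nPerm = 1000L, k = 5L,
               measures = c("ASI", "BAI", "BDI", "STAI_T")),
    outputDir = NULL)
  mergeList <- function(base, over) {
    for (nm in names(over))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        mergeList(base[[nm]], over[[nm]]) else over[[nm]]
    base
  }
  cfg <- mergeList(def, config)
  if (!is.null(cfg$cohort$nPerGroup)) cfg$cohort$nPerGroup <- unlist(cfg$cohort$nPerGroup)
  cfg$nbs$comparisons <- lapply(cfg$nbs$comparisons, unlist)
  class(cfg) <- "pipelineConfig"
  cfg
}

.writeProvenanced <- function(obj, path, meta, report) {
  if (is.data.frame(obj)) utils::write.csv(obj, path, row.names = FALSE)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  report$provenance[[basename(path)]] <- c(meta, md5 = unname(tools::md5sum(path)))
  report
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes all stages in dependency order: cohort generation, per-subject
#' jackknife trial FC, time-block averaging, connectivity change (CS+, CS-,
#' differential), NBS group inference per configured comparison,
#' network-level summaries of each significant component, the
#' component-level differential-change t-test, cross-phase regression (per
#' group) against recall activation, cross-phase NBS against recall edge FC
#' when present, and CCA of connectivity change against clinical measures.
#' All stage seeds derive deterministically from the top-level seed, so
#' identical configs reproduce every statistic.
#'
#' @param config a [pipelineConfig()] (or list / YAML path coercible to one).
#' @return a nested run report (list) with per-stage results, parameters
#'   and seeds; when \code{config$outputDir} is set, key tables are also
#'   written there with md5 provenance recorded in the report.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (!inherits(config, "pipelineConfig")) config <- pipelineConfig(config)
  stageSeed <- function(k) as.integer((config$seed * 97L + k * 1009L) %% .Machine$integer.max)
  report <- list(config = unclass(config), provenance = list(), stages = list())

  cohortArgs <- config$cohort
  cohortArgs$seed <- stageSeed(1L)
  cohort <- generateCohort(do.call(cohortConfig, cohortArgs))
  R <- cohort@config$nRegions
  atlas <- if (R == 432L) defaultAtlas() else syntheticAtlas(R)
  des <- subjects(cohort)
  n <- nrow(des)

  deltaPlus <- vector("list", n); deltaMinus <- vector("list", n)
  for (s in seq_len(n)) {
    tfc <- jackknifeTrialFC(cohort@betaSeries[[s]], method = config$fc$method,
                            fisherTransform = config$fc$fisherTransform,
                            pool = config$fc$pool)
    bfc <- blockAverage(tfc, nBlocks = config$blocks$nBlocks)
    deltaPlus[[s]] <- deltaFC(bfc$CSplus)
    deltaMinus[[s]] <- deltaFC(bfc$CSminus)
  }
  dPlus <- deltaMatrix(deltaPlus)
  dMinus <- deltaMatrix(deltaMinus)
  dDiff <- dPlus - dMinus
  edgeIdx <- edgeIndex(deltaPlus[[1L]])

  planted <- truth(cohort)$planted_edges
  report$stages$nbs <- list()
  primaryComponent <- NULL
  for (cmp in config$nbs$comparisons) {
    key <- paste(cmp, collapse = "_vs_")
    res <- nbs(dPlus, des, cmp, thresholdP = config$nbs$thresholdP,
               nPerm = config$nbs$nPerm, direction = config$nbs$direction,
               seed = stageSeed(2L), edgeIdx = edgeIdx)
    st <- componentStats(res)
    entry <- list(contrast = key, n_components = nrow(st),
                  threshold_p = res@thresholdP, n_perm = res@nPerm,
                  seed = res@seed)
    if (nrow(st)) {
      comp <- components(res)[[1L]]
      entry$component_size <- st$size[1L]
      entry$p_fwe <- st$p_fwe[1L]
      pos <- edgeRowsToPos(comp, R)
      entry$component_ttest <- componentLevelTtest(rowMeans(dDiff[, pos, drop = FALSE]),
                                                   des, cmp)
      frac <- edgeFractionMatrix(comp, atlas)
      entry$network_pair_proportion <- frac$proportion
      entry$top_degree_regions <- utils::head(
        sort(nodeAbnormalDegree(comp, atlas), decreasing = TRUE), 5L)
      ## downstream stages condition on a *significant* component only
      if (is.null(primaryComponent) && st$p_fwe[1L] < 0.05)
        primaryComponent <- comp
    }
    report$stages$nbs[[key]] <- entry
  }
  componentEdges <- if (!is.null(primaryComponent)) primaryComponent else planted
  report$stages$component_source <-
    if (is.null(primaryComponent)) "planted (no significant component)" else "nbs"
  report$stages$primary_component_edges <-
    matrix(as.integer(componentEdges), ncol = 2L,
           dimnames = list(NULL, c("i", "j")))

  ## cross-phase: predictor = mean CS+ delta FC over the component
  pos <- edgeRowsToPos(componentEdges, R)
  predictor <- rowMeans(dPlus[, pos, drop = FALSE])
  recallRegion <- truth(cohort)$recall_region
  cp <- list()
  for (g in unique(des$group)) {
    sel <- des$group == g
    reg <- crossphaseRegression(predictor[sel], cohort@recall[sel, , drop = FALSE],
                                des[sel, , drop = FALSE],
                                nPerm = config$crossphase$nPerm,
                                seed = stageSeed(3L))
    cp[[g]] <- list(
      detected_regions = reg$region[reg$p_fwe < 0.05],
      planted_region_partial_r = reg$partial_r[recallRegion],
      planted_region_p_fwe = reg$p_fwe[recallRegion])
  }
  grps <- unique(des$group)
  if (length(grps) >= 2L) {
    n1 <- sum(des$group == grps[1L]); n2 <- sum(des$group == grps[2L])
    cp$correlation_comparison <- compareCorrelations(
      cp[[grps[1L]]]$planted_region_partial_r, n1,
      cp[[grps[2L]]]$planted_region_partial_r, n2)
  }
  report$stages$crossphase <- cp

  if (length(cohort@recallEdgeFC)) {
    cpn <- list()
    for (g in grps) {
      sel <- des$group == g
      for (dir in c("greater", "less")) {
        res <- crossphaseNBS(predictor[sel], cohort@recallEdgeFC[sel, , drop = FALSE],
                             des[sel, , drop = FALSE],
                             thresholdP = config$nbs$thresholdP,
                             nPerm = config$crossphase$nPerm,
                             direction = dir, seed = stageSeed(4L),
                             edgeIdx = edgeIdx)
        st <- componentStats(res)
        cpn[[paste(g, dir, sep = "_")]] <-
          list(n_components = nrow(st),
               largest = if (nrow(st)) st$size[1L] else 0L,
               p_fwe = if (nrow(st)) st$p_fwe[1L] else NA_real_)
      }
    }
    report$stages$crossphase_nbs <- cpn
  }

  measures <- intersect(config$cca$measures, names(clinicalTable(cohort)))
  Y <- as.matrix(clinicalTable(cohort)[measures])
  X <- dPlus[, pos, drop = FALSE]
  fit <- ccaPermutation(X, Y, nPerm = config$cca$nPerm, seed = stageSeed(5L))
  cv <- ccaCrossValidation(X, Y, k = config$cca$k,
                           nPerm = max(100L, config$cca$nPerm %/% 5L),
                           seed = stageSeed(6L))
  loads <- canonicalLoadings(fit, X, Y, componentEdges, atlas)
  report$stages$cca <- list(
    canonical_r = canonicalR(fit), perm_p = fit@permP,
    cv_r = cv$cvR, cv_perm_p = cv$cvPermP,
    reduction_rank = fit@reductionRank,
    clinical_loadings = loads$clinical,
    network_loadings = loads$network[!is.na(loads$network)],
    n_perm = fit@nPerm, seed = fit@seed)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    report <- .writeProvenanced(des, file.path(config$outputDir, "subjects.csv"),
                                list(stage = "cohort", seed = stageSeed(1L)), report)
    compDf <- as.data.frame(componentEdges)
    report <- .writeProvenanced(compDf, file.path(config$outputDir, "component_edges.csv"),
                                list(stage = "nbs", seed = stageSeed(2L)), report)
    rep2 <- report
    jsonlite::write_json(rep2, file.path(config$outputDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
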