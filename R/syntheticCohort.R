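#' @include AllClasses.R utils.R
NULL

#' Default planted connectivity component
#'
#' Returns the default planted edge set: two 6-region cliques sharing one
#' region (11 regions, 30 edges, connected). Within each clique the trial-wise
#' correlation is equicorrelated, which keeps the per-trial correlation matrix
#' positive definite for planted correlations up to about 0.55 — an arbitrary
#' 30-edge graph with correlation placed on edges only need not be a valid
#' correlation matrix.
#'
#' @param offset shift all region indices by this amount (default 0, i.e.
#'   regions 1..11).
#' @return integer edge matrix with columns \code{i}, \code{j}.
#' @export
#' @examples
#' nrow(plantedComponentEdges())  # 30
plantedComponentEdges <- function(offset = 0L) {
  cl1 <- t(utils::combn(1:6, 2L))
  cl2 <- t(utils::combn(6:11, 2L))
  normalizeEdges(rbind(cl1, cl2) + as.integer(offset))
}

#' Configuration for a synthetic fear-extinction cohort
#'
#' Defines the statistical structure of a generated cohort: two interleaved
#' stimulus types (CS+ reinforced during conditioning, CS- never reinforced)
#' with 16 extinction-learning trials each; a planted edge component whose
#' CS+ coupling changes linearly across trials with a group-specific slope
#' (increasing in controls, flat-to-decreasing in patient groups); a
#' recall-phase regional signal linearly linked to each subject's true
#' connectivity change in designated groups only; and clinical scores
#' linearly linked to the same latent change.
#'
#' Per-subject heterogeneity: subject i in group g has latent slope
#' \code{s_i ~ N(slope_g, slopeSD)} (truncated to the valid correlation
#' range); the CS+ planted-edge correlation at within-type trial m (of T)
#' is \code{baselineRho + s_i (m-1)/(T-1)}, and CS- trials stay at
#' \code{baselineRho}. The subject's true change proxy — the quantity the
#' recall and clinical signals are linked to — is the subject's realized
#' planted-component mean connectivity change, computed from the drawn
#' betas with the same jackknife/time-block machinery the analysis uses.
#'
#' @param nPerGroup named integer vector, subjects per group (names are the
#'   group labels), e.g. \code{c(HC = 40, AX = 40)}.
#' @param nRegions number of atlas regions (default 432: 400 cortical + 32
#'   subcortical).
#' @param nTrialsPerCS extinction-learning trials per CS type; must be
#'   divisible by 4 (default 16, i.e. 4 time-blocks of 4).
#' @param plantedEdges integer edge matrix of the planted component
#'   (default [plantedComponentEdges()]).
#' @param baselineRho planted-edge correlation at trial 1 and on all CS-
#'   trials, in \[0, 1).
#' @param slopeByGroup named numeric: total planted-correlation change over
#'   the CS+ trials per group.
#' @param slopeSD between-subject SD of the latent slope; subject slopes are
#'   drawn from a normal truncated so every trialwise correlation stays
#'   inside \code{rhoRange}.
#' @param rhoRange admissible range of the planted trialwise correlation;
#'   both endpoints must yield a positive-definite planted correlation
#'   matrix (checked), which bounds them well inside (-1, 1).
#' @param recallRegion region index carrying the planted recall signal
#'   (default: first region after the planted component).
#' @param recallLink named numeric per group: slope linking the change proxy
#'   to the recall region's activation contrast (0 = no link).
#' @param recallNoiseSD SD of recall activation noise (all regions).
#' @param recallFCLink named numeric per group: slope linking the change
#'   proxy to recall-phase FC on the planted edges (positive in controls,
#'   negative in the anxiety group by default, mirroring opposite-signed
#'   cross-phase coupling).
#' @param recallFCNoiseSD SD of recall edge-FC noise.
#' @param includeRecallEdgeFC generate the subjects x edges recall FC table
#'   (memory grows with R^2; off by default).
#' @param clinicalWeights named numeric: weight of the change proxy in each
#'   clinical measure. Negative weights encode "higher severity with lower
#'   connectivity change".
#' @param clinicalMeans,clinicalNoiseSD location and noise SD per measure.
#' @param interleaving trial order: \code{"alternating"} (CS+, CS-, ...),
#'   \code{"random"}, or \code{"blocked"}.
#' @param trialSpacing seconds between trial onsets; \code{trialDuration}
#'   seconds of cue presentation (recorded in events tables).
#' @param trialDuration cue duration in seconds.
#' @param seed integer RNG seed; identical configs generate identical cohorts.
#' @return a validated config list of class \code{cohortConfig}.
#' @export
#' @examples
#' cfg <- cohortConfig(nPerGroup = c(HC = 4, AX = 4), nRegions = 20, seed = 1)
cohortConfig <- function(nPerGroup = c(HC = 77, AX = 91, PTSD = 81, TENC = 89),
                         nRegions = 432L,
                         nTrialsPerCS = 16L,
                         plantedEdges = plantedComponentEdges(),
                         baselineRho = 0.1,
                         slopeByGroup = c(HC = 0.3, AX = -0.05, PTSD = -0.1, TENC = 0.25),
                         slopeSD = 0.1,
                         rhoRange = c(-0.15, 0.5),
                         recallRegion = NULL,
                         recallLink = c(HC = 1, AX = 0, PTSD = 0, TENC = 0),
                         recallNoiseSD = 0.2,
                         recallFCLink = c(HC = 1, AX = -1, PTSD = 0, TENC = 0),
                         recallFCNoiseSD = 0.3,
                         includeRecallEdgeFC = FALSE,
                         clinicalWeights = c(ASI = -40, BAI = -30, BDI = -25,
                                             STAI_T = -35, CAPS_5 = -60),
                         clinicalMeans = c(ASI = 20, BAI = 12, BDI = 10,
                                           STAI_T = 40, CAPS_5 = 18),
                         clinicalNoiseSD = c(ASI = 12, BAI = 10, BDI = 8,
                                             STAI_T = 12, CAPS_5 = 18),
                         interleaving = c("alternating", "random", "blocked"),
                         trialSpacing = 12, trialDuration = 6,
                         seed = 1L) {
  interleaving <- match.arg(interleaving)
  if (is.null(names(nPerGroup)) || any(!nzchar(names(nPerGroup))))
    stop("nPerGroup must be a named vector of group sizes")
  groups <- names(nPerGroup)
  if (nTrialsPerCS %% 4L != 0L)
    stop("nTrialsPerCS must be divisible by 4 (time-block design)")
  plantedEdges <- normalizeEdges(plantedEdges)
  if (max(plantedEdges) > nRegions)
    stop("plantedEdges reference region indices beyond nRegions = ", nRegions)
  if (baselineRho < 0 || baselineRho >= 1) stop("baselineRho must lie in [0, 1)")
  slopeByGroup <- slopeByGroup[groups]
  if (any(is.na(slopeByGroup)))
    stop("slopeByGroup must name every group in nPerGroup")
  if (length(rhoRange) != 2L || rhoRange[1L] >= rhoRange[2L] ||
      rhoRange[1L] <= -1 || rhoRange[2L] >= 1)
    stop("rhoRange must be an increasing pair inside (-1, 1)")
  if (baselineRho > rhoRange[2L] || baselineRho < rhoRange[1L])
    stop("baselineRho outside rhoRange")
  if (any(slopeByGroup > rhoRange[2L] - baselineRho) ||
      any(slopeByGroup < rhoRange[1L] - baselineRho))
    stop("group slope pushes the mean trialwise correlation outside rhoRange; ",
         "trialwise correlations must stay in (-1, 1) and positive definite")
  if (is.null(recallRegion)) recallRegion <- max(plantedEdges) + 1L
  if (recallRegion > nRegions) stop("recallRegion beyond nRegions")
  cfg <- list(
    nPerGroup = nPerGroup, groups = groups, nRegions = as.integer(nRegions),
    nTrialsPerCS = as.integer(nTrialsPerCS), plantedEdges = plantedEdges,
    baselineRho = baselineRho, slopeByGroup = slopeByGroup, slopeSD = slopeSD,
    rhoRange = rhoRange,
    recallRegion = as.integer(recallRegion),
    recallLink = recallLink[groups], recallNoiseSD = recallNoiseSD,
    recallFCLink = recallFCLink[groups], recallFCNoiseSD = recallFCNoiseSD,
    includeRecallEdgeFC = isTRUE(includeRecallEdgeFC),
    clinicalWeights = clinicalWeights, clinicalMeans = clinicalMeans,
    clinicalNoiseSD = clinicalNoiseSD,
    interleaving = interleaving, trialSpacing = trialSpacing,
    trialDuration = trialDuration, seed = as.integer(seed))
  cfg$recallLink[is.na(cfg$recallLink)] <- 0
  cfg$recallFCLink[is.na(cfg$recallFCLink)] <- 0
  names(cfg$recallLink) <- names(cfg$recallFCLink) <- groups
  class(cfg) <- "cohortConfig"
  ## every reachable trialwise planted correlation matrix must be positive
  ## definite: subject slopes are truncated so rho stays inside rhoRange,
  ## so checking the range endpoints (and baseline) suffices
  for (rho in unique(c(rhoRange, baselineRho))) {
    C <- .plantedCorrelation(plantedEdges, rho)
    ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop("planted correlation matrix not positive definite at rho = ",
           signif(rho, 3), "; shrink rhoRange or restructure plantedEdges")
  }
  cfg
}

## truncated-normal slope draw keeping baseline + slope inside rhoRange
.truncNormSlopes <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## correlation matrix over the planted subgraph's nodes (identity + rho on edges)
.plantedCorrelation <- function(plantedEdges, rho) {
  nodes <- sort(unique(as.vector(plantedEdges)))
  k <- length(nodes)
  C <- diag(k)
  i <- match(plantedEdges[, 1L], nodes)
  j <- match(plantedEdges[, 2L], nodes)
  C[cbind(i, j)] <- rho
  C[cbind(j, i)] <- rho
  C
}

#' Generate a synthetic cohort with planted connectivity dynamics
#'
#' Draws, for every subject, a 2T-trial extinction-learning beta series
#' (T trials per CS type, interleaved) from zero-mean multivariate normals:
#' on the planted component the correlation follows the subject's latent
#' slope during CS+ trials and stays at baseline during CS- trials; all
#' other regions are independent unit-variance noise. Also generates the
#' recall-phase activation table, optional recall edge-FC table, clinical
#' scores, subject covariates (age, sex), and the ground truth needed for
#' recovery tests. Identical configs (including seed) give identical output.
#'
#' @param config a [cohortConfig()].
#' @return a [SyntheticCohort-class].
#' @export
#' @examples
#' cfg <- cohortConfig(nPerGroup = c(HC = 3, AX = 3), nRegions = 16, seed = 7)
#' coh <- generateCohort(cfg)
#' coh
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  withSeed(config$seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(cfg) {
  Tcs <- cfg$nTrialsPerCS
  Ttot <- 2L * Tcs
  R <- cfg$nRegions
  nodes <- sort(unique(as.vector(cfg$plantedEdges)))
  k <- length(nodes)
  n <- sum(cfg$nPerGroup)
  group <- rep(cfg$groups, times = cfg$nPerGroup)
  ids <- sprintf("sub-%03d", seq_len(max(n, 1L)))[seq_len(n)]

  ## trial ordering
  csSeq <- switch(cfg$interleaving,
    alternating = rep(c("CSplus", "CSminus"), Tcs),
    blocked = rep(c("CSplus", "CSminus"), each = Tcs),
    random = NULL) # drawn per subject below
  subjectsDf <- data.frame(
    subject_id = ids, group = group,
    age = round(stats::runif(n, 18, 60), 1),
    sex = stats::rbinom(n, 1L, 0.5),
    stringsAsFactors = FALSE)

  ## subject slopes: normal around the group mean, truncated to the slope
  ## range that keeps every trialwise correlation inside rhoRange
  slopeLo <- cfg$rhoRange[1L] - cfg$baselineRho
  slopeHi <- cfg$rhoRange[2L] - cfg$baselineRho
  slopes <- numeric(n)
  for (g in cfg$groups) {
    sel <- group == g
    slopes[sel] <- .truncNormSlopes(sum(sel), cfg$slopeByGroup[[g]],
                                    cfg$slopeSD, slopeLo, slopeHi)
  }
  betaList <- vector("list", n)
  names(betaList) <- ids
  regionLabels <- sprintf("R%03d", seq_len(R))
  for (s in seq_len(n)) {
    ord <- if (cfg$interleaving == "random")
      sample(rep(c("CSplus", "CSminus"), Tcs)) else csSeq
    X <- matrix(stats::rnorm(Ttot * R), Ttot, R)
    mIdx <- integer(Ttot)   # within-CS-type presentation index
    cnt <- c(CSplus = 0L, CSminus = 0L)
    for (t in seq_len(Ttot)) {
      cnt[ord[t]] <- cnt[ord[t]] + 1L
      mIdx[t] <- cnt[ord[t]]
      rho <- if (ord[t] == "CSplus")
        cfg$baselineRho + slopes[s] * (mIdx[t] - 1) / (Tcs - 1)
      else cfg$baselineRho
      C <- .plantedCorrelation(cfg$plantedEdges, rho)
      L <- tryCatch(chol(C), error = function(e)
        stop("correlation matrix not positive definite at trial ", t,
             " (subject ", ids[s], ", rho = ", signif(rho, 3), ")", call. = FALSE))
      X[t, nodes] <- drop(crossprod(L, stats::rnorm(k)))
    }
    tt <- data.frame(trial = seq_len(Ttot), cs_type = ord,
                     onset = (seq_len(Ttot) - 1) * cfg$trialSpacing,
                     duration = cfg$trialDuration,
                     stringsAsFactors = FALSE)
    colnames(X) <- regionLabels
    betaList[[s]] <- new("BetaSeries", subjectId = ids[s],
                         phase = "extinction_learning",
                         trialTable = tt, values = X)
  }

  ## the subject's true change proxy: realized planted-component mean
  ## connectivity change, computed on the planted subgraph with the same
  ## jackknife/block machinery the analysis uses (deterministic given the
  ## drawn betas, so RNG state is untouched)
  subPos <- {
    remap <- cbind(match(cfg$plantedEdges[, 1L], nodes),
                   match(cfg$plantedEdges[, 2L], nodes))
    edgeRowsToPos(remap, k)
  }
  proxy <- vapply(betaList, function(b) {
    sub <- new("BetaSeries", subjectId = subjectId(b), phase = phase(b),
               trialTable = trialTable(b),
               values = values(b)[, nodes, drop = FALSE])
    bfc <- blockAverage(jackknifeTrialFC(sub))
    mean(edgeVector(deltaFC(bfc$CSplus))[subPos])
  }, numeric(1))
  if (n == 0L) proxy <- numeric(0)

  recall <- matrix(stats::rnorm(n * R, 0, cfg$recallNoiseSD), n, R,
                   dimnames = list(ids, regionLabels))
  if (n > 0)
    recall[, cfg$recallRegion] <- recall[, cfg$recallRegion] +
      cfg$recallLink[group] * proxy

  recallEdgeFC <- matrix(numeric(0), 0L, 0L)
  if (cfg$includeRecallEdgeFC && n > 0) {
    nE <- R * (R - 1) / 2
    recallEdgeFC <- matrix(stats::rnorm(n * nE, 0, cfg$recallFCNoiseSD), n, nE,
                           dimnames = list(ids, sprintf("e%06d", seq_len(nE))))
    pos <- edgeRowsToPos(cfg$plantedEdges, R)
    recallEdgeFC[, pos] <- recallEdgeFC[, pos] + cfg$recallFCLink[group] * proxy
  }

  meas <- names(cfg$clinicalWeights)
  clin <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (mn in meas)
    clin[[mn]] <- cfg$clinicalMeans[[mn]] + cfg$clinicalWeights[[mn]] * proxy +
      stats::rnorm(n, 0, cfg$clinicalNoiseSD[[mn]])

  truth <- list(planted_edges = cfg$plantedEdges,
                true_slopes = cfg$slopeByGroup,
                subject_slopes = stats::setNames(slopes, ids),
                change_proxy = stats::setNames(proxy, ids),
                recall_region = cfg$recallRegion,
                recall_slopes = cfg$recallLink,
                recall_fc_slopes = cfg$recallFCLink,
                true_canonical_weights = list(
                  x = rep(1 / nrow(cfg$plantedEdges), nrow(cfg$plantedEdges)),
                  y = cfg$clinicalWeights))
  new("SyntheticCohort", betaSeries = betaList, recall = recall,
      recallEdgeFC = recallEdgeFC, clinical = clin, subjects = subjectsDf,
      truth = truth, config = unclass(cfg))
}

#' Simulate connectivity-change matrices directly at the edge level
#'
#' Benchmark generator for the inference stage: draws per-subject
#' connectivity-change edge vectors as unit-variance Gaussians, adding a
#' mean shift of \code{effectSize} (edgewise Cohen's d) on the planted
#' edges for the first group only. Bypasses the trial-level pipeline, so
#' null calibration and planted-recovery studies of the edgewise GLM / NBS
#' stage run at scale.
#'
#' @param n1,n2 subjects in the first and second group.
#' @param nRegions atlas size.
#' @param plantedEdges edge matrix receiving the group-1 mean shift
#'   (NULL for a global null).
#' @param effectSize edgewise Cohen's d of the group difference.
#' @param groups labels for the two groups.
#' @param seed RNG seed.
#' @return list with \code{delta} (subjects x edges matrix), \code{design}
#'   (data.frame: subject_id, group, age, sex) and \code{edgeIndex}.
#' @export
simulateDeltaMatrix <- function(n1, n2, nRegions, plantedEdges = NULL,
                                effectSize = 0.8, groups = c("HC", "AX"),
                                seed = 1L) {
  withSeed(seed, {
    n <- n1 + n2
    idx <- edgeIndexTable(nRegions)
    delta <- matrix(stats::rnorm(n * nrow(idx)), n, nrow(idx))
    if (!is.null(plantedEdges) && nrow(plantedEdges)) {
      pos <- edgeRowsToPos(plantedEdges, nRegions)
      delta[seq_len(n1), pos] <- delta[seq_len(n1), pos] + effectSize
    }
    design <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = rep(groups, c(n1, n2)),
      age = round(stats::runif(n, 18, 60), 1),
      sex = stats::rbinom(n, 1L, 0.5),
      stringsAsFactors = FALSE)
    rownames(delta) <- design$subject_id
    list(delta = delta, design = design, edgeIndex = idx)
  })
}
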