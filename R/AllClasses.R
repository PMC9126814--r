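#' @import methods
NULL

#' BetaSeries: per-trial amplitude estimates for one subject and phase
#'
#' Holds the trials x regions matrix of single-trial response amplitudes
#' (GLM betas, arbitrary units) for one subject in one task phase, together
#' with the trial table (presentation index, stimulus type, onset). This is
#' the substrate of all connectivity estimation.
#'
#' @slot subjectId subject identifier.
#' @slot phase one of \code{"conditioning"}, \code{"extinction_learning"},
#'   \code{"extinction_recall"}.
#' @slot trialTable data.frame with columns \code{trial}, \code{cs_type},
#'   \code{onset}; one row per matrix row, in presentation order.
#' @slot values trials x regions numeric matrix; column names are region labels.
#' @export
setClass("BetaSeries", representation(
  subjectId = "character",
  phase = "character",
  trialTable = "data.frame",
  values = "matrix"
))

setValidity("BetaSeries", function(object) {
  msg <- character()
  if (!object@phase %in% c("conditioning", "extinction_learning", "extinction_recall"))
    msg <- c(msg, "phase must be conditioning, extinction_learning or extinction_recall")
  if (!all(c("trial", "cs_type", "onset") %in% names(object@trialTable)))
    msg <- c(msg, "trialTable needs columns trial, cs_type, onset")
  if (nrow(object@trialTable) != nrow(object@values))
    msg <- c(msg, "trialTable rows must match beta matrix rows")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "beta values must be finite (no NaN/NA rows)")
  if (length(msg)) msg else TRUE
})

#' TrialFC: trial-resolved connectivity tensor
#'
#' One symmetric regions x regions matrix per trial, from the jackknife
#' (leave-one-trial-out) procedure. The diagonal is undefined and stored
#' as 0. For method \code{jackknife_zflip} every edge's trial series is
#' standardised to mean 0, SD 1 across trials.
#'
#' @slot subjectId subject identifier.
#' @slot phase task phase.
#' @slot method \code{"jackknife_zflip"} or \code{"jackknife_pseudovalue"}.
#' @slot tensor trials x regions x regions array, each slice symmetric.
#' @slot trialTable trial table carried from the input [BetaSeries-class].
#' @slot nFlagged count of zero-variance edge entries set to 0.
#' @export
setClass("TrialFC", representation(
  subjectId = "character",
  phase = "character",
  method = "character",
  tensor = "array",
  trialTable = "data.frame",
  nFlagged = "integer"
))

setValidity("TrialFC", function(object) {
  msg <- character()
  d <- dim(object@tensor)
  if (length(d) != 3L || d[2L] != d[3L])
    msg <- c(msg, "tensor must be trials x regions x regions")
  if (nrow(object@trialTable) != d[1L])
    msg <- c(msg, "trialTable rows must match tensor trials")
  if (!object@method %in% c("jackknife_zflip", "jackknife_pseudovalue"))
    msg <- c(msg, "unknown method")
  ## spot-check symmetry on a few slices (full check is O(T R^2))
  for (t in unique(c(1L, d[1L]))) {
    s <- object@tensor[t, , ]
    if (max(abs(s - t(s))) > 1e-8) { msg <- c(msg, "tensor slices must be symmetric"); break }
  }
  if (length(msg)) msg else TRUE
})

#' BlockFC: time-block-averaged connectivity for one stimulus type
#'
#' Trials of one CS type, in presentation order, are evenly divided into
#' contiguous time-blocks (default 4, early to late learning) and averaged.
#'
#' @slot subjectId subject identifier.
#' @slot csType \code{"CSplus"} or \code{"CSminus"}.
#' @slot blocks nBlocks x regions x regions array (block 1 earliest).
#' @slot nTrialsPerBlock trials averaged into each block (equal across blocks).
#' @export
setClass("BlockFC", representation(
  subjectId = "character",
  csType = "character",
  blocks = "array",
  nTrialsPerBlock = "integer"
))

setValidity("BlockFC", function(object) {
  msg <- character()
  d <- dim(object@blocks)
  if (length(d) != 3L || d[2L] != d[3L]) msg <- c(msg, "blocks must be nBlocks x R x R")
  s <- object@blocks[1L, , ]
  if (max(abs(s - t(s))) > 1e-8) msg <- c(msg, "each block must be symmetric")
  if (length(msg)) msg else TRUE
})

#' DeltaFC: early-to-late connectivity change as an edge vector
#'
#' The central quantity of the analysis: connectivity in the last time-block
#' minus the first, vectorised over the upper triangle (i < j, row-major).
#'
#' @slot subjectId subject identifier.
#' @slot csType \code{"CSplus"} or \code{"CSminus"}.
#' @slot edgeVector numeric vector of length R(R-1)/2.
#' @slot edgeIndex two-column (i, j) matrix, the [edgeIndexTable()] ordering.
#' @export
setClass("DeltaFC", representation(
  subjectId = "character",
  csType = "character",
  edgeVector = "numeric",
  edgeIndex = "matrix"
))

setValidity("DeltaFC", function(object) {
  if (length(object@edgeVector) != nrow(object@edgeIndex))
    return("edgeVector length must match edgeIndex rows")
  if (any(object@edgeIndex[, 1L] >= object@edgeIndex[, 2L]))
    return("edgeIndex must be strictly i < j")
  TRUE
})

#' EdgeStatMap: edgewise group statistics
#'
#' Per-edge t statistics and two-sided p-values from the covariate-adjusted
#' group (or continuous-predictor) model.
#'
#' @slot t numeric t statistic per edge.
#' @slot p two-sided p per edge.
#' @slot df residual degrees of freedom (n1+n2-2-#covariates for a
#'   two-group contrast).
#' @slot contrast character description, e.g. \code{"HC-AX"}.
#' @slot edgeIndex edge index table the statistics refer to.
#' @export
setClass("EdgeStatMap", representation(
  t = "numeric", p = "numeric", df = "integer",
  contrast = "character", edgeIndex = "matrix"
))

setValidity("EdgeStatMap", function(object) {
  msg <- character()
  if (length(object@t) != length(object@p)) msg <- c(msg, "t and p lengths differ")
  if (any(!is.finite(object@t))) msg <- c(msg, "t must be finite")
  if (any(object@p <= 0 | object@p > 1)) msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' NBSResult: Network-Based Statistic inference result
#'
#' Supra-threshold connected components with family-wise-error-corrected
#' p-values from a max-component-size permutation null.
#'
#' @slot components list of edge matrices (two columns i, j), one per
#'   supra-threshold connected component, ordered by decreasing size.
#' @slot componentStats data.frame with \code{size}, \code{intensity}
#'   (summed |t|) and \code{p_fwe} per component.
#' @slot nullMaxSizes permutation distribution of the maximum component
#'   statistic.
#' @slot thresholdP primary component-forming threshold.
#' @slot nPerm permutations performed (= permutation-space size when
#'   exhaustively enumerated).
#' @slot direction \code{"greater"}, \code{"less"} or \code{"two.sided"}.
#' @slot exhaustive TRUE when the permutation space was fully enumerated.
#' @slot edgeStats the [EdgeStatMap-class] the thresholding was based on.
#' @slot seed RNG seed used for sampling permutations (NA when exhaustive).
#' @export
setClass("NBSResult", representation(
  components = "list",
  componentStats = "data.frame",
  nullMaxSizes = "numeric",
  thresholdP = "numeric",
  nPerm = "integer",
  direction = "character",
  exhaustive = "logical",
  edgeStats = "EdgeStatMap",
  seed = "integer"
))

setValidity("NBSResult", function(object) {
  msg <- character()
  if (nrow(object@componentStats) != length(object@components))
    msg <- c(msg, "componentStats rows must match components")
  p <- object@componentStats$p_fwe
  if (length(p) && any(p <= 0 | p > 1)) msg <- c(msg, "p_fwe must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' CCAResult: canonical correlation between connectivity change and clinical measures
#'
#' First canonical pair between (rank-reduced) edge-level connectivity change
#' and clinical measures, with permutation significance, 5-fold
#' cross-validated out-of-sample correlation, and canonical loadings.
#'
#' @slot canonicalR first canonical correlation, in \[0, 1\].
#' @slot xScores,yScores per-subject canonical variates.
#' @slot xWeights,yWeights canonical weights (X weights in reduced space).
#' @slot xLoadings correlations of per-network connectivity-change summaries
#'   with the connectivity variate (filled by [canonicalLoadings()]).
#' @slot yLoadings correlations of each clinical measure with the clinical variate.
#' @slot permP permutation p for the canonical correlation (NA until computed).
#' @slot cvR pooled held-out correlation from cross-validation (NA until computed).
#' @slot cvPermP permutation p for cvR.
#' @slot nPerm permutations used.
#' @slot seed RNG seed.
#' @slot reductionRank principal-component rank the X side was reduced to.
#' @slot reduction internal fitted reduction (centering/scaling + rotation),
#'   kept so new subjects can be projected.
#' @export
setClass("CCAResult", representation(
  canonicalR = "numeric",
  xScores = "numeric", yScores = "numeric",
  xWeights = "numeric", yWeights = "numeric",
  xLoadings = "numeric", yLoadings = "numeric",
  permP = "numeric", cvR = "numeric", cvPermP = "numeric",
  nPerm = "integer", seed = "integer", reductionRank = "integer",
  reduction = "list"
))

setValidity("CCAResult", function(object) {
  msg <- character()
  if (object@canonicalR < -1e-8 || object@canonicalR > 1 + 1e-8)
    msg <- c(msg, "canonicalR must lie in [0, 1]")
  for (nm in c("permP", "cvPermP")) {
    v <- slot(object, nm)
    if (length(v) && !is.na(v) && (v <= 0 || v > 1)) msg <- c(msg, paste(nm, "must lie in (0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: generated test-bed cohort with ground truth
#'
#' Output of [generateCohort()]: per-subject learning-phase beta series,
#' recall-phase regional signals (and optionally recall edge FC), clinical
#' scores, subject covariates, and the planted ground truth.
#'
#' @slot betaSeries named list of [BetaSeries-class], one per subject.
#' @slot recall subjects x regions matrix of recall-phase activation
#'   contrasts (extinguished vs unextinguished cue).
#' @slot recallEdgeFC subjects x edges matrix of recall-phase FC contrasts
#'   (empty matrix unless requested).
#' @slot clinical data.frame of clinical scores (one row per subject).
#' @slot subjects data.frame with subject_id, group, age, sex.
#' @slot truth list with planted edges, per-group slopes, per-subject latent
#'   change proxies, recall slopes and clinical weights.
#' @slot config the [cohortConfig()] the cohort was generated from.
#' @export
setClass("SyntheticCohort", representation(
  betaSeries = "list",
  recall = "matrix",
  recallEdgeFC = "matrix",
  clinical = "data.frame",
  subjects = "data.frame",
  truth = "list",
  config = "list"
))

setValidity("SyntheticCohort", function(object) {
  n <- nrow(object@subjects)
  if (length(object@betaSeries) != n) return("one BetaSeries per subject required")
  if (n && nrow(object@recall) != n) return("recall rows must match subjects")
  TRUE
})
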