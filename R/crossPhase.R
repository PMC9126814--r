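#' @include groupNBS.R utils.R
NULL

#' Region-level cross-phase regression with max-statistic FWE
#'
#' Relates a per-subject scalar from extinction learning (the mean
#' connectivity change over an identified component) to recall-phase
#' regional signals: per region, OLS of the response on
#' \[intercept, predictor, age, sex\]. Family-wise error across regions is
#' controlled with a max-|t| permutation null: the predictor is
#' residualised against the covariates, the residuals are shuffled across
#' subjects and added back to the covariate fit, and the maximum |t| over
#' regions is recorded per permutation.
#'
#' @param predictor numeric per-subject scalar (constant predictors are an
#'   error).
#' @param response subjects x regions matrix of recall-phase values (e.g.
#'   activation contrast of the extinguished vs unextinguished cue).
#' @param design data.frame with covariate columns aligned to subjects.
#' @param covariates covariate column names (default age, sex; use
#'   \code{character(0)} for a plain correlation).
#' @param nPerm permutations for the max-statistic null (default 2000).
#' @param seed RNG seed.
#' @return data.frame per region: \code{slope}, \code{t}, \code{partial_r}
#'   (sign-carrying, from the predictor t), \code{p_raw} (two-sided),
#'   \code{p_fwe}.
#' @export
crossphaseRegression <- function(predictor, response, design = NULL,
                                 covariates = c("age", "sex"),
                                 nPerm = 2000L, seed = 1L) {
  response <- as.matrix(response)
  n <- nrow(response)
  if (n < 10L) stop("cross-phase regression requires at least 10 subjects")
  stopifnot(length(predictor) == n)
  if (stats::sd(predictor) == 0) stop("constant predictor")
  if (is.null(design)) design <- data.frame(row.names = seq_len(n))
  nuis <- .designNuisance(design, covariates)
  fit <- .edgeOLS(response, predictor, nuis)
  partialR <- fit$t / sqrt(fit$t^2 + fit$df)
  ## residualised-predictor permutation (covariate part held fixed)
  qrN <- qr(nuis)
  pHat <- qr.fitted(qrN, predictor)
  pRes <- qr.resid(qrN, predictor)
  prep <- .fwPrep(response, nuis)
  nullMax <- withSeed(seed, vapply(seq_len(nPerm), function(k) {
    max(abs(.fwT(prep, pHat + sample(pRes))))
  }, numeric(1)))
  pf <- vapply(abs(fit$t), function(tt) (1 + sum(nullMax >= tt)) / (1 + nPerm),
               numeric(1))
  data.frame(region = if (!is.null(colnames(response))) colnames(response) else
               sprintf("R%03d", seq_len(ncol(response))),
             slope = unname(fit$coef), t = unname(fit$t),
             partial_r = unname(partialR),
             p_raw = unname(fit$p), p_fwe = pf)
}

#' Cross-phase NBS with a continuous predictor
#'
#' The component-based analogue of [crossphaseRegression()]: per recall-phase
#' edge, the t statistic on the learning-phase predictor (with covariates)
#' is thresholded directionally, connected components are formed, and a
#' max-component permutation null is built by shuffling the predictor
#' across subjects. Positive and negative coupling are run as separate
#' directions.
#'
#' @param predictor per-subject scalar (mean component connectivity change).
#' @param edgeFC subjects x edges matrix of recall-phase FC.
#' @param design covariate data.frame.
#' @param thresholdP primary threshold on the directional p (default 0.001).
#' @param nPerm permutations (default 5000).
#' @param direction \code{"greater"} for positive coupling, \code{"less"}
#'   for negative, \code{"two.sided"}.
#' @param covariates covariate columns.
#' @param seed RNG seed.
#' @param edgeIdx edge index table; inferred from the edge count if omitted.
#' @return an [NBSResult-class].
#' @export
crossphaseNBS <- function(predictor, edgeFC, design = NULL,
                          thresholdP = 0.001, nPerm = 5000L,
                          direction = c("greater", "less", "two.sided"),
                          covariates = c("age", "sex"), seed = 1L,
                          edgeIdx = NULL) {
  direction <- match.arg(direction)
  edgeFC <- as.matrix(edgeFC)
  n <- nrow(edgeFC)
  stopifnot(length(predictor) == n)
  if (stats::sd(predictor) == 0) stop("constant predictor")
  if (is.null(design)) design <- data.frame(row.names = seq_len(n))
  if (is.null(edgeIdx)) {
    R <- (1 + sqrt(1 + 8 * ncol(edgeFC))) / 2
    if (abs(R - round(R)) > 1e-9)
      stop("cannot infer region count from ", ncol(edgeFC), " edges; pass edgeIdx")
    edgeIdx <- edgeIndexTable(round(R))
  }
  nuis <- .designNuisance(design, covariates)
  fit <- .edgeOLS(edgeFC, predictor, nuis)
  obsMap <- new("EdgeStatMap", t = unname(fit$t), p = unname(fit$p),
                df = fit$df, contrast = "continuous-predictor",
                edgeIndex = edgeIdx)
  pDir <- .directionalP(fit$t, fit$df, direction)
  obsComp <- .supraComponents(which(pDir < thresholdP), edgeIdx, weights = fit$t)
  tcrit <- .criticalT(thresholdP, fit$df, direction)
  prep <- .fwPrep(edgeFC, nuis)
  nullMax <- withSeed(seed, vapply(seq_len(nPerm), function(k) {
    tv <- .fwT(prep, sample(predictor))
    sup <- .supraFromT(tv, tcrit, direction)
    if (length(sup) == 0L) return(0)
    .supraComponents(sup, edgeIdx, weights = tv)$maxStat
  }, numeric(1)))
  pf <- vapply(obsComp$stats, function(s) (1 + sum(nullMax >= s)) / (1 + nPerm),
               numeric(1))
  compEdges <- lapply(obsComp$comps, function(pp) {
    m <- edgeIdx[pp, , drop = FALSE]; attr(m, "t") <- fit$t[pp]; m
  })
  stats <- data.frame(size = vapply(obsComp$comps, length, integer(1)),
                      intensity = vapply(obsComp$comps, function(pp) sum(abs(fit$t[pp])), numeric(1)),
                      p_fwe = pf)
  new("NBSResult", components = compEdges, componentStats = stats,
      nullMaxSizes = nullMax, thresholdP = thresholdP, nPerm = as.integer(nPerm),
      direction = direction, exhaustive = FALSE, edgeStats = obsMap,
      seed = as.integer(seed))
}

#' Compare two correlation coefficients
#'
#' Tests whether two Pearson correlations differ. For correlations from
#' disjoint groups (the usual case here: the same cross-phase correlation
#' estimated in two diagnostic groups) the independent-samples Fisher test
#' applies: \eqn{z = (\mathrm{atanh}\, r_1 - \mathrm{atanh}\, r_2) /
#' \sqrt{1/(n_1-3) + 1/(n_2-3)}}. For two correlations sharing a variable
#' within one sample, Steiger's Z for dependent overlapping correlations is
#' provided; it needs the inter-correlation \code{r12} of the two
#' non-shared variables and a common n.
#'
#' @param r1,n1 first correlation and its sample size.
#' @param r2,n2 second correlation and its sample size.
#' @param method \code{"independent_fisher"} (default) or
#'   \code{"dependent_steiger"}.
#' @param r12 inter-correlation of the non-shared variables (Steiger only).
#' @return list with \code{delta_r} (= r1 - r2), \code{z}, \code{p}
#'   (two-sided), \code{method}.
#' @export
#' @examples
#' compareCorrelations(0.48, 77, 0.05, 91)
compareCorrelations <- function(r1, n1, r2, n2,
                                method = c("independent_fisher", "dependent_steiger"),
                                r12 = NULL) {
  method <- match.arg(method)
  for (r in c(r1, r2)) if (abs(r) >= 1)
    stop("|r| = 1 gives infinite z; correlations must satisfy |r| < 1")
  if (min(n1, n2) < 4L) stop("need n >= 4")
  if (method == "independent_fisher") {
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (n1 != n2) stop("dependent (Steiger) comparison requires a common sample: n1 == n2")
    if (is.null(r12)) stop("dependent comparison needs r12, the correlation of the two non-shared variables")
    n <- n1
    rm2 <- ((r1 + r2) / 2)^2
    covTerm <- (r12 * (1 - 2 * rm2) - 0.5 * rm2 * (1 - 2 * rm2 - r12^2)) / (1 - rm2)^2
    z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - covTerm)))
  }
  list(delta_r = r1 - r2, z = z,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE), method = method)
}
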