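#' @include AllClasses.R utils.R
NULL

## Vectorised OLS of every column of Y on [nuisance, x]; returns t and
## two-sided p on the x coefficient. Columns of `nuisance` must include the
## intercept. Errors on collinearity, naming the offending columns.
.edgeOLS <- function(Y, x, nuisance) {
  D <- cbind(nuisance, x = x)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    piv <- qrD$pivot[seq_len(qrD$rank)]
    bad <- setdiff(colnames(D), colnames(D)[piv])
    stop("collinear design; offending column(s): ",
         paste(if (length(bad)) bad else "unknown", collapse = ", "))
  }
  k <- ncol(D)
  df <- nrow(D) - k
  coefs <- qr.coef(qrD, Y)
  res <- qr.resid(qrD, Y)
  s2 <- colSums(res^2) / df
  Rinv <- backsolve(qr.R(qrD), diag(k))
  xtxInv <- tcrossprod(Rinv)
  se <- sqrt(pmax(s2 * xtxInv[k, k], 0))
  tval <- coefs[k, ] / se
  tval[se == 0] <- 0
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  p[p == 0] <- .Machine$double.xmin
  list(t = tval, p = p, df = as.integer(df), coef = coefs[k, ])
}

.designNuisance <- function(design, covariates = c("age", "sex")) {
  covariates <- intersect(covariates, names(design))
  cov <- vapply(covariates, function(cv) as.numeric(design[[cv]]),
                numeric(nrow(design)))
  if (length(covariates) == 0L) cov <- matrix(0, nrow(design), 0L)
  if (is.null(dim(cov))) cov <- matrix(cov, nrow = nrow(design),
                                       dimnames = list(NULL, covariates))
  cbind(`(Intercept)` = rep(1, nrow(design)), cov)
}

#' Edgewise covariate-adjusted group comparison
#'
#' Per edge, ordinary least squares of the connectivity-change vector on
#' \[intercept, group indicator, age, sex\]; the t statistic and two-sided p
#' refer to the group coefficient, oriented as \code{contrast[1] - contrast[2]}.
#' Residual df is n1 + n2 - 2 - (number of covariates).
#'
#' @param delta subjects x edges matrix (e.g. from [deltaMatrix()]), or a
#'   list of [DeltaFC-class].
#' @param design data.frame with \code{subject_id}, \code{group}, and the
#'   covariate columns; rows must align with \code{delta}.
#' @param contrast character of length 2: the two group labels, direction
#'   \code{contrast[1] - contrast[2]}.
#' @param covariates covariate column names (default age and sex).
#' @param edgeIdx optional edge index table (inferred from a DeltaFC list).
#' @return an [EdgeStatMap-class].
#' @export
edgewiseGLM <- function(delta, design, contrast, covariates = c("age", "sex"),
                        edgeIdx = NULL) {
  if (is.list(delta) && !is.matrix(delta)) {
    edgeIdx <- edgeIndex(delta[[1L]])
    delta <- deltaMatrix(delta)
  }
  stopifnot(is.matrix(delta), nrow(delta) == nrow(design))
  if (anyNA(design[c("group", covariates)])) stop("missing covariates in design")
  keep <- design$group %in% contrast
  if (sum(design$group[keep] == contrast[1L]) < 2L ||
      sum(design$group[keep] == contrast[2L]) < 2L)
    stop("need at least 2 subjects per compared group")
  Y <- delta[keep, , drop = FALSE]
  des <- design[keep, , drop = FALSE]
  x <- as.numeric(des$group == contrast[1L])
  fit <- .edgeOLS(Y, x, .designNuisance(des, covariates))
  if (is.null(edgeIdx)) {
    R <- (1 + sqrt(1 + 8 * ncol(delta))) / 2
    edgeIdx <- if (abs(R - round(R)) < 1e-9) edgeIndexTable(round(R)) else
      cbind(i = seq_len(ncol(delta)), j = seq_len(ncol(delta)) + 1L)
  }
  new("EdgeStatMap", t = unname(fit$t), p = unname(fit$p), df = fit$df,
      contrast = paste(contrast, collapse = "-"), edgeIndex = edgeIdx)
}

## Frisch-Waugh fast path for permutation loops: residualise Y against the
## (fixed) nuisance block once, then each permuted x costs one crossprod
.fwPrep <- function(Y, nuisance) {
  qrN <- qr(nuisance)
  Yr <- qr.resid(qrN, Y)
  list(qrN = qrN, Yr = Yr, YrSS = colSums(Yr^2),
       df = nrow(Y) - ncol(nuisance) - 1L)
}

.fwT <- function(prep, x) {
  xr <- qr.resid(prep$qrN, x)
  sxx <- sum(xr^2)
  if (sxx <= 0) return(rep(0, ncol(prep$Yr)))
  b <- as.numeric(crossprod(prep$Yr, xr)) / sxx
  s2 <- pmax(prep$YrSS - b^2 * sxx, 0) / prep$df
  tv <- b * sqrt(sxx) / sqrt(s2)
  tv[s2 == 0] <- 0
  tv
}

## directional critical t for a primary threshold
.criticalT <- function(thresholdP, df, direction) {
  switch(direction,
    greater = stats::qt(thresholdP, df, lower.tail = FALSE),
    less = stats::qt(thresholdP, df, lower.tail = TRUE),
    two.sided = stats::qt(thresholdP / 2, df, lower.tail = FALSE))
}

.supraFromT <- function(tval, tcrit, direction) {
  switch(direction,
    greater = which(tval > tcrit),
    less = which(tval < tcrit),
    two.sided = which(abs(tval) > tcrit))
}

## directional edge p-values from t and df
.directionalP <- function(tval, df, direction) {
  switch(direction,
    greater = stats::pt(tval, df, lower.tail = FALSE),
    less = stats::pt(tval, df, lower.tail = TRUE),
    two.sided = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

## connected components of the supra-threshold edge graph; returns list of
## edge-position vectors (into the canonical edge ordering) sorted by the
## component statistic, plus the max statistic
.supraComponents <- function(pos, edgeIdx, weights = NULL,
                             stat = c("extent", "intensity")) {
  stat <- match.arg(stat)
  if (length(pos) == 0L)
    return(list(comps = list(), stats = numeric(0), maxStat = 0))
  e <- edgeIdx[pos, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(as.character(e[, 1L]),
                                         as.character(e[, 2L])),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  vnames <- igraph::V(g)$name
  edgeComp <- memb[match(as.character(e[, 1L]), vnames)]
  comps <- split(pos, edgeComp)
  st <- if (stat == "extent") lengths(comps) else
    vapply(comps, function(pp) sum(abs(weights[pp])), numeric(1))
  ord <- order(st, decreasing = TRUE)
  list(comps = unname(comps[ord]), stats = unname(as.numeric(st[ord])),
       maxStat = max(st))
}

## All distinct two-group label assignments (as logical membership of group 1)
.enumerateAssignments <- function(n, n1) {
  sets <- utils::combn(n, n1)
  lapply(seq_len(ncol(sets)), function(k) {
    x <- numeric(n); x[sets[, k]] <- 1; x
  })
}

#' Network-Based Statistic inference on connectivity change
#'
#' Builds the graph of edges whose directional p-value beats the primary
#' component-forming threshold, finds its connected components over regions,
#' and assigns each component a family-wise-error-corrected p-value from a
#' permutation null of the maximum component statistic: group labels are
#' exchanged across subjects (covariates stay attached to their subjects),
#' the edgewise GLM is refit, and the maximum supra-threshold component
#' statistic is recorded per permutation. When the label-assignment space
#' \code{choose(n, n1)} does not exceed \code{nPerm}, all assignments are
#' enumerated exactly (with a message) and
#' \code{p_fwe = #\{null >= observed\} / n_assignments}; otherwise
#' assignments are sampled and the add-one estimator
#' \code{(1 + #\{null >= observed\}) / (1 + nPerm)} is used.
#'
#' Defaults follow standard practice for this analysis: edge-level
#' p < 0.001 forms components, significance is read at p_fwe < 0.05.
#'
#' @param delta subjects x edges matrix or list of [DeltaFC-class].
#' @param design data.frame with \code{subject_id}, \code{group}, covariates.
#' @param contrast the two group labels, direction \code{contrast[1] - contrast[2]}.
#' @param thresholdP primary component-forming threshold (default 0.001).
#' @param nPerm permutations (default 5000).
#' @param direction \code{"greater"} (contrast\[1\] > contrast\[2\]),
#'   \code{"less"}, or \code{"two.sided"}.
#' @param componentStat \code{"extent"} (edge count, default) or
#'   \code{"intensity"} (summed |t|).
#' @param covariates covariate columns.
#' @param seed RNG seed for sampled permutations.
#' @param edgeIdx optional edge index table.
#' @return an [NBSResult-class]. With no supra-threshold edges the
#'   component list is empty (not an error); the null is still computed.
#' @export
nbs <- function(delta, design, contrast, thresholdP = 0.001, nPerm = 5000L,
                direction = c("greater", "less", "two.sided"),
                componentStat = c("extent", "intensity"),
                covariates = c("age", "sex"), seed = 1L, edgeIdx = NULL) {
  direction <- match.arg(direction)
  componentStat <- match.arg(componentStat)
  if (thresholdP <= 0 || thresholdP >= 1) stop("thresholdP must lie in (0, 1)")
  if (nPerm < 100L) stop("nPerm must be at least 100")
  if (is.list(delta) && !is.matrix(delta)) {
    edgeIdx <- edgeIndex(delta[[1L]])
    delta <- deltaMatrix(delta)
  }
  obs <- edgewiseGLM(delta, design, contrast, covariates, edgeIdx)
  edgeIdx <- edgeIndex(obs)
  keep <- design$group %in% contrast
  Y <- delta[keep, , drop = FALSE]
  des <- design[keep, , drop = FALSE]
  nuis <- .designNuisance(des, covariates)
  x <- as.numeric(des$group == contrast[1L])
  n <- length(x); n1 <- sum(x == 1)

  pDir <- .directionalP(obs@t, obs@df, direction)
  obsComp <- .supraComponents(which(pDir < thresholdP), edgeIdx,
                              weights = obs@t, stat = componentStat)

  nAssign <- choose(n, n1)
  exhaustive <- nAssign <= nPerm
  permX <- if (exhaustive) {
    message("permutation space (", nAssign, " assignments) <= nPerm: exact enumeration")
    .enumerateAssignments(n, n1)
  } else {
    withSeed(seed, lapply(seq_len(nPerm), function(k) sample(x)))
  }
  tcrit <- .criticalT(thresholdP, obs@df, direction)
  prep <- .fwPrep(Y, nuis)
  nullMax <- vapply(permX, function(xp) {
    tv <- .fwT(prep, xp)
    sup <- .supraFromT(tv, tcrit, direction)
    if (length(sup) == 0L) return(0)
    .supraComponents(sup, edgeIdx, weights = tv, stat = componentStat)$maxStat
  }, numeric(1))

  pf <- vapply(obsComp$stats, function(s)
    if (exhaustive) sum(nullMax >= s) / nAssign
    else (1 + sum(nullMax >= s)) / (1 + length(nullMax)), numeric(1))
  compEdges <- lapply(obsComp$comps, function(pp) {
    m <- edgeIdx[pp, , drop = FALSE]
    attr(m, "t") <- obs@t[pp]
    m
  })
  stats <- data.frame(size = vapply(obsComp$comps, length, integer(1)),
                      intensity = vapply(obsComp$comps, function(pp) sum(abs(obs@t[pp])), numeric(1)),
                      p_fwe = pf)
  new("NBSResult", components = compEdges, componentStats = stats,
      nullMaxSizes = nullMax, thresholdP = thresholdP,
      nPerm = as.integer(length(permX)), direction = direction,
      exhaustive = exhaustive, edgeStats = obs,
      seed = if (exhaustive) NA_integer_ else as.integer(seed))
}

#' Plain two-sample t-test on per-subject component summaries
#'
#' Pooled-variance two-sample t-test on a per-subject scalar (typically the
#' component-mean differential connectivity change), df = n1 + n2 - 2.
#' Used after a component has been identified to report the group effect in
#' conventional t units.
#'
#' @param x per-subject values.
#' @param design data.frame with a \code{group} column aligned to \code{x}.
#' @param contrast the two group labels; direction \code{contrast[1] - contrast[2]}.
#' @return list with \code{t}, \code{df}, \code{p} (two-sided).
#' @export
componentLevelTtest <- function(x, design, contrast) {
  g1 <- x[design$group == contrast[1L]]
  g2 <- x[design$group == contrast[2L]]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 3L || n2 < 3L) stop("need at least 3 subjects per group")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) / df
  tval <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}
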