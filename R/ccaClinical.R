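#' @include utils.R networkMaps.R
NULL

#' Simulate data with a known first canonical correlation
#'
#' Latent-variable construction with a closed-form ground truth. Two latent
#' scores u, v with correlation \eqn{\rho} drive all columns:
#' \eqn{X = a u' + E}, \eqn{Y = b v' + F} with unit-variance Gaussian noise.
#' For this model the population first canonical correlation is
#' \eqn{\rho \sqrt{\alpha_x \alpha_y}} with
#' \eqn{\alpha = \lVert a\rVert^2 / (1 + \lVert a\rVert^2)}
#' (Sherman-Morrison on \eqn{\Sigma_{xx} = a a' + I}). Loading norms are set
#' from \code{attenuation} (\eqn{\sqrt{\alpha_x \alpha_y}} squared, split
#' evenly) and \eqn{\rho} solved so the first canonical correlation equals
#' \code{canonicalR} exactly.
#'
#' @param n subjects.
#' @param pX,pY columns of X and Y.
#' @param canonicalR target population first canonical correlation.
#' @param attenuation per-side signal fraction \eqn{\alpha} in (0, 1\];
#'   must satisfy \code{canonicalR <= attenuation}.
#' @param seed RNG seed.
#' @return list with \code{x}, \code{y}, \code{trueR}, and the latent scores.
#' @export
simulateCanonicalData <- function(n, pX = 30L, pY = 4L, canonicalR = 0.6,
                                  attenuation = 0.9, seed = 1L) {
  if (canonicalR < 0 || canonicalR > 1) stop("canonicalR must lie in [0, 1]")
  if (attenuation <= 0 || attenuation > 1) stop("attenuation must lie in (0, 1]")
  rho <- canonicalR / attenuation
  if (rho > 1) stop("canonicalR/attenuation > 1: unreachable construction")
  normA2 <- attenuation / (1 - attenuation + 1e-12)
  withSeed(seed, {
    u <- stats::rnorm(n)
    v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
    a <- rep(sqrt(normA2 / pX), pX)
    b <- rep(sqrt(normA2 / pY), pY)
    x <- tcrossprod(u, a) + matrix(stats::rnorm(n * pX), n, pX)
    y <- tcrossprod(v, b) + matrix(stats::rnorm(n * pY), n, pY)
    colnames(x) <- sprintf("x%02d", seq_len(pX))
    colnames(y) <- sprintf("y%02d", seq_len(pY))
    list(x = x, y = y, trueR = canonicalR, latent = cbind(u = u, v = v))
  })
}

## deterministic sign for principal components: largest-|loading| element positive
.fixPCSigns <- function(rotation) {
  flip <- apply(rotation, 2L, function(cc) sign(cc[which.max(abs(cc))]))
  flip[flip == 0] <- 1
  sweep(rotation, 2L, flip, "*")
}

## default PC rank for the X side: standard remedy for edges >> subjects
.defaultRank <- function(n, p) max(1L, min(floor(n / 10), 30L, p, n - 1L))

#' First canonical pair between connectivity change and clinical measures
#'
#' Reduces the (typically wide) X side by principal components to
#' \code{reductionRank}, then computes the first canonical correlation with
#' the clinical matrix Y. Canonical signs are arbitrary; they are fixed
#' mechanically so the connectivity variate correlates non-negatively with
#' the first X principal component (whose own sign is fixed by making its
#' largest-magnitude loading positive), which keeps runs comparable.
#'
#' Rows with missing values are dropped listwise with a message. With a
#' single clinical measure the canonical correlation equals the multiple R
#' of regressing that measure on the reduced X.
#'
#' @param x subjects x features matrix (e.g. connectivity change of all
#'   edges of an identified component).
#' @param y subjects x measures matrix or data.frame (numeric columns).
#' @param reductionRank principal components retained on the X side;
#'   default \code{min(floor(n/10), 30, ncol(x), n-1)}, at least 1.
#' @param standardize scale columns to unit variance before analysis
#'   (default TRUE).
#' @return a [CCAResult-class] without permutation/CV fields.
#' @seealso [ccaPermutation()], [ccaCrossValidation()], [canonicalLoadings()]
#' @export
fitCCA <- function(x, y, reductionRank = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  ok <- stats::complete.cases(x) & stats::complete.cases(y)
  if (any(!ok)) message(sum(!ok), " subject(s) dropped listwise for missing values")
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  n <- nrow(x)
  if (n <= ncol(y)) stop("need more subjects than clinical measures")
  if (is.null(reductionRank)) reductionRank <- .defaultRank(n, ncol(x))
  if (reductionRank > min(n - 1L, ncol(x)))
    stop("reductionRank exceeds min(n-1, ncol(x))")
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  if (pc$sdev[reductionRank] < 1e-12)
    stop("rank deficiency after reduction: X has rank < ", reductionRank)
  rot <- .fixPCSigns(pc$rotation[, seq_len(reductionRank), drop = FALSE])
  xr <- scale(x, center = pc$center,
              scale = if (standardize) pc$scale else FALSE) %*% rot
  ysd <- apply(y, 2L, stats::sd)
  if (any(ysd == 0)) stop("constant clinical column(s): ",
                          paste(colnames(y)[ysd == 0], collapse = ", "))
  yc <- scale(y, center = TRUE, scale = standardize)
  cc <- stats::cancor(xr, yc)
  wx <- cc$xcoef[, 1L]
  wy <- cc$ycoef[, 1L]
  xScores <- drop(sweep(xr, 2L, cc$xcenter) %*% wx)
  yScores <- drop(sweep(yc, 2L, cc$ycenter) %*% wy)
  if (stats::cor(xScores, xr[, 1L]) < 0) { wx <- -wx; xScores <- -xScores
                                           wy <- -wy; yScores <- -yScores }
  yl <- drop(stats::cor(y, yScores))
  new("CCAResult", canonicalR = cc$cor[1L],
      xScores = xScores, yScores = yScores,
      xWeights = unname(wx), yWeights = unname(wy),
      xLoadings = numeric(0), yLoadings = stats::setNames(yl, colnames(y)),
      permP = NA_real_, cvR = NA_real_, cvPermP = NA_real_,
      nPerm = 0L, seed = NA_integer_, reductionRank = as.integer(reductionRank),
      reduction = list(center = pc$center,
                       scale = if (standardize) pc$scale else NULL,
                       rotation = rot, xcenter = cc$xcenter,
                       ycenter = cc$ycenter,
                       ycolCenter = attr(yc, "scaled:center"),
                       ycolScale = if (standardize) attr(yc, "scaled:scale") else NULL,
                       standardize = standardize, keptRows = which(ok)))
}

## largest canonical correlation from orthonormal bases (fast permutation path)
.orthoBasis <- function(m) qr.Q(qr(scale(m, center = TRUE, scale = FALSE)))

#' Permutation test for the first canonical correlation
#'
#' Shuffles subject rows of Y (the X side and its reduction are unchanged),
#' refits the first canonical correlation, and reports the add-one
#' permutation p-value \code{(1 + #\{null >= observed\}) / (1 + nPerm)}.
#'
#' @param x,y,reductionRank,standardize as in [fitCCA()].
#' @param nPerm permutations (default 10000).
#' @param seed RNG seed.
#' @return the fitted [CCAResult-class] with \code{permP}, \code{nPerm},
#'   \code{seed} filled in.
#' @export
ccaPermutation <- function(x, y, reductionRank = NULL, nPerm = 10000L,
                           seed = 1L, standardize = TRUE) {
  if (nPerm < 100L) stop("nPerm must be at least 100")
  fit <- fitCCA(x, y, reductionRank, standardize)
  keep <- fit@reduction$keptRows
  x <- as.matrix(x)[keep, , drop = FALSE]
  y <- as.matrix(y)[keep, , drop = FALSE]
  xr <- scale(x, center = fit@reduction$center,
              scale = if (fit@reduction$standardize) fit@reduction$scale else FALSE) %*%
    fit@reduction$rotation
  Qx <- .orthoBasis(xr)
  Qy <- .orthoBasis(y)
  n <- nrow(Qx)
  nullR <- withSeed(seed, vapply(seq_len(nPerm), function(k) {
    svd(crossprod(Qx, Qy[sample.int(n), , drop = FALSE]), nu = 0, nv = 0)$d[1L]
  }, numeric(1)))
  fit@permP <- (1 + sum(nullR >= fit@canonicalR - 1e-12)) / (1 + nPerm)
  fit@nPerm <- as.integer(nPerm)
  fit@seed <- as.integer(seed)
  fit
}

## project new rows onto a fitted canonical pair; returns score pairs
.projectCCA <- function(fit, xNew, yNew) {
  rd <- fit@reduction
  xr <- scale(xNew, center = rd$center,
              scale = if (rd$standardize) rd$scale else FALSE) %*% rd$rotation
  yc <- scale(yNew, center = rd$ycolCenter,
              scale = if (rd$standardize) rd$ycolScale else FALSE)
  cbind(x = drop(sweep(xr, 2L, rd$xcenter) %*% fit@xWeights),
        y = drop(sweep(yc, 2L, rd$ycenter) %*% fit@yWeights))
}

#' K-fold cross-validated canonical correlation
#'
#' Splits subjects into k folds; per fold, the reduction and canonical pair
#' are fit on the training fraction and the held-out subjects are projected
#' onto the trained variates. Held-out score pairs are pooled across folds
#' and their Pearson correlation is the out-of-sample canonical correlation
#' \code{cvR}. Its permutation p-value reruns the entire procedure with Y
#' rows shuffled.
#'
#' @param x,y,reductionRank,standardize as in [fitCCA()].
#' @param k folds (default 5).
#' @param nPerm permutations for the cv null (default 1000).
#' @param seed RNG seed (fold assignment and permutations).
#' @return list with \code{cvR}, \code{cvPermP}, \code{folds}, and the
#'   pooled held-out \code{scores}.
#' @export
ccaCrossValidation <- function(x, y, reductionRank = NULL, k = 5L,
                               nPerm = 1000L, seed = 1L, standardize = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(y) <- "double"
  ok <- stats::complete.cases(x) & stats::complete.cases(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  n <- nrow(x)
  if (is.null(reductionRank)) {
    nTrainMin <- n - ceiling(n / k)
    reductionRank <- .defaultRank(nTrainMin, ncol(x))
  }
  runCV <- function(yUse, folds) {
    pooled <- matrix(NA_real_, n, 2L)
    for (f in seq_len(k)) {
      test <- which(folds == f)
      train <- setdiff(seq_len(n), test)
      if (length(train) < ncol(yUse) + 2L)
        stop("fold ", f, " leaves too few training subjects")
      fit <- fitCCA(x[train, , drop = FALSE], yUse[train, , drop = FALSE],
                    reductionRank, standardize)
      pooled[test, ] <- .projectCCA(fit, x[test, , drop = FALSE],
                                    yUse[test, , drop = FALSE])
    }
    stats::cor(pooled[, 1L], pooled[, 2L])
  }
  withSeed(seed, {
    folds <- sample(rep(seq_len(k), length.out = n))
    cvR <- runCV(y, folds)
    nullCv <- vapply(seq_len(nPerm), function(p)
      runCV(y[sample.int(n), , drop = FALSE], folds), numeric(1))
    list(cvR = cvR,
         cvPermP = (1 + sum(nullCv >= cvR - 1e-12)) / (1 + nPerm),
         folds = folds, nPerm = nPerm)
  })
}

#' Canonical loadings per clinical measure and per canonical network
#'
#' Clinical loadings are the correlations of each clinical column with the
#' clinical variate. Connectivity loadings are computed at network level:
#' for each of the canonical networks, each subject's mean connectivity
#' change over component edges incident to that network is correlated with
#' the connectivity variate.
#'
#' @param fit a fitted [CCAResult-class].
#' @param x the subjects x edges matrix the fit used.
#' @param y the clinical matrix the fit used.
#' @param edges component edge matrix corresponding to the columns of
#'   \code{x} (same row order).
#' @param atlas atlas table.
#' @return list with \code{clinical} (named loadings), \code{network}
#'   (named loadings over networks with at least one incident edge), and
#'   \code{networkMeans} (subjects x networks matrix).
#' @export
canonicalLoadings <- function(fit, x, y, edges, atlas) {
  stopifnot(is(fit, "CCAResult"))
  x <- as.matrix(x); y <- as.matrix(y)
  keep <- fit@reduction$keptRows
  x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  edges <- normalizeEdges(edges)
  stopifnot(nrow(edges) == ncol(x))
  nets <- intersect(canonicalNetworks(), unique(atlas$network))
  nets <- c(nets, setdiff(unique(atlas$network), nets))
  nw <- matrix(atlas$network[match(as.vector(edges), atlas$region_id)], ncol = 2L)
  nm <- sapply(nets, function(net) {
    sel <- nw[, 1L] == net | nw[, 2L] == net
    if (!any(sel)) return(rep(NA_real_, nrow(x)))
    rowMeans(x[, sel, drop = FALSE])
  })
  present <- colSums(is.na(nm)) == 0
  netLoad <- rep(NA_real_, length(nets))
  names(netLoad) <- nets
  if (any(present))
    netLoad[present] <- drop(stats::cor(nm[, present, drop = FALSE], fit@xScores))
  list(clinical = stats::setNames(drop(stats::cor(y, fit@yScores)), colnames(y)),
       network = netLoad,
       networkMeans = nm)
}
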