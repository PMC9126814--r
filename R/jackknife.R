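#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Trial-resolved connectivity from leave-one-trial-out (jackknife) correlation
#'
#' For each edge (i, j) and trial t, the Pearson correlation of the two
#' regions' beta series is computed over all trials of the phase except t,
#' Fisher z-transformed, and sign-flipped: dropping a trial that carries
#' strong coupling lowers the remaining correlation, so the flipped
#' leave-one-out value is high exactly when that trial contributes strongly
#' to the edge's coupling. Two variants are provided:
#'
#' \describe{
#'   \item{\code{jackknife_zflip}}{the flipped leave-one-out series is
#'     standardised per edge to mean 0, SD 1 across trials (the default;
#'     units are relative within subject and edge).}
#'   \item{\code{jackknife_pseudovalue}}{classical jackknife pseudovalues
#'     \eqn{T z_{all} - (T-1) z_{(-t)}} on the Fisher scale, unstandardised
#'     (the flip is implicit in the \eqn{-(T-1)} term).}
#' }
#'
#' By default the leave-one-out pool is all trials of the phase (both CS
#' types pooled); matrices are subsequently reordered by CS type downstream.
#' With \code{pool = "per_cs"} the pool (and, for zflip, the
#' standardisation) is restricted to each trial's own CS type.
#'
#' Edges whose leave-one-out subsample has zero variance are set to 0 and
#' counted in the \code{nFlagged} slot rather than propagating NaN.
#'
#' @param beta a [BetaSeries-class] with at least 5 trials and no
#'   zero-variance region.
#' @param method jackknife variant, see above.
#' @param fisherTransform apply the Fisher z-transform to each leave-one-out
#'   correlation (default TRUE; variance stabilisation).
#' @param zCap cap on |z| for perfect correlations (default 6).
#' @param pool leave-one-out pool: \code{"all"} trials of the phase, or
#'   \code{"per_cs"}.
#' @return a [TrialFC-class] with a trials x regions x regions tensor,
#'   each slice symmetric, diagonal stored as 0.
#' @seealso [blockAverage()], [deltaFC()], [staticFC()]
#' @rdname jackknifeTrialFC
#' @export
#' @examples
#' cfg <- cohortConfig(nPerGroup = c(HC = 1), nRegions = 12, seed = 3)
#' b <- generateCohort(cfg)@betaSeries[[1]]
#' tfc <- jackknifeTrialFC(b)
#' dim(fcTensor(tfc))
setMethod("jackknifeTrialFC", "BetaSeries",
  function(beta, method = c("jackknife_zflip", "jackknife_pseudovalue"),
           fisherTransform = TRUE, zCap = 6, pool = c("all", "per_cs")) {
    method <- match.arg(method)
    pool <- match.arg(pool)
    X <- values(beta)
    Ttot <- nrow(X); R <- ncol(X)
    if (Ttot < 5L) stop("jackknife requires at least 5 trials, got ", Ttot)
    v <- apply(X, 2L, stats::var)
    if (any(v == 0))
      stop("zero-variance region(s) across trials: ",
           paste(which(v == 0), collapse = ", "))
    tensor <- array(0, c(Ttot, R, R))
    nFlagged <- 0L
    cs <- trialTable(beta)$cs_type
    poolSets <- if (pool == "all") list(seq_len(Ttot)) else
      split(seq_len(Ttot), cs)
    for (setTrials in poolSets) {
      Xs <- X[setTrials, , drop = FALSE]
      Tn <- nrow(Xs)
      if (Tn < 5L) stop("pool '", pool, "' leaves fewer than 5 trials")
      S1 <- colSums(Xs)
      S2 <- crossprod(Xs)
      Sd <- diag(S2)
      if (method == "jackknife_pseudovalue") {
        rAll <- .sumsToCor(Tn, S1, S2, Sd)
        zAll <- if (fisherTransform) fisherZ(rAll$r, zCap) else rAll$r
      }
      for (ti in seq_along(setTrials)) {
        x <- Xs[ti, ]
        n <- Tn - 1L
        s1 <- S1 - x
        s2 <- S2 - tcrossprod(x)
        sd2 <- n * (Sd - x^2) - s1^2
        loo <- .sumsToCorRaw(n, s1, s2, sd2)
        nFlagged <- nFlagged + loo$nBad
        z <- if (fisherTransform) fisherZ(loo$r, zCap) else loo$r
        slice <- if (method == "jackknife_zflip") -z else Tn * zAll - n * z
        diag(slice) <- 0
        tensor[setTrials[ti], , ] <- slice
      }
      if (method == "jackknife_zflip") {
        ## standardise each edge's series to mean 0, SD 1 over the pool;
        ## constant series (e.g. identical leave-one-out values) stay 0
        sub <- tensor[setTrials, , , drop = FALSE]
        mu <- colMeans(sub, dims = 1L)
        sdv <- sqrt(colMeans(sweep(sub, c(2L, 3L), mu)^2, dims = 1L) * Tn / (Tn - 1L))
        sdv[sdv == 0] <- Inf
        tensor[setTrials, , ] <- sweep(sweep(sub, c(2L, 3L), mu), c(2L, 3L), sdv, "/")
        for (t in setTrials) { s <- tensor[t, , ]; diag(s) <- 0; tensor[t, , ] <- s }
      }
    }
    new("TrialFC", subjectId = subjectId(beta), phase = phase(beta),
        method = method, tensor = tensor, trialTable = trialTable(beta),
        nFlagged = nFlagged)
  })

## correlation matrix from sufficient statistics over n observations
.sumsToCor <- function(n, S1, S2, Sd) {
  sd2 <- n * Sd - S1^2
  .sumsToCorRaw(n, S1, S2, sd2)
}

.sumsToCorRaw <- function(n, s1, s2, sd2) {
  sd2[sd2 < 0] <- 0  # guard tiny negative rounding
  num <- n * s2 - tcrossprod(s1)
  den <- sqrt(outer(sd2, sd2))
  r <- num / den
  bad <- !is.finite(r)
  diag(bad) <- FALSE
  nBad <- sum(bad) # symmetric double count kept: entries, not edges
  r[!is.finite(r)] <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  list(r = r, nBad = as.integer(nBad))
}

#' Static beta-series connectivity over all trials of one CS type
#'
#' A single regions x regions Pearson correlation matrix over all trials of
#' the requested CS type, Fisher z-transformed (capped at \code{zCap}).
#' The complement of the dynamic jackknife estimate: it ignores when in
#' learning the coupling occurred.
#'
#' @param beta a [BetaSeries-class].
#' @param csType which trials to use (\code{"CSplus"}, \code{"CSminus"},
#'   or \code{"all"}).
#' @param zCap cap on |z|.
#' @return symmetric matrix with diagonal 0; attribute \code{nFlagged}
#'   counts zero-variance entries set to 0.
#' @rdname staticFC
#' @export
setMethod("staticFC", "BetaSeries", function(beta, csType = "CSplus", zCap = 6) {
  tt <- trialTable(beta)
  keep <- if (identical(csType, "all")) seq_len(nrow(tt)) else which(tt$cs_type == csType)
  if (length(keep) < 5L)
    stop("static FC requires at least 5 trials of type ", csType)
  X <- values(beta)[keep, , drop = FALSE]
  n <- nrow(X)
  cr <- .sumsToCor(n, colSums(X), crossprod(X), colSums(X^2))
  z <- fisherZ(cr$r, zCap)
  diag(z) <- 0
  attr(z, "nFlagged") <- cr$nBad
  z
})
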