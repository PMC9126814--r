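#' @include AllClasses.R utils.R
NULL

#' Canonical double-gamma haemodynamic response function
#'
#' The standard double-gamma HRF (peak ~5 s, undershoot ~15 s, undershoot
#' ratio 1/6), sampled at \code{dt} seconds, unit peak.
#'
#' @param t time points in seconds.
#' @return HRF values at \code{t}.
#' @export
canonicalHrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

## convolve a stick/boxcar regressor with the HRF on a fine grid, sample at TR
.convolveEvents <- function(onsets, durations, nScans, tr, oversample = 16L) {
  dt <- tr / oversample
  nFine <- nScans * oversample
  u <- numeric(nFine)
  for (k in seq_along(onsets)) {
    a <- floor(onsets[k] / dt) + 1L
    b <- min(nFine, floor((onsets[k] + max(durations[k], dt)) / dt))
    if (a <= nFine) u[a:min(b, nFine)] <- 1
  }
  h <- canonicalHrf(seq(0, 32, by = dt))
  x <- stats::convolve(u, rev(h), type = "open")[seq_len(nFine)]
  x[seq(1L, nFine, by = oversample)]
}

.polyDrift <- function(nScans, order = 2L) {
  tt <- seq_len(nScans) / nScans
  out <- vapply(0:order, function(k) tt^k, numeric(nScans))
  colnames(out) <- paste0("drift", 0:order)
  out
}

.asBoldArray <- function(bold) {
  if (is.character(bold)) bold <- RNifti::readNifti(bold)
  bold <- unclass(as.array(bold))
  if (length(dim(bold)) != 4L) stop("BOLD input must be a 4-D image")
  bold
}

.asAtlasArray <- function(atlas) {
  if (is.character(atlas)) atlas <- RNifti::readNifti(atlas)
  atlas <- unclass(as.array(atlas))
  if (!length(dim(atlas)) %in% c(3L)) stop("atlas must be a 3-D label image")
  atlas
}

#' Simulate BOLD data from known trial amplitudes
#'
#' Forward model for validating the GLM path: each region's time series is
#' the sum over trials of amplitude x HRF-convolved event regressor, plus
#' AR(1) Gaussian noise; each voxel of a region carries the region signal.
#'
#' @param beta a [BetaSeries-class] supplying trial amplitudes and onsets.
#' @param tr repetition time in seconds.
#' @param nScans number of volumes (default: covers the last onset + 20 s).
#' @param atlasDim 3-D grid dimensions; regions are assigned voxels in
#'   blocks.
#' @param noiseSD innovation SD of the AR(1) noise (0 = noiseless).
#' @param arCoef AR(1) coefficient.
#' @param seed RNG seed.
#' @return list with \code{bold} (4-D array), \code{atlas} (3-D label
#'   array), \code{events} (onset/duration/trial_type data.frame),
#'   \code{tr}.
#' @export
simulateBoldFromBetas <- function(beta, tr = 2, nScans = NULL,
                                  atlasDim = c(6L, 6L, 3L),
                                  noiseSD = 0, arCoef = 0.3, seed = 1L) {
  tt <- trialTable(beta)
  X <- values(beta)
  R <- ncol(X)
  if (is.null(nScans)) nScans <- ceiling((max(tt$onset) + 20) / tr)
  nVox <- prod(atlasDim)
  if (nVox < R) stop("atlas grid too small for ", R, " regions")
  atlas <- array(0L, atlasDim)
  per <- nVox %/% R
  atlas[seq_len(per * R)] <- rep(seq_len(R), each = per)
  dur <- if ("duration" %in% names(tt)) tt$duration else rep(tr, nrow(tt))
  ts <- matrix(0, nScans, R)
  for (k in seq_len(nrow(tt))) {
    reg <- .convolveEvents(tt$onset[k], dur[k], nScans, tr)
    ts <- ts + outer(reg, X[k, ])
  }
  withSeed(seed, {
    if (noiseSD > 0) {
      for (r in seq_len(R)) {
        e <- as.numeric(stats::arima.sim(list(ar = arCoef), nScans, sd = noiseSD))
        ts[, r] <- ts[, r] + e
      }
    }
    bold <- array(0, c(atlasDim, nScans))
    flat <- matrix(bold, nVox, nScans)
    for (r in seq_len(R)) flat[which(atlas == r), ] <-
      matrix(ts[, r], nrow = sum(atlas == r), ncol = nScans, byrow = TRUE)
    bold <- array(flat, c(atlasDim, nScans))
    list(bold = bold, atlas = atlas,
         events = data.frame(onset = tt$onset, duration = dur,
                             trial_type = tt$cs_type),
         tr = tr)
  })
}

#' Estimate per-trial beta series from BOLD data (least-squares-separate)
#'
#' One amplitude per trial per region via the LSS scheme: for each trial, a
#' GLM with that trial's HRF-convolved regressor, one regressor pooling all
#' other trials of each condition, and polynomial drift terms; the region
#' value is the mean over the region's voxels of the trial coefficient.
#' Suited to event-related designs where trial regressors overlap.
#'
#' @param bold 4-D array, NIfTI image or path.
#' @param events data.frame with \code{onset}, \code{duration},
#'   \code{trial_type}; onsets must fall inside the scan.
#' @param atlas 3-D label array, NIfTI image or path; label r defines
#'   region r, 0 = background.
#' @param tr repetition time in seconds.
#' @param hrfModel only \code{"double_gamma"} is implemented.
#' @param driftOrder polynomial drift order (default 2).
#' @param subjectIdLabel subject id recorded on the output.
#' @param phaseLabel phase recorded on the output.
#' @return a [BetaSeries-class] (trials x regions).
#' @export
estimateBetaSeries <- function(bold, events, atlas, tr = 2,
                               hrfModel = c("double_gamma"),
                               driftOrder = 2L,
                               subjectIdLabel = "sub-001",
                               phaseLabel = "extinction_learning") {
  hrfModel <- match.arg(hrfModel)
  bold <- .asBoldArray(bold)
  atlas <- .asAtlasArray(atlas)
  if (!identical(dim(bold)[1:3], dim(atlas)))
    stop("atlas grid does not match the BOLD image grid")
  nScans <- dim(bold)[4L]
  scanDur <- nScans * tr
  if (any(events$onset < 0 | events$onset >= scanDur))
    stop("event onsets fall outside the scan (0 to ", scanDur, " s)")
  nT <- nrow(events)
  regions <- sort(setdiff(unique(as.integer(atlas)), 0L))
  R <- length(regions)
  nVox <- prod(dim(atlas))
  flat <- matrix(bold, nVox, nScans)
  regionTs <- t(vapply(regions, function(r)
    colMeans(flat[which(as.integer(atlas) == r), , drop = FALSE]),
    numeric(nScans)))           # R x nScans
  drift <- .polyDrift(nScans, driftOrder)
  trialReg <- vapply(seq_len(nT), function(k)
    .convolveEvents(events$onset[k], events$duration[k], nScans, tr),
    numeric(nScans))
  conds <- unique(events$trial_type)
  betas <- matrix(0, nT, R)
  for (k in seq_len(nT)) {
    others <- vapply(conds, function(cc) {
      sel <- setdiff(which(events$trial_type == cc), k)
      if (length(sel) == 0L) return(rep(0, nScans))
      rowSums(trialReg[, sel, drop = FALSE])
    }, numeric(nScans))
    keepCols <- c(TRUE, apply(others, 2L, function(v) any(v != 0)))
    D <- cbind(this = trialReg[, k], others)[, keepCols, drop = FALSE]
    D <- cbind(D, drift)
    qrD <- qr(D)
    if (qrD$rank < ncol(D))
      stop("rank-deficient LSS design at trial ", k)
    betas[k, ] <- qr.coef(qrD, t(regionTs))[1L, ]
  }
  tt <- data.frame(trial = seq_len(nT), cs_type = events$trial_type,
                   onset = events$onset, duration = events$duration,
                   stringsAsFactors = FALSE)
  colnames(betas) <- sprintf("R%03d", regions)
  new("BetaSeries", subjectId = subjectIdLabel, phase = phaseLabel,
      trialTable = tt, values = betas)
}
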