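# Independent brute-force oracles used across the suite. These deliberately
# recompute quantities with naive loops and base-R primitives, never via the
# package's own fast paths.

# naive leave-one-trial-out jackknife: loops + stats::cor per pair
bruteJackknife <- function(X, method = "jackknife_zflip", fisherTransform = TRUE,
                           zCap = 6) {
  Tn <- nrow(X); R <- ncol(X)
  z <- array(0, c(Tn, R, R))
  capz <- function(r) pmin(pmax(atanh(pmin(pmax(r, -1), 1)), -zCap), zCap)
  zAll <- matrix(0, R, R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    r <- stats::cor(X[, i], X[, j])
    zAll[i, j] <- zAll[j, i] <- if (fisherTransform) capz(r) else r
  }
  for (t in seq_len(Tn)) {
    for (i in seq_len(R - 1)) for (j in (i + 1):R) {
      r <- stats::cor(X[-t, i], X[-t, j])
      zz <- if (fisherTransform) capz(r) else r
      val <- if (method == "jackknife_zflip") -zz else Tn * zAll[i, j] - (Tn - 1) * zz
      z[t, i, j] <- z[t, j, i] <- val
    }
  }
  if (method == "jackknife_zflip") {
    for (i in seq_len(R - 1)) for (j in (i + 1):R) {
      s <- z[, i, j]
      sdv <- stats::sd(s)
      s <- if (sdv == 0) rep(0, Tn) else (s - mean(s)) / sdv
      z[, i, j] <- z[, j, i] <- s
    }
  }
  z
}

# simple BetaSeries builder with alternating CS labels
makeBeta <- function(X, csTypes = NULL, subject = "sub-001", spacing = 12) {
  Tn <- nrow(X)
  if (is.null(csTypes)) csTypes <- rep(c("CSplus", "CSminus"), length.out = Tn)
  if (is.null(colnames(X))) colnames(X) <- sprintf("R%03d", seq_len(ncol(X)))
  new("BetaSeries", subjectId = subject, phase = "extinction_learning",
      trialTable = data.frame(trial = seq_len(Tn), cs_type = csTypes,
                              onset = (seq_len(Tn) - 1) * spacing,
                              duration = 6, stringsAsFactors = FALSE),
      values = X)
}

# brute-force NBS: directional supra-threshold graph -> max component edge
# count, via adjacency flood fill (no igraph)
bruteMaxComponent <- function(tval, df, edgeIdx, thresholdP, direction = "greater") {
  p <- switch(direction,
              greater = stats::pt(tval, df, lower.tail = FALSE),
              less = stats::pt(tval, df, lower.tail = TRUE),
              two.sided = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  sup <- which(p < thresholdP)
  if (length(sup) == 0) return(0L)
  e <- edgeIdx[sup, , drop = FALSE]
  nodes <- unique(as.vector(e))
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(e))) {
      a <- as.character(e[r, 1]); b <- as.character(e[r, 2])
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab <- comp[as.character(e[, 1])]
  max(table(lab))
}

# per-edge covariate-adjusted two-group t via stats::lm (oracle for edgewiseGLM)
lmEdgeT <- function(y, group1, age, sex) {
  fit <- stats::lm(y ~ group1 + age + sex)
  summary(fit)$coefficients["group1", c("t value", "Pr(>|t|)")]
}
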