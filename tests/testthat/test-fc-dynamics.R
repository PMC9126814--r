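test_that("block averaging partitions trials contiguously and averages exactly", {
  set.seed(2)
  X <- matrix(rnorm(32 * 6), 32, 6)
  tfc <- jackknifeTrialFC(makeBeta(X))
  bfc <- blockAverage(tfc)
  expect_named(bfc, c("CSplus", "CSminus"), ignore.order = TRUE)
  expect_equal(dim(blocks(bfc$CSplus)), c(4L, 6L, 6L))
  expect_equal(bfc$CSplus@nTrialsPerBlock, 4L)
  ## brute-force recomputation of block means per edge
  tt <- trialTable(tfc)
  plusTrials <- which(tt$cs_type == "CSplus")
  tensor <- fcTensor(tfc)
  for (b in 1:4) {
    sel <- plusTrials[((b - 1) * 4 + 1):(b * 4)]
    want <- apply(tensor[sel, , ], c(2, 3), mean)
    expect_equal(blocks(bfc$CSplus)[b, , ], want, tolerance = 1e-12)
  }
})

test_that("non-divisible trial counts follow the stated remainder policy", {
  set.seed(4)
  X <- matrix(rnorm(22 * 5), 22, 5)
  cs <- c(rep("CSplus", 10), rep("CSminus", 12))
  tfc <- jackknifeTrialFC(makeBeta(X, cs))
  expect_error(blockAverage(tfc), "truncate_late")
  bfc <- blockAverage(tfc, remainder = "truncate_late")
  expect_equal(bfc$CSplus@nTrialsPerBlock, 2L)  # 10 -> 8 trials, 4 blocks
  expect_equal(bfc$CSminus@nTrialsPerBlock, 3L)
})

test_that("constant trial FC gives identical blocks and zero delta", {
  tensor <- array(0, c(16, 5, 5))
  m <- unvecUpper(rnorm(10), 5)
  for (t in 1:16) tensor[t, , ] <- m
  tfc <- new("TrialFC", subjectId = "s", phase = "extinction_learning",
             method = "jackknife_pseudovalue", tensor = tensor,
             trialTable = data.frame(trial = 1:16,
                                     cs_type = rep(c("CSplus", "CSminus"), 8),
                                     onset = 0:15 * 12),
             nFlagged = 0L)
  bfc <- blockAverage(tfc)
  expect_equal(blocks(bfc$CSplus)[1, , ], blocks(bfc$CSplus)[4, , ])
  expect_equal(edgeVector(deltaFC(bfc$CSplus)), rep(0, 10))
})

test_that("delta vectorisation follows the row-major upper-triangle convention", {
  idx <- edgeIndexTable(4)
  expect_equal(idx, cbind(i = c(1L, 1L, 1L, 2L, 2L, 3L),
                          j = c(2L, 3L, 4L, 3L, 4L, 4L)))
  expect_equal(nrow(edgeIndexTable(432)), 93096L)
  m <- matrix(0, 4, 4); m[cbind(idx[, 1], idx[, 2])] <- 1:6
  m <- m + t(m)
  expect_equal(vecUpper(m), as.numeric(1:6))
  expect_equal(unvecUpper(vecUpper(m), 4), m)
  ## positions computed arithmetically agree with table lookup
  pos <- dynfc:::edgeRowsToPos(idx, 4)
  expect_equal(pos, 1:6)
})

test_that("differential change equals the CS+ minus CS- identity", {
  set.seed(6)
  X <- matrix(rnorm(32 * 8), 32, 8)
  bfc <- blockAverage(jackknifeTrialFC(makeBeta(X)))
  dp <- deltaFC(bfc$CSplus); dm <- deltaFC(bfc$CSminus)
  dd <- differentialChange(dp, dm)
  expect_identical(edgeVector(dd), edgeVector(dp) - edgeVector(dm))
  expect_equal(csType(dd), "differential")
})

test_that("block-then-delta equals delta on trialwise means (linearity)", {
  set.seed(7)
  X <- matrix(rnorm(32 * 6), 32, 6)
  tfc <- jackknifeTrialFC(makeBeta(X))
  bfc <- blockAverage(tfc)
  d <- edgeVector(deltaFC(bfc$CSplus))
  tt <- trialTable(tfc)
  plusTrials <- which(tt$cs_type == "CSplus")
  tensor <- fcTensor(tfc)
  lastMean <- apply(tensor[plusTrials[13:16], , ], c(2, 3), mean)
  firstMean <- apply(tensor[plusTrials[1:4], , ], c(2, 3), mean)
  expect_equal(d, vecUpper(lastMean - firstMean), tolerance = 1e-12)
})

test_that("z-flip standardisation makes block means sum to zero per edge", {
  set.seed(8)
  X <- matrix(rnorm(32 * 6), 32, 6)
  bfc <- blockAverage(jackknifeTrialFC(makeBeta(X)))
  total <- blocks(bfc$CSplus) + blocks(bfc$CSminus)
  perEdge <- apply(total, c(2, 3), sum) / 8
  expect_lt(max(abs(perEdge)), 1e-8)
})

test_that("component mean series tracks planted learning dynamics", {
  set.seed(9)
  cfg <- cohortConfig(nPerGroup = c(HC = 25), nRegions = 14, seed = 31)
  coh <- generateCohort(cfg)
  planted <- truth(coh)$planted_edges
  seriesPlus <- matrix(0, 25, 4); seriesMinus <- matrix(0, 25, 4)
  for (s in 1:25) {
    bfc <- blockAverage(jackknifeTrialFC(coh@betaSeries[[s]]))
    seriesPlus[s, ] <- componentMeanSeries(bfc$CSplus, planted)
    seriesMinus[s, ] <- componentMeanSeries(bfc$CSminus, planted)
    if (s == 1) {
      one <- componentMeanSeries(bfc$CSplus, planted[1, , drop = FALSE])
      e <- planted[1, ]
      expect_equal(one, blocks(bfc$CSplus)[, e[1], e[2]])
      expect_error(componentMeanSeries(bfc$CSplus, matrix(0L, 0, 2)), "empty")
    }
  }
  mp <- colMeans(seriesPlus)
  expect_gt(stats::cor(mp, 1:4, method = "spearman"), 0)
  expect_gt(mp[4], mp[1])
  expect_lt(abs(mean(seriesMinus[, 4] - seriesMinus[, 1])),
            2 * stats::sd(seriesMinus[, 4] - seriesMinus[, 1]) / 5 + 0.05)
})
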