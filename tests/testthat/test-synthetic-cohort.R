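test_that("cohort generation is deterministic and has the designed shape", {
  cfg <- cohortConfig(nPerGroup = c(HC = 3, AX = 2), nRegions = 20, seed = 7)
  coh1 <- generateCohort(cfg)
  coh2 <- generateCohort(cfg)
  expect_identical(coh1@betaSeries, coh2@betaSeries)
  expect_identical(coh1@recall, coh2@recall)
  expect_identical(clinicalTable(coh1), clinicalTable(coh2))
  expect_identical(truth(coh1)$change_proxy, truth(coh2)$change_proxy)

  b <- coh1@betaSeries[[1]]
  expect_equal(dim(values(b)), c(32L, 20L))   # 16 CS+ interleaved with 16 CS-
  tt <- trialTable(b)
  expect_equal(as.vector(table(tt$cs_type)), c(16L, 16L))
  expect_equal(tt$cs_type[1:4], c("CSplus", "CSminus", "CSplus", "CSminus"))
  expect_equal(nrow(subjects(coh1)), 5L)
  expect_setequal(names(coh1@betaSeries), subjects(coh1)$subject_id)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(cohortConfig(nPerGroup = c(HC = 2), nTrialsPerCS = 10),
               "divisible by 4")
  expect_error(cohortConfig(nPerGroup = c(HC = 2), nRegions = 8), "beyond nRegions")
  expect_error(cohortConfig(nPerGroup = c(ZZ = 2)), "slopeByGroup")
  expect_error(cohortConfig(nPerGroup = c(HC = 2), baselineRho = 1.2), "baselineRho")
  ## a dense star with strong correlation on spokes only is not a valid
  ## correlation matrix: config must be rejected, not silently generated
  star <- cbind(1L, 2:7)
  expect_error(
    cohortConfig(nPerGroup = c(HC = 2), nRegions = 10, plantedEdges = star,
                 baselineRho = 0, slopeByGroup = c(HC = 0),
                 rhoRange = c(-0.1, 0.9)),
    "positive definite")
})

test_that("zero slopes leave planted-edge correlation flat across blocks", {
  cfg <- cohortConfig(nPerGroup = c(HC = 100, AX = 100), nRegions = 14,
                      slopeByGroup = c(HC = 0, AX = 0), slopeSD = 0, seed = 21)
  coh <- generateCohort(cfg)
  planted <- truth(coh)$planted_edges
  diffByCS <- function(cs) {
    sapply(coh@betaSeries, function(b) {
      tt <- trialTable(b)
      rows <- which(tt$cs_type == cs)
      early <- values(b)[rows[1:4], , drop = FALSE]
      late <- values(b)[rows[13:16], , drop = FALSE]
      mean(stats::cor(late)[planted]) - mean(stats::cor(early)[planted])
    })
  }
  d <- diffByCS("CSplus")
  expect_lt(abs(mean(d)), 2 * stats::sd(d) / sqrt(length(d)) + 0.02)
})

test_that("planted CS+ dynamics are monotone and CS-specific", {
  cfg <- cohortConfig(nPerGroup = c(HC = 40), nRegions = 14, seed = 3)
  coh <- generateCohort(cfg)
  planted <- truth(coh)$planted_edges
  sampleCorDiff <- function(cs) {
    sapply(coh@betaSeries, function(b) {
      tt <- trialTable(b)
      rows <- which(tt$cs_type == cs)
      mean(stats::cor(values(b)[rows[13:16], ])[planted]) -
        mean(stats::cor(values(b)[rows[1:4], ])[planted])
    })
  }
  dPlus <- sampleCorDiff("CSplus")
  expect_lt(stats::t.test(dPlus, alternative = "greater")$p.value, 0.01)
  dMinus <- sampleCorDiff("CSminus")
  expect_lt(abs(mean(dMinus)), 2 * stats::sd(dMinus) / sqrt(length(dMinus)))
})

test_that("the truth proxy equals the analysis-side planted-component change", {
  cfg <- cohortConfig(nPerGroup = c(HC = 4), nRegions = 16, seed = 13)
  coh <- generateCohort(cfg)
  pos <- dynfc:::edgeRowsToPos(truth(coh)$planted_edges, 16)
  measured <- vapply(coh@betaSeries, function(b) {
    bfc <- blockAverage(jackknifeTrialFC(b))
    mean(edgeVector(deltaFC(bfc$CSplus))[pos])
  }, numeric(1))
  expect_equal(unname(measured), unname(truth(coh)$change_proxy), tolerance = 1e-12)
})

test_that("simulateDeltaMatrix plants the requested edgewise effect", {
  planted <- plantedComponentEdges()
  sim <- simulateDeltaMatrix(200, 200, 30, planted, effectSize = 0.8, seed = 2)
  expect_equal(dim(sim$delta), c(400L, 435L))
  pos <- dynfc:::edgeRowsToPos(planted, 30)
  gap <- colMeans(sim$delta[1:200, pos]) - colMeans(sim$delta[201:400, pos])
  expect_lt(abs(mean(gap) - 0.8), 0.06)
  off <- setdiff(seq_len(435), pos)
  expect_lt(abs(mean(sim$delta[, off])), 0.02)
})

test_that("cohorts round-trip through the file tree losslessly", {
  cfg <- cohortConfig(nPerGroup = c(HC = 2, PTSD = 2), nRegions = 12, seed = 5,
                      includeRecallEdgeFC = TRUE)
  coh <- generateCohort(cfg)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  ev <- utils::read.delim(file.path(dir, "sub-001",
                                    "sub-001_task-extinction_events.tsv"))
  expect_true(all(ev$trial_type %in% c("CSplus", "CSminus")))
  expect_named(ev, c("onset", "duration", "trial_type"))
  back <- readCohort(dir)
  expect_equal(values(back@betaSeries[["sub-002"]]),
               values(coh@betaSeries[["sub-002"]]), tolerance = 0)
  expect_equal(back@recall, coh@recall, tolerance = 0)
  expect_equal(back@recallEdgeFC, coh@recallEdgeFC, tolerance = 0)
  expect_equal(truth(back)$planted_edges, truth(coh)$planted_edges)
  expect_equal(subjects(back), subjects(coh))
})

test_that("an empty cohort writes a valid header-only tree", {
  cfg <- cohortConfig(nPerGroup = c(HC = 0), nRegions = 12, seed = 1)
  coh <- generateCohort(cfg)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  back <- readCohort(dir)
  expect_equal(nrow(subjects(back)), 0L)
  expect_length(back@betaSeries, 0L)
})
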