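test_that("identical groups give exactly zero t on every edge", {
  set.seed(1)
  X <- matrix(rnorm(10 * 45), 10, 45)
  delta <- rbind(X, X)
  design <- data.frame(subject_id = sprintf("s%02d", 1:20),
                       group = rep(c("HC", "AX"), each = 10),
                       age = rep(runif(10, 20, 50), 2),
                       sex = rep(rbinom(10, 1, 0.5), 2))
  stat <- edgewiseGLM(delta, design, c("HC", "AX"))
  expect_true(all(abs(stat@t) < 1e-8))
  expect_equal(stat@df, 20L - 4L)
})

test_that("edgewise GLM matches the lm oracle edge by edge", {
  set.seed(2)
  sim <- simulateDeltaMatrix(10, 10, 8, plantedComponentEdges()[1:4, ] , 1, seed = 3)
  stat <- edgewiseGLM(sim$delta, sim$design, c("HC", "AX"))
  g1 <- as.numeric(sim$design$group == "HC")
  for (e in c(1, 5, 17, 28)) {
    want <- lmEdgeT(sim$delta[, e], g1, sim$design$age, sim$design$sex)
    expect_equal(stat@t[e], unname(want[1]), tolerance = 1e-10)
    expect_equal(stat@p[e], unname(want[2]), tolerance = 1e-10)
  }
})

test_that("edgewise p-values are calibrated under the global null", {
  set.seed(4)
  hits <- 0; total <- 0
  for (k in 1:10) {
    sim <- simulateDeltaMatrix(20, 20, 100, NULL, seed = 100 + k)
    stat <- edgewiseGLM(sim$delta, sim$design, c("HC", "AX"))
    hits <- hits + sum(stat@p < 0.05)
    total <- total + length(stat@p)
  }
  rate <- hits / total   # 49,500 edge tests
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), 3 * se + 0.003)
})

test_that("collinear designs are refused with the offending column named", {
  set.seed(5)
  sim <- simulateDeltaMatrix(6, 6, 6, NULL, seed = 1)
  sim$design$age <- 33
  expect_error(edgewiseGLM(sim$delta, sim$design, c("HC", "AX")), "collinear")
})

test_that("NBS returns empty components but a null when nothing is supra-threshold", {
  sim <- simulateDeltaMatrix(12, 12, 10, NULL, seed = 6)
  res <- nbs(sim$delta, sim$design, c("HC", "AX"), thresholdP = 1e-9,
             nPerm = 120, seed = 2)
  expect_length(components(res), 0L)
  expect_length(res@nullMaxSizes, 120L)
  expect_s4_class(res, "NBSResult")
})

test_that("3-vs-3 permutation p equals exhaustive enumeration over all 20 assignments", {
  set.seed(7)
  planted <- cbind(c(1L, 1L, 2L), c(2L, 3L, 3L))
  sim <- simulateDeltaMatrix(3, 3, 8, planted, effectSize = 6, seed = 8)
  expect_message(
    res <- nbs(sim$delta, sim$design, c("HC", "AX"), thresholdP = 0.01,
               nPerm = 5000, covariates = character(0)),
    "exact enumeration")
  expect_true(res@exhaustive)
  expect_equal(res@nPerm, 20L)
  ## independent oracle: enumerate all 20 assignments by hand
  idx <- sim$edgeIndex
  sets <- utils::combn(6, 3)
  nullMax <- apply(sets, 2, function(g1idx) {
    x <- numeric(6); x[g1idx] <- 1
    tval <- apply(sim$delta, 2, function(y) {
      f <- stats::lm(y ~ x)
      summary(f)$coefficients["x", "t value"]
    })
    bruteMaxComponent(tval, 4L, idx, 0.01, "greater")
  })
  st <- componentStats(res)
  for (k in seq_len(nrow(st)))
    expect_equal(st$p_fwe[k], sum(nullMax >= st$size[k]) / 20)
})

test_that("lowering the threshold never grows the supra-threshold graph", {
  sim <- simulateDeltaMatrix(15, 15, 20, plantedComponentEdges(), 0.9, seed = 9)
  stat <- edgewiseGLM(sim$delta, sim$design, c("HC", "AX"))
  pDir <- stats::pt(stat@t, stat@df, lower.tail = FALSE)
  counts <- vapply(c(0.05, 0.01, 0.001), function(th) sum(pDir < th), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("NBS is deterministic under a fixed permutation seed", {
  sim <- simulateDeltaMatrix(15, 15, 15, plantedComponentEdges(), 1.2, seed = 10)
  r1 <- nbs(sim$delta, sim$design, c("HC", "AX"), nPerm = 150, seed = 42)
  r2 <- nbs(sim$delta, sim$design, c("HC", "AX"), nPerm = 150, seed = 42)
  expect_identical(componentStats(r1), componentStats(r2))
  expect_identical(r1@nullMaxSizes, r2@nullMaxSizes)
})

test_that("component-level t-test matches the textbook formula and df conventions", {
  set.seed(11)
  x <- rnorm(168)
  design <- data.frame(group = rep(c("HC", "AX"), c(77, 91)))
  got <- componentLevelTtest(x, design, c("HC", "AX"))
  expect_equal(got$df, 166L)   # 77 + 91 - 2
  want <- stats::t.test(x[design$group == "HC"], x[design$group == "AX"],
                        var.equal = TRUE)
  expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$p, want$p.value, tolerance = 1e-12)

  design2 <- data.frame(group = rep(c("HC", "PTSD"), c(77, 81)))
  got2 <- componentLevelTtest(rnorm(158), design2, c("HC", "PTSD"))
  expect_equal(got2$df, 156L)  # 77 + 81 - 2

  same <- componentLevelTtest(rep(c(1, 2, 3), 4),
                              data.frame(group = rep(c("a", "b"), each = 6)),
                              c("a", "b"))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(componentLevelTtest(rnorm(4), data.frame(group = c("a", "a", "b", "b")),
                                   c("a", "b")), "at least 3")
})
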