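test_that("correlation comparison reproduces the Fisher formula exactly", {
  got <- compareCorrelations(0.48, 77, 0.05, 91)
  want <- (atanh(0.48) - atanh(0.05)) / sqrt(1 / (77 - 3) + 1 / (91 - 3))
  expect_identical(got$z, want)
  expect_equal(got$z, 2.9987, tolerance = 1e-4)  # frozen closed-form value
  expect_equal(got$delta_r, 0.43)
  expect_equal(got$p, 2 * pnorm(-abs(want)))

  eq <- compareCorrelations(0.3, 50, 0.3, 80)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  a <- compareCorrelations(0.5, 40, 0.2, 60)
  b <- compareCorrelations(0.2, 60, 0.5, 40)
  expect_equal(a$z, -b$z)

  expect_error(compareCorrelations(1, 40, 0.2, 60), "infinite z")
  expect_error(compareCorrelations(0.2, 3, 0.1, 50), "n >= 4")
})

test_that("the dependent (Steiger) variant behaves and guards its inputs", {
  s <- compareCorrelations(0.5, 60, 0.2, 60, method = "dependent_steiger", r12 = 0.3)
  expect_gt(s$z, 0)
  s2 <- compareCorrelations(0.2, 60, 0.5, 60, method = "dependent_steiger", r12 = 0.3)
  expect_equal(s$z, -s2$z)
  expect_equal(compareCorrelations(0.4, 60, 0.4, 60,
                                   method = "dependent_steiger", r12 = 0.5)$z, 0)
  expect_error(compareCorrelations(0.5, 60, 0.2, 50,
                                   method = "dependent_steiger", r12 = 0.3),
               "common sample")
  expect_error(compareCorrelations(0.5, 60, 0.2, 60, method = "dependent_steiger"),
               "r12")
})

test_that("independent-samples comparison is calibrated under equal population r", {
  set.seed(12)
  nSim <- 2000
  rej <- 0
  for (k in seq_len(nSim)) {
    x1 <- rnorm(40); y1 <- 0.5 * x1 + rnorm(40, sd = sqrt(0.75))
    x2 <- rnorm(60); y2 <- 0.5 * x2 + rnorm(60, sd = sqrt(0.75))
    out <- compareCorrelations(cor(x1, y1), 40, cor(x2, y2), 60)
    if (out$p < 0.05) rej <- rej + 1
  }
  ci <- stats::binom.test(rej, nSim)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2] + 0.015)
})

test_that("cross-phase regression recovers exact linear responses", {
  set.seed(1)
  n <- 40
  pred <- rnorm(n)
  resp <- cbind(outer(pred, c(2, -1)), matrix(rnorm(n * 3), n, 3))
  des <- data.frame(age = runif(n, 20, 50), sex = rbinom(n, 1, 0.5))
  out <- crossphaseRegression(pred, resp, des, nPerm = 300, seed = 2)
  expect_equal(out$partial_r[1], 1, tolerance = 1e-6)
  expect_equal(out$partial_r[2], -1, tolerance = 1e-6)
  expect_equal(out$p_fwe[1], 1 / 301)
  expect_gt(min(out$p_fwe[3:5]), 0.1)
  expect_equal(out$slope[1], 2, tolerance = 1e-8)
  expect_error(crossphaseRegression(rep(1, n), resp, des), "constant predictor")
})

test_that("with no covariates the partial r equals the plain Pearson r", {
  set.seed(3)
  n <- 30
  pred <- rnorm(n)
  resp <- matrix(rnorm(n * 4), n, 4)
  out <- crossphaseRegression(pred, resp, covariates = character(0),
                              nPerm = 200, seed = 1)
  want <- as.numeric(stats::cor(resp, pred))
  expect_equal(out$partial_r, want, tolerance = 1e-10)
})

test_that("cross-phase NBS finds planted positive and negative coupling", {
  set.seed(4)
  n <- 60; R <- 20
  planted <- plantedComponentEdges()
  pos <- dynfc:::edgeRowsToPos(planted, R)
  pred <- rnorm(n)
  fc <- matrix(rnorm(n * R * (R - 1) / 2, sd = 0.5), n)
  fc[, pos] <- fc[, pos] + pred          # positive coupling on planted edges
  des <- data.frame(age = runif(n, 20, 50), sex = rbinom(n, 1, 0.5))
  up <- crossphaseNBS(pred, fc, des, nPerm = 300, seed = 5)
  expect_gt(nrow(componentStats(up)), 0)
  expect_lt(componentStats(up)$p_fwe[1], 0.05)
  got <- components(up)[[1]]
  sens <- nrow(componentIntersection(got, planted)) / nrow(planted)
  expect_gte(sens, 0.8)
  down <- crossphaseNBS(pred, fc, des, direction = "less", nPerm = 300, seed = 5)
  if (nrow(componentStats(down)))
    expect_gt(componentStats(down)$p_fwe[1], 0.05)
  ## negative coupling shows up in the "less" direction
  fcNeg <- fc; fcNeg[, pos] <- fcNeg[, pos] - 2 * pred
  dn <- crossphaseNBS(pred, fcNeg, des, direction = "less", nPerm = 300, seed = 6)
  expect_gt(nrow(componentStats(dn)), 0)
  expect_lt(componentStats(dn)$p_fwe[1], 0.05)
})
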