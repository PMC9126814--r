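test_that("jackknife matches the brute-force leave-one-out oracle", {
  set.seed(42)
  for (k in 1:6) {
    R <- sample(3:8, 1); Tn <- sample(6:16, 1)
    X <- matrix(rnorm(Tn * R), Tn, R)
    b <- makeBeta(X)
    for (m in c("jackknife_zflip", "jackknife_pseudovalue")) {
      got <- fcTensor(jackknifeTrialFC(b, method = m))
      want <- bruteJackknife(X, method = m)
      expect_lt(max(abs(got - want)), 1e-10)
    }
  }
})

test_that("tensor slices are symmetric with zero diagonal at scale", {
  set.seed(1)
  X <- matrix(rnorm(32 * 25), 32, 25)
  tfc <- jackknifeTrialFC(makeBeta(X))
  expect_equal(dim(fcTensor(tfc)), c(32L, 25L, 25L))
  s <- fcTensor(tfc)[7, , ]
  expect_equal(s, t(s))
  expect_true(all(diag(s) == 0))
  ## standardisation: each edge's trial series has mean 0, sd 1
  series <- fcTensor(tfc)[, 3, 11]
  expect_equal(mean(series), 0, tolerance = 1e-12)
  expect_equal(stats::sd(series), 1, tolerance = 1e-12)
})

test_that("constant leave-one-out series standardise to zero", {
  ## a duplicated region gives LOO correlation exactly 1 for every t,
  ## capped on the Fisher scale; the z-flip series is then constant -> 0
  set.seed(3)
  X <- matrix(rnorm(12 * 4), 12, 4)
  X[, 2] <- 2 * X[, 1]
  tfc <- jackknifeTrialFC(makeBeta(X))
  expect_true(all(fcTensor(tfc)[, 1, 2] == 0))
  ## other edges unaffected
  expect_gt(stats::sd(fcTensor(tfc)[, 3, 4]), 0)
})

test_that("the sole trial driving an edge gets the maximum jackknife value", {
  set.seed(8)
  X <- matrix(rnorm(12 * 3, sd = 0.5), 12, 3)
  X[5, 1] <- 8; X[5, 2] <- 8   # trial 5 alone creates the coupling
  tfc <- jackknifeTrialFC(makeBeta(X))
  series <- fcTensor(tfc)[, 1, 2]
  expect_equal(which.max(series), 5L)
})

test_that("trial order permutation permutes tensor slices identically", {
  set.seed(11)
  X <- matrix(rnorm(16 * 6), 16, 6)
  cs <- rep(c("CSplus", "CSminus"), 8)
  perm <- sample(16)
  t1 <- fcTensor(jackknifeTrialFC(makeBeta(X, cs)))
  t2 <- fcTensor(jackknifeTrialFC(makeBeta(X[perm, ], cs[perm])))
  expect_equal(t2, t1[perm, , ], tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(4 * 3), 4, 3)
  expect_error(jackknifeTrialFC(makeBeta(X)), "at least 5 trials")
  X2 <- matrix(rnorm(8 * 3), 8, 3); X2[, 2] <- 1
  expect_error(jackknifeTrialFC(makeBeta(X2)), "zero-variance region")
})

test_that("static FC equals the plain correlation oracle per CS type", {
  set.seed(5)
  X <- matrix(rnorm(24 * 5), 24, 5)
  cs <- rep(c("CSplus", "CSminus"), 12)
  b <- makeBeta(X, cs)
  z <- staticFC(b, "CSplus")
  want <- atanh(stats::cor(X[cs == "CSplus", ]))
  diag(want) <- 0
  expect_equal(unname(z[1:5, 1:5]), want, tolerance = 1e-12, ignore_attr = TRUE)
  ## duplicated region: perfect correlation capped at the configured z
  X[, 2] <- X[, 1]
  z2 <- staticFC(makeBeta(X, cs), "CSplus")
  expect_equal(z2[1, 2], 6)
  expect_error(staticFC(makeBeta(X[1:8, ], cs[1:8]), "CSplus"), "at least 5 trials")
})

test_that("LSS GLM recovers known trial amplitudes from simulated BOLD", {
  set.seed(9)
  amp <- matrix(rnorm(12 * 4, mean = 2), 12, 4)
  beta <- makeBeta(amp, spacing = 36)   # events separated beyond the HRF span
  sim <- simulateBoldFromBetas(beta, tr = 2, noiseSD = 0)
  est <- estimateBetaSeries(sim$bold, sim$events, sim$atlas, tr = sim$tr)
  expect_equal(dim(values(est)), dim(amp))
  for (r in 1:4) expect_gt(stats::cor(values(est)[, r], amp[, r]), 0.99)
  ## zero signal in, zero betas out
  zero <- estimateBetaSeries(array(0, dim(sim$bold)), sim$events, sim$atlas,
                             tr = sim$tr)
  expect_equal(max(abs(values(zero))), 0)
  ## onsets outside the scan are refused
  ev <- sim$events; ev$onset[1] <- 1e5
  expect_error(estimateBetaSeries(sim$bold, ev, sim$atlas, tr = sim$tr),
               "outside the scan")
})

test_that("beta estimation survives AR(1) noise with high fidelity", {
  set.seed(10)
  amp <- matrix(rnorm(10 * 3, mean = 3, sd = 1.5), 10, 3)
  beta <- makeBeta(amp, spacing = 20)
  sim <- simulateBoldFromBetas(beta, tr = 2, noiseSD = 0.2, arCoef = 0.3, seed = 4)
  est <- estimateBetaSeries(sim$bold, sim$events, sim$atlas, tr = sim$tr)
  for (r in 1:3) expect_gt(stats::cor(values(est)[, r], amp[, r]), 0.9)
})
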