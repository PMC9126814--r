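test_that("a noise-free shared column gives canonical correlation 1", {
  set.seed(1)
  x <- matrix(rnorm(50 * 6), 50, 6)
  y <- cbind(x[, 3], rnorm(50))
  colnames(y) <- c("shared", "noise")
  fit <- fitCCA(x, y, reductionRank = 6)
  expect_equal(canonicalR(fit), 1, tolerance = 1e-6)
})

test_that("the latent-mode construction is recovered at large n", {
  sim <- simulateCanonicalData(10000, pX = 8, pY = 4, canonicalR = 0.6, seed = 2)
  fit <- fitCCA(sim$x, sim$y, reductionRank = 8)
  expect_equal(canonicalR(fit), 0.6, tolerance = 0.02)
})

test_that("single-measure CCA reduces to the multiple R of a regression", {
  set.seed(3)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y <- matrix(x %*% rnorm(5) + rnorm(60), ncol = 1,
              dimnames = list(NULL, "CAPS_5"))
  fit <- fitCCA(x, y, reductionRank = 5)
  mr <- sqrt(summary(stats::lm(y ~ x))$r.squared)
  expect_equal(canonicalR(fit), mr, tolerance = 1e-8)
  expect_equal(abs(unname(fit@yLoadings)), 1, tolerance = 1e-8)
})

test_that("canonical correlation is scale invariant and dominates univariate r", {
  set.seed(4)
  for (k in 1:5) {
    x <- matrix(rnorm(40 * 4), 40, 4)
    y <- matrix(rnorm(40 * 3), 40, 3)
    y[, 1] <- y[, 1] + 0.5 * x[, 2]
    f1 <- fitCCA(x, y, reductionRank = 4)
    xs <- x; xs[, 2] <- 1000 * xs[, 2]
    ys <- y; ys[, 3] <- 0.001 * ys[, 3]
    f2 <- fitCCA(xs, ys, reductionRank = 4)
    expect_equal(canonicalR(f1), canonicalR(f2), tolerance = 1e-8)
    expect_gte(canonicalR(f1) + 1e-10, max(abs(stats::cor(x, y))))
  }
})

test_that("permutation p honours its floor and reproduces under a seed", {
  set.seed(5)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- cbind(a = x[, 1], b = rnorm(40))
  fit <- ccaPermutation(x, y, reductionRank = 3, nPerm = 199, seed = 9)
  expect_equal(fit@permP, 1 / 200)   # perfect dependence -> floor
  f2 <- ccaPermutation(x, y, reductionRank = 3, nPerm = 199, seed = 9)
  expect_identical(fit@permP, f2@permP)
  xi <- matrix(rnorm(40 * 3), 40, 3)
  yi <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b")))
  fi <- ccaPermutation(xi, yi, reductionRank = 3, nPerm = 199, seed = 1)
  expect_gt(fi@permP, 0.005)
})

test_that("cross-validation pools held-out scores deterministically", {
  sim <- simulateCanonicalData(150, pX = 20, pY = 4, canonicalR = 0.6, seed = 6)
  cv1 <- ccaCrossValidation(sim$x, sim$y, k = 5, nPerm = 100, seed = 3)
  cv2 <- ccaCrossValidation(sim$x, sim$y, k = 5, nPerm = 100, seed = 3)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$cvR, cv2$cvR)
  expect_gt(cv1$cvR, 0.2)
  expect_lt(cv1$cvPermP, 0.05)
  ## independent data: held-out correlation near zero
  set.seed(8)
  xi <- matrix(rnorm(100 * 10), 100, 10)
  yi <- matrix(rnorm(100 * 4), 100, 4)
  cvn <- ccaCrossValidation(xi, yi, k = 5, nPerm = 100, seed = 2)
  expect_lt(abs(cvn$cvR), 0.35)
  expect_error(ccaCrossValidation(xi[1:7, ], yi[1:7, ], k = 5, nPerm = 100),
               "too few training subjects")
})

test_that("network loadings localise a single-network signal", {
  set.seed(9)
  atlas <- syntheticAtlas(40)
  edges <- rbind(t(utils::combn(which(atlas$network == "Cont")[1:4], 2)),
                 t(utils::combn(which(atlas$network == "Vis")[1:4], 2)))
  n <- 80
  latent <- rnorm(n)
  x <- matrix(rnorm(n * nrow(edges), sd = 0.4), n, nrow(edges))
  contRows <- seq_len(6)            # first six edges are within Cont
  x[, contRows] <- x[, contRows] + latent
  y <- cbind(ASI = 2 * latent + rnorm(n, sd = 0.5), BAI = rnorm(n))
  fit <- fitCCA(x, y, reductionRank = 5)
  loads <- canonicalLoadings(fit, x, y, edges, atlas)
  present <- loads$network[!is.na(loads$network)]
  expect_equal(names(which.max(abs(present))), "Cont")
  expect_equal(length(loads$clinical), 2L)
  ## loading of the driven measure is near +-1
  expect_gt(abs(loads$clinical["ASI"]), 0.9)
})

test_that("missing clinical rows are dropped listwise with a message", {
  set.seed(10)
  x <- matrix(rnorm(30 * 4), 30, 4)
  y <- cbind(a = rnorm(30), b = rnorm(30))
  y[3, 1] <- NA
  expect_message(fit <- fitCCA(x, y, reductionRank = 3), "dropped listwise")
  expect_length(fit@xScores, 29L)
})
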