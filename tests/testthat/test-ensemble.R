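kkt_holds <- function(A, b, x, tol = 1e-8) {
  g <- as.vector(crossprod(A, b - A %*% x))
  scale <- max(sqrt(colSums(A^2))) * sqrt(sum(b^2)) + 1
  active <- x > 0
  all(abs(g[active]) <= tol * scale) && all(g[!active] <= tol * scale)
}

test_that("NNLS closed forms: exact membership and identity design", {
  q <- seq(0.01, 0.3, length.out = 40)
  A <- cbind(exp(-q * 5), exp(-q * 20), q^2)
  b <- A[, 2]
  ex <- new("ScatteringCurve", q = q, intensity = b)
  fit <- nnlsSelect(A, ex)
  expect_identical(modelNumbers(fit), 2L)
  expect_equal(percents(fit), 100)
  expect_lt(sum((intensities(reconstructed(fit)) - b)^2), 1e-20)

  fit2 <- nnlsSelect(diag(2), new("ScatteringCurve", q = c(1, 2),
                                  intensity = c(2, 3)))
  expect_equal(fitWeights(fit2), c(2, 3))
  expect_equal(percents(fit2), c(40, 60))
})

test_that("noiseless mixtures are recovered exactly and zero columns stay zero", {
  q <- seq(0.01, 0.5, length.out = 60)
  A <- cbind(exp(-(q * 18)^2 / 3), exp(-(q * 30)^2 / 3),
             exp(-(q * 45)^2 / 3))
  b <- 0.6 * A[, 1] + 0.4 * A[, 2]
  fit <- nnlsSelect(A, new("ScatteringCurve", q = q, intensity = b))
  p <- setNames(rep(0, 3), 1:3)
  p[as.character(modelNumbers(fit))] <- percents(fit)
  expect_equal(unname(p), c(60, 40, 0), tolerance = 1e-6)
})

test_that("active-set solution equals exhaustive subset enumeration with a negative unconstrained optimum", {
  set.seed(8)
  for (case in 1:25) {
    n <- sample(5:12, 1)
    A <- matrix(rnorm(n * 3), n, 3)
    b <- rnorm(n)
    sol <- nnls(A, b)
    oracle <- enumerate_nnls(A, b)
    expect_equal(sol$deviance, oracle$dev, tolerance = 1e-8)
    expect_equal(sol$x, oracle$x, tolerance = 1e-6)
    expect_true(kkt_holds(A, b, sol$x))
  }
  # a case engineered to have a negative unconstrained coefficient
  A <- cbind(c(1, 0, 0.5), c(0, 1, 0.5), c(0.6, 0.6, 0.7))
  b <- c(1, 1, -0.2)
  expect_true(any(qr.coef(qr(A), b) < 0))
  sol <- nnls(A, b)
  oracle <- enumerate_nnls(A, b)
  expect_equal(sol$deviance, oracle$dev, tolerance = 1e-10)
  expect_true(kkt_holds(A, b, sol$x))
})

test_that("1/SD weighting: constant SDs match unweighted; missing SDs fall back with a warning", {
  q <- seq(0.02, 0.4, length.out = 30)
  A <- cbind(exp(-q * 3), exp(-q * 12), 1 / (1 + q * 10))
  b <- 0.5 * A[, 1] + 0.2 * A[, 3] + 0.001 * sin(q * 40)
  exp_con <- new("ScatteringCurve", q = q, intensity = b,
                 sd = rep(0.05, 30))
  exp_no <- new("ScatteringCurve", q = q, intensity = b)
  f1 <- nnlsSelect(A, exp_con, useSdWeighting = TRUE)
  f2 <- nnlsSelect(A, exp_no, useSdWeighting = FALSE)
  expect_equal(fitWeights(f1), fitWeights(f2), tolerance = 1e-10)
  expect_warning(f3 <- nnlsSelect(A, exp_no, useSdWeighting = TRUE),
                 "falling back")
  expect_equal(fitWeights(f3), fitWeights(f2))
})

test_that("weight recovery from toy conformer mixtures, noiseless and 1% noise", {
  toy <- buildToyChain(20, 10, 20)
  cfg <- mcConfig(alignRange = c(1, 20), trialAttempts = 2000, seed = 21)
  pool <- runMC(toy, detectFlexibleRegions(confidence(toy), 60), cfg)
  q <- seq(0.005, 0.5, length.out = 150)
  # 5 conformers with well-separated scattering profiles
  mods <- pickSeparatedModels(pool, q, m = 5, candidateStride = 10)
  truth <- c(0.35, 0.25, 0.2, 0.15, 0.05)

  noiseless <- makeSyntheticExperiment(pool, mods, truth, q,
                                       noiseFraction = 0, seed = 5)
  fit <- nnlsSelect(noiseless$iqProfiles, noiseless$iq,
                    modelNumbers = mods)
  p <- setNames(rep(0, 5), mods)
  p[as.character(modelNumbers(fit))] <- percents(fit)
  expect_equal(unname(p), 100 * truth, tolerance = 1e-6)

  noisy <- makeSyntheticExperiment(pool, mods, truth, q,
                                   noiseFraction = 0.01, seed = 5)
  fitn <- nnlsSelect(noisy$iqProfiles, noisy$iq, useSdWeighting = TRUE,
                     modelNumbers = mods)
  pn <- setNames(rep(0, 5), mods)
  pn[as.character(modelNumbers(fitn))] <- percents(fitn)
  expect_lt(max(abs(unname(pn) - 100 * truth)), 5)
})

test_that("percents always total 100 and weighted Rg follows its formula", {
  expect_equal(weightedRg(40, 100), 40)
  expect_equal(weightedRg(c(30, 50), c(50, 50)), sqrt(1700))
  # published-style table of five models (rounded cells): hand-computed
  rg <- c(45.3, 36.4, 53.4, 30.2, 35.2)
  pc <- c(13.7, 43.8, 19.9, 12.5, 10.1)
  expect_equal(sum(pc), 100)
  expect_equal(weightedRg(rg, pc), 40.842, tolerance = 1e-3)
  expect_error(weightedRg(c(30, 50), c(60, 50)), "sum to 100")
  expect_error(weightedRg(c(30, 50), 100), "length")
})

test_that("curve reconstruction propagates SDs and rejects zero weights", {
  q <- c(0.1, 0.2, 0.3)
  one <- cbind(c(1, 2, 3))
  r1 <- reconstructCurve(one, 1, q, sds = cbind(c(0.1, 0.2, 0.3)))
  expect_equal(intensities(r1), c(1, 2, 3))
  expect_equal(curveSd(r1), c(0.1, 0.2, 0.3))

  two <- cbind(c(1, 2, 3), c(1, 2, 3))
  sds <- cbind(rep(0.2, 3), rep(0.2, 3))
  r2 <- reconstructCurve(two, c(0.5, 0.5), q, sds = sds)
  expect_equal(intensities(r2), c(1, 2, 3))
  expect_equal(curveSd(r2), rep(0.2 / sqrt(2), 3))
  expect_error(reconstructCurve(two, c(0, 0), q), "zero")
})

test_that("composite P(r) reproduces its generating mixture and is linear in area", {
  r <- 0:20
  p1 <- pmax(10 - abs(r - 5), 0)
  p2 <- pmax(8 - abs(r - 12), 0)
  comp_true <- 0.7 * p1 + 0.3 * p2
  expr <- new("PofR", r = r, p = comp_true)
  out <- reconstructPr(cbind(p1, p2), c(70, 30), expr)
  expect_lt(out$rmsd, 1e-9)
  expect_equal(sum(pValues(out$composite)),
               0.7 * sum(p1) + 0.3 * sum(p2))
  expect_error(reconstructPr(cbind(p1[-1], p2[-1]), c(70, 30), expr),
               "grids differ")
})
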