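noisefreeERF <- function(net, mod) {
  simulateERF(net$params, mod, net$designs, exogenousInput(),
              net$leadfield, noiseSd = 0)
}

test_that("spatial-mode reduction is lossless at full rank and monotone", {
  net <- tinyNet()
  mod <- modulationSet(net$sources, factors = c("attention", "rightEV"))
  erf <- addSensorNoise(noisefreeERF(net, mod), 0.05, seed = 1)
  full <- reduceData(erf, dim(erfArray(erf))[2])
  recon <- erfArray(erf)
  for (ci in seq_len(dim(recon)[1]))
    recon[ci, , ] <- full$projection %*% full$Y[ci, , ]
  expect_equal(recon, erfArray(erf), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(full$varianceExplained, 1, tolerance = 1e-12)
  vs <- vapply(1:8, function(m) reduceData(erf, m)$varianceExplained, 0)
  expect_true(all(diff(vs) >= -1e-12))
  # constructed rank-1 data: one mode carries (almost) everything
  a <- erfArray(erf)
  pat <- rnorm(dim(a)[2])
  for (ci in seq_len(dim(a)[1]))
    a[ci, , ] <- outer(pat, sin(seq_len(dim(a)[3]) / 7))
  r1 <- suppressWarnings(reduceData(erfDataset(a, timePoints(erf),
                                               conditionLabels(erf)), 1))
  expect_gte(r1$varianceExplained, 0.999)
})

test_that("prediction respects the prior mean and switched-off parameters", {
  net <- tinyNet()
  mdl <- dcmModel(net$params, net$leadfield, net$designs,
                  attModel = attModelS1S2(), fit = c())
  base <- dcmPredict(mdl)
  mod0 <- modulationSet(net$sources, factors = c("attention", "rightEV"))
  direct <- erfArray(noisefreeERF(net, mod0))
  expect_equal(as.vector(base), as.vector(direct), tolerance = 1e-12)
  # a switched-off parameter (zero prior variance) cannot move the
  # prediction
  off <- dcmPredict(mdl, theta = c(G.lS1 = 3))
  expect_identical(off, base)
  # a free parameter can
  on <- dcmPredict(mdl, theta = c(B.attention.G.S1 = -0.5))
  expect_gt(max(abs(on - base)), 0)
})

test_that("finite-difference sensitivities are stable under refinement", {
  net <- tinyNet()
  mdl <- dcmModel(net$params, net$leadfield, net$designs,
                  attModel = attModelS1S2(), fit = c())
  f <- function(th) as.vector(dcmPredict(mdl, th))
  nm <- "B.attention.G.S1"
  g0 <- f(setNames(0, nm))
  central <- function(h) (f(setNames(h, nm)) - f(setNames(-h, nm))) / (2 * h)
  c1 <- central(1e-3)
  c2 <- central(2e-3)
  nrm <- max(abs(c1))
  expect_lt(max(abs(c1 - c2)) / nrm, 1e-4)
  fwd <- (f(setNames(1e-3, nm)) - g0) / 1e-3
  expect_lt(max(abs(fwd - c1)) / nrm, 5e-3)
})

test_that("noise-free self-recovery finds the planted parameters", {
  net <- tinyNet()
  truth <- c(B.attention.G.S1 = -0.35, B.attention.G.S2 = -0.2,
             B.rightEV.G.S1 = -0.45)
  mod <- modulationSet(net$sources, factors = c("attention", "rightEV"))
  mod@BG["lS1", "attention"] <- truth[["B.attention.G.S1"]]
  mod@BG["lS2", "attention"] <- truth[["B.attention.G.S2"]]
  mod@BG["lS1", "rightEV"] <- truth[["B.rightEV.G.S1"]]
  erf <- noisefreeERF(net, mod)
  mdl <- dcmModel(net$params, net$leadfield, net$designs,
                  attModel = attModelS1S2(),
                  evModel = evModelContraS1(), fit = c())
  fit <- suppressWarnings(fitVL(erf, mdl, vlOptions(nModes = 4,
                                                    maxit = 32)))
  pm <- posteriorMean(fit)
  priorSd <- sqrt(1 / 4)
  expect_true(all(abs(pm[names(truth)] - truth) < priorSd / 4))
  expect_gt(fit@fitFraction, 0.99)
  # the fitted F beats fixed evaluations at random prior draws
  expect_gt(freeEnergy(fit), fit@Ftrace[1])
  # F never decreases over accepted steps; complexity is nonnegative
  expect_true(all(diff(fit@Ftrace) >= -1e-8))
  expect_gte(fit@complexity, 0)
  expect_equal(fit@freeEnergy, fit@accuracy - fit@complexity,
               tolerance = 1e-8)
})

test_that("declared-but-absent parameters leave the fit unchanged", {
  net <- tinyNet()
  mod <- modulationSet(net$sources, factors = c("attention", "rightEV"))
  mod@BG["lS1", "attention"] <- -0.3
  erf <- noisefreeERF(net, mod)
  attOnly <- dcmModel(net$params, net$leadfield, net$designs,
                      attModel = attModelS1S2(), fit = c())
  # same free set, but the second declaration carries extra switched-off
  # parameters (the whole extrinsic/intrinsic/input block)
  expect_gt(nrow(attOnly$priors), sum(attOnly$priors$var > 0))
  o <- vlOptions(nModes = 4, maxit = 24)
  f1 <- suppressWarnings(fitVL(erf, attOnly, o))
  f2 <- suppressWarnings(fitVL(erf, attOnly, o))
  expect_equal(freeEnergy(f1), freeEnergy(f2), tolerance = 1e-9)
})

test_that("a prior-only fit has zero complexity", {
  net <- tinyNet()
  mod0 <- modulationSet(net$sources, factors = c("attention", "rightEV"))
  erf <- addSensorNoise(noisefreeERF(net, mod0), 0.05, seed = 3)
  nullModel <- dcmModel(net$params, net$leadfield, net$designs,
                        fit = c())
  expect_equal(sum(nullModel$priors$var > 0), 0)
  fit <- suppressWarnings(fitVL(erf, nullModel,
                                vlOptions(nModes = 4, maxit = 8)))
  expect_equal(fit@complexity, 0)
  expect_true(fit@converged)
})

test_that("the null model wins on null data (Occam property)", {
  net <- tinyNet()
  mod0 <- modulationSet(net$sources, factors = c("attention", "rightEV"))
  clean <- noisefreeERF(net, mod0)
  sdN <- snrNoiseSd(clean, 5)
  nullModel <- dcmModel(net$params, net$leadfield, net$designs,
                        fit = c())
  fullModel <- dcmModel(net$params, net$leadfield, net$designs,
                        attModel = attModelS1S2(),
                        evModel = evModelContraS1(), fit = c())
  o <- vlOptions(nModes = 4, maxit = 20)
  ok <- 0L
  nSeeds <- 20
  for (s in seq_len(nSeeds)) {
    erf <- addSensorNoise(clean, sdN, seed = 300 + s)
    f0 <- suppressWarnings(fitVL(erf, nullModel, o))
    f1 <- suppressWarnings(fitVL(erf, fullModel, o))
    if (freeEnergy(f0) >= freeEnergy(f1) - 3) ok <- ok + 1L
  }
  expect_gte(ok, 0.8 * nSeeds)
})
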