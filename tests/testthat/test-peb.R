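pnames <- paste0("P", 1:5)

test_that("a degenerate cohort recovers the common value with a null slope", {
  recs <- simulateSubjectPosteriors(pnames, nSubjects = 10,
                                    groupMean = setNames(c(0.5, -0.2, 0,
                                                           0.1, 0),
                                                         pnames),
                                    betweenSd = 0, covariateSlope = c(),
                                    covariateNoiseSd = 0.4,
                                    firstLevelSd = 1e-3, seed = 1)
  peb <- pebFit(recs)
  expect_equal(unname(peb@betaMean["mean", ]), c(0.5, -0.2, 0, 0.1, 0),
               tolerance = 0.02)
  expect_true(all(abs(peb@betaMean["covariate", ]) < 0.02))
})

test_that("a planted covariate slope is recovered within its uncertainty", {
  ok <- 0L
  for (s in 1:10) {
    recs <- simulateSubjectPosteriors(pnames, nSubjects = 22,
                                      betweenSd = 0.2,
                                      covariateSlope = c(P2 = -4),
                                      covariateNoiseSd = 0.2,
                                      firstLevelSd = 0.02, seed = 40 + s)
    peb <- pebFit(recs)
    # implied group effect of the z-scored covariate on P2
    cv <- vapply(recs, function(r) r@ratingModulation, 0)
    dev <- vapply(recs, function(r) r@mean[["P2"]], 0)
    bTrue <- cov(dev, cv) / sd(cv) # regression scale used by the GLM
    i <- length(pnames) + 2 # covariate block, parameter P2
    sdPost <- sqrt(peb@betaCov[i, i])
    if (abs(peb@betaMean["covariate", "P2"] - bTrue) <= 2 * sdPost)
      ok <- ok + 1L
  }
  expect_gte(ok, 9)
})

test_that("inflating first-level uncertainty widens the group posterior", {
  recs <- simulateSubjectPosteriors(pnames, nSubjects = 12,
                                    betweenSd = 0.1,
                                    covariateSlope = c(P1 = -2),
                                    covariateNoiseSd = 0.3,
                                    firstLevelSd = 0.1, seed = 5)
  wide <- lapply(recs, function(r) {
    r@cov <- r@cov * 4
    r
  })
  v1 <- diag(pebFit(recs)@betaCov)
  v2 <- diag(pebFit(wide)@betaCov)
  expect_gt(mean(v2 / v1), 1)
})

test_that("degenerate designs and tiny cohorts are rejected", {
  recs <- simulateSubjectPosteriors(pnames, nSubjects = 2, seed = 1)
  expect_error(pebFit(recs), "at least 3")
  recs3 <- simulateSubjectPosteriors(pnames, nSubjects = 5,
                                     covariateNoiseSd = 0, seed = 1)
  # constant covariate: z-column degenerates, the design loses rank
  expect_error(pebFit(recs3), "rank deficient")
})

test_that("reduction of the full pattern reproduces the full free energy", {
  recs <- simulateSubjectPosteriors(pnames, nSubjects = 15,
                                    betweenSd = 0.15,
                                    covariateSlope = c(P1 = -3),
                                    covariateNoiseSd = 0.3,
                                    firstLevelSd = 0.05, seed = 9)
  peb <- pebFit(recs)
  full <- painDCM:::.bmrReduce(
    as.vector(t(peb@betaMean)), peb@betaCov,
    rep(peb@priorVar, each = length(pnames)), integer(0))
  expect_lt(abs(full$dF), 1e-6)
})

test_that("reduction retains strong effects and prunes null cohorts", {
  retainedStrong <- 0L
  for (s in 1:10) {
    recs <- simulateSubjectPosteriors(pnames, nSubjects = 22,
                                      betweenSd = 0.2,
                                      covariateSlope = c(P3 = -6),
                                      covariateNoiseSd = 0.15,
                                      firstLevelSd = 0.02, seed = 70 + s)
    red <- bmrPrune(pebFit(recs))
    if (identical(red@retained, "P3")) retainedStrong <- retainedStrong + 1L
  }
  expect_gte(retainedStrong, 9)
  nullRetained <- 0L
  for (s in 1:10) {
    recs0 <- simulateSubjectPosteriors(pnames, nSubjects = 22,
                                       betweenSd = 0.2,
                                       covariateSlope = c(),
                                       covariateNoiseSd = 0.4,
                                       firstLevelSd = 0.02, seed = 90 + s)
    red0 <- bmrPrune(pebFit(recs0))
    if (length(red0@retained) == 0) nullRetained <- nullRetained + 1L
  }
  expect_gte(nullRetained, 8)
  # greedy and exhaustive search agree on a small problem
  recs <- simulateSubjectPosteriors(pnames, nSubjects = 22,
                                    betweenSd = 0.2,
                                    covariateSlope = c(P3 = -6),
                                    covariateNoiseSd = 0.15,
                                    firstLevelSd = 0.02, seed = 71)
  peb <- pebFit(recs)
  expect_identical(bmrPrune(peb)@retained,
                   bmrPrune(peb, exhaustive = TRUE)@retained)
})

test_that("leave-one-out prediction behaves in the exact linear case", {
  # noiseless linear cohort: covariate perfectly encoded in P1
  n <- 12
  recs <- lapply(seq_len(n), function(i) {
    x <- (i - (n + 1) / 2) / n
    subjectRecord(paste0("S", i),
                  setNames(c(0.3 + 0.5 * x, 0, 0.1, 0, 0), pnames),
                  diag(1e-6, 5), x)
  })
  loo <- looCV(recs, retained = "P1")
  expect_gt(loo$correlation, 0.999)
  # predictions are invariant to an affine rescaling of the covariate
  recs2 <- lapply(recs, function(r) {
    r@ratingModulation <- 10 * r@ratingModulation + 3
    r
  })
  loo2 <- looCV(recs2, retained = "P1")
  expect_equal(loo2$pairs$predicted, loo$pairs$predicted,
               tolerance = 1e-6)
  expect_equal(loo2$correlation, loo$correlation, tolerance = 1e-6)
})

test_that("leave-one-out reports an undefined correlation for constant
           covariates", {
  recs <- simulateSubjectPosteriors(pnames, nSubjects = 6,
                                    covariateNoiseSd = 0, seed = 2)
  loo <- looCV(recs)
  expect_true(is.na(loo$correlation))
  expect_match(loo$note, "constant covariate")
  expect_error(looCV(recs[1:3]), "at least 4")
})

test_that("group outputs serialize to CSV", {
  recs <- simulateSubjectPosteriors(pnames, nSubjects = 8,
                                    betweenSd = 0.15,
                                    covariateSlope = c(P1 = -4),
                                    covariateNoiseSd = 0.2,
                                    firstLevelSd = 0.05, seed = 3)
  red <- bmrPrune(pebFit(recs))
  f <- tempfile(fileext = ".csv")
  writePEB(red, f)
  df <- read.csv(f)
  expect_equal(df$parameter, pnames)
  expect_true(all(c("covariateEffect", "probEffect", "retained") %in%
                  names(df)))
})
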