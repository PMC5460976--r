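test_that("ground-truth profiles plant the advertised effect pattern", {
  tn <- makeGroundTruth("null")
  expect_length(modulationEntries(tn$mod), 0)
  tp <- makeGroundTruth("paper_like")
  e <- modulationEntries(tp$mod)
  # attention: somatosensory disinhibition, right-frontal inhibition
  expect_true(all(e[paste0("B.attention.G.", c("lS1", "rS1", "lS2",
                                               "rS2"))] < 0))
  expect_gt(e[["B.attention.G.rIFG"]], 0)
  # contralateral S1 disinhibition under expectation violation
  expect_lt(e[["B.leftEV.G.rS1"]], 0)
  expect_lt(e[["B.rightEV.G.lS1"]], 0)
  expect_identical(modulationEntries(makeGroundTruth("paper_like",
                                                     seed = 4)$mod), e)
  # the winning architecture backs the default truth
  expect_equal(tp$architecture$id, 10)
  # modulation entries survive a set/get round trip
  m2 <- setModulationEntries(modulationSet(tp$params@sources), e)
  expect_identical(modulationEntries(m2)[names(e)], e)
})

test_that("a zero-variability cohort is perfectly homogeneous", {
  truth <- makeGroundTruth("paper_like")
  spec <- cohortSpec(nSubjects = 3, betweenSd = 0, ratingNoiseSd = 0,
                     noiseSd = 0, nSensors = 16)
  co <- simulateCohort(truth, spec, tGrid = erfTimeGrid(rateHz = 100))
  a1 <- erfArray(co$subjects[[1]]$erf)
  expect_identical(a1, erfArray(co$subjects[[2]]$erf))
  # averaging n identical subjects reproduces any single subject (up to
  # floating-point summation)
  expect_equal(erfArray(co$grandAverage), a1, tolerance = 1e-12)
  rat <- vapply(co$subjects, function(s) s$ratingModulation, 0)
  expect_equal(rat, rep(spec$ratingMean, 3))
  expect_equal(co$resampled, 0L)
})

test_that("cohorts are reproducible and couple ratings to parameters", {
  truth <- makeGroundTruth("paper_like")
  spec <- cohortSpec(nSubjects = 6, betweenSd = 0.15, ratingNoiseSd = 0.1,
                     noiseSd = 0.02, nSensors = 16, masterSeed = 11)
  tg <- erfTimeGrid(rateHz = 100)
  co <- simulateCohort(truth, spec, tGrid = tg)
  co2 <- simulateCohort(truth, spec, tGrid = tg)
  expect_identical(erfArray(co$grandAverage), erfArray(co2$grandAverage))
  expect_identical(vapply(co$subjects, `[[`, 0, "ratingModulation"),
                   vapply(co2$subjects, `[[`, 0, "ratingModulation"))
  # ratings reflect the coupled parameter deviations
  slope <- spec$covariateSlope
  drive <- vapply(co$subjects, function(s)
    sum(slope * s$deviations[names(slope)]), 0)
  rat <- vapply(co$subjects, function(s) s$ratingModulation, 0)
  expect_gt(cor(drive, rat), 0.8)
})

test_that("the ratings table respects VAS bounds and the planted effect", {
  truth <- makeGroundTruth("paper_like")
  co <- simulateCohort(truth,
                       cohortSpec(nSubjects = 6, betweenSd = 0.1,
                                  ratingNoiseSd = 0.1, noiseSd = 0,
                                  nSensors = 16, ratingMean = 0.8),
                       tGrid = erfTimeGrid(rateHz = 100))
  rt <- ratingsTable(co)
  expect_true(all(rt$rating_attended >= 0 & rt$rating_attended <= 10))
  expect_gt(mean(rt$rating_attended), mean(rt$rating_unattended))
  expect_equal(rt$modulation, rt$rating_attended - rt$rating_unattended)
  expect_identical(rt, ratingsTable(co))
  # clipping is counted
  coBig <- co
  coBig$spec$ratingBase <- 9.9
  rtBig <- suppressMessages(ratingsTable(coBig))
  expect_gt(attr(rtBig, "clipped"), 0)
  expect_true(all(rtBig$rating_attended <= 10))
})

test_that("the full pipeline recovers the planted generative account", {
  # end-to-end at reduced scale: simulate a cohort from the paper-like
  # truth restricted to a bilateral S1-S2 network, invert the grand
  # average under three candidate models, pick by fixed-effects BMS,
  # fit subjects under the winner, and relate posteriors to ratings
  net <- smallNet(16)
  src <- net$sources
  modTruth <- modulationSet(src)
  modTruth@BG[, "attention"] <- -0.3
  modTruth@BG["rS1", "leftEV"] <- -0.4
  modTruth@BG["lS1", "rightEV"] <- -0.4
  truth <- structure(list(architecture = NULL, params = net$params,
                          mod = modTruth, input = exogenousInput(),
                          leadfieldSeed = 3L, profile = "custom"),
                     class = "cmcGroundTruth")
  spec <- cohortSpec(nSubjects = 8, betweenSd = 0.12,
                     covariateSlope = c(B.attention.G.lS1 = -2,
                                        B.attention.G.rS1 = -2,
                                        B.attention.G.lS2 = -2,
                                        B.attention.G.rS2 = -2),
                     ratingNoiseSd = 0.08, noiseSd = 0.01,
                     nSensors = 16, masterSeed = 21)
  co <- simulateCohort(truth, spec)
  o <- vlOptions(nModes = 6, maxit = 24)
  mNull <- dcmModel(truth$params, co$leadfield, co$designs, fit = c())
  mAtt <- dcmModel(truth$params, co$leadfield, co$designs,
                   attModel = attModelS1S2(), fit = c())
  mFull <- dcmModel(truth$params, co$leadfield, co$designs,
                    attModel = attModelS1S2(),
                    evModel = evModelContraS1(), fit = c())
  fits <- lapply(list(mNull, mAtt, mFull), function(m)
    suppressWarnings(fitVL(co$grandAverage, m, o)))
  bms <- ffxBMS(fits, modelIds = c("null", "attention", "attention+EV"))
  expect_equal(bms@modelIds[which.max(bms@posteriorProbs)],
               "attention+EV")
  # subject-level fits of the winning model feed the group stage
  recs <- lapply(co$subjects, function(s) {
    fit <- suppressWarnings(fitVL(s$erf, mFull, o))
    subjectRecordFromFit(s$subjectId, fit, s$ratingModulation)
  })
  peb <- pebFit(recs)
  # the covariate couples to the attention gains: their group effect
  # should dominate the unrelated EV effects
  attIdx <- grep("attention", peb@parameters)
  expect_gt(max(abs(peb@betaMean["covariate", attIdx])),
            max(abs(peb@betaMean["covariate", -attIdx])))
  loo <- looCV(recs, retained = peb@parameters[attIdx])
  expect_gt(loo$correlation, 0.3)
})
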