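## Synthetic ground truth and cohorts: planted modulation effects, subject
## variability coupled to a behavioural pain-modulation covariate, and the
## grand-average evoked fields the analysis consumes.

#' Flatten / set the nonzero entries of a modulation set
#'
#' Names follow the parameter convention of the inversion:
#' \code{B.<factor>.G.<source>} for gain modulation and
#' \code{B.<factor>.F/B.<to>.<from>} for extrinsic modulation.
#'
#' @param mod a [ModulationSet-class].
#' @return named numeric vector of the nonzero entries.
#' @export
modulationEntries <- function(mod) {
  src <- rownames(mod@BG)
  out <- numeric(0)
  for (f in mod@factors) {
    gz <- which(mod@BG[, f] != 0)
    if (length(gz))
      out <- c(out, setNames(mod@BG[gz, f],
                             paste0("B.", f, ".G.", src[gz])))
    for (mt in c("F", "B")) {
      M <- if (mt == "F") mod@BF[[f]] else mod@BB[[f]]
      idx <- which(M != 0, arr.ind = TRUE)
      if (nrow(idx))
        out <- c(out, setNames(M[idx],
                               paste0("B.", f, ".", mt, ".",
                                      src[idx[, 1]], ".", src[idx[, 2]])))
    }
  }
  out
}

#' @rdname modulationEntries
#' @param values named numeric vector in the same naming scheme; entries
#'   overwrite the corresponding modulation values.
#' @return for \code{setModulationEntries}, the updated
#'   [ModulationSet-class].
#' @export
setModulationEntries <- function(mod, values) {
  src <- rownames(mod@BG)
  for (nm in names(values)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    f <- parts[2]; kind <- parts[3]
    if (kind == "G") {
      mod@BG[match(parts[4], src), f] <- values[[nm]]
    } else {
      i <- match(parts[4], src); j <- match(parts[5], src)
      if (kind == "F") mod@BF[[f]][i, j] <- values[[nm]]
      else mod@BB[[f]][i, j] <- values[[nm]]
    }
  }
  mod
}

#' Construct a ground-truth generative model
#'
#' Profiles: \code{"null"} plants no modulation; \code{"paper_like"}
#' plants the qualitative effect pattern the analysis is designed to
#' recover — attention disinhibits (negative gain modulation) bilateral
#' S1 and S2 and inhibits right IFG; expectation violation disinhibits
#' contralateral S1 and modulates S2 in a lateralized fashion, with
#' right-lateralized increases in forward connectivity and decreases in
#' backward connectivity contralateral to the violated side. Magnitudes
#' (0.1-0.3 log-units) are package defaults. \code{"custom"} takes a
#' user-supplied modulation set.
#'
#' @param profile "paper_like", "null" or "custom".
#' @param seed seed stored for downstream lead-field generation.
#' @param architecture network architecture (default the winning
#'   structure: all eight sources, IPC above IFG, S1 connected to both
#'   fronto-parietal nodes, S2 to IFG).
#' @param mod modulation set for \code{profile = "custom"}.
#' @return object of class \code{cmcGroundTruth}: architecture, baseline
#'   parameters, planted modulation, input, lead-field seed.
#' @export
makeGroundTruth <- function(profile = c("paper_like", "null", "custom"),
                            seed = 1L,
                            architecture = enumerateArchitectures()[[10]],
                            mod = NULL) {
  profile <- match.arg(profile)
  masks <- architectureMasks(architecture)
  src <- architecture$sources
  params <- cmcParameters(src, AF = masks$AF, AB = masks$AB)
  if (profile != "custom")
    mod <- modulationSet(src)
  if (profile == "paper_like") {
    plant <- c(
      # attention: somatosensory disinhibition, right-frontal inhibition
      B.attention.G.lS1 = -0.3, B.attention.G.rS1 = -0.3,
      B.attention.G.lS2 = -0.3, B.attention.G.rS2 = -0.3,
      B.attention.G.rIFG = 0.3,
      # expectation violation: contralateral S1 disinhibition,
      # lateralized S2 modulation
      B.leftEV.G.rS1 = -0.3, B.leftEV.G.rS2 = -0.3, B.leftEV.G.lS2 = 0.2,
      B.rightEV.G.lS1 = -0.3, B.rightEV.G.rS2 = -0.3,
      B.rightEV.G.lS2 = -0.1)
    # recurrent extrinsic modulation: right-lateralized forward increase,
    # backward decrease contralateral to the violated side
    fwdR <- c(B.leftEV.F.rS2.rS1 = 0.2, B.rightEV.F.rS2.rS1 = 0.2)
    bwd <- c(B.leftEV.B.rS1.rS2 = -0.2, B.rightEV.B.lS1.lS2 = -0.2)
    mod <- setModulationEntries(mod, c(plant, fwdR, bwd))
  }
  structure(list(architecture = architecture, params = params, mod = mod,
                 input = exogenousInput(), leadfieldSeed = as.integer(seed),
                 profile = profile),
            class = "cmcGroundTruth")
}

#' @export
print.cmcGroundTruth <- function(x, ...) {
  cat("cmcGroundTruth (", x$profile, "): ", nSources(x$params),
      " sources, ", length(modulationEntries(x$mod)),
      " planted modulation entries\n", sep = "")
  invisible(x)
}

#' Cohort specification
#'
#' Study conditions for a synthetic cohort: 22 subjects (the reference
#' sample size), between-subject variability on the planted modulation
#' entries, and a behavioural covariate generated from selected
#' parameter deviations.
#'
#' @param nSubjects number of subjects (default 22).
#' @param betweenSd between-subject standard deviation of the modulation
#'   entries (log-units).
#' @param covariateSlope named mapping from modulation-entry deviations to
#'   the pain-modulation rating (VAS units per log-unit); default couples
#'   the attention self-inhibition of left S1 and right S2.
#' @param ratingNoiseSd rating noise (VAS units).
#' @param noiseSd sensor noise standard deviation.
#' @param masterSeed master seed; per-subject seeds derive via
#'   [blockSeed()].
#' @param nSensors sensors in the synthetic lead field.
#' @param ratingBase baseline VAS rating around which attended/unattended
#'   ratings are placed.
#' @param ratingMean mean attended-minus-unattended modulation (VAS
#'   units) added to every subject.
#' @export
cohortSpec <- function(nSubjects = 22, betweenSd = 0.15,
                       covariateSlope = c(B.attention.G.lS1 = -3,
                                          B.attention.G.rS2 = -3),
                       ratingNoiseSd = 0.3, noiseSd = 0.05,
                       masterSeed = 1L, nSensors = 32, ratingBase = 5,
                       ratingMean = 0.8) {
  stopifnot(nSubjects >= 1, betweenSd >= 0, ratingNoiseSd >= 0,
            noiseSd >= 0)
  list(nSubjects = nSubjects, betweenSd = betweenSd,
       covariateSlope = covariateSlope, ratingNoiseSd = ratingNoiseSd,
       noiseSd = noiseSd, masterSeed = as.integer(masterSeed),
       nSensors = nSensors, ratingBase = ratingBase,
       ratingMean = ratingMean)
}

#' Simulate a synthetic cohort
#'
#' Each subject's modulation entries are the ground truth plus Gaussian
#' deviations; the pain-modulation rating couples to selected deviations
#' through \code{covariateSlope}; each subject's evoked fields are
#' simulated with sensor noise, and the grand average is their mean.
#' Subjects whose parameter draw makes the network diverge are resampled
#' (count reported in the result).
#'
#' @param truth a \code{cmcGroundTruth} from [makeGroundTruth()].
#' @param spec a [cohortSpec()].
#' @param tGrid sampling grid (ms).
#' @return object of class \code{cmcCohort}: per-subject evoked fields,
#'   true modulation entries and ratings, plus the grand-average
#'   [ERFDataset-class] and the lead field used.
#' @export
simulateCohort <- function(truth, spec = cohortSpec(),
                           tGrid = erfTimeGrid()) {
  src <- truth$params@sources
  lf <- buildLeadfield(defaultSourceCoords(src), spec$nSensors,
                       seed = truth$leadfieldSeed)
  designs <- conditionSet(src, factors = truth$mod@factors)
  base <- modulationEntries(truth$mod)
  if (!length(base)) # null profile: deviations still need a support
    base <- setNames(numeric(length(spec$covariateSlope)),
                     names(spec$covariateSlope))
  subjects <- list()
  resampled <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  sumA <- NULL
  for (i in seq_len(spec$nSubjects)) {
    erf <- NULL
    for (attempt in 1:10) {
      set.seed(blockSeed(spec$masterSeed, 100 * i + attempt))
      dev <- rnorm(length(base), 0, spec$betweenSd)
      names(dev) <- names(base)
      entries <- base + dev
      modi <- setModulationEntries(modulationSet(src, truth$mod@factors),
                                   entries)
      erf <- tryCatch(
        simulateERF(truth$params, modi, designs, truth$input, lf,
                    noiseSd = spec$noiseSd,
                    seed = blockSeed(spec$masterSeed, 7000 + i),
                    tGrid = tGrid),
        cmcDivergence = function(e) NULL)
      if (!is.null(erf)) break
      resampled <- resampled + 1L
    }
    if (is.null(erf))
      stop("cohort simulation: subject ", i, " diverged repeatedly",
           call. = FALSE)
    slope <- spec$covariateSlope
    ratingMod <- spec$ratingMean +
      sum(slope * dev[names(slope)]) + rnorm(1, 0, spec$ratingNoiseSd)
    subjects[[i]] <- list(subjectId = sprintf("S%02d", i), erf = erf,
                          trueEntries = entries, deviations = dev,
                          ratingModulation = ratingMod)
    sumA <- if (is.null(sumA)) erf@data else sumA + erf@data
  }
  ga <- erfDataset(sumA / spec$nSubjects, tGrid, names(designs),
                   noiseSd = spec$noiseSd / sqrt(spec$nSubjects))
  structure(list(subjects = subjects, grandAverage = ga, truth = truth,
                 spec = spec, leadfield = lf, designs = designs,
                 resampled = resampled),
            class = "cmcCohort")
}

#' @export
print.cmcCohort <- function(x, ...) {
  cat("cmcCohort:", length(x$subjects), "subjects,",
      length(x$designs), "conditions; grand average available\n")
  invisible(x)
}

#' Behavioural ratings table of a cohort
#'
#' Maps each subject's pain-modulation score into attended and unattended
#' VAS ratings around the cohort baseline, clipped to [0, 10] (clipping
#' is counted and reported as an attribute; the modulation column is
#' attended minus unattended after clipping).
#'
#' @param cohort a \code{cmcCohort}.
#' @return data.frame with columns subject_id, rating_attended,
#'   rating_unattended, modulation; attribute \code{clipped} counts
#'   clipped ratings.
#' @export
ratingsTable <- function(cohort) {
  base <- cohort$spec$ratingBase
  m <- vapply(cohort$subjects, function(s) s$ratingModulation, 0)
  att <- base + m / 2
  una <- base - m / 2
  clipped <- sum(att < 0 | att > 10 | una < 0 | una > 10)
  att <- pmin(pmax(att, 0), 10)
  una <- pmin(pmax(una, 0), 10)
  out <- data.frame(
    subject_id = vapply(cohort$subjects, function(s) s$subjectId, ""),
    rating_attended = att, rating_unattended = una,
    modulation = att - una, stringsAsFactors = FALSE)
  attr(out, "clipped") <- clipped
  if (clipped > 0)
    message(clipped, " rating(s) clipped to the VAS bounds")
  out
}

#' Simulate subject-level posteriors for the group stage
#'
#' Generates [SubjectRecord-class] objects directly: subject parameters
#' are a group mean plus Gaussian between-subject deviations, the
#' covariate couples to selected deviations, and the "estimated"
#' posterior mean adds first-level estimation noise with a known isotropic
#' posterior covariance. This isolates the parametric-empirical-Bayes
#' stage from the cost of first-level model fitting.
#'
#' @param paramNames first-level parameter names.
#' @param nSubjects cohort size (default 22).
#' @param groupMean named group-mean parameter values (default 0).
#' @param betweenSd between-subject deviation SD.
#' @param covariateSlope named slopes mapping deviations to the covariate.
#' @param covariateNoiseSd covariate noise SD.
#' @param firstLevelSd first-level posterior SD (estimation noise SD uses
#'   the same value).
#' @param seed RNG seed.
#' @return list of [SubjectRecord-class] objects.
#' @export
simulateSubjectPosteriors <- function(paramNames, nSubjects = 22,
                                      groupMean = NULL, betweenSd = 0.15,
                                      covariateSlope = c(),
                                      covariateNoiseSd = 0.3,
                                      firstLevelSd = 0.05, seed = 1L) {
  p <- length(paramNames)
  if (is.null(groupMean)) groupMean <- setNames(rep(0, p), paramNames)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  out <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    dev <- setNames(rnorm(p, 0, betweenSd), paramNames)
    theta <- groupMean + dev
    mhat <- theta + rnorm(p, 0, firstLevelSd)
    cvv <- sum(covariateSlope * dev[names(covariateSlope)]) +
      rnorm(1, 0, covariateNoiseSd)
    out[[i]] <- subjectRecord(sprintf("S%02d", i),
                              setNames(mhat, paramNames),
                              diag(firstLevelSd^2, p), cvv)
  }
  out
}
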