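#' @import methods
#' @importFrom stats rnorm runif optimize setNames sd cor dist qnorm
#' @importFrom utils head tail write.csv
#' @useDynLib painDCM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Population and coupling-pair conventions used throughout: four neural
## populations per cortical source (SS spiny stellate, SP superficial
## pyramidal, II inhibitory interneurons, DP deep pyramidal) and the ten
## intrinsic coupling pairs of the canonical microcircuit.

.populations <- c("SS", "SP", "II", "DP")
.gammaPairs <- c("SS_SS", "SP_SS", "II_SS", "SS_II", "DP_II",
                 "II_II", "SS_SP", "SP_SP", "DP_DP", "II_DP")

#' Canonical-microcircuit parameters for an N-source network
#'
#' Holds all rate constants, intrinsic coupling gains, extrinsic connection
#' matrices and input gains of a canonical-microcircuit (CMC) neural-mass
#' network. Each cortical source contains four populations (spiny stellate
#' SS, superficial pyramidal SP, inhibitory interneurons II, deep pyramidal
#' DP); sources are coupled by excitatory forward connections (SP of the
#' lower source to SS and DP of the higher source) and inhibitory backward
#' connections (DP of the higher source to SP and II of the lower source).
#'
#' @slot kappa 4 x N matrix of synaptic rate constants (1/ms), rows
#'   SS/SP/II/DP.
#' @slot gamma 10 x N matrix of intrinsic coupling gains, rows named by the
#'   ten coupling pairs (e.g. \code{"SP_SS"} is the SP to SS gain).
#' @slot AF,AB N x N forward and backward extrinsic matrices; entry
#'   \code{[i, j]} couples source j to source i. Zero diagonal.
#' @slot C length-N input gain vector scaling the thalamic input u.
#' @slot sigmoidSlope slope r of the centred firing-rate sigmoid.
#' @slot sources character labels of the N sources.
#' @exportClass CMCParameters
setClass("CMCParameters",
  representation(kappa = "matrix", gamma = "matrix", AF = "matrix",
                 AB = "matrix", C = "numeric", sigmoidSlope = "numeric",
                 sources = "character"))

setValidity("CMCParameters", function(object) {
  n <- length(object@sources)
  msg <- character(0)
  if (ncol(object@kappa) != n || nrow(object@kappa) != 4)
    msg <- c(msg, "kappa must be 4 x n_sources")
  if (ncol(object@gamma) != n || nrow(object@gamma) != 10)
    msg <- c(msg, "gamma must be 10 x n_sources")
  if (!all(dim(object@AF) == c(n, n)) || !all(dim(object@AB) == c(n, n)))
    msg <- c(msg, "AF and AB must be n_sources x n_sources")
  if (any(object@kappa <= 0)) msg <- c(msg, "all kappa must be > 0")
  if (n > 0 && (any(diag(object@AF) != 0) || any(diag(object@AB) != 0)))
    msg <- c(msg, "AF and AB must have zero diagonal")
  if (any(object@AF < 0) || any(object@AB < 0))
    msg <- c(msg, "extrinsic connection strengths must be >= 0")
  if (length(object@C) != n) msg <- c(msg, "C must have one entry per source")
  if (length(object@sigmoidSlope) != 1 || object@sigmoidSlope <= 0)
    msg <- c(msg, "sigmoidSlope must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Condition-specific modulation of connectivity (B-matrices)
#'
#' Log-scaling of extrinsic connections and of the superficial-pyramidal
#' self-inhibition gain, per experimental factor. A zero entry leaves the
#' corresponding connection unmodulated; a negative entry on the SP
#' self-gain is disinhibition (increased gain).
#'
#' @slot factors ordered factor labels (e.g. attention, leftEV, rightEV).
#' @slot BF,BB lists (one N x N matrix per factor) of log-scalings applied
#'   to AF and AB.
#' @slot BG N x K matrix of log-scalings of the SP self-inhibition gain
#'   (rows = sources, columns = factors).
#' @exportClass ModulationSet
setClass("ModulationSet",
  representation(factors = "character", BF = "list", BB = "list",
                 BG = "matrix"))

setValidity("ModulationSet", function(object) {
  k <- length(object@factors)
  msg <- character(0)
  if (length(object@BF) != k || length(object@BB) != k)
    msg <- c(msg, "BF and BB need one matrix per factor")
  if (ncol(object@BG) != k)
    msg <- c(msg, "BG needs one column per factor")
  n <- nrow(object@BG)
  for (m in c(object@BF, object@BB))
    if (!is.matrix(m) || !all(dim(m) == c(n, n)))
      msg <- c(msg, "all BF/BB matrices must be n_sources x n_sources")
  if (length(msg)) unique(msg) else TRUE
})

#' Exogenous (thalamic) input waveform
#'
#' Gaussian input bump u(t) = amplitude * exp(-(t - latency)^2 /
#' (2 dispersion^2)) describing the stimulus-evoked thalamic volley.
#'
#' @slot latencyMs mean latency of the bump (ms post-stimulus).
#' @slot dispersionMs standard deviation of the bump (ms); must be > 0.
#' @slot amplitude scale of the bump.
#' @exportClass ExogenousInput
setClass("ExogenousInput",
  representation(latencyMs = "numeric", dispersionMs = "numeric",
                 amplitude = "numeric"))

setValidity("ExogenousInput", function(object) {
  if (length(object@dispersionMs) != 1 || object@dispersionMs <= 0)
    return("dispersionMs must be a single positive number")
  TRUE
})

#' Synthetic lead field mapping sources to sensors
#'
#' @slot gain sensor x source gain matrix applied to superficial-pyramidal
#'   voltage.
#' @slot sensorPos sensor positions (mm, MNI-like frame).
#' @slot sourceCoords source MNI coordinates (mm).
#' @slot seed integer seed the geometry was generated from.
#' @exportClass LeadField
setClass("LeadField",
  representation(gain = "matrix", sensorPos = "matrix",
                 sourceCoords = "matrix", seed = "integer"))

setValidity("LeadField", function(object) {
  msg <- character(0)
  if (ncol(object@gain) != nrow(object@sourceCoords))
    msg <- c(msg, "gain needs one column per source")
  if (nrow(object@gain) != nrow(object@sensorPos))
    msg <- c(msg, "gain needs one row per sensor")
  if (length(msg)) msg else TRUE
})

#' Condition-average evoked-field dataset
#'
#' Container for the eight (or fewer, at reduced scale) condition-average
#' evoked fields over a peristimulus window, as produced by averaging MEG
#' epochs per condition or by the simulator.
#'
#' @slot data condition x sensor x time array.
#' @slot timeMs strictly increasing peristimulus time base (ms).
#' @slot conditionLabels unique condition labels (e.g. uLS, aRD).
#' @slot noiseSd per-sensor Gaussian noise standard deviation used when the
#'   dataset was simulated (0 for noise-free).
#' @exportClass ERFDataset
setClass("ERFDataset",
  representation(data = "array", timeMs = "numeric",
                 conditionLabels = "character", noiseSd = "numeric"))

setValidity("ERFDataset", function(object) {
  d <- dim(object@data)
  msg <- character(0)
  if (length(d) != 3) msg <- c(msg, "data must be condition x sensor x time")
  else {
    if (d[1] != length(object@conditionLabels))
      msg <- c(msg, "one condition label per data slice required")
    if (d[3] != length(object@timeMs))
      msg <- c(msg, "time base must match the third data dimension")
  }
  if (anyDuplicated(object@conditionLabels))
    msg <- c(msg, "condition labels must be unique")
  if (length(object@timeMs) > 1 && any(diff(object@timeMs) <= 0))
    msg <- c(msg, "timeMs must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Roving-oddball session design
#'
#' Ordered event table of a full session of roving-oddball blocks, with
#' attention labels per block and deviant/standard/filler roles per event.
#'
#' @slot events data.frame with columns block, attention, time_ms, hand,
#'   role, train_index, position_in_train.
#' @slot blockOrder string over \{A, B\} (A = unattended/visual task,
#'   B = attended/pain task) or explicit attention labels.
#' @slot repProbs probability vector over train lengths 3 to 7.
#' @slot crossEvents data.frame of fixation-cross colour-change times
#'   (metadata only; not part of the modelled design).
#' @exportClass SessionDesign
setClass("SessionDesign",
  representation(events = "data.frame", blockOrder = "character",
                 repProbs = "numeric", crossEvents = "data.frame"))

setValidity("SessionDesign", function(object) {
  msg <- character(0)
  need <- c("block", "attention", "time_ms", "hand", "role",
            "train_index", "position_in_train")
  if (!all(need %in% names(object@events)))
    msg <- c(msg, paste("events must have columns:",
                        paste(need, collapse = ", ")))
  if (abs(sum(object@repProbs) - 1) > 1e-9)
    msg <- c(msg, "repProbs must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Result of variational-Laplace model inversion
#'
#' Gaussian posterior over the free (log-scale) parameters of a dynamic
#' causal model plus the free-energy approximation to log model evidence and
#' its accuracy/complexity decomposition.
#'
#' @slot posteriorMean named posterior expectation per free parameter.
#' @slot posteriorCov posterior covariance (symmetric positive semidefinite).
#' @slot logPrecision posterior log observation precision hyperparameter.
#' @slot freeEnergy variational free energy F.
#' @slot accuracy,complexity terms of F = accuracy - complexity; the
#'   complexity term is the KL divergence from prior to posterior (>= 0).
#' @slot fitFraction fraction of data variance explained at the posterior
#'   mean.
#' @slot iterations number of optimizer iterations performed.
#' @slot converged logical convergence flag.
#' @slot Ftrace free energy at each accepted optimizer step.
#' @slot priors data.frame of the prior specification (name, type, mean,
#'   var) over all declared parameters, including switched-off ones.
#' @slot details list of auxiliary results (projection, options, model id).
#' @exportClass InversionResult
setClass("InversionResult",
  representation(posteriorMean = "numeric", posteriorCov = "matrix",
                 logPrecision = "numeric", freeEnergy = "numeric",
                 accuracy = "numeric", complexity = "numeric",
                 fitFraction = "numeric", iterations = "integer",
                 converged = "logical", Ftrace = "numeric",
                 priors = "data.frame", details = "list"))

setValidity("InversionResult", function(object) {
  msg <- character(0)
  if (length(object@complexity) == 1 && object@complexity < -1e-8)
    msg <- c(msg, "complexity term must be >= 0")
  if (length(object@freeEnergy) == 1 &&
      abs(object@freeEnergy - (object@accuracy - object@complexity)) > 1e-8)
    msg <- c(msg, "free energy must equal accuracy - complexity")
  p <- length(object@posteriorMean)
  if (p > 0) {
    if (!all(dim(object@posteriorCov) == c(p, p)))
      msg <- c(msg, "posterior covariance must be p x p")
    else if (max(abs(object@posteriorCov - t(object@posteriorCov))) > 1e-8)
      msg <- c(msg, "posterior covariance must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' Fixed-effects Bayesian model selection result
#'
#' @slot modelIds model identifiers.
#' @slot freeEnergies free energy per model.
#' @slot relativeF free energy relative to the best model (best = 0).
#' @slot posteriorProbs softmax model posterior probabilities.
#' @exportClass BMSResult
setClass("BMSResult",
  representation(modelIds = "character", freeEnergies = "numeric",
                 relativeF = "numeric", posteriorProbs = "numeric"))

setValidity("BMSResult", function(object) {
  msg <- character(0)
  if (abs(sum(object@posteriorProbs) - 1) > 1e-12)
    msg <- c(msg, "posterior probabilities must sum to 1")
  if (length(object@relativeF) && max(object@relativeF) != 0)
    msg <- c(msg, "best model must have relative F of 0")
  if (length(msg)) msg else TRUE
})

#' Bayesian model averaging result
#'
#' Evidence-weighted mixture of per-model Gaussian posteriors, summarized by
#' seeded Monte-Carlo draws over the union parameter set. Parameters
#' switched off in a model contribute their prior mean under that model's
#' weight.
#'
#' @slot parameters union parameter names.
#' @slot mean,sd Monte-Carlo mixture mean and spread per parameter.
#' @slot draws draws x parameters matrix of mixture samples.
#' @slot weights model weights used (the BMS posterior probabilities).
#' @exportClass BMAResult
setClass("BMAResult",
  representation(parameters = "character", mean = "numeric", sd = "numeric",
                 draws = "matrix", weights = "numeric"))

#' Parametric-empirical-Bayes group result
#'
#' Posterior over group-level effects (a mean regressor and a standardized
#' behavioural covariate regressor) on subject-level connectivity
#' parameters, with the model free energy, and after reduction the retained
#' effects and their posterior probabilities.
#'
#' @slot parameters first-level parameter names (p of them).
#' @slot betaMean 2 x p matrix of group effects (rows mean/covariate).
#' @slot betaCov 2p x 2p posterior covariance of vec(beta) (parameter-major
#'   within regressor).
#' @slot freeEnergy PEB free energy at the optimized random-effect
#'   precision.
#' @slot logLambda optimized log random-effect precision.
#' @slot priorVar prior variances of the group effects (length 2: mean,
#'   covariate).
#' @slot probEffect posterior probability of a nonzero covariate effect per
#'   parameter (filled by reduction).
#' @slot retained names of parameters whose covariate effect survives
#'   reduction.
#' @slot details list (design matrix, subject ids, reduction path).
#' @exportClass PEBResult
setClass("PEBResult",
  representation(parameters = "character", betaMean = "matrix",
                 betaCov = "matrix", freeEnergy = "numeric",
                 logLambda = "numeric", priorVar = "numeric",
                 probEffect = "numeric", retained = "character",
                 details = "list"))

setValidity("PEBResult", function(object) {
  msg <- character(0)
  if (!all(object@retained %in% object@parameters))
    msg <- c(msg, "retained must be a subset of the parameter set")
  pe <- object@probEffect
  if (length(pe) && (any(pe <= 0) || any(pe >= 1)))
    msg <- c(msg, "effect probabilities must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Subject-level record for the group stage
#'
#' A subject's first-level posterior (over the winning model's parameters)
#' together with their behavioural pain-modulation score
#' (attended-minus-unattended mean pain rating, VAS units).
#'
#' @slot subjectId subject identifier.
#' @slot mean named posterior mean over first-level parameters.
#' @slot cov posterior covariance.
#' @slot ratingModulation attended minus unattended mean pain rating.
#' @exportClass SubjectRecord
setClass("SubjectRecord",
  representation(subjectId = "character", mean = "numeric", cov = "matrix",
                 ratingModulation = "numeric"))

setValidity("SubjectRecord", function(object) {
  p <- length(object@mean)
  if (!all(dim(object@cov) == c(p, p)))
    return("posterior covariance must match the parameter dimension")
  TRUE
})
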