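## Fixed-effects Bayesian model selection over free energies and Bayesian
## model averaging of Gaussian posteriors.

#' Fixed-effects Bayesian model selection
#'
#' Softmax of the free energies: the posterior probability of model i is
#' \eqn{\exp(F_i - \max F) / \sum_j \exp(F_j - \max F)}, invariant to
#' adding a constant to all free energies. For multi-subject fixed-effects
#' comparison, pass group free energies (sums over subjects).
#'
#' @param results list of [InversionResult-class] objects, or a numeric
#'   vector of free energies.
#' @param modelIds optional model identifiers.
#' @return a [BMSResult-class].
#' @export
ffxBMS <- function(results, modelIds = NULL) {
  Fvec <- if (is.numeric(results)) results
          else vapply(results, freeEnergy, 0)
  if (length(Fvec) < 2)
    stop("need at least two models to compare", call. = FALSE)
  if (any(!is.finite(Fvec)))
    stop("non-finite free energy for model ",
         paste(which(!is.finite(Fvec)), collapse = ", "), call. = FALSE)
  if (is.null(modelIds)) modelIds <- names(Fvec) %||%
      paste0("M", seq_along(Fvec))
  rel <- Fvec - max(Fvec)
  pp <- exp(rel) / sum(exp(rel))
  pp <- pp / sum(pp)
  new("BMSResult", modelIds = as.character(modelIds),
      freeEnergies = unname(Fvec), relativeF = unname(rel),
      posteriorProbs = unname(pp))
}

setMethod("show", "BMSResult", function(object) {
  cat("BMSResult (fixed effects,", length(object@modelIds), "models)\n")
  df <- data.frame(model = object@modelIds, F = object@freeEnergies,
                   dF = object@relativeF, prob = object@posteriorProbs)
  print(head(df[order(-df$prob), ], 5), row.names = FALSE, digits = 4)
})

#' @describeIn ffxBMS model posterior probabilities.
#' @param object a \code{BMSResult}.
#' @export
posteriorProbs <- function(object)
  setNames(object@posteriorProbs, object@modelIds)

#' Write a model-comparison leaderboard as CSV
#'
#' @param bms a [BMSResult-class].
#' @param file output path.
#' @export
writeLeaderboard <- function(bms, file) {
  df <- data.frame(model = bms@modelIds, F = bms@freeEnergies,
                   deltaF = bms@relativeF, prob = bms@posteriorProbs)
  write.csv(df[order(-df$prob), ], file, row.names = FALSE)
  invisible(file)
}

#' Bayesian model averaging
#'
#' Evidence-weighted mixture of the per-model Gaussian posteriors,
#' summarized by seeded Monte-Carlo draws over the union of all model
#' parameter sets. Each draw first samples a model according to its BMS
#' posterior probability and then a parameter vector from that model's
#' posterior; parameters switched off in the sampled model take their
#' prior mean (zero).
#'
#' @param results list of [InversionResult-class] objects.
#' @param bms matching [BMSResult-class].
#' @param nSamples number of Monte-Carlo draws (default 1e4).
#' @param seed RNG seed.
#' @return a [BMAResult-class].
#' @export
bma <- function(results, bms = NULL, nSamples = 1e4, seed = 1L) {
  if (is.null(bms)) bms <- ffxBMS(results)
  if (length(results) != length(bms@modelIds))
    stop("results do not align with the BMS result", call. = FALSE)
  pars <- unique(unlist(lapply(results, function(r) r@priors$name)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  w <- bms@posteriorProbs
  pick <- sample.int(length(results), nSamples, replace = TRUE, prob = w)
  draws <- matrix(0, nSamples, length(pars),
                  dimnames = list(NULL, pars))
  for (m in seq_along(results)) {
    rows <- which(pick == m)
    if (!length(rows)) next
    r <- results[[m]]
    pm <- r@posteriorMean
    if (length(pm)) {
      S <- r@posteriorCov
      ev <- eigen(S, symmetric = TRUE)
      rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
      z <- matrix(rnorm(length(rows) * length(pm)), length(rows))
      draws[rows, names(pm)] <-
        sweep(z %*% rt, 2, pm, "+")
    }
  }
  new("BMAResult", parameters = pars, mean = colMeans(draws),
      sd = apply(draws, 2, sd), draws = draws, weights = w)
}

setMethod("show", "BMAResult", function(object) {
  cat("BMAResult:", length(object@parameters), "parameters,",
      nrow(object@draws), "Monte-Carlo draws over",
      length(object@weights), "models\n")
})

#' Flag parameters with decisive posterior sign
#'
#' Flags parameters whose mixture mass on one side of zero exceeds the
#' threshold, reporting the sign (a negative gain modulation is
#' disinhibition, i.e. increased superficial-pyramidal gain).
#'
#' @param bmaResult a [BMAResult-class].
#' @param threshold posterior probability threshold in (0, 1); the
#'   convention for decisive effects is 0.99.
#' @return data.frame with columns parameter, probability, sign, mean for
#'   the flagged parameters.
#' @export
significantParameters <- function(bmaResult, threshold = 0.99) {
  stopifnot(threshold > 0, threshold < 1)
  n <- nrow(bmaResult@draws)
  # continuity correction: a finite sample never yields probability 1
  pPos <- colSums(bmaResult@draws > 0) / (n + 1)
  pNeg <- colSums(bmaResult@draws < 0) / (n + 1)
  pr <- pmax(pPos, pNeg)
  keep <- pr > threshold
  data.frame(parameter = bmaResult@parameters[keep],
             probability = unname(pr[keep]),
             sign = ifelse(pPos[keep] >= pNeg[keep], 1, -1),
             mean = unname(bmaResult@mean[keep]),
             stringsAsFactors = FALSE)
}
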