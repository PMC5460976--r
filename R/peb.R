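## Parametric empirical Bayes over subject-level posteriors: a
## between-subject GLM (group mean + standardized behavioural covariate)
## on connectivity parameters, Bayesian model reduction to prune
## covariate effects, and leave-one-out cross-validated prediction of the
## covariate.

#' Construct a subject record
#'
#' @param subjectId identifier.
#' @param mean named first-level posterior mean.
#' @param cov first-level posterior covariance.
#' @param ratingModulation attended-minus-unattended mean pain rating (VAS
#'   units).
#' @return a [SubjectRecord-class].
#' @export
subjectRecord <- function(subjectId, mean, cov, ratingModulation) {
  new("SubjectRecord", subjectId = as.character(subjectId), mean = mean,
      cov = as.matrix(cov), ratingModulation = ratingModulation)
}

setMethod("show", "SubjectRecord", function(object) {
  cat("SubjectRecord", object@subjectId, ":", length(object@mean),
      "parameters, rating modulation", round(object@ratingModulation, 3),
      "\n")
})

#' Build a subject record from an inversion result and a rating
#'
#' @param subjectId identifier.
#' @param fit an [InversionResult-class] (the subject's fit of the winning
#'   model).
#' @param ratingModulation behavioural covariate value.
#' @export
subjectRecordFromFit <- function(subjectId, fit, ratingModulation) {
  subjectRecord(subjectId, posteriorMean(fit), posteriorCov(fit),
                ratingModulation)
}

#' Between-subject design matrix
#'
#' Column 1 models the mean connection strength across subjects; column 2
#' is the Z-scored pain-modulation covariate.
#'
#' @param records list of [SubjectRecord-class] objects.
#' @return n x 2 design matrix.
#' @export
pebDesign <- function(records) {
  cv <- vapply(records, function(r) r@ratingModulation, 0)
  s <- sd(cv)
  z <- if (s > 0) (cv - mean(cv)) / s else cv * 0
  X <- cbind(mean = 1, covariate = z)
  rownames(X) <- vapply(records, function(r) r@subjectId, "")
  X
}

# log evidence (and beta posterior) of the PEB model at a given log
# random-effect precision
.pebEvidence <- function(M, Slist, X, priorVarBeta, logLambda) {
  n <- nrow(M); p <- ncol(M); q <- ncol(X)
  Vb0 <- rep(priorVarBeta, each = p)            # vec(beta), regressor-major
  Pb0 <- diag(1 / Vb0, p * q)
  AtVA <- matrix(0, p * q, p * q)
  AtVy <- numeric(p * q)
  quad <- 0; logdetV <- 0
  lamI <- diag(exp(-logLambda), p)
  for (i in seq_len(n)) {
    Vi <- Slist[[i]] + lamI
    cVi <- chol(Vi)
    logdetV <- logdetV + 2 * sum(log(diag(cVi)))
    Wi <- chol2inv(cVi)
    xi <- X[i, ]
    AtVA <- AtVA + kronecker(tcrossprod(xi), Wi)
    AtVy <- AtVy + kronecker(xi, Wi %*% M[i, ])
    quad <- quad + drop(M[i, ] %*% Wi %*% M[i, ])
  }
  Pb <- Pb0 + AtVA
  cPb <- chol(Pb)
  mu <- backsolve(cPb, forwardsolve(t(cPb), AtVy))
  logEv <- -0.5 * (quad - sum(AtVy * mu) + logdetV +
                   sum(log(Vb0)) + 2 * sum(log(diag(cPb))) +
                   n * p * log(2 * pi))
  list(logEv = logEv, mu = mu, Pb = Pb, Vb0 = Vb0)
}

#' Fit the parametric-empirical-Bayes group model
#'
#' Treats each subject's first-level posterior (mean and covariance) as
#' data with known uncertainty and estimates Gaussian group effects (one
#' per regressor per parameter) with a single log-precision random-effect
#' hyperparameter, optimized against the model evidence under a
#' weakly-informative gamma-form hyperprior.
#'
#' @param records list of [SubjectRecord-class] objects (>= 3 subjects, all
#'   sharing the same parameter dimension).
#' @param X between-subject design (default [pebDesign()]: mean +
#'   standardized covariate). Must be full rank.
#' @param priorVarBeta prior variances of the group effects, one per
#'   regressor (default 1 for the mean, 1/4 for the covariate).
#' @param hyperA,hyperB gamma-form hyperprior weights on the log
#'   random-effect precision.
#' @return a [PEBResult-class].
#' @export
pebFit <- function(records, X = pebDesign(records),
                   priorVarBeta = c(1, 1 / 4),
                   hyperA = 1 / 16, hyperB = 1 / 16) {
  n <- length(records)
  if (n < 3) stop("data error: need at least 3 subjects", call. = FALSE)
  pnames <- names(records[[1]]@mean)
  p <- length(pnames)
  if (!all(vapply(records, function(r) length(r@mean) == p, TRUE)))
    stop("data error: subjects have differing parameter dimensions",
         call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design error: between-subject design is rank deficient",
         call. = FALSE)
  if (length(priorVarBeta) != ncol(X))
    priorVarBeta <- rep_len(priorVarBeta, ncol(X))
  M <- do.call(rbind, lapply(records, function(r) unname(r@mean)))
  Slist <- lapply(records, function(r) r@cov)
  obj <- function(l) .pebEvidence(M, Slist, X, priorVarBeta, l)$logEv +
    hyperA * l - hyperB * exp(l)
  opt <- optimize(obj, c(-8, 8), maximum = TRUE, tol = 1e-4)
  fit <- .pebEvidence(M, Slist, X, priorVarBeta, opt$maximum)
  betaMean <- matrix(fit$mu, ncol(X), p, byrow = TRUE,
                     dimnames = list(colnames(X), pnames))
  Vb <- chol2inv(chol(fit$Pb))
  new("PEBResult", parameters = pnames, betaMean = betaMean,
      betaCov = (Vb + t(Vb)) / 2, freeEnergy = opt$objective,
      logLambda = opt$maximum, priorVar = priorVarBeta,
      probEffect = numeric(0), retained = character(0),
      details = list(X = X, M = M, Slist = Slist,
                     subjects = vapply(records,
                                       function(r) r@subjectId, ""),
                     hyper = c(hyperA, hyperB)))
}

setMethod("show", "PEBResult", function(object) {
  cat("PEBResult:", length(object@parameters), "parameters,",
      nrow(object@details$X), "subjects, F =",
      round(object@freeEnergy, 2), "\n")
  if (length(object@retained))
    cat("  retained covariate effects:",
        paste(object@retained, collapse = ", "), "\n")
})

# analytic log-evidence change and reduced posterior when the prior
# variances of a subset of effects are shrunk to (near) zero
.bmrReduce <- function(mu, Sigma, v0, off, offVar = 1e-8) {
  pq <- length(mu)
  v0r <- v0
  v0r[off] <- offVar
  P <- chol2inv(chol(Sigma))
  P0 <- diag(1 / v0, pq)
  P0r <- diag(1 / v0r, pq)
  Pr <- P + P0r - P0
  cPr <- tryCatch(chol(Pr), error = function(e) NULL)
  if (is.null(cPr)) return(list(dF = -Inf))
  w <- P %*% mu
  mur <- backsolve(cPr, forwardsolve(t(cPr), w))
  # 0.5 [ logdet(P) - logdet(Pr) + logdet(P0r) - logdet(P0) ]
  #   + 0.5 [ mur' Pr mur - mu' P mu ]
  dF <- 0.5 * (2 * sum(log(diag(chol(P)))) - 2 * sum(log(diag(cPr))) +
               sum(log(v0)) - sum(log(v0r))) +
        0.5 * (sum(mur * (Pr %*% mur)) - sum(mu * (P %*% mu)))
  list(dF = drop(dF), mu = drop(mur), Sigma = chol2inv(cPr))
}

#' Prune group effects by Bayesian model reduction
#'
#' Greedy bidirectional search over on/off patterns of the covariate
#' effects, scored by the reduced free energy computed analytically from
#' the full posterior (no refitting). After the search, each effect's
#' posterior probability of being nonzero is the logistic of the
#' free-energy change of toggling it from the final pattern; effects with
#' probability above the threshold are retained.
#'
#' @param peb a [PEBResult-class] from [pebFit()].
#' @param threshold retention probability threshold (default 0.95).
#' @param exhaustive search all on/off patterns instead of greedily (only
#'   for 16 or fewer effects).
#' @return the reduced [PEBResult-class] with \code{retained} and
#'   \code{probEffect} filled in.
#' @export
bmrPrune <- function(peb, threshold = 0.95, exhaustive = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  p <- length(peb@parameters)
  q <- nrow(peb@betaMean)
  mu <- as.vector(t(peb@betaMean)) # regressor-major: mean block then cov
  v0 <- rep(peb@priorVar, each = p)
  Sigma <- peb@betaCov
  covIdx <- p + seq_len(p) # covariate-effect block
  score <- function(offMask)
    .bmrReduce(mu, Sigma, v0, covIdx[offMask])$dF
  if (exhaustive) {
    if (p > 16) stop("exhaustive search limited to 16 effects",
                     call. = FALSE)
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
    dFs <- apply(masks, 1, function(m) score(as.logical(m)))
    best <- as.logical(masks[which.max(dFs), ])
  } else {
    best <- rep(FALSE, p) # start from the full model (nothing off)
    repeat {
      dF0 <- score(best)
      cand <- lapply(seq_len(p), function(k) {
        m <- best; m[k] <- !m[k]; m
      })
      dFs <- vapply(cand, score, 0)
      if (max(dFs) > dF0 + 1e-8) best <- cand[[which.max(dFs)]]
      else break
    }
  }
  # per-effect posterior probability: toggle each effect off/on from the
  # final pattern
  prob <- numeric(p)
  for (k in seq_len(p)) {
    mOn <- best; mOn[k] <- FALSE
    mOff <- best; mOff[k] <- TRUE
    dOn <- score(mOn); dOff <- score(mOff)
    prob[k] <- 1 / (1 + exp(dOff - dOn))
  }
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  red <- .bmrReduce(mu, Sigma, v0, covIdx[best])
  retained <- peb@parameters[!best & prob > threshold]
  out <- peb
  out@betaMean <- matrix(red$mu, q, p, byrow = TRUE,
                         dimnames = dimnames(peb@betaMean))
  out@betaCov <- (red$Sigma + t(red$Sigma)) / 2
  out@freeEnergy <- peb@freeEnergy + red$dF
  out@probEffect <- setNames(prob, peb@parameters)
  out@retained <- retained
  out@details$offPattern <- best
  out
}

#' Leave-one-out cross-validated covariate prediction
#'
#' For each left-out subject the PEB model is refitted on the remaining
#' subjects; the left-out subject's covariate is predicted by regressing
#' their first-level posterior means onto the group mapping restricted to
#' the retained effects (least-squares inversion of
#' \eqn{m \approx \beta_{mean} + x \beta_{cov}}). Returns the Pearson
#' correlation between predicted and observed covariates.
#'
#' @param records list of [SubjectRecord-class] objects (>= 4).
#' @param retained names of parameters whose covariate effect is used for
#'   prediction (e.g. from [bmrPrune()]); default all.
#' @param priorVarBeta,hyperA,hyperB passed to [pebFit()].
#' @return list with \code{correlation}, and a data.frame \code{pairs}
#'   (subject, observed, predicted, both on the training z-scale).
#' @export
looCV <- function(records, retained = NULL, priorVarBeta = c(1, 1 / 4),
                  hyperA = 1 / 16, hyperB = 1 / 16) {
  n <- length(records)
  if (n < 4) stop("need at least 4 subjects for leave-one-out",
                  call. = FALSE)
  cv <- vapply(records, function(r) r@ratingModulation, 0)
  if (sd(cv) == 0)
    return(list(correlation = NA_real_,
                pairs = data.frame(subject = character(0)),
                note = "constant covariate: correlation undefined"))
  if (is.null(retained)) retained <- names(records[[1]]@mean)
  pred <- obs <- numeric(n)
  for (i in seq_len(n)) {
    train <- records[-i]
    Xt <- pebDesign(train)
    fit <- pebFit(train, Xt, priorVarBeta, hyperA, hyperB)
    sel <- match(retained, fit@parameters)
    sel <- sel[!is.na(sel)]
    b1 <- fit@betaMean["mean", sel]
    b2 <- fit@betaMean["covariate", sel]
    mj <- unname(records[[i]]@mean)[sel]
    denom <- sum(b2^2)
    pred[i] <- if (denom > 0) sum(b2 * (mj - b1)) / denom else 0
    # observed covariate on the training z-scale
    mu <- mean(vapply(train, function(r) r@ratingModulation, 0))
    s <- sd(vapply(train, function(r) r@ratingModulation, 0))
    obs[i] <- (cv[i] - mu) / s
  }
  list(correlation = if (sd(pred) > 0) cor(pred, obs) else NA_real_,
       pairs = data.frame(
         subject = vapply(records, function(r) r@subjectId, ""),
         observed = obs, predicted = pred, stringsAsFactors = FALSE))
}

#' Write group-stage outputs as CSV
#'
#' @param peb a [PEBResult-class].
#' @param file output path.
#' @export
writePEB <- function(peb, file) {
  df <- data.frame(parameter = peb@parameters,
                   groupMean = peb@betaMean["mean", ],
                   covariateEffect = peb@betaMean["covariate", ],
                   probEffect = if (length(peb@probEffect))
                     unname(peb@probEffect) else NA_real_,
                   retained = peb@parameters %in% peb@retained)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
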