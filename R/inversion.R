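## Variational-Laplace inversion of a dynamic causal model: log-scale
## parameterization with Gaussian priors, Gauss-Newton ascent on the
## Laplace free energy with Levenberg-Marquardt regularization, and a
## single log-precision observation-noise hyperparameter.

.regionOf <- function(source) sub("^[lr]", "", source)
.hemiOf <- function(source) substr(source, 1, 1)

#' Prior specification and parameter map for a DCM
#'
#' Builds the log-scale parameter vector of a dynamic causal model:
#' log-scaling parameters on the baseline quantities (extrinsic connection
#' strengths, superficial-pyramidal self-inhibition gains, input gain,
#' input amplitude and latency) plus additive log-scale modulatory (B)
#' parameters defined by an attention model and an expectation-violation
#' model. Model identity is encoded through the prior variances: parameters
#' absent from a model are switched off (variance exactly 0) and fixed at
#' their prior mean.
#'
#' Modulatory effects are tied across hemispheres (one parameter per
#' region and factor, applied to the homologous entries), matching the
#' convention that contextual effects operate on homologous connections in
#' each hemisphere; the contralateral scope routes the left-violation
#' factor onto right-hemisphere sites and vice versa.
#'
#' Default prior variances: extrinsic 1/8, intrinsic gain 1/16, modulatory
#' 1/4, input amplitude 1/8; input latency is parameterized in units of its
#' 16 ms prior standard deviation (unit prior variance).
#'
#' @param params baseline [CMCParameters-class] (nonzero AF/AB entries
#'   define the architecture).
#' @param attModel,evModel \code{cmcModulationModel} objects (or NULL).
#' @param factors contextual factor labels the conditions use.
#' @param fit which baseline parameter groups are free: subset of
#'   "extrinsic", "intrinsic", "input".
#' @param priorVar named overrides of the group prior variances
#'   (extrinsic, intrinsic, modulatory, input).
#' @return data.frame (name, type, mean, var) with attribute \code{map}
#'   describing the target entries of each parameter.
#' @export
buildPriors <- function(params, attModel = NULL, evModel = NULL,
                        factors = c("attention", "leftEV", "rightEV"),
                        fit = c("extrinsic", "intrinsic", "input"),
                        priorVar = c()) {
  pv <- c(extrinsic = 1 / 8, intrinsic = 1 / 16, modulatory = 1 / 4,
          input = 1 / 8)
  pv[names(priorVar)] <- priorVar
  src <- params@sources
  rows <- list(); map <- list()
  addPar <- function(name, type, var, target) {
    rows[[name]] <<- data.frame(name = name, type = type, mean = 0,
                                var = var, stringsAsFactors = FALSE)
    map[[name]] <<- target
  }
  # baseline extrinsic scales, tied over homologous entries
  for (mat in c("AF", "AB")) {
    M <- slot(params, mat)
    idx <- which(M > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      key <- paste0(sub("A", "", mat), ".", .regionOf(src[idx[, 1]]), ".",
                    .regionOf(src[idx[, 2]]))
      for (k in unique(key)) {
        sel <- idx[key == k, , drop = FALSE]
        addPar(paste0("A.", k), "extrinsic",
               if ("extrinsic" %in% fit) pv["extrinsic"] else 0,
               list(kind = mat, entries = sel))
      }
    }
  }
  # intrinsic superficial-pyramidal gain per source
  for (i in seq_along(src))
    addPar(paste0("G.", src[i]), "intrinsic",
           if ("intrinsic" %in% fit) pv["intrinsic"] else 0,
           list(kind = "G", sources = i))
  # input gain, amplitude, latency
  addPar("C", "input", if ("input" %in% fit) pv["input"] else 0,
         list(kind = "C"))
  addPar("u.amp", "input", if ("input" %in% fit) pv["input"] else 0,
         list(kind = "amp"))
  addPar("u.lat", "input", if ("input" %in% fit) 1 else 0,
         list(kind = "lat"))
  # modulatory gain parameters from the two factor models
  addGainMod <- function(model, factorName, hemiRule) {
    if (is.null(model)) return()
    for (reg in names(model$scope)) {
      scope <- model$scope[[reg]]
      if (scope == "none") next
      hemis <- hemiRule(scope)
      tgt <- which(src %in% paste0(hemis, reg))
      if (!length(tgt)) next
      addPar(paste0("B.", factorName, ".G.", reg), "modulatory",
             pv["modulatory"],
             list(kind = "BG", factor = factorName, sources = tgt))
    }
  }
  if ("attention" %in% factors)
    addGainMod(attModel, "attention", function(s) c("l", "r"))
  if ("leftEV" %in% factors)
    addGainMod(evModel, "leftEV",
               function(s) if (s == "contralateral") "r" else c("l", "r"))
  if ("rightEV" %in% factors)
    addGainMod(evModel, "rightEV",
               function(s) if (s == "contralateral") "l" else c("l", "r"))
  # recurrent extrinsic modulation by expectation violation
  if (!is.null(evModel) && isTRUE(evModel$extrinsic)) {
    for (fac in intersect(c("leftEV", "rightEV"), factors)) {
      for (mat in c("AF", "AB")) {
        M <- slot(params, mat)
        idx <- which(M > 0, arr.ind = TRUE)
        if (!nrow(idx)) next
        key <- paste0(sub("A", "", mat), ".", .regionOf(src[idx[, 1]]),
                      ".", .regionOf(src[idx[, 2]]))
        for (k in unique(key)) {
          sel <- idx[key == k, , drop = FALSE]
          addPar(paste0("B.", fac, ".", k), "modulatory",
                 pv["modulatory"],
                 list(kind = if (mat == "AF") "BF" else "BB",
                      factor = fac, entries = sel))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "map") <- map
  out
}

#' Assemble a dynamic causal model for inversion
#'
#' Bundles the generative-model ingredients — baseline network parameters,
#' lead field, exogenous input, condition designs and the prior
#' specification implied by an (attention, expectation-violation) model
#' pair — into a fit-ready object.
#'
#' @inheritParams buildPriors
#' @param leadfield a [LeadField-class].
#' @param designs condition designs from [conditionSet()].
#' @param input prior [ExogenousInput-class].
#' @param tGrid prediction time grid (ms), default [erfTimeGrid()].
#' @param dt integration step (ms).
#' @return object of class \code{dcmModel}.
#' @export
dcmModel <- function(params, leadfield, designs,
                     input = exogenousInput(), attModel = NULL,
                     evModel = NULL, fit = c("extrinsic", "intrinsic",
                                             "input"),
                     priorVar = c(), tGrid = erfTimeGrid(), dt = 1) {
  factors <- names(designs[[1]]$x)
  priors <- buildPriors(params, attModel, evModel, factors = factors,
                        fit = fit, priorVar = priorVar)
  structure(list(params = params, leadfield = leadfield,
                 designs = designs, input = input, factors = factors,
                 priors = priors, map = attr(priors, "map"),
                 tGrid = tGrid, dt = dt,
                 attId = if (is.null(attModel)) NA else attModel$id,
                 evId = if (is.null(evModel)) NA else evModel$id),
            class = "dcmModel")
}

#' @export
print.dcmModel <- function(x, ...) {
  cat("dcmModel:", nSources(x$params), "sources,", length(x$designs),
      "conditions,", sum(x$priors$var > 0), "free parameters (of",
      nrow(x$priors), ")\n")
  invisible(x)
}

# materialize effective parameters, modulation set and input from a full
# parameter vector (named over all declared parameters)
.applyTheta <- function(model, theta) {
  p <- model$params
  input <- model$input
  mod <- modulationSet(p@sources, model$factors)
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (v == 0) next
    tg <- model$map[[nm]]
    switch(tg$kind,
      AF = { p@AF[tg$entries] <- p@AF[tg$entries] * exp(v) },
      AB = { p@AB[tg$entries] <- p@AB[tg$entries] * exp(v) },
      G = { p@gamma["SP_SP", tg$sources] <-
              p@gamma["SP_SP", tg$sources] * exp(v) },
      C = { p@C <- p@C * exp(v) },
      amp = { input@amplitude <- input@amplitude * exp(v) },
      lat = { input@latencyMs <- input@latencyMs + 16 * v },
      BG = { mod@BG[tg$sources, tg$factor] <-
               mod@BG[tg$sources, tg$factor] + v },
      BF = { mod@BF[[tg$factor]][tg$entries] <-
               mod@BF[[tg$factor]][tg$entries] + v },
      BB = { mod@BB[[tg$factor]][tg$entries] <-
               mod@BB[[tg$factor]][tg$entries] + v })
  }
  list(params = p, mod = mod, input = input)
}

# full named parameter vector from free-subvector
.fullTheta <- function(model, thetaFree) {
  th <- setNames(rep(0, nrow(model$priors)), model$priors$name)
  th[names(thetaFree)] <- thetaFree
  th
}

#' Model prediction at a parameter vector
#'
#' Deterministically maps a (log-scale) parameter vector through the
#' generative model: exponentiate scales onto the baseline, integrate the
#' network per condition, project superficial-pyramidal voltages through
#' the lead field and optionally onto stored spatial modes.
#'
#' @param model a \code{dcmModel}.
#' @param theta named parameter vector (entries default to the prior mean
#'   0; switched-off parameters are ignored).
#' @param projection optional sensors x modes projection matrix from
#'   [reduceData()].
#' @return condition x channel x time array, or NULL (with a warning) if
#'   the integration diverged.
#' @export
dcmPredict <- function(model, theta = NULL, projection = NULL) {
  th <- .fullTheta(model, theta %||% numeric(0))
  off <- model$priors$var == 0
  th[off] <- 0 # switched-off parameters stay at the prior mean
  eff <- .applyTheta(model, th)
  inputFn <- function(t) gaussianInput(t, eff$input)
  nC <- length(model$designs)
  L <- model$leadfield@gain
  if (!is.null(projection)) L <- t(projection) %*% L
  out <- array(0, dim = c(nC, nrow(L), length(model$tGrid)),
               dimnames = list(names(model$designs), NULL, NULL))
  for (ci in seq_len(nC)) {
    d <- model$designs[[ci]]
    V <- tryCatch(
      integrateCMC(eff$params, model$tGrid, inputFn, mod = eff$mod,
                   x = d$x, inputSources = d$inputSources, dt = model$dt),
      cmcDivergence = function(e) NULL)
    if (is.null(V)) {
      warning("prediction diverged; returning NULL", call. = FALSE)
      return(NULL)
    }
    out[ci, , ] <- L %*% V["SP", , ]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project an evoked-field dataset onto principal spatial modes
#'
#' Singular-value decomposition of the pooled condition data over sensors;
#' the top \code{nModes} left singular vectors define the spatial modes the
#' inversion is performed in. \code{nModes} equal to the sensor count is
#' lossless. A degenerate (rank-deficient) pooled covariance falls back to
#' the available rank with a warning.
#'
#' @param erf an [ERFDataset-class].
#' @param nModes number of spatial modes (1 to sensor count).
#' @return list with the reduced array \code{Y} (condition x mode x time),
#'   the \code{projection} (sensors x modes), the fraction of
#'   \code{varianceExplained}, and the time base.
#' @export
reduceData <- function(erf, nModes) {
  d <- dim(erf@data)
  stopifnot(nModes >= 1, nModes <= d[2])
  X <- matrix(aperm(erf@data, c(2, 1, 3)), d[2], d[1] * d[3])
  sv <- svd(X)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < nModes) {
    warning("pooled data rank ", rank, " below requested modes ", nModes,
            "; using ", rank, " modes", call. = FALSE)
    nModes <- rank
  }
  U <- sv$u[, seq_len(nModes), drop = FALSE]
  Y <- array(0, dim = c(d[1], nModes, d[3]))
  for (ci in seq_len(d[1]))
    Y[ci, , ] <- t(U) %*% erf@data[ci, , ]
  list(Y = Y, projection = U,
       varianceExplained = sum(sv$d[seq_len(nModes)]^2) / sum(sv$d^2),
       timeMs = erf@timeMs, conditionLabels = erf@conditionLabels)
}

#' Options for variational-Laplace inversion
#'
#' @param nModes spatial modes to invert in (default 8).
#' @param maxit maximum optimizer iterations (default 64).
#' @param tolF convergence tolerance on consecutive free-energy increments
#'   (default 0.05 nats over \code{tolCount} consecutive iterations).
#' @param tolCount consecutive small increments required (default 3).
#' @param fdStep forward finite-difference step on the log scale.
#' @param hyperA,hyperB gamma-form hyperprior weights on the log
#'   observation precision.
#' @export
vlOptions <- function(nModes = 8, maxit = 64, tolF = 0.05, tolCount = 3,
                      fdStep = 1e-3, hyperA = 1 / 32, hyperB = 1 / 32) {
  list(nModes = nModes, maxit = maxit, tolF = tolF, tolCount = tolCount,
       fdStep = fdStep, hyperA = hyperA, hyperB = hyperB)
}

# free energy, accuracy/complexity split and posterior covariance at a
# given residual, Jacobian, parameter value and log precision
.vlFreeEnergy <- function(e, J, dth0, v0, lam, opts) {
  N <- length(e); p <- length(dth0)
  h <- exp(lam)
  hyp <- opts$hyperA * lam - opts$hyperB * h
  if (p == 0) {
    acc <- -0.5 * h * sum(e^2) + 0.5 * N * lam - 0.5 * N * log(2 * pi) +
      hyp
    return(list(F = acc, accuracy = acc, complexity = 0,
                Sigma = matrix(0, 0, 0)))
  }
  JJ <- crossprod(J)
  P <- h * JJ + diag(1 / v0, p)
  Sigma <- tryCatch(solve(P), error = function(e) NULL)
  if (is.null(Sigma)) return(list(F = -Inf))
  Sigma <- (Sigma + t(Sigma)) / 2
  trSJJ <- sum(Sigma * JJ)
  acc <- -0.5 * h * (sum(e^2) + trSJJ) + 0.5 * N * lam -
    0.5 * N * log(2 * pi) + hyp
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(F = -Inf))
  logdetSigma <- 2 * sum(log(diag(ch)))
  trP0S <- sum(diag(Sigma) / v0)
  quad <- sum(dth0^2 / v0)
  comp <- 0.5 * (trP0S + quad - p + sum(log(v0)) - logdetSigma)
  list(F = acc - comp, accuracy = acc, complexity = comp, Sigma = Sigma)
}

#' Fit a DCM by variational Laplace
#'
#' Gauss-Newton ascent on the Laplace free energy with
#' Levenberg-Marquardt regularization, alternating parameter updates with
#' a 1-D optimization of the observation log-precision hyperparameter.
#' Rejected steps shrink the trust region; the best-F iterate is returned.
#' The free energy decomposes as accuracy minus complexity, the complexity
#' being the KL divergence from the prior to the Gaussian posterior.
#'
#' @param erf an [ERFDataset-class] covering the model's conditions.
#' @param model a \code{dcmModel}.
#' @param opts options from [vlOptions()].
#' @return an [InversionResult-class].
#' @export
fitVL <- function(erf, model, opts = vlOptions()) {
  stopifnot(all(names(model$designs) %in% erf@conditionLabels))
  red <- reduceData(erf, min(opts$nModes, dim(erf@data)[2]))
  # align condition order with the model's designs
  ord <- match(names(model$designs), red$conditionLabels)
  y <- as.vector(red$Y[ord, , , drop = FALSE])
  N <- length(y)
  free <- model$priors[model$priors$var > 0, , drop = FALSE]
  p <- nrow(free)
  v0 <- free$var
  fd <- opts$fdStep
  predictVec <- function(thf) {
    a <- dcmPredict(model, setNames(thf, free$name),
                    projection = red$projection)
    if (is.null(a)) NULL else as.vector(a)
  }
  jacobian <- function(thf, g0) {
    J <- matrix(0, N, p)
    for (k in seq_len(p)) {
      thk <- thf
      thk[k] <- thk[k] + fd
      gk <- predictVec(thk)
      if (!is.null(gk)) J[, k] <- (gk - g0) / fd
    }
    J
  }
  th <- rep(0, p)
  g <- predictVec(th)
  if (is.null(g))
    stop("inversion error: model diverges at the prior mean",
         call. = FALSE)
  lamBest <- 0
  Fbest <- -Inf; accB <- NA; compB <- NA; SigB <- matrix(0, p, p)
  thBest <- th; eBest <- y - g; Jbest <- NULL
  nu <- 1e-6; cc <- 0L; iter <- 0L; converged <- FALSE
  Ftrace <- numeric(0)
  thTry <- th
  while (iter < opts$maxit) {
    iter <- iter + 1L
    gTry <- if (iter == 1) g else predictVec(thTry)
    if (is.null(gTry)) { # divergence: reject with a large penalty
      nu <- nu * 64
      thTry <- thBest
      next
    }
    e <- y - gTry
    J <- if (p > 0) jacobian(thTry, gTry) else matrix(0, N, 0)
    fOfLam <- function(l) .vlFreeEnergy(e, J, thTry, v0, l, opts)$F
    lamOpt <- optimize(fOfLam, c(-12, 12), maximum = TRUE,
                       tol = 1e-4)$maximum
    fe <- .vlFreeEnergy(e, J, thTry, v0, lamOpt, opts)
    if (fe$F > Fbest) {
      dF <- fe$F - Fbest
      Fbest <- fe$F; accB <- fe$accuracy; compB <- fe$complexity
      SigB <- fe$Sigma; thBest <- thTry; eBest <- e; Jbest <- J
      lamBest <- lamOpt
      Ftrace <- c(Ftrace, Fbest)
      nu <- max(nu / 4, 1e-8)
      cc <- if (is.finite(dF) && dF < opts$tolF) cc + 1L else 0L
      if (cc >= opts$tolCount || p == 0) { converged <- TRUE; break }
    } else {
      # a rejected proposal that is within tolerance of the optimum still
      # counts as a vanishing free-energy increment
      if (is.finite(fe$F) && Fbest - fe$F < opts$tolF) {
        cc <- cc + 1L
        if (cc >= opts$tolCount) { converged <- TRUE; break }
      }
      nu <- nu * 16
      if (nu > 1e10) break
    }
    h <- exp(lamBest)
    A <- h * crossprod(Jbest) + diag(1 / v0, p)
    b <- h * crossprod(Jbest, eBest) - (thBest - 0) / v0
    dth <- tryCatch(solve(A + nu * diag(diag(A), p), b),
                    error = function(e) NULL)
    if (is.null(dth)) break
    thTry <- thBest + as.vector(dth)
  }
  if (!is.finite(Fbest))
    stop("inversion error: free energy non-finite", call. = FALSE)
  ssTot <- sum((y - mean(y))^2)
  new("InversionResult",
      posteriorMean = setNames(thBest, free$name),
      posteriorCov = SigB, logPrecision = lamBest, freeEnergy = Fbest,
      accuracy = accB, complexity = compB,
      fitFraction = 1 - sum(eBest^2) / max(ssTot, .Machine$double.eps),
      iterations = iter, converged = converged, Ftrace = Ftrace,
      priors = model$priors[, c("name", "type", "mean", "var")],
      details = list(projection = red$projection,
                     varianceExplained = red$varianceExplained,
                     opts = opts, attId = model$attId,
                     evId = model$evId))
}

#' @describeIn fitVL free energy of an inversion result.
#' @param object an \code{InversionResult}.
#' @export
freeEnergy <- function(object) object@freeEnergy

#' @describeIn fitVL posterior mean over free parameters.
#' @export
posteriorMean <- function(object) object@posteriorMean

#' @describeIn fitVL posterior covariance over free parameters.
#' @export
posteriorCov <- function(object) object@posteriorCov

setMethod("show", "InversionResult", function(object) {
  cat(sprintf(
    "InversionResult: F = %.2f (accuracy %.2f - complexity %.2f)\n",
    object@freeEnergy, object@accuracy, object@complexity))
  cat(sprintf("  %d free parameters, %d iterations, converged: %s, R2 = %.3f\n",
              length(object@posteriorMean), object@iterations,
              object@converged, object@fitFraction))
})
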