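## Canonical-microcircuit neural-mass dynamics.
##
## Units: time in ms, rate constants kappa in 1/ms, voltages dimensionless
## "mV-like". The firing-rate nonlinearity is a centred logistic so that the
## zero state is a fixed point of the undriven system.

.defaultKappa <- c(SS = 1 / 4, SP = 1 / 8, II = 1 / 16, DP = 1 / 28)
.defaultGamma <- c(SS_SS = 2, SP_SS = 1, II_SS = 1, SS_II = 1, DP_II = 0.5,
                   II_II = 2, SS_SP = 1, SP_SP = 2, DP_DP = 1, II_DP = 0.5)

#' Construct canonical-microcircuit parameters
#'
#' Builds a [CMCParameters-class] object for an N-source network. Defaults
#' give a stable, damped network whose driven response peaks within the
#' early-to-mid peristimulus window; all values are overridable.
#'
#' @param sources character vector of source labels.
#' @param AF,AB forward and backward extrinsic matrices (target x origin);
#'   default no extrinsic connections.
#' @param kappa synaptic rate constants (1/ms). Either a named length-4
#'   vector (per population, recycled over sources) or a 4 x N matrix.
#' @param gamma intrinsic coupling gains. Either a named length-10 vector
#'   (recycled over sources) or a 10 x N matrix with the pair names as rows.
#' @param C input gain per source (scales the thalamic input u).
#' @param sigmoidSlope slope r of the firing-rate sigmoid.
#' @return a [CMCParameters-class] object.
#' @examples
#' p <- cmcParameters(c("lS1", "rS1"))
#' nSources(p)
#' @export
cmcParameters <- function(sources, AF = NULL, AB = NULL,
                          kappa = .defaultKappa, gamma = .defaultGamma,
                          C = 1, sigmoidSlope = 2) {
  n <- length(sources)
  if (is.null(AF)) AF <- matrix(0, n, n)
  if (is.null(AB)) AB <- matrix(0, n, n)
  dimnames(AF) <- dimnames(AB) <- list(sources, sources)
  if (!is.matrix(kappa)) {
    kappa <- kappa[.populations]
    kappa <- matrix(kappa, 4, n, dimnames = list(.populations, sources))
  }
  if (!is.matrix(gamma)) {
    gamma <- gamma[.gammaPairs]
    gamma <- matrix(gamma, 10, n, dimnames = list(.gammaPairs, sources))
  }
  C <- rep_len(C, n)
  names(C) <- sources
  # Class= spelled out: a slot named C would otherwise partially match it
  new(Class = "CMCParameters", kappa = kappa, gamma = gamma, AF = AF,
      AB = AB, C = C, sigmoidSlope = sigmoidSlope, sources = sources)
}

#' @describeIn cmcParameters number of sources in a network object.
#' @param object a \code{CMCParameters} object.
#' @export
nSources <- function(object) length(object@sources)

#' @describeIn cmcParameters source labels.
#' @export
sourceNames <- function(object) object@sources

setMethod("show", "CMCParameters", function(object) {
  cat("CMCParameters:", nSources(object), "sources (",
      paste(object@sources, collapse = ", "), ")\n")
  cat("  forward connections:", sum(object@AF > 0),
      " backward:", sum(object@AB > 0), "\n")
  cat("  sigmoid slope r =", object@sigmoidSlope, "\n")
})

#' Firing-rate sigmoid
#'
#' Centred logistic transforming postsynaptic potential into presynaptic
#' firing rate: \eqn{\sigma(V) = 1/(1+e^{-rV}) - 1/2}. Odd, bounded,
#' strictly increasing, with \eqn{\sigma(0) = 0} so that the zero state is a
#' fixed point of the undriven network.
#'
#' @param V voltage (any numeric shape).
#' @param r slope (> 0).
#' @export
cmcSigmoid <- function(V, r = 2) {
  stopifnot(r > 0)
  1 / (1 + exp(-r * V)) - 0.5
}

#' Network state derivative (reference implementation)
#'
#' Pure-R evaluation of the CMC equations of motion, used as the slow
#' reference path for the compiled integrator. The state of each population
#' follows damped second-order synaptic kinetics
#' \eqn{\dot V = I,\ \dot I = \kappa\,\mathrm{drive} - 2\kappa I - \kappa^2 V},
#' with drives: SS receives forward extrinsic input, intrinsic inhibition
#' and the thalamic input C u; II and SP receive backward extrinsic
#' inhibition and intrinsic input; DP receives forward extrinsic input and
#' intrinsic inhibition.
#'
#' @param state list with elements \code{V} and \code{I}, each a 4 x N
#'   matrix (rows SS, SP, II, DP).
#' @param params a [CMCParameters-class] object.
#' @param u scalar input value.
#' @param inputSources optional character vector; only these sources receive
#'   C u (default all).
#' @return list with \code{dV} and \code{dI} matrices.
#' @export
cmcDeriv <- function(state, params, u = 0, inputSources = NULL) {
  V <- state$V; I <- state$I
  if (is.null(rownames(V))) rownames(V) <- .populations
  if (is.null(rownames(I))) rownames(I) <- .populations
  if (any(!is.finite(V)))
    stop("non-finite state passed to cmcDeriv", call. = FALSE)
  g <- params@gamma
  s <- cmcSigmoid(V, params@sigmoidSlope)
  Cvec <- params@C
  if (!is.null(inputSources))
    Cvec <- Cvec * (params@sources %in% inputSources)
  fwd <- drop(params@AF %*% s["SP", ])
  bwd <- drop(params@AB %*% s["DP", ])
  drive <- rbind(
    SS = fwd - g["SS_SS", ] * s["SS", ] - g["SP_SS", ] * s["SP", ] -
         g["II_SS", ] * s["II", ] + Cvec * u,
    SP = -bwd + g["SS_SP", ] * s["SS", ] - g["SP_SP", ] * s["SP", ],
    II = -bwd + g["SS_II", ] * s["SS", ] + g["DP_II", ] * s["DP", ] -
         g["II_II", ] * s["II", ],
    DP = fwd - g["DP_DP", ] * s["DP", ] - g["II_DP", ] * s["II", ])
  drive <- drive[.populations, , drop = FALSE]
  k <- params@kappa
  list(dV = I, dI = k * drive - 2 * k * I - k^2 * V)
}

#' Apply condition-specific modulation to baseline parameters
#'
#' Scales the extrinsic matrices elementwise by
#' \eqn{\exp(\sum_k B^F_k x_k)} (likewise backward) and the SP
#' self-inhibition gain per source by \eqn{\exp(\sum_k B^G_k x_k)}. With
#' \code{x = 0} the baseline is returned unchanged. A negative gain
#' modulation is disinhibition, i.e. increased superficial-pyramidal gain.
#'
#' @param params baseline [CMCParameters-class].
#' @param mod a [ModulationSet-class].
#' @param x modulatory input vector, one entry per factor (typically 0/1).
#' @return effective [CMCParameters-class].
#' @export
applyModulation <- function(params, mod, x) {
  stopifnot(length(x) == length(mod@factors))
  if (length(x) == 0) return(params)
  n <- nSources(params)
  sF <- matrix(0, n, n); sB <- matrix(0, n, n); sG <- numeric(n)
  for (k in seq_along(x)) {
    sF <- sF + mod@BF[[k]] * x[k]
    sB <- sB + mod@BB[[k]] * x[k]
    sG <- sG + mod@BG[, k] * x[k]
  }
  params@AF <- params@AF * exp(sF)
  params@AB <- params@AB * exp(sB)
  params@gamma["SP_SP", ] <- params@gamma["SP_SP", ] * exp(sG)
  params
}

#' Construct an empty modulation set
#'
#' @param sources source labels.
#' @param factors factor labels (default the three contextual factors:
#'   attention, left expectation violation, right expectation violation).
#' @return a [ModulationSet-class] with all entries zero.
#' @export
modulationSet <- function(sources,
                          factors = c("attention", "leftEV", "rightEV")) {
  n <- length(sources)
  z <- matrix(0, n, n, dimnames = list(sources, sources))
  new("ModulationSet", factors = factors,
      BF = setNames(rep(list(z), length(factors)), factors),
      BB = setNames(rep(list(z), length(factors)), factors),
      BG = matrix(0, n, length(factors),
                  dimnames = list(sources, factors)))
}

setMethod("show", "ModulationSet", function(object) {
  nz <- sum(sapply(object@BF, function(m) sum(m != 0))) +
        sum(sapply(object@BB, function(m) sum(m != 0))) + sum(object@BG != 0)
  cat("ModulationSet with factors:",
      paste(object@factors, collapse = ", "), "|", nz,
      "nonzero modulation entries\n")
})

#' Integrate the CMC network
#'
#' Fixed-step fourth-order Runge-Kutta integration of the network from the
#' zero state, sampled onto a requested time grid by linear interpolation.
#' The integration span starts at \code{tStart} (before stimulus onset) and
#' runs to the end of \code{tGrid}.
#'
#' @param params a [CMCParameters-class] (effective parameters; apply
#'   modulation first or pass \code{mod}/\code{x}).
#' @param tGrid times (ms) at which to sample the trajectory.
#' @param inputFn function of time (ms) returning the scalar input u.
#' @param mod,x optional [ModulationSet-class] and modulatory input vector,
#'   applied via [applyModulation()] before integrating.
#' @param inputSources sources receiving the thalamic input (default all).
#' @param dt integration step (ms).
#' @param tStart integration start (ms).
#' @param vmax divergence bound on |V|; exceeding it raises an error of
#'   class \code{cmcDivergence} carrying the offending time.
#' @return array voltage\[population, source, time\].
#' @export
integrateCMC <- function(params, tGrid, inputFn = function(t) 0,
                         mod = NULL, x = NULL, inputSources = NULL,
                         dt = 1, tStart = -100, vmax = 1e3) {
  stopifnot(dt > 0, all(tGrid >= tStart))
  if (!is.null(mod)) params <- applyModulation(params, mod, x)
  n <- nSources(params)
  tEnd <- max(tGrid)
  nsteps <- ceiling((tEnd - tStart) / dt)
  tFull <- tStart + dt * (0:nsteps)
  uHalf <- inputFn(tStart + dt / 2 * (0:(2 * nsteps)))
  if (length(uHalf) == 1) uHalf <- rep(uHalf, 2 * nsteps + 1)
  Cvec <- params@C
  if (!is.null(inputSources))
    Cvec <- Cvec * (params@sources %in% inputSources)
  res <- .cmc_rk4(params@kappa, params@gamma, params@AF, params@AB, Cvec,
                  params@sigmoidSlope, uHalf, dt, as.integer(nsteps), vmax)
  if (res$diverged) {
    cnd <- structure(class = c("cmcDivergence", "error", "condition"),
                     list(message = sprintf(
                            "CMC integration diverged at t = %g ms",
                            tFull[res$step + 1]),
                          call = sys.call(-1), timeMs = tFull[res$step + 1]))
    stop(cnd)
  }
  V <- res$V # 4 x n x (nsteps + 1)
  out <- array(0, dim = c(4, n, length(tGrid)),
               dimnames = list(.populations, params@sources, NULL))
  for (p in 1:4)
    for (i in seq_len(n))
      out[p, i, ] <- approx(tFull, V[p, i, ], xout = tGrid)$y
  out
}

#' @importFrom stats approx
NULL

## ---- plain-text serialization -------------------------------------------

#' Read/write CMC parameters as YAML
#'
#' Parameters serialize to a YAML document holding all slots; trajectories
#' and evoked fields use CSV (see [writeERF()]).
#'
#' @param params a [CMCParameters-class] object.
#' @param file path to a YAML file.
#' @export
writeCMCParameters <- function(params, file) {
  yaml::write_yaml(list(
    sources = params@sources,
    kappa = as.list(as.data.frame(params@kappa)),
    gamma = as.list(as.data.frame(params@gamma)),
    AF = apply(params@AF, 1, identity, simplify = FALSE),
    AB = apply(params@AB, 1, identity, simplify = FALSE),
    C = as.numeric(params@C),
    sigmoidSlope = params@sigmoidSlope), file, precision = 15)
  invisible(file)
}

#' @rdname writeCMCParameters
#' @export
readCMCParameters <- function(file) {
  d <- yaml::read_yaml(file)
  n <- length(d$sources)
  toM <- function(lst, nr) matrix(unlist(lst), nr, n)
  kappa <- toM(d$kappa, 4); rownames(kappa) <- .populations
  gamma <- toM(d$gamma, 10); rownames(gamma) <- .gammaPairs
  AF <- matrix(unlist(d$AF), n, n, byrow = TRUE)
  AB <- matrix(unlist(d$AB), n, n, byrow = TRUE)
  cmcParameters(d$sources, AF = AF, AB = AB, kappa = kappa, gamma = gamma,
                C = d$C, sigmoidSlope = d$sigmoidSlope)
}
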