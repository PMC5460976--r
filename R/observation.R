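## Observation model: exogenous input waveform, synthetic lead field over
## the eight source locations, condition-average ERF synthesis, sensor
## noise.

#' Default source geometry
#'
#' MNI coordinates (mm) of the eight cortical sources of the somatosensory
#' hierarchy: bilateral primary (S1) and secondary (S2) somatosensory
#' cortex, inferior frontal gyrus (IFG) and inferior parietal cortex (IPC).
#'
#' @param sources optional subset of source labels.
#' @return matrix with rows lS1, rS1, lS2, rS2, lIFG, rIFG, lIPC, rIPC.
#' @export
defaultSourceCoords <- function(sources = NULL) {
  co <- rbind(lS1 = c(-26, -36, 58), rS1 = c(32, -40, 64),
              lS2 = c(-62, 14, 20),  rS2 = c(62, 24, 26),
              lIFG = c(-54, 8, 16),  rIFG = c(54, 0, 10),
              lIPC = c(-32, -64, 46), rIPC = c(36, -66, 40))
  colnames(co) <- c("x", "y", "z")
  if (!is.null(sources)) co <- co[sources, , drop = FALSE]
  co
}

#' Exogenous input constructor and waveform
#'
#' The thalamic volley driving contralateral S1 and S2 is a Gaussian bump
#' with prior mean latency 36 ms post-stimulus and standard deviation 16 ms.
#'
#' @param latencyMs mean latency (ms).
#' @param dispersionMs standard deviation (ms).
#' @param amplitude scale.
#' @return an [ExogenousInput-class] object.
#' @export
exogenousInput <- function(latencyMs = 36, dispersionMs = 16,
                           amplitude = 1) {
  new("ExogenousInput", latencyMs = latencyMs, dispersionMs = dispersionMs,
      amplitude = amplitude)
}

#' @rdname exogenousInput
#' @param tGrid times (ms) at which to evaluate the waveform.
#' @param input an [ExogenousInput-class] object.
#' @return for \code{gaussianInput}, the waveform
#'   \eqn{u(t) = a \exp(-(t-\mu)^2 / (2 s^2))} evaluated on \code{tGrid}.
#' @export
gaussianInput <- function(tGrid, input = exogenousInput()) {
  input@amplitude *
    exp(-(tGrid - input@latencyMs)^2 / (2 * input@dispersionMs^2))
}

setMethod("show", "ExogenousInput", function(object) {
  cat(sprintf("ExogenousInput: latency %g ms, dispersion %g ms, amplitude %g\n",
              object@latencyMs, object@dispersionMs, object@amplitude))
})

#' Build a synthetic lead field
#'
#' Stand-in for an anatomical head model: sensors are placed on a helmet-like
#' hemisphere above the sources and the gain from source j to sensor s is a
#' smooth Gaussian kernel of their distance. Sensor positions are laid out
#' in left/right mirrored pairs with a small seeded jitter applied
#' symmetrically, so columns of homologous (left/right) sources are mirror
#' images of each other under the sensor left-right flip.
#'
#' @param sourceCoords N x 3 matrix of source positions (mm).
#' @param nSensors number of sensors (even; default 32).
#' @param seed integer seed for the jitter.
#' @param kernelWidth Gaussian kernel width (mm).
#' @param maxCondition upper bound on the gain-matrix condition number;
#'   exceeding it (or rank deficiency) is a geometry error.
#' @return a [LeadField-class] object.
#' @export
buildLeadfield <- function(sourceCoords, nSensors = 32, seed = 1L,
                           kernelWidth = 55, maxCondition = 1e6) {
  stopifnot(nSensors >= 2, nSensors %% 2 == 0)
  nh <- nSensors / 2
  # deterministic helmet: right-hemisphere sensors on a spherical cap,
  # mirrored to the left
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(nh)
  zf <- 0.25 + 0.7 * (k - 0.5) / nh
  th <- golden * k
  radius <- 110
  right <- cbind(x = radius * sqrt(1 - zf^2) * abs(cos(th)) * 0.9 + 5,
                 y = radius * sqrt(1 - zf^2) * sin(th) * 0.9 - 20,
                 z = radius * zf + 10)
  right <- right + matrix(rnorm(3 * nh, sd = 2), nh, 3)
  left <- right
  left[, "x"] <- -left[, "x"]
  pos <- rbind(right, left)
  rownames(pos) <- c(paste0("R", k), paste0("L", k))
  d2 <- outer(seq_len(nrow(pos)), seq_len(nrow(sourceCoords)),
              Vectorize(function(s, j) sum((pos[s, ] - sourceCoords[j, ])^2)))
  gain <- exp(-d2 / (2 * kernelWidth^2))
  dimnames(gain) <- list(rownames(pos), rownames(sourceCoords))
  sv <- svd(gain)$d
  if (min(sv) <= 0 || max(sv) / min(sv) > maxCondition)
    stop("lead-field geometry error: gain matrix ill-conditioned ",
         "(condition number ", format(max(sv) / max(min(sv), 1e-300)),
         ")", call. = FALSE)
  new("LeadField", gain = gain, sensorPos = pos,
      sourceCoords = as.matrix(sourceCoords), seed = as.integer(seed))
}

# save/restore global RNG state so seeded builders do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @rdname buildLeadfield
#' @details \code{identityLeadfield} places one sensor directly on each
#'   source (identity gain), the degenerate layout in which sensors equal
#'   sources.
#' @export
identityLeadfield <- function(sourceCoords) {
  n <- nrow(sourceCoords)
  new("LeadField", gain = diag(n), sensorPos = as.matrix(sourceCoords),
      sourceCoords = as.matrix(sourceCoords), seed = 0L)
}

setMethod("show", "LeadField", function(object) {
  cat("LeadField:", nrow(object@gain), "sensors x", ncol(object@gain),
      "sources (seed", object@seed, ")\n")
})

#' The eight-condition factorial design
#'
#' Builds the set of condition designs for the 2 (attention) x 2
#' (laterality) x 2 (expectation) factorial: each condition carries a
#' modulatory input vector x over the contextual factors and the hemisphere
#' whose S1/S2 receive the thalamic input (contralateral routing: left-hand
#' stimulation drives right S1/S2 and vice versa).
#'
#' @param sources source labels of the network.
#' @param hands which stimulation sides to include ("L", "R").
#' @param factors contextual factors to include (subset of attention,
#'   leftEV, rightEV).
#' @return named list of condition designs, each with elements
#'   \code{label}, \code{x} (named numeric over \code{factors}) and
#'   \code{inputSources}.
#' @export
conditionSet <- function(sources, hands = c("L", "R"),
                         factors = c("attention", "leftEV", "rightEV")) {
  out <- list()
  for (att in c(0, 1)) {
    for (hand in hands) {
      for (dev in c(0, 1)) {
        lab <- paste0(ifelse(att == 1, "a", "u"), hand,
                      ifelse(dev == 1, "D", "S"))
        x <- setNames(numeric(length(factors)), factors)
        if ("attention" %in% factors) x["attention"] <- att
        ev <- if (hand == "L") "leftEV" else "rightEV"
        if (ev %in% factors) x[ev] <- dev
        contra <- if (hand == "L") "r" else "l"
        inp <- intersect(paste0(contra, c("S1", "S2")), sources)
        out[[lab]] <- list(label = lab, x = x, inputSources = inp)
      }
    }
  }
  out
}

#' Construct an evoked-field dataset
#'
#' @param data condition x sensor x time array.
#' @param timeMs peristimulus time base (ms).
#' @param conditionLabels condition labels.
#' @param noiseSd sensor noise standard deviation used in simulation.
#' @return an [ERFDataset-class] object.
#' @export
erfDataset <- function(data, timeMs, conditionLabels, noiseSd = 0) {
  dimnames(data) <- list(conditionLabels, dimnames(data)[[2]], NULL)
  new("ERFDataset", data = data, timeMs = timeMs,
      conditionLabels = conditionLabels, noiseSd = noiseSd)
}

#' @describeIn erfDataset condition labels of a dataset.
#' @param object an \code{ERFDataset}.
#' @export
conditionLabels <- function(object) object@conditionLabels

#' @describeIn erfDataset the condition x sensor x time array.
#' @export
erfArray <- function(object) object@data

#' @describeIn erfDataset the peristimulus time base (ms).
#' @export
timePoints <- function(object) object@timeMs

setMethod("show", "ERFDataset", function(object) {
  d <- dim(object@data)
  cat(sprintf("ERFDataset: %d conditions x %d sensors x %d samples (%g-%g ms)\n",
              d[1], d[2], d[3], min(object@timeMs), max(object@timeMs)))
  cat("  conditions:", paste(object@conditionLabels, collapse = ", "), "\n")
})

#' Default peristimulus sampling grid
#'
#' The analysis window is 20-400 ms post-stimulus (the first 20 ms contain
#' stimulation artifact in the recordings this emulates), sampled at 300
#' samples per second.
#'
#' @param from,to window limits (ms).
#' @param rateHz sampling rate.
#' @export
erfTimeGrid <- function(from = 20, to = 400, rateHz = 300) {
  seq(from, to, by = 1000 / rateHz)
}

#' Simulate condition-average evoked fields
#'
#' For each condition: apply the condition's contextual modulation to the
#' baseline parameters, integrate the network with the thalamic input routed
#' to the contralateral S1/S2, project the superficial-pyramidal voltages
#' through the lead field, sample the 20-400 ms window, and add i.i.d.
#' Gaussian sensor noise. The MEG signal is taken as proportional to SP
#' voltage only (the dominant superficial-pyramidal contribution).
#'
#' @param params baseline [CMCParameters-class].
#' @param mod a [ModulationSet-class] (use [modulationSet()] for none).
#' @param designs condition designs from [conditionSet()].
#' @param input an [ExogenousInput-class].
#' @param leadfield a [LeadField-class].
#' @param noiseSd sensor noise standard deviation (0 allowed).
#' @param seed seed for the noise draws.
#' @param tGrid sampling grid (ms), default [erfTimeGrid()].
#' @param dt integration step (ms).
#' @return an [ERFDataset-class].
#' @export
simulateERF <- function(params, mod, designs, input, leadfield,
                        noiseSd = 0, seed = 1L, tGrid = erfTimeGrid(),
                        dt = 1) {
  stopifnot(ncol(leadfield@gain) == nSources(params))
  nC <- length(designs); nS <- nrow(leadfield@gain); nT <- length(tGrid)
  out <- array(0, dim = c(nC, nS, nT))
  inputFn <- function(t) gaussianInput(t, input)
  for (ci in seq_len(nC)) {
    d <- designs[[ci]]
    V <- integrateCMC(params, tGrid, inputFn, mod = mod, x = d$x,
                      inputSources = d$inputSources, dt = dt)
    out[ci, , ] <- leadfield@gain %*% V["SP", , ]
  }
  if (noiseSd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    out <- out + array(rnorm(length(out), sd = noiseSd), dim = dim(out))
  }
  erfDataset(out, tGrid, names(designs), noiseSd = noiseSd)
}

#' Write / read an evoked-field dataset as CSV
#'
#' Long-format CSV with columns condition, sensor, time_ms, value plus a
#' JSON sidecar-free header row convention: noiseSd is stored as an
#' attribute column on the first row.
#'
#' @param erf an [ERFDataset-class].
#' @param file path to a CSV file.
#' @export
writeERF <- function(erf, file) {
  d <- dim(erf@data)
  sens <- dimnames(erf@data)[[2]]
  if (is.null(sens)) sens <- paste0("s", seq_len(d[2]))
  df <- expand.grid(condition = erf@conditionLabels, sensor = sens,
                    time_ms = erf@timeMs, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$value <- as.vector(erf@data)
  df$noise_sd <- erf@noiseSd
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeERF
#' @export
readERF <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  conds <- unique(df$condition); sens <- unique(df$sensor)
  times <- sort(unique(df$time_ms))
  a <- array(0, dim = c(length(conds), length(sens), length(times)),
             dimnames = list(conds, sens, NULL))
  a[cbind(match(df$condition, conds), match(df$sensor, sens),
          match(df$time_ms, times))] <- df$value
  erfDataset(a, times, conds, noiseSd = df$noise_sd[1])
}
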