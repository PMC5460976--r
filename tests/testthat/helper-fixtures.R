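# Shared fixtures: small networks built in code, planted effects, and
# noise scaled to a target signal-to-noise ratio.

.gammaNames <- c("SS_SS", "SP_SS", "II_SS", "SS_II", "DP_II",
                 "II_II", "SS_SP", "SP_SP", "DP_DP", "II_DP")

# bilateral S1-S2 network (4 sources), the scaled-down inversion testbed
smallNet <- function(nSensors = 16) {
  src <- c("lS1", "rS1", "lS2", "rS2")
  AF <- matrix(0, 4, 4, dimnames = list(src, src))
  AF["lS2", "lS1"] <- 1
  AF["rS2", "rS1"] <- 1
  AB <- t(AF)
  params <- cmcParameters(src, AF = AF, AB = AB)
  lf <- buildLeadfield(defaultSourceCoords(src), nSensors = nSensors,
                       seed = 3)
  list(params = params, leadfield = lf, designs = conditionSet(src),
       sources = src)
}

# single-hemisphere S1-S2 pair (2 sources) driven by right-hand stimuli
tinyNet <- function(nSensors = 8) {
  src <- c("lS1", "lS2")
  AF <- matrix(0, 2, 2, dimnames = list(src, src))
  AF["lS2", "lS1"] <- 1
  AB <- t(AF)
  params <- cmcParameters(src, AF = AF, AB = AB)
  lf <- buildLeadfield(defaultSourceCoords(src), nSensors = nSensors,
                       seed = 5)
  designs <- conditionSet(src, hands = "R",
                          factors = c("attention", "rightEV"))
  list(params = params, leadfield = lf, designs = designs, sources = src)
}

# sensor noise SD giving a target SNR relative to a noise-free dataset
snrNoiseSd <- function(erf, snr) stats::sd(erfArray(erf)) / snr

# add seeded sensor noise to a noise-free dataset
addSensorNoise <- function(erf, noiseSd, seed) {
  a <- erfArray(erf)
  set.seed(seed)
  a <- a + array(stats::rnorm(length(a), sd = noiseSd), dim = dim(a))
  erfDataset(a, timePoints(erf), conditionLabels(erf), noiseSd = noiseSd)
}

# modulation-model stubs for scaled-down fits
attModelS1S2 <- function() {
  m <- enumerateAttentionModels()[[6]] # gain sites {S1, S2}
  stopifnot(identical(unname(m$scope[c("S1", "S2")]),
                      c("bilateral", "bilateral")))
  m
}

evModelContraS1 <- function(extrinsic = FALSE) {
  m <- enumerateEVModels()[[14]] # contralateral S1, no fronto-parietal
  m$extrinsic <- extrinsic
  m
}
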