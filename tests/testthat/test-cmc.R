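test_that("the firing-rate sigmoid is centred, odd and has the right slope", {
  expect_equal(cmcSigmoid(0), 0)
  v <- seq(-5, 5, by = 0.37)
  expect_equal(cmcSigmoid(v) + cmcSigmoid(-v), rep(0, length(v)))
  expect_true(all(diff(cmcSigmoid(v)) > 0))
  expect_true(all(abs(cmcSigmoid(v * 100)) <= 0.5))
  # derivative at 0 against a central finite difference
  h <- 1e-6
  fd <- (cmcSigmoid(h, r = 2) - cmcSigmoid(-h, r = 2)) / (2 * h)
  expect_equal(fd, 2 / 4, tolerance = 1e-6)
})

test_that("the zero state is a fixed point and drives have the right sign", {
  net <- smallNet()
  st <- list(V = matrix(0, 4, 4), I = matrix(0, 4, 4))
  d <- cmcDeriv(st, net$params, u = 0)
  expect_equal(max(abs(d$dV)), 0)
  expect_equal(max(abs(d$dI)), 0)
  # raising a forward connection raises the SS drive of its target when
  # the origin's SP voltage is positive
  st$V[2, 1] <- 0.5 # SP of lS1
  d0 <- cmcDeriv(st, net$params)
  p2 <- net$params
  p2@AF["lS2", "lS1"] <- p2@AF["lS2", "lS1"] + 0.5
  d1 <- cmcDeriv(st, p2)
  expect_gt(d1$dI["SS", "lS2"], d0$dI["SS", "lS2"])
  st$V[1, 1] <- NaN
  expect_error(cmcDeriv(st, net$params), "non-finite")
})

test_that("a decoupled population follows the closed-form synaptic kernel", {
  p <- cmcParameters("x", gamma = setNames(rep(0, 10), .gammaNames))
  kap <- 1 / 4 # the SS rate constant
  u <- function(t) exp(-(t - 30)^2 / (2 * 4^2))
  tg <- seq(0, 200, by = 1)
  V <- integrateCMC(p, tg, u, dt = 1, tStart = -20)["SS", 1, ]
  # independent oracle: analytic kernel kappa * t * exp(-kappa t)
  # convolved with the input on a fine grid
  fine <- seq(-20, 200, by = 0.01)
  h <- function(t) ifelse(t >= 0, kap * t * exp(-kap * t), 0)
  conv <- vapply(tg, function(t) sum(h(t - fine) * u(fine)) * 0.01, 0)
  expect_lt(max(abs(V - conv)) / max(abs(conv)), 1e-3)
  # kernel peak at 1/kappa: near-impulse input, peak latency 1/kappa
  Vimp <- integrateCMC(p, seq(0, 60, by = 0.25),
                       function(t) ifelse(t >= 0 & t < 0.25, 4, 0),
                       dt = 0.25, tStart = -5)["SS", 1, ]
  expect_equal(seq(0, 60, by = 0.25)[which.max(Vimp)], 1 / kap,
               tolerance = 0.07)
})

test_that("halving the step leaves the trajectory unchanged to tolerance", {
  net <- smallNet()
  u <- function(t) gaussianInput(t)
  tg <- erfTimeGrid()
  V1 <- integrateCMC(net$params, tg, u, dt = 1,
                     inputSources = c("rS1", "rS2"))
  V2 <- integrateCMC(net$params, tg, u, dt = 0.25,
                     inputSources = c("rS1", "rS2"))
  expect_lt(max(abs(V1 - V2)) / max(abs(V2)), 1e-3)
  # zero input gives identically zero trajectories
  V0 <- integrateCMC(net$params, tg, function(t) 0 * t)
  expect_equal(max(abs(V0)), 0)
})

test_that("the compiled integrator agrees with an R-level reference RK4", {
  p <- cmcParameters(c("lS1", "lS2"),
                     AF = matrix(c(0, 1, 0, 0), 2, 2,
                                 dimnames = list(c("lS1", "lS2"),
                                                 c("lS1", "lS2"))),
                     AB = matrix(c(0, 0, 1, 0), 2, 2))
  u <- function(t) gaussianInput(t)
  dt <- 1; t0 <- -20; tEnd <- 120
  nsteps <- (tEnd - t0) / dt
  V <- matrix(0, 4, 2); I <- matrix(0, 4, 2)
  rownames(V) <- rownames(I) <- c("SS", "SP", "II", "DP")
  step <- function(V, I, t) {
    k1 <- cmcDeriv(list(V = V, I = I), p, u(t))
    k2 <- cmcDeriv(list(V = V + dt / 2 * k1$dV, I = I + dt / 2 * k1$dI),
                   p, u(t + dt / 2))
    k3 <- cmcDeriv(list(V = V + dt / 2 * k2$dV, I = I + dt / 2 * k2$dI),
                   p, u(t + dt / 2))
    k4 <- cmcDeriv(list(V = V + dt * k3$dV, I = I + dt * k3$dI),
                   p, u(t + dt))
    list(V = V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV),
         I = I + dt / 6 * (k1$dI + 2 * k2$dI + 2 * k3$dI + k4$dI))
  }
  for (s in seq_len(nsteps)) {
    out <- step(V, I, t0 + (s - 1) * dt)
    V <- out$V; I <- out$I
  }
  Vc <- integrateCMC(p, tEnd, u, dt = dt, tStart = t0)
  expect_equal(max(abs(Vc[, , 1] - V)), 0, tolerance = 1e-10)
})

test_that("modulation scales connections as advertised", {
  net <- smallNet()
  mod <- modulationSet(net$sources)
  # x = 0 leaves the baseline untouched
  eff0 <- applyModulation(net$params, mod, c(0, 0, 0))
  expect_identical(eff0@AF, net$params@AF)
  expect_identical(eff0@gamma, net$params@gamma)
  mod@BG["lS1", "attention"] <- -0.3
  eff <- applyModulation(net$params, mod, c(1, 0, 0))
  expect_equal(eff@gamma["SP_SP", "lS1"],
               net$params@gamma["SP_SP", "lS1"] * exp(-0.3))
  # two factors on one connection add in the exponent, in either order
  mod@BF[["attention"]]["lS2", "lS1"] <- 0.2
  mod@BF[["leftEV"]]["lS2", "lS1"] <- 0.1
  e12 <- applyModulation(net$params, mod, c(1, 1, 0))
  expect_equal(e12@AF["lS2", "lS1"],
               net$params@AF["lS2", "lS1"] * exp(0.3))
  modSwap <- modulationSet(net$sources)
  modSwap@BF[["attention"]]["lS2", "lS1"] <- 0.1
  modSwap@BF[["leftEV"]]["lS2", "lS1"] <- 0.2
  modSwap@BG["lS1", "leftEV"] <- -0.3
  eSwap <- applyModulation(net$params, modSwap, c(1, 1, 0))
  expect_equal(eSwap@AF["lS2", "lS1"], e12@AF["lS2", "lS1"])
  # x = 0 reproduces baseline trajectories bit for bit
  tg <- erfTimeGrid()
  u <- function(t) gaussianInput(t)
  Vb <- integrateCMC(net$params, tg, u, inputSources = "rS1")
  Vm <- integrateCMC(net$params, tg, u, mod = mod, x = c(0, 0, 0),
                     inputSources = "rS1")
  expect_identical(Vb, Vm)
})

test_that("hemisphere-symmetric networks have mirror-symmetric responses", {
  net <- smallNet()
  tg <- erfTimeGrid()
  u <- function(t) gaussianInput(t)
  VL <- integrateCMC(net$params, tg, u, inputSources = c("rS1", "rS2"))
  VR <- integrateCMC(net$params, tg, u, inputSources = c("lS1", "lS2"))
  perm <- c("rS1", "lS1", "rS2", "lS2")
  expect_equal(VL[, net$sources, ], VR[, perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("runaway parameters raise a divergence error with a time stamp", {
  src <- c("a", "b")
  AF <- matrix(c(0, 1e6, 0, 0), 2, 2)
  p <- cmcParameters(src, AF = AF, AB = t(AF) * 1e6)
  err <- tryCatch(
    integrateCMC(p, seq(0, 400), function(t) gaussianInput(t),
                 vmax = 1e3),
    cmcDivergence = function(e) e)
  expect_s3_class(err, "cmcDivergence")
  expect_true(is.finite(err$timeMs))
})

test_that("parameters round-trip through YAML", {
  net <- smallNet()
  f <- tempfile(fileext = ".yaml")
  writeCMCParameters(net$params, f)
  back <- readCMCParameters(f)
  expect_equal(back@AF, net$params@AF, ignore_attr = TRUE)
  expect_equal(back@gamma, net$params@gamma, ignore_attr = TRUE)
  expect_equal(back@kappa, net$params@kappa, ignore_attr = TRUE)
  expect_equal(back@sources, net$params@sources)
})
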