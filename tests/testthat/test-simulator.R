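cfgSmall <- function(proto = "frequency", ...) {
  simulationConfig(proto, nNeurons = 6, durationMs = 3000, ...)
}

test_that("configuration defaults follow the case-study table and are validated", {
  cfg <- simulationConfig("frequency")
  expect_identical(nNeurons(cfg), 30L)
  expect_equal(cfg@tauM, 10)
  expect_equal(cfg@vRest, -70)
  expect_equal(cfg@vTheta, -50)
  expect_equal(cfg@jSyn, 1)
  expect_equal(cfg@jExt, 30)
  expect_equal(c(cfg@tauR1, cfg@tauR2, cfg@tauO1, cfg@tauO2),
               c(16.8, 575, 33.7, 47))
  expect_equal(c(cfg@a2Plus, cfg@a3Plus, cfg@a2Minus, cfg@a3Minus),
               c(4.6e-3, 9.1e-3, 3.0e-3, 7.5e-9))
  expect_equal(cfg@dt, 1)
  expect_identical(cfg@traceMode, "reset")

  expect_error(simulationConfig("frequency", tauM = -1), "positive")
  expect_error(simulationConfig("frequency", vRest = -40), "vTheta")
  expect_error(simulationConfig("frequency", escapeDeltaU = 0),
               "escapeDeltaU")
  expect_error(simulationConfig("frequency", nonsense = 1), "unknown")
})

test_that("escape-noise firing probability behaves like a smoothed threshold", {
  cfg <- simulationConfig("frequency")
  expect_lt(fireProbability(cfg@vRest, cfg), 1e-3)
  expect_gt(fireProbability(cfg@vRest + cfg@jExt, cfg), 0.999)
  v <- seq(-80, -30, by = 0.5)
  expect_true(all(diff(fireProbability(v, cfg)) >= 0))
  # P -> 0 as dt -> 0 (rate x time limit)
  tiny <- simulationConfig("frequency", dt = 1e-6)
  expect_lt(fireProbability(-55, tiny), 1e-4)
})

test_that("frequency protocol delivers the configured rates", {
  cfg <- simulationConfig("frequency", nNeurons = 5, durationMs = 100000,
                          jitterFrac = 0)
  ev <- frequencyProtocol(cfg, seed = 1)
  rates <- seq(cfg@rateRange[1], cfg@rateRange[2], length.out = 5)
  # jitter-free trains are exactly periodic
  expect_equal(diff(ev[[1]]), rep(1000 / rates[1], length(ev[[1]]) - 1))
  cfgJ <- simulationConfig("frequency", nNeurons = 5, durationMs = 100000,
                           jitterFrac = 0.05)
  for (sd in 1:2) {
    evJ <- frequencyProtocol(cfgJ, seed = sd)
    got <- lengths(evJ) / 100
    expect_true(all(abs(got - rates) / rates < 0.02))
  }
  # different seeds jitter differently
  expect_false(identical(frequencyProtocol(cfgJ, seed = 1),
                         frequencyProtocol(cfgJ, seed = 2)))
  expect_error(frequencyProtocol(simulationConfig(
    "frequency", rateRange = c(0, 10), nNeurons = 5, durationMs = 1000)),
    "rates must be positive")
})

test_that("sequential protocol is an arithmetic progression across cycles", {
  cfg <- simulationConfig("sequential", nNeurons = 3, durationMs = 260,
                          jitterFrac = 0)
  ev <- sequentialProtocol(cfg, seed = 1)
  # delay 20 ms, cycle 60 ms: neuron i fires at 20 i, 60 + 20 i, ...
  expect_equal(ev[[1]], c(20, 80, 140, 200))
  expect_equal(ev[[2]], c(40, 100, 160, 220))
  expect_equal(ev[[3]], c(60, 120, 180, 240))
  expect_true(all(lengths(ev) == 4))  # equal counts per cycle

  # small jitter rarely breaks the within-cycle ordering
  cfgJ <- simulationConfig("sequential", nNeurons = 10, durationMs = 2e5,
                           jitterFrac = 0.05)
  evJ <- sequentialProtocol(cfgJ, seed = 2)
  cycles <- floor(2e5 / (10 * 20))
  firstTwo <- cbind(evJ[[1]][seq_len(cycles)], evJ[[2]][seq_len(cycles)])
  expect_lt(mean(firstTwo[, 1] > firstTwo[, 2]), 0.01)
  expect_error(sequentialProtocol(simulationConfig(
    "sequential", seqDelay = -1, nNeurons = 3, durationMs = 100)), "delay")
})

test_that("a zero learning rate freezes the weights exactly", {
  cfg <- cfgSmall(eta = 0)
  res <- runSimulation(cfg, seed = 5)
  tr <- sTrajectory(res)
  expect_equal(tr$s[1], tr$s[nrow(tr)])
  set.seed(5)
  spec <- nullModelSpec("uniform")
  W0 <- randomNetwork(6, spec)
  expect_identical(weights(finalWeights(res)), weights(W0))
})

test_that("identical seeds reproduce the simulation bitwise", {
  cfg <- cfgSmall("sequential")
  a <- runSimulation(cfg, seed = 11)
  b <- runSimulation(cfg, seed = 11)
  expect_identical(weights(finalWeights(a)), weights(finalWeights(b)))
  expect_identical(sTrajectory(a), sTrajectory(b))
  expect_identical(a@spikes, b@spikes)
  c <- runSimulation(cfg, seed = 12)
  expect_false(identical(sTrajectory(a), sTrajectory(c)))
})

test_that("weights respect hard bounds and pruned entries stay at zero", {
  cfg <- simulationConfig("frequency", nNeurons = 8, durationMs = 20000,
                          pruneP = 0.3)
  res <- runSimulation(cfg, seed = 21)
  w <- weights(finalWeights(res))
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(w[res@mask] == 0))
  expect_true(all(sTrajectory(res)$s >= 0 & sTrajectory(res)$s <= 1))
})

test_that("initial s is distributed as the null model predicts", {
  cfg <- simulationConfig("frequency", nNeurons = 10, durationMs = 1000,
                          eta = 0)
  s0 <- vapply(1:100, function(sd) sTrajectory(runSimulation(cfg, sd))$s[1],
               numeric(1))
  null <- momentsS(nullModelSpec("uniform"), 10)
  ks <- suppressWarnings(ks.test(s0, "pnorm", muS(null), sqrt(varS(null))))
  expect_gt(ks$p.value, 0.01)
})

test_that("the two protocols drive s in opposite directions", {
  seeds <- 1:5
  for (fam in c("uniform", "gaussian")) {
    fr <- sapply(seeds, function(sd) {
      tr <- sTrajectory(runSimulation(simulationConfig(
        "frequency", nNeurons = 10, durationMs = 60000,
        initFamily = fam), sd))
      c(tr$s[1], tr$s[nrow(tr)])
    })
    expect_gt(mean(fr[2, ] - fr[1, ]), 0)
    sq <- sapply(seeds, function(sd) {
      tr <- sTrajectory(runSimulation(simulationConfig(
        "sequential", nNeurons = 10, durationMs = 60000,
        initFamily = fam), sd))
      c(tr$s[1], tr$s[nrow(tr)])
    })
    expect_lt(mean(sq[2, ] - sq[1, ]), 0)
  }
})
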