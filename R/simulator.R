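#' @include AllClasses.R generators.R
NULL

#' Build a simulation configuration
#'
#' Assembles the parameters of the spiking-network case study: N leaky
#' integrate-and-fire neurons with escape noise, all-to-all plastic
#' excitatory connections updated by the triplet STDP rule, and an external
#' stimulation protocol. Neuron-model and STDP defaults follow the
#' case-study parameter table (see [SimulationConfig-class]); the two
#' protocol learning rates default to values calibrated so that each
#' protocol reaches its characteristic steady state within a few minutes of
#' simulated time.
#'
#' @param protocol "frequency" (distinct per-neuron stimulation rates;
#'   drives the network toward reciprocal, symmetric connectivity) or
#'   "sequential" (neurons stimulated in a fixed order; drives it toward
#'   one-way, asymmetric connectivity).
#' @param nNeurons network size (default 30).
#' @param durationMs simulated time in ms (default 200000).
#' @param pruneP pruning probability applied before learning (default 0).
#' @param initFamily initial-weight family, "uniform" or "gaussian".
#' @param eta learning rate; \code{NULL} picks the per-protocol default.
#' @param rateRange frequency-protocol rate range in Hz (default 15 to 35,
#'   evenly spaced across neurons; all rates sit above the triplet rule's
#'   potentiation/depression crossover, so sustained stimulation drives
#'   pairs bidirectional).
#' @param seqDelay sequential-protocol inter-neuron delay in ms (default 20).
#' @param jitterFrac stimulation jitter SD as a fraction of the period /
#'   delay (default 0.05).
#' @param recordIntervalMs sampling interval of the s trajectory (default
#'   1000 ms).
#' @param traceMode "reset" (nearest-spike variant, default) or
#'   "accumulate".
#' @param ... further slots of [SimulationConfig-class] to override
#'   (e.g. \code{tauM}, \code{jExt}, \code{escapeDeltaU}, \code{initSigma}).
#' @return A validated [SimulationConfig-class].
#' @examples
#' simulationConfig("frequency", nNeurons = 10, durationMs = 5000)
#' @export
simulationConfig <- function(protocol = c("frequency", "sequential"),
                             nNeurons = 30, durationMs = 200000, pruneP = 0,
                             initFamily = c("uniform", "gaussian"),
                             eta = NULL, rateRange = c(15, 35), seqDelay = 20,
                             jitterFrac = 0.05, recordIntervalMs = 1000,
                             traceMode = c("reset", "accumulate"), ...) {
  protocol <- match.arg(protocol)
  initFamily <- match.arg(initFamily)
  traceMode <- match.arg(traceMode)
  if (is.null(eta)) {
    eta <- if (protocol == "frequency") 2 else 2
  }
  cfg <- new("SimulationConfig",
    nNeurons = as.integer(nNeurons), tauM = 10, vRest = -70, vReset = -70,
    vTheta = -50, jSyn = 1, jExt = 30, dt = 1, delaySteps = 1L,
    tauR1 = 16.8, tauR2 = 575, tauO1 = 33.7, tauO2 = 47,
    a2Plus = 4.6e-3, a3Plus = 9.1e-3, a2Minus = 3.0e-3, a3Minus = 7.5e-9,
    eta = eta, wMin = 0, wMax = 1, escapeRate = 1, escapeDeltaU = 2,
    protocol = protocol, rateRange = rateRange, seqDelay = seqDelay,
    jitterFrac = jitterFrac, durationMs = durationMs, pruneP = pruneP,
    initFamily = initFamily, initMu = 0.5, initSigma = 0.1,
    recordIntervalMs = recordIntervalMs, traceMode = traceMode)
  extra <- list(...)
  for (nm in names(extra)) {
    if (!nm %in% slotNames(cfg)) stop("unknown configuration field: ", nm)
    cur <- slot(cfg, nm)
    val <- extra[[nm]]
    if (is.integer(cur)) val <- as.integer(val)
    slot(cfg, nm) <- val
  }
  validObject(cfg)
  cfg
}

#' Per-step firing probability under escape noise
#'
#' Instead of a deterministic threshold, spikes are drawn stochastically:
#' the instantaneous escape rate grows exponentially with the membrane
#' potential, \eqn{\rho(V) = \rho_0 \exp((V - \theta)/\Delta u)}, and the
#' probability of firing within one step of length dt is
#' \eqn{1 - \exp(-\rho(V)\, dt)}. Far below threshold this is negligible; an
#' external +30 mV kick from rest lands 10 mV above threshold, where firing
#' is near-certain.
#'
#' @param v membrane potential(s), mV.
#' @param config a [SimulationConfig-class].
#' @return firing probability in \code{[0, 1]}, vectorised over \code{v}.
#' @examples
#' cfg <- simulationConfig("frequency")
#' fireProbability(-70, cfg)  # essentially 0 at rest
#' fireProbability(-40, cfg)  # essentially 1 after an external event
#' @export
fireProbability <- function(v, config) {
  stopifnot(is(config, "SimulationConfig"))
  arg <- pmin((v - config@vTheta) / config@escapeDeltaU, 30)
  rate <- config@escapeRate * exp(arg)
  1 - exp(-rate * config@dt)
}

#' Frequency-protocol stimulation trains
#'
#' Each neuron is driven periodically at its own rate; rates are evenly
#' spaced across \code{rateRange}. Event times are jittered by a zero-mean
#' Gaussian with standard deviation \code{jitterFrac} times the neuron's
#' period. Neurons firing at distinct sustained rates develop reciprocal
#' connections under the triplet rule, pushing s upward.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional RNG seed; \code{NULL} uses the current RNG state.
#' @return List of per-neuron event-time vectors (ms, sorted).
#' @examples
#' ev <- frequencyProtocol(simulationConfig("frequency", nNeurons = 5,
#'                                          durationMs = 2000), seed = 1)
#' lengths(ev)
#' @export
frequencyProtocol <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- config@nNeurons
  rates <- seq(config@rateRange[1], config@rateRange[2], length.out = n)
  if (any(rates <= 0)) stop("stimulation rates must be positive")
  lapply(seq_len(n), function(i) {
    period <- 1000 / rates[i]
    base <- seq(period, config@durationMs, by = period)
    t <- base + stats::rnorm(length(base), 0, config@jitterFrac * period)
    sort(t[t > 0 & t <= config@durationMs])
  })
}

#' Sequential-protocol stimulation trains
#'
#' Neurons are driven in a fixed order, one after the other with a constant
#' inter-neuron delay, the pattern repeating cyclically; event times are
#' jittered by a zero-mean Gaussian with standard deviation
#' \code{jitterFrac} times the delay. The consistent pre-before-post timing
#' potentiates connections along the sequence and depresses the reverse
#' ones, pushing s downward.
#'
#' @inheritParams frequencyProtocol
#' @return List of per-neuron event-time vectors (ms, sorted).
#' @examples
#' ev <- sequentialProtocol(simulationConfig("sequential", nNeurons = 3,
#'                          durationMs = 200, jitterFrac = 0), seed = 1)
#' ev[[1]][1:3]  # multiples of N * seqDelay
#' @export
sequentialProtocol <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- config@nNeurons
  d <- config@seqDelay
  if (d <= 0) stop("sequential inter-neuron delay must be positive")
  cyclePeriod <- n * d
  nCycles <- floor(config@durationMs / cyclePeriod)
  if (nCycles < 1) stop("duration shorter than one stimulation cycle")
  cycles <- (seq_len(nCycles) - 1) * cyclePeriod
  lapply(seq_len(n), function(i) {
    base <- cycles + (i - 1) * d + d
    t <- base + stats::rnorm(length(base), 0, config@jitterFrac * d)
    sort(t[t > 0 & t <= config@durationMs])
  })
}

#' Run the spiking-network simulation
#'
#' Draws the initial weights from the configured family, applies the
#' pruning mask (pruned connections stay at zero for the entire run), then
#' integrates the network with a fixed 1 ms step: exponential membrane and
#' trace decay, delayed synaptic and external impulses, escape-noise spike
#' generation, and the triplet STDP update (reading trace values from just
#' before each spike's own increment). The symmetry measure of the evolving
#' weight matrix is recorded at regular intervals. Fully reproducible:
#' identical seeds give identical results.
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer RNG seed.
#' @return A [SimulationResult-class].
#' @examples
#' cfg <- simulationConfig("sequential", nNeurons = 5, durationMs = 2000)
#' res <- runSimulation(cfg, seed = 1)
#' sTrajectory(res)
#' @export
runSimulation <- function(config, seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  n <- config@nNeurons

  initSpec <- if (config@initFamily == "uniform") {
    nullModelSpec("uniform", wMin = config@wMin, wMax = config@wMax)
  } else {
    nullModelSpec("gaussian", wMin = config@wMin, wMax = config@wMax,
                  mu = config@initMu, sigma = config@initSigma)
  }
  W0 <- randomNetwork(n, initSpec)  # unpruned draw; mask applied next
  pr <- applyPruning(W0, config@pruneP)
  w0 <- pr$weights@weights
  mask <- pr$mask

  events <- if (config@protocol == "frequency") {
    frequencyProtocol(config)
  } else {
    sequentialProtocol(config)
  }
  nSteps <- as.integer(round(config@durationMs / config@dt))
  extSteps <- lapply(events, function(t) {
    st <- as.integer(round(t / config@dt))
    sort(st[st >= 1 & st <= nSteps])
  })
  recordEvery <- max(1L, as.integer(round(config@recordIntervalMs /
                                            config@dt)))

  out <- sim_loop_cpp(w0, mask, extSteps, nSteps, config@dt, config@tauM,
                      config@vRest, config@vTheta, config@jSyn, config@jExt,
                      config@escapeRate, config@escapeDeltaU,
                      config@delaySteps, config@tauR1, config@tauR2,
                      config@tauO1, config@tauO2, config@a2Plus,
                      config@a3Plus, config@a2Minus, config@a3Minus,
                      config@eta, config@wMin, config@wMax,
                      config@traceMode == "reset", recordEvery)

  traj <- data.frame(time_ms = out$steps * config@dt, s = out$s)
  spikes <- lapply(out$raster, function(st) st * config@dt)
  new("SimulationResult", sTrajectory = traj,
      finalWeights = WeightMatrix(out$weights, wMax = config@wMax),
      spikes = spikes, mask = mask, seed = as.integer(seed), config = config)
}
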