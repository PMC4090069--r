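#' @include netsym-package.R
NULL

#' Weighted directed connectivity matrix
#'
#' An N x N matrix of non-negative synaptic weights with zero diagonal.
#' Entry \code{w[i, j]} is the strength of the connection from presynaptic
#' neuron \code{j} onto postsynaptic neuron \code{i} (row = postsynaptic,
#' column = presynaptic). The symmetry measure itself is
#' transpose-invariant, so the orientation convention only matters for the
#' spiking-network simulator.
#'
#' @slot weights numeric matrix of weights in \code{[0, wMax]}, zero diagonal.
#' @slot wMax positive upper bound on the weights (default 1).
#'
#' @seealso [WeightMatrix()], [symmetryMeasure()], [pairDecompose()]
#' @export
setClass("WeightMatrix",
  representation(weights = "matrix", wMax = "numeric"),
  prototype(weights = matrix(0, 2, 2), wMax = 1)
)

setValidity("WeightMatrix", function(object) {
  w <- object@weights
  if (!is.numeric(w)) return("weights must be a numeric matrix")
  if (nrow(w) != ncol(w)) {
    return(sprintf("matrix not square: %d rows, %d columns", nrow(w), ncol(w)))
  }
  if (nrow(w) < 2) return("at least 2 neurons are required")
  if (length(object@wMax) != 1 || !is.finite(object@wMax) || object@wMax <= 0) {
    return("wMax must be a single positive number")
  }
  if (anyNA(w)) return("weights contain missing values")
  bad <- which(w < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    return(sprintf("negative weight at [%d, %d]", bad[1, 1], bad[1, 2]))
  }
  bad <- which(w > object@wMax, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    return(sprintf("weight above wMax at [%d, %d]", bad[1, 1], bad[1, 2]))
  }
  d <- which(diag(w) != 0)
  if (length(d) > 0) {
    return(sprintf("nonzero diagonal entry at [%d, %d]", d[1], d[1]))
  }
  TRUE
})

#' Construct a WeightMatrix
#'
#' Validates and wraps a square numeric matrix of non-negative weights with
#' zero diagonal.
#'
#' @param weights square numeric matrix, non-negative entries, zero diagonal.
#' @param wMax positive upper weight bound; entries must not exceed it.
#' @return A [WeightMatrix-class] object.
#' @examples
#' w <- matrix(c(0, 0.6, 0.5, 0.2, 0, 0, 0.5, 0, 0), 3, 3)
#' W <- WeightMatrix(w)
#' symmetryMeasure(W)
#' @export
WeightMatrix <- function(weights, wMax = 1) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  dimnames(weights) <- NULL
  new("WeightMatrix", weights = weights, wMax = as.numeric(wMax))
}

#' Pair decomposition of a connectivity matrix
#'
#' For every unordered neuron pair (i, j), i < j, holds the pair sum
#' u = w_ij + w_ji, the absolute difference v = |w_ij - w_ji| and the
#' normalised asymmetry z = v / u. Pairs with both weights zero carry no
#' information about reciprocity and are excluded from the counted set.
#'
#' @slot pairs data.frame with columns i, j, u, v, z (z is NA for (0,0) pairs).
#' @slot nZeroPairs number of (0,0) pairs (excluded from the measure).
#' @slot nCounted number of counted pairs, N(N-1)/2 - nZeroPairs.
#' @export
setClass("PairDecomposition",
  representation(pairs = "data.frame", nZeroPairs = "integer",
                 nCounted = "integer")
)

setValidity("PairDecomposition", function(object) {
  p <- object@pairs
  need <- c("i", "j", "u", "v", "z")
  if (!all(need %in% names(p))) return("pairs must have columns i, j, u, v, z")
  z <- p$z[!is.na(p$z)]
  if (any(z < -1e-12 | z > 1 + 1e-12)) return("z outside [0, 1]")
  if (object@nZeroPairs + object@nCounted != nrow(p)) {
    return("nZeroPairs + nCounted must equal the number of pairs")
  }
  TRUE
})

#' Symmetry measure report
#'
#' The symmetry measure s = 1 - mean(z) over counted pairs, optionally with
#' the z-score and p-value of a significance test against a random-network
#' null model.
#'
#' @slot s symmetry measure in \code{[0, 1]}; 1 = fully reciprocal,
#'   0 = fully unidirectional.
#' @slot nCounted number of counted pairs.
#' @slot nZeroPairs number of excluded (0,0) pairs.
#' @slot zScore standardised distance from the null mean (NA if untested).
#' @slot pValue p-value of the test (NA if untested).
#' @slot verdict one of "symmetric", "asymmetric", "random", "untested".
#' @slot alpha significance level used (NA if untested).
#' @export
setClass("SymmetryReport",
  representation(s = "numeric", nCounted = "integer", nZeroPairs = "integer",
                 zScore = "numeric", pValue = "numeric", verdict = "character",
                 alpha = "numeric"),
  prototype(zScore = NA_real_, pValue = NA_real_, verdict = "untested",
            alpha = NA_real_)
)

setValidity("SymmetryReport", function(object) {
  if (length(object@s) != 1 || object@s < -1e-12 || object@s > 1 + 1e-12) {
    return("s must be a single value in [0, 1]")
  }
  if (!object@verdict %in% c("symmetric", "asymmetric", "random", "untested")) {
    return("invalid verdict")
  }
  if (is.na(object@zScore) != is.na(object@pValue)) {
    return("pValue must be present exactly when zScore is present")
  }
  if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1)) {
    return("pValue must lie in (0, 1]")
  }
  TRUE
})

#' Null-model specification
#'
#' Describes the random-network null: i.i.d. off-diagonal weights from either
#' a uniform distribution on \code{[wMin, wMax]} or a truncated Gaussian
#' (mean at the interval midpoint, small sigma), with each directed
#' connection independently pruned (set permanently to zero) with
#' probability \code{pruneP}.
#'
#' @slot family "uniform" or "gaussian".
#' @slot wMin,wMax weight bounds (defaults 0 and 1).
#' @slot mu Gaussian mean; must equal the interval midpoint.
#' @slot sigma Gaussian standard deviation; must be narrow enough that the
#'   mass outside \code{[wMin, wMax]} is below 1e-4.
#' @slot pruneP pruning probability in \code{[0, 1)}.
#' @export
setClass("NullModelSpec",
  representation(family = "character", wMin = "numeric", wMax = "numeric",
                 mu = "numeric", sigma = "numeric", pruneP = "numeric"),
  prototype(family = "uniform", wMin = 0, wMax = 1, mu = 0.5, sigma = 0.1,
            pruneP = 0)
)

setValidity("NullModelSpec", function(object) {
  if (!object@family %in% c("uniform", "gaussian")) {
    return("family must be 'uniform' or 'gaussian'")
  }
  if (object@wMin >= object@wMax) return("wMin must be below wMax")
  if (object@pruneP < 0 || object@pruneP >= 1) {
    return("pruneP must lie in [0, 1); p = 1 leaves no counted pairs")
  }
  if (object@family == "gaussian") {
    mid <- (object@wMin + object@wMax) / 2
    if (abs(object@mu - mid) > 1e-9) {
      return("gaussian mean must sit at the midpoint of [wMin, wMax]")
    }
    if (object@sigma <= 0) return("sigma must be positive")
    mass <- stats::pnorm(object@wMin, object@mu, object@sigma) +
      stats::pnorm(object@wMax, object@mu, object@sigma, lower.tail = FALSE)
    if (mass >= 1e-4) {
      return(sprintf(paste0("gaussian too wide: mass %.3g outside ",
                            "[wMin, wMax] exceeds 1e-4"), mass))
    }
  }
  TRUE
})

#' Construct a NullModelSpec
#'
#' @param family "uniform" or "gaussian".
#' @param wMin,wMax weight bounds.
#' @param mu Gaussian mean (midpoint of the interval).
#' @param sigma Gaussian standard deviation.
#' @param pruneP pruning probability in \code{[0, 1)}.
#' @return A [NullModelSpec-class] object.
#' @examples
#' nullModelSpec("uniform", pruneP = 0.3)
#' nullModelSpec("gaussian", sigma = 0.1)
#' @export
nullModelSpec <- function(family = c("uniform", "gaussian"), wMin = 0,
                          wMax = 1, mu = (wMin + wMax) / 2, sigma = 0.1,
                          pruneP = 0) {
  family <- match.arg(family)
  new("NullModelSpec", family = family, wMin = as.numeric(wMin),
      wMax = as.numeric(wMax), mu = as.numeric(mu), sigma = as.numeric(sigma),
      pruneP = as.numeric(pruneP))
}

#' Probability densities of pair statistics under a null model
#'
#' Closed-form densities of a single weight w, the pair sum u, the absolute
#' pair difference v and the joint density of (u, v), conditioned on at
#' least one weight of the pair being alive. With pruning p, the joint law
#' is a mixture: with weight (1-p)/(1+p) both weights survive and (u, v)
#' follows the continuous unpruned joint density; with weight 2p/(1+p)
#' exactly one weight survives, concentrating mass on the line v = u.
#'
#' @slot pdfW function(w): continuous part of the single-weight density
#'   (weight \code{wContWeight}); an atom at 0 carries weight \code{wAtomZero}.
#' @slot pdfU,pdfV function(x): full (mixture) marginal densities of u and v.
#' @slot jointCont function(u, v): continuous part of the joint density on
#'   the triangle \code{0 <= v <= u}, carrying weight \code{contWeight}.
#' @slot lineDensity function(u): density along the singular line v = u,
#'   carrying weight \code{pruneWeight}.
#' @slot contWeight,pruneWeight mixture weights, (1-p)/(1+p) and 2p/(1+p).
#' @slot wContWeight,wAtomZero mixture weights of the single-weight law,
#'   (1-p) and p.
#' @slot support named list with elements w, u, v: support intervals.
#' @slot spec the generating [NullModelSpec-class].
#' @export
setClass("DensityBundle",
  representation(pdfW = "function", pdfU = "function", pdfV = "function",
                 jointCont = "function", lineDensity = "function",
                 contWeight = "numeric", pruneWeight = "numeric",
                 wContWeight = "numeric", wAtomZero = "numeric",
                 support = "list", spec = "NullModelSpec")
)

#' Null statistics of z and s
#'
#' First two moments of the pair asymmetry z and of the symmetry measure s
#' under a random-network null model, together with the expected number of
#' counted pairs E[P] = (1 - p^2) N(N-1)/2.
#'
#' @slot muZ,varZ mean and variance of z for a single counted pair.
#' @slot muS,varS mean and variance of s (muS = 1 - muZ,
#'   varS = varZ / E[P] for analytic methods).
#' @slot expectedPairs expected number of counted pairs E[P].
#' @slot nNeurons network size N the s-moments refer to.
#' @slot method "closed_form", "quadrature" or "monte_carlo".
#' @slot nNetworks number of Monte-Carlo networks (NA for analytic methods).
#' @slot seed RNG seed used for Monte Carlo (NA otherwise).
#' @slot spec the generating [NullModelSpec-class].
#' @export
setClass("NullStatistics",
  representation(muZ = "numeric", varZ = "numeric", muS = "numeric",
                 varS = "numeric", expectedPairs = "numeric",
                 nNeurons = "integer", method = "character",
                 nNetworks = "integer", seed = "integer",
                 spec = "NullModelSpec"),
  prototype(nNetworks = NA_integer_, seed = NA_integer_)
)

setValidity("NullStatistics", function(object) {
  if (object@muZ < -1e-9 || object@muZ > 1 + 1e-9) return("muZ outside [0, 1]")
  if (abs(object@muS - (1 - object@muZ)) > 1e-9) return("muS must be 1 - muZ")
  if (object@varZ < 0 || object@varS < 0) return("variances must be >= 0")
  if (!object@method %in% c("closed_form", "quadrature", "monte_carlo")) {
    return("invalid method")
  }
  TRUE
})

#' Motif classification summary
#'
#' Fractions of unidirectional and bidirectional connection pairs relative
#' to a z threshold derived from the null model: a counted pair is
#' unidirectional when its asymmetry z exceeds the threshold, bidirectional
#' otherwise.
#'
#' @slot zThreshold classification threshold in \code{[0, 1]}.
#' @slot fracUnidirectional,fracBidirectional fractions over counted pairs;
#'   they sum to 1.
#' @slot nCounted number of counted pairs.
#' @export
setClass("MotifSummary",
  representation(zThreshold = "numeric", fracUnidirectional = "numeric",
                 fracBidirectional = "numeric", nCounted = "integer")
)

setValidity("MotifSummary", function(object) {
  if (object@zThreshold < 0 || object@zThreshold > 1) {
    return("zThreshold outside [0, 1]")
  }
  tot <- object@fracUnidirectional + object@fracBidirectional
  if (abs(tot - 1) > 1e-12) return("motif fractions must sum to 1")
  TRUE
})

#' Spectral summary of a connectivity matrix
#'
#' Fraction of eigenvalues with non-negligible imaginary part. Real
#' symmetric matrices have only real eigenvalues, so this fraction is an
#' alternative (and, under pruning, less discriminating) asymmetry
#' diagnostic.
#'
#' @slot fractionComplex fraction of non-real eigenvalues in \code{[0, 1]}.
#' @slot nEigenvalues number of eigenvalues (= N).
#' @slot tolerance relative tolerance used to call an eigenvalue complex.
#' @export
setClass("SpectralSummary",
  representation(fractionComplex = "numeric", nEigenvalues = "integer",
                 tolerance = "numeric")
)

setValidity("SpectralSummary", function(object) {
  k <- object@fractionComplex * object@nEigenvalues
  if (abs(k - round(k)) > 1e-9 || round(k) %% 2 != 0) {
    return("complex eigenvalues must come in conjugate pairs")
  }
  TRUE
})

#' Spiking-network simulation configuration
#'
#' Parameters of the leaky integrate-and-fire network with escape noise and
#' triplet spike-timing-dependent plasticity, plus the external stimulation
#' protocol. Defaults follow the case-study parameter table: membrane time
#' constant 10 ms, rest/reset -70 mV, threshold -50 mV, 1 mV per unit weight
#' per presynaptic spike, 30 mV per external event, weights bounded in
#' [0, 1], triplet-STDP constants from the visual-cortex nearest-spike
#' parameter set.
#'
#' @slot nNeurons network size N.
#' @slot tauM membrane time constant (ms).
#' @slot vRest,vReset,vTheta resting/reset and threshold potentials (mV).
#' @slot jSyn voltage jump per presynaptic spike per unit weight (mV).
#' @slot jExt voltage jump per external event (mV).
#' @slot dt simulation step (ms).
#' @slot delaySteps synaptic delivery delay in steps.
#' @slot tauR1,tauR2 decay constants of the two presynaptic traces (ms).
#' @slot tauO1,tauO2 decay constants of the two postsynaptic traces (ms).
#' @slot a2Plus,a3Plus pair and triplet long-term potentiation amplitudes.
#' @slot a2Minus,a3Minus pair and triplet long-term depression amplitudes.
#' @slot eta learning rate.
#' @slot wMin,wMax hard weight bounds.
#' @slot escapeRate escape-noise rate scale rho0 at threshold (1/ms).
#' @slot escapeDeltaU escape-noise voltage sensitivity (mV).
#' @slot protocol "frequency" or "sequential".
#' @slot rateRange min and max stimulation rate (Hz) for the frequency
#'   protocol; neurons get evenly spaced rates across the range.
#' @slot seqDelay inter-neuron delay (ms) for the sequential protocol.
#' @slot jitterFrac jitter standard deviation as a fraction of the period
#'   (frequency protocol) or of the delay (sequential protocol).
#' @slot durationMs simulated time (ms).
#' @slot pruneP pruning probability applied before learning.
#' @slot initFamily,initMu,initSigma initial-weight distribution ("uniform"
#'   on [wMin, wMax] or truncated "gaussian" with the given mean and sd).
#' @slot recordIntervalMs interval between s-trajectory samples (ms).
#' @slot traceMode "reset" (nearest-spike: traces reset to 1 on a spike) or
#'   "accumulate" (traces increase by 1).
#' @export
setClass("SimulationConfig",
  representation(nNeurons = "integer", tauM = "numeric", vRest = "numeric",
                 vReset = "numeric", vTheta = "numeric", jSyn = "numeric",
                 jExt = "numeric", dt = "numeric", delaySteps = "integer",
                 tauR1 = "numeric", tauR2 = "numeric", tauO1 = "numeric",
                 tauO2 = "numeric", a2Plus = "numeric", a3Plus = "numeric",
                 a2Minus = "numeric", a3Minus = "numeric", eta = "numeric",
                 wMin = "numeric", wMax = "numeric", escapeRate = "numeric",
                 escapeDeltaU = "numeric", protocol = "character",
                 rateRange = "numeric", seqDelay = "numeric",
                 jitterFrac = "numeric", durationMs = "numeric",
                 pruneP = "numeric", initFamily = "character",
                 initMu = "numeric", initSigma = "numeric",
                 recordIntervalMs = "numeric", traceMode = "character")
)

setValidity("SimulationConfig", function(object) {
  pos <- c(tauM = object@tauM, dt = object@dt, tauR1 = object@tauR1,
           tauR2 = object@tauR2, tauO1 = object@tauO1, tauO2 = object@tauO2,
           durationMs = object@durationMs,
           recordIntervalMs = object@recordIntervalMs)
  if (any(pos <= 0)) {
    return(sprintf("%s must be positive", names(pos)[which(pos <= 0)[1]]))
  }
  if (object@nNeurons < 2) return("need at least 2 neurons")
  if (object@vRest >= object@vTheta) return("vRest must be below vTheta")
  if (object@wMin >= object@wMax) return("weight bounds must be ordered")
  if (object@escapeDeltaU <= 0) return("escapeDeltaU must be positive")
  if (object@escapeRate <= 0) return("escapeRate must be positive")
  if (!object@protocol %in% c("frequency", "sequential")) {
    return("protocol must be 'frequency' or 'sequential'")
  }
  if (object@protocol == "frequency" && any(object@rateRange <= 0)) {
    return("stimulation rates must be positive")
  }
  if (object@protocol == "sequential" && object@seqDelay <= 0) {
    return("sequential inter-neuron delay must be positive")
  }
  if (object@pruneP < 0 || object@pruneP >= 1) return("pruneP outside [0, 1)")
  if (!object@traceMode %in% c("reset", "accumulate")) {
    return("traceMode must be 'reset' or 'accumulate'")
  }
  if (!object@initFamily %in% c("uniform", "gaussian")) {
    return("initFamily must be 'uniform' or 'gaussian'")
  }
  if (object@delaySteps < 1) return("delaySteps must be >= 1")
  TRUE
})

#' Spiking-network simulation result
#'
#' @slot sTrajectory data.frame with columns time_ms and s, sampled every
#'   \code{recordIntervalMs} (first row is the pre-learning state).
#' @slot finalWeights the learned [WeightMatrix-class].
#' @slot spikes list of per-neuron spike times (ms).
#' @slot mask logical pruning mask (TRUE = permanently disconnected).
#' @slot seed RNG seed of the run.
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("SimulationResult",
  representation(sTrajectory = "data.frame", finalWeights = "WeightMatrix",
                 spikes = "list", mask = "matrix", seed = "integer",
                 config = "SimulationConfig")
)
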