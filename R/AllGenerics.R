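#' @include AllClasses.R
NULL

#' Number of neurons
#'
#' @param object a [WeightMatrix-class], [SimulationConfig-class] or other
#'   object carrying a network size.
#' @return integer network size N.
#' @export
setGeneric("nNeurons", function(object) standardGeneric("nNeurons"))

#' @describeIn nNeurons network size of a weight matrix.
#' @export
setMethod("nNeurons", "WeightMatrix", function(object) nrow(object@weights))

#' @describeIn nNeurons configured network size.
#' @export
setMethod("nNeurons", "SimulationConfig", function(object) object@nNeurons)

#' Extract the weight matrix
#'
#' @param object a [WeightMatrix-class].
#' @param ... unused.
#' @return the underlying numeric matrix.
#' @export
setMethod("weights", "WeightMatrix", function(object, ...) object@weights)

#' Symmetry measure value
#'
#' @param object a [SymmetryReport-class].
#' @return the value of s.
#' @export
setGeneric("sValue", function(object) standardGeneric("sValue"))

#' @describeIn sValue value of s in a report.
#' @export
setMethod("sValue", "SymmetryReport", function(object) object@s)

#' Test verdict
#'
#' @param object a [SymmetryReport-class].
#' @return "symmetric", "asymmetric", "random" or "untested".
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @describeIn verdict verdict of a report.
#' @export
setMethod("verdict", "SymmetryReport", function(object) object@verdict)

#' p-value of a significance test
#'
#' @param object a [SymmetryReport-class].
#' @return the p-value, or NA when untested.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @describeIn pValue p-value of a report.
#' @export
setMethod("pValue", "SymmetryReport", function(object) object@pValue)

#' Null-model moments accessors
#'
#' @param object a [NullStatistics-class].
#' @return the requested moment.
#' @name null-accessors
NULL

#' @rdname null-accessors
#' @export
setGeneric("muS", function(object) standardGeneric("muS"))

#' @rdname null-accessors
#' @export
setMethod("muS", "NullStatistics", function(object) object@muS)

#' @rdname null-accessors
#' @export
setGeneric("varS", function(object) standardGeneric("varS"))

#' @rdname null-accessors
#' @export
setMethod("varS", "NullStatistics", function(object) object@varS)

#' @rdname null-accessors
#' @export
setGeneric("muZ", function(object) standardGeneric("muZ"))

#' @rdname null-accessors
#' @export
setMethod("muZ", "NullStatistics", function(object) object@muZ)

#' @rdname null-accessors
#' @export
setGeneric("varZ", function(object) standardGeneric("varZ"))

#' @rdname null-accessors
#' @export
setMethod("varZ", "NullStatistics", function(object) object@varZ)

#' s trajectory of a simulation
#'
#' @param object a [SimulationResult-class].
#' @return data.frame with columns time_ms and s.
#' @export
setGeneric("sTrajectory", function(object) standardGeneric("sTrajectory"))

#' @describeIn sTrajectory recorded trajectory.
#' @export
setMethod("sTrajectory", "SimulationResult",
          function(object) object@sTrajectory)

#' Final weights of a simulation
#'
#' @param object a [SimulationResult-class].
#' @return a [WeightMatrix-class].
#' @export
setGeneric("finalWeights", function(object) standardGeneric("finalWeights"))

#' @describeIn finalWeights learned weight matrix.
#' @export
setMethod("finalWeights", "SimulationResult",
          function(object) object@finalWeights)

setMethod("show", "WeightMatrix", function(object) {
  n <- nNeurons(object)
  nz <- sum(object@weights > 0)
  cat(sprintf("WeightMatrix: %d neurons, %d/%d nonzero connections, wMax = %g\n",
              n, nz, n * (n - 1), object@wMax))
})

setMethod("show", "PairDecomposition", function(object) {
  cat(sprintf("PairDecomposition: %d counted pairs, %d (0,0) pairs excluded\n",
              object@nCounted, object@nZeroPairs))
})

setMethod("show", "SymmetryReport", function(object) {
  cat(sprintf("SymmetryReport: s = %.6f over %d pairs (%d excluded)\n",
              object@s, object@nCounted, object@nZeroPairs))
  if (!is.na(object@zScore)) {
    cat(sprintf("  z = %.3f, p = %.3g, verdict: %s (alpha = %g)\n",
                object@zScore, object@pValue, object@verdict, object@alpha))
  } else {
    cat("  verdict: untested\n")
  }
})

setMethod("show", "NullModelSpec", function(object) {
  cat(sprintf("NullModelSpec: %s on [%g, %g]", object@family, object@wMin,
              object@wMax))
  if (object@family == "gaussian") {
    cat(sprintf(", mu = %g, sigma = %g", object@mu, object@sigma))
  }
  cat(sprintf(", pruning p = %g\n", object@pruneP))
})

setMethod("show", "NullStatistics", function(object) {
  cat(sprintf("NullStatistics (%s): mu_s = %.6f, sigma_s = %.6f (N = %d)\n",
              object@method, object@muS, sqrt(object@varS), object@nNeurons))
  cat(sprintf("  mu_z = %.6f, var_z = %.6f, E[pairs] = %.2f\n",
              object@muZ, object@varZ, object@expectedPairs))
  if (!is.na(object@nNetworks)) {
    cat(sprintf("  Monte Carlo over %d networks\n", object@nNetworks))
  }
})

setMethod("show", "MotifSummary", function(object) {
  cat(sprintf(paste0("MotifSummary: %.1f%% bidirectional, %.1f%% ",
                     "unidirectional (z threshold %.4f, %d pairs)\n"),
              100 * object@fracBidirectional, 100 * object@fracUnidirectional,
              object@zThreshold, object@nCounted))
})

setMethod("show", "SpectralSummary", function(object) {
  cat(sprintf("SpectralSummary: %d/%d complex eigenvalues (fraction %.3f)\n",
              round(object@fractionComplex * object@nEigenvalues),
              object@nEigenvalues, object@fractionComplex))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: N = %d, %s protocol, %.0f ms, dt = %g ms\n",
              object@nNeurons, object@protocol, object@durationMs, object@dt))
  cat(sprintf("  init %s weights, pruning p = %g, eta = %g, traces: %s\n",
              object@initFamily, object@pruneP, object@eta, object@traceMode))
})

setMethod("show", "SimulationResult", function(object) {
  tr <- object@sTrajectory
  cat(sprintf("SimulationResult: seed %d, s: %.4f -> %.4f over %.0f ms\n",
              object@seed, tr$s[1], tr$s[nrow(tr)],
              tr$time_ms[nrow(tr)]))
})
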