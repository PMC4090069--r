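#' @include AllClasses.R null-stats.R
NULL

#' Significance test of an observed symmetry measure
#'
#' Tests whether an observed s is compatible with the null model of random
#' connectivity: the z-score is (s_obs - mu_s) / sigma_s and the p-value
#' follows from the normal approximation of the s null distribution (s is a
#' mean over many approximately independent pairs). The verdict is
#' "symmetric" when the null is rejected with s_obs above the null mean,
#' "asymmetric" when rejected below it, and "random" otherwise.
#'
#' @param sObs observed symmetry measure, either a number or a
#'   [SymmetryReport-class] (whose pair counts are carried through).
#' @param null a [NullStatistics-class] for the matching family, pruning
#'   and network size.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param sided "two" (default), "greater" (alternative: more symmetric
#'   than random) or "less" (more asymmetric).
#' @return A [SymmetryReport-class] with z-score, p-value and verdict.
#' @examples
#' null <- momentsS(nullModelSpec("uniform"), 30)
#' significanceTest(0.75, null)            # verdict "symmetric"
#' significanceTest(muS(null), null)       # p = 1, verdict "random"
#' @export
significanceTest <- function(sObs, null, alpha = 0.05,
                             sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  stopifnot(is(null, "NullStatistics"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly inside (0, 1)")
  }
  nCounted <- NA_integer_
  nZero <- NA_integer_
  if (is(sObs, "SymmetryReport")) {
    nCounted <- sObs@nCounted
    nZero <- sObs@nZeroPairs
    sObs <- sObs@s
  }
  stopifnot(is.numeric(sObs), length(sObs) == 1)
  if (null@varS <= 0) {
    stop("degenerate null model: varS must be positive")
  }
  z <- (sObs - null@muS) / sqrt(null@varS)
  p <- switch(sided,
    two = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z)
  )
  p <- min(1, max(p, .Machine$double.xmin))
  verdict <- if (p >= alpha) "random" else if (sObs > null@muS) {
    "symmetric"
  } else {
    "asymmetric"
  }
  new("SymmetryReport", s = sObs, nCounted = nCounted, nZeroPairs = nZero,
      zScore = z, pValue = p, verdict = verdict, alpha = alpha)
}

#' Motif classification threshold
#'
#' The z value separating unidirectional from bidirectional connection
#' pairs: the null-model mean of z, i.e. 1 - mu_s. Pairs more asymmetric
#' than a random pair (z above the threshold) count as unidirectional.
#'
#' @param null a [NullStatistics-class].
#' @return The threshold z value in \code{[0, 1]}.
#' @examples
#' motifThreshold(momentsS(nullModelSpec("uniform"), 30))  # 2 log 2 - 1
#' @export
motifThreshold <- function(null) {
  stopifnot(is(null, "NullStatistics"))
  1 - null@muS
}

#' Classify connection pairs into motifs
#'
#' Each counted pair is unidirectional when its asymmetry z strictly
#' exceeds the threshold, bidirectional otherwise (ties count as
#' bidirectional). The fraction of bidirectional pairs grows linearly with
#' the symmetry measure s of the network.
#'
#' @param W a [WeightMatrix-class].
#' @param zThreshold threshold in \code{[0, 1]}, typically from
#'   [motifThreshold()].
#' @param floor optional detection floor passed to [pairDecompose()].
#' @return A [MotifSummary-class].
#' @examples
#' W <- randomNetwork(30, nullModelSpec("uniform"), seed = 1)
#' classifyMotifs(W, motifThreshold(momentsS(nullModelSpec("uniform"), 30)))
#' @export
classifyMotifs <- function(W, zThreshold, floor = 0) {
  if (!is.numeric(zThreshold) || length(zThreshold) != 1 ||
      zThreshold < 0 || zThreshold > 1) {
    stop("zThreshold must lie in [0, 1]")
  }
  pd <- pairDecompose(W, floor = floor)
  if (pd@nCounted == 0) {
    stop("motif fractions undefined: every pair is (0,0)")
  }
  z <- pd@pairs$z[!is.na(pd@pairs$z)]
  uni <- mean(z > zThreshold)
  new("MotifSummary", zThreshold = zThreshold, fracUnidirectional = uni,
      fracBidirectional = 1 - uni, nCounted = pd@nCounted)
}
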