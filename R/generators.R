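#' @include AllClasses.R null-stats.R
NULL

#' Apply random synaptic pruning
#'
#' Each off-diagonal directed connection is permanently removed (set to
#' zero) independently with probability p. The boolean mask is returned so
#' that downstream code (notably the plasticity simulator) can hold the
#' pruned connections at zero for all time.
#'
#' @param W a [WeightMatrix-class].
#' @param p pruning probability in \code{[0, 1)}.
#' @param seed optional RNG seed; \code{NULL} uses the current RNG state.
#' @return List with elements \code{weights} (the pruned
#'   [WeightMatrix-class]) and \code{mask} (logical matrix, TRUE =
#'   permanently disconnected; diagonal TRUE by convention).
#' @examples
#' W <- randomNetwork(10, nullModelSpec("uniform"), seed = 1)
#' pr <- applyPruning(W, 0.5, seed = 2)
#' sum(pr$mask[upper.tri(pr$mask) | lower.tri(pr$mask)])
#' @export
applyPruning <- function(W, p, seed = NULL) {
  stopifnot(is(W, "WeightMatrix"))
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p >= 1) {
    stop("pruning probability must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nNeurons(W)
  mask <- matrix(stats::runif(n * n) < p, n, n)
  diag(mask) <- TRUE
  w <- W@weights
  w[mask] <- 0
  list(weights = WeightMatrix(w, wMax = W@wMax), mask = mask)
}

# Fill the off-diagonal of an n x n matrix with i.i.d. family draws and
# apply an independent pruning mask; internal core of randomNetwork.
.randomWeights <- function(n, spec) {
  w <- matrix(0, n, n)
  off <- row(w) != col(w)
  w[off] <- .sampleFamily(sum(off), spec)
  if (spec@pruneP > 0) {
    w[off][stats::runif(sum(off)) < spec@pruneP] <- 0
  }
  w
}

#' Random network from a null model
#'
#' Off-diagonal weights are i.i.d. draws from the family (uniform on
#' \code{[wMin, wMax]} or truncated Gaussian), each then independently
#' pruned to zero with probability \code{pruneP}.
#'
#' @param n network size (>= 2).
#' @param spec a [NullModelSpec-class].
#' @param seed optional RNG seed; \code{NULL} uses the current RNG state.
#' @return A [WeightMatrix-class].
#' @examples
#' W <- randomNetwork(30, nullModelSpec("uniform"), seed = 1)
#' sValue(symmetryMeasure(W))  # near 2 - 2 log 2
#' @export
randomNetwork <- function(n, spec, seed = NULL) {
  stopifnot(is(spec, "NullModelSpec"), n >= 2)
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  WeightMatrix(.randomWeights(as.integer(n), spec), wMax = spec@wMax)
}

#' Symmetric random network
#'
#' The upper triangle is drawn from the family and mirrored below the
#' diagonal, so that without pruning every pair has z = 0 and s = 1
#' exactly. Pruning (if any) is applied per directed connection after
#' mirroring, so it can break the symmetry: the more one prunes, the more a
#' symmetric network appears asymmetric.
#'
#' @inheritParams randomNetwork
#' @return A [WeightMatrix-class].
#' @examples
#' sValue(symmetryMeasure(symmetricNetwork(10, nullModelSpec("uniform"),
#'                                         seed = 1)))  # exactly 1
#' @export
symmetricNetwork <- function(n, spec, seed = NULL) {
  stopifnot(is(spec, "NullModelSpec"), n >= 2)
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- .sampleFamily(sum(ut), spec)
  w <- w + t(w)
  if (spec@pruneP > 0) {
    off <- row(w) != col(w)
    w[off][stats::runif(sum(off)) < spec@pruneP] <- 0
  }
  WeightMatrix(w, wMax = spec@wMax)
}

#' Asymmetric random network
#'
#' For each unordered pair one direction is drawn from the family and the
#' other is set to a small value uniform on \code{[0, eps]} (with
#' \code{eps = 0}, strictly unidirectional, giving s = 0 exactly). Which
#' direction carries the strong weight is chosen uniformly at random.
#' Pruning is applied afterwards; it cannot raise s when the weak side is
#' already zero, so the lower bound s = 0 is unchanged under pruning.
#'
#' @inheritParams randomNetwork
#' @param eps upper bound of the weak direction (must be below
#'   \code{wMax}; default 0).
#' @return A [WeightMatrix-class].
#' @examples
#' sValue(symmetryMeasure(asymmetricNetwork(10, nullModelSpec("uniform"),
#'                                          seed = 1)))  # exactly 0
#' @export
asymmetricNetwork <- function(n, spec, eps = 0, seed = NULL) {
  stopifnot(is(spec, "NullModelSpec"), n >= 2)
  validObject(spec)
  if (!is.numeric(eps) || length(eps) != 1 || eps < 0 || eps >= spec@wMax) {
    stop("eps must lie in [0, wMax)")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  w <- matrix(0, n, n)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  m <- nrow(idx)
  strong <- .sampleFamily(m, spec)
  weak <- if (eps > 0) stats::runif(m, 0, eps) else numeric(m)
  flip <- stats::runif(m) < 0.5
  up <- ifelse(flip, strong, weak)
  dn <- ifelse(flip, weak, strong)
  w[idx] <- up
  w[idx[, c(2, 1), drop = FALSE]] <- dn
  if (spec@pruneP > 0) {
    off <- row(w) != col(w)
    w[off][stats::runif(sum(off)) < spec@pruneP] <- 0
  }
  WeightMatrix(w, wMax = spec@wMax)
}

#' Network with a prescribed symmetry measure
#'
#' Random networks only cover a narrow band of s values; to sample the full
#' range, pair asymmetries are prescribed directly. For each unordered pair
#' the larger weight a is drawn from the family, z is drawn from a Gaussian
#' centred at 1 - sTarget with standard deviation sigmaZ (clipped to
#' \code{[0, 1]}), and the smaller weight is a (1 - z) / (1 + z), which
#' keeps both weights inside \code{[0, wMax]} by construction. The strong
#' direction is assigned uniformly at random and pruning (if configured in
#' \code{spec}) is applied afterwards.
#'
#' The default sigmaZ is adaptive: 0.5 in the mid-range, shrunk to
#' 1.4 min(1 - sTarget, sTarget) near the extremes so that boundary
#' clipping does not pull the realised mean far off target (the measured s
#' stays within about 0.05 of sTarget, much closer away from the
#' extremes). The wide mid-range spread gives each network a broad
#' within-network distribution of pair asymmetries, as random networks
#' have, which makes the bidirectional-motif fraction vary linearly with s
#' across the whole domain; a narrow spread (e.g. 0.05) prescribes nearly
#' identical z for every pair instead and turns that relation into a step.
#'
#' @inheritParams randomNetwork
#' @param sTarget target symmetry measure, strictly inside (0, 1).
#' @param sigmaZ standard deviation of the prescribed z values, or
#'   \code{NULL} (default) for the adaptive choice described above.
#' @return A [WeightMatrix-class] whose measured s is close to
#'   \code{sTarget} (exactly equal as sigmaZ tends to 0 without pruning).
#' @examples
#' W <- prescribedSNetwork(30, 0.5, nullModelSpec("uniform"), seed = 1)
#' sValue(symmetryMeasure(W))
#' @export
prescribedSNetwork <- function(n, sTarget, spec, sigmaZ = NULL,
                               seed = NULL) {
  stopifnot(is(spec, "NullModelSpec"), n >= 2)
  validObject(spec)
  if (!is.numeric(sTarget) || length(sTarget) != 1 || sTarget <= 0 ||
      sTarget >= 1) {
    stop("sTarget must lie strictly inside (0, 1)")
  }
  if (is.null(sigmaZ)) {
    sigmaZ <- min(0.5, 1.4 * min(sTarget, 1 - sTarget))
  }
  if (!is.numeric(sigmaZ) || sigmaZ <= 0) stop("sigmaZ must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  w <- matrix(0, n, n)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  m <- nrow(idx)
  a <- .sampleFamily(m, spec)
  z <- pmin(1, pmax(0, stats::rnorm(m, 1 - sTarget, sigmaZ)))
  b <- a * (1 - z) / (1 + z)  # z clipped at 1 gives b = 0: unidirectional
  flip <- stats::runif(m) < 0.5
  up <- ifelse(flip, a, b)
  dn <- ifelse(flip, b, a)
  w[idx] <- up
  w[idx[, c(2, 1), drop = FALSE]] <- dn
  if (spec@pruneP > 0) {
    off <- row(w) != col(w)
    w[off][stats::runif(sum(off)) < spec@pruneP] <- 0
  }
  WeightMatrix(w, wMax = spec@wMax)
}
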