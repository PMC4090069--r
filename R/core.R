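#' @include AllClasses.R
NULL

# Internal fast path: s from a plain weight matrix. Returns list(s, nCounted,
# nZeroPairs); s is NA when every pair is (0,0).
.sFromMatrix <- function(w, floor = 0) {
  if (floor > 0) w[w < floor] <- 0
  ut <- upper.tri(w)
  a <- w[ut]
  b <- t(w)[ut]
  u <- a + b
  counted <- u > 0
  p <- sum(counted)
  n0 <- sum(!counted)
  s <- if (p == 0) NA_real_ else 1 - mean(abs(a[counted] - b[counted]) /
                                            u[counted])
  list(s = s, nCounted = p, nZeroPairs = n0)
}

#' Decompose a connectivity matrix into connection pairs
#'
#' For each unordered neuron pair (i, j), i < j, computes the pair sum
#' u = w_ij + w_ji, the absolute difference v = |w_ij - w_ji| and the
#' normalised asymmetry z = v / u. Pairs with both weights zero carry no
#' reciprocity information and are excluded from the counted set (their z
#' is undefined); they are tallied separately.
#'
#' @param W a [WeightMatrix-class] (or a plain matrix, which is validated).
#' @param floor detection floor: weights strictly below it are treated as
#'   zero before decomposition (default 0, i.e. only exact zeros are
#'   excluded). Mimics a measurement detection limit.
#' @return A [PairDecomposition-class].
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- 0.2; w[2, 1] <- 0.6   # pair (1,2): z = 0.5
#' w[1, 3] <- 0.5; w[3, 1] <- 0.5   # pair (1,3): z = 0
#' pairDecompose(WeightMatrix(w))   # pair (2,3) is (0,0): excluded
#' @export
pairDecompose <- function(W, floor = 0) {
  if (!is(W, "WeightMatrix")) W <- WeightMatrix(W)
  stopifnot(is.numeric(floor), length(floor) == 1, floor >= 0)
  w <- W@weights
  if (floor > 0) w[w < floor] <- 0
  n <- nrow(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  i <- idx[, 1]
  j <- idx[, 2]
  # orientation is irrelevant for u, v: w[i,j] + w[j,i] is symmetric in (i,j)
  a <- w[cbind(i, j)]
  b <- w[cbind(j, i)]
  u <- a + b
  v <- abs(a - b)
  z <- ifelse(u > 0, v / u, NA_real_)
  pairs <- data.frame(i = i, j = j, u = u, v = v, z = z)
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  n0 <- sum(u == 0)
  new("PairDecomposition", pairs = pairs, nZeroPairs = as.integer(n0),
      nCounted = as.integer(nrow(pairs) - n0))
}

#' Symmetry measure of a connectivity matrix
#'
#' Computes s = 1 - mean(z) over all counted connection pairs, where
#' z = |w_ij - w_ji| / (w_ij + w_ji) and pairs with both weights zero are
#' excluded. s = 1 for a fully reciprocal (symmetric) matrix, s = 0 for a
#' strictly unidirectional one. The measure needs no weight threshold and
#' no knowledge of the maximal weight: it is invariant under rescaling,
#' transposition and simultaneous row/column permutation.
#'
#' @inheritParams pairDecompose
#' @return A [SymmetryReport-class] with verdict "untested"; pass it to
#'   [significanceTest()] to test against a null model.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- 0.2; w[2, 1] <- 0.6
#' w[1, 3] <- 0.5; w[3, 1] <- 0.5
#' sValue(symmetryMeasure(WeightMatrix(w)))  # 1 - (0.5 + 0)/2 = 0.75
#' @export
symmetryMeasure <- function(W, floor = 0) {
  if (!is(W, "WeightMatrix")) W <- WeightMatrix(W)
  res <- .sFromMatrix(W@weights, floor = floor)
  if (res$nCounted == 0) {
    stop("symmetry measure undefined: every pair is (0,0)")
  }
  new("SymmetryReport", s = res$s, nCounted = as.integer(res$nCounted),
      nZeroPairs = as.integer(res$nZeroPairs))
}
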