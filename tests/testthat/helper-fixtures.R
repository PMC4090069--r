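# Hand-worked 3-neuron matrix: pair (1,2) has z = 0.5, pair (1,3) has
# z = 0, pair (2,3) is (0,0) and is excluded; s = 1 - (0.5 + 0)/2 = 0.75.
handWorked3 <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 0.2
  w[2, 1] <- 0.6
  w[1, 3] <- 0.5
  w[3, 1] <- 0.5
  WeightMatrix(w)
}

# Independent brute-force evaluation of the symmetry measure, written
# directly from the definition as a double loop over ordered index pairs
# (i < j), with no shared code with the package internals.
bruteForceS <- function(w) {
  n <- nrow(w)
  total <- 0
  counted <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (w[i, j] == 0 && w[j, i] == 0) next
      total <- total + abs(w[i, j] - w[j, i]) / (w[i, j] + w[j, i])
      counted <- counted + 1
    }
  }
  1 - total / counted
}

# Random valid weight matrix (possibly with zeroed entries).
randomTestMatrix <- function(n, zeroFrac = 0) {
  w <- matrix(runif(n * n), n, n)
  if (zeroFrac > 0) w[runif(n * n) < zeroFrac] <- 0
  diag(w) <- 0
  w
}

uspec <- function(p = 0) nullModelSpec("uniform", pruneP = p)
gspec <- function(p = 0) nullModelSpec("gaussian", sigma = 0.1, pruneP = p)
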