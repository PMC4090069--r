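#' @include AllClasses.R generators.R
NULL

#' Fraction of complex eigenvalues
#'
#' Real symmetric matrices have purely real spectra, so the fraction of
#' eigenvalues with non-negligible imaginary part is an asymmetry
#' diagnostic. An eigenvalue counts as complex when |Im| exceeds
#' \code{relTol * max(1, spectral radius)}: relative to the spectral radius
#' for scale invariance, with an absolute floor of \code{relTol} so that
#' rounding noise on small spectra is not misread as complexity.
#'
#' @param W a [WeightMatrix-class].
#' @param relTol relative tolerance (default 1e-9).
#' @return A [SpectralSummary-class].
#' @examples
#' sym <- symmetricNetwork(10, nullModelSpec("uniform"), seed = 1)
#' fractionComplexEigenvalues(sym)  # 0: symmetric spectra are real
#' @export
fractionComplexEigenvalues <- function(W, relTol = 1e-9) {
  stopifnot(is(W, "WeightMatrix"), is.numeric(relTol), relTol >= 0)
  ev <- eigen(W@weights, only.values = TRUE)$values
  rad <- max(Mod(ev))
  k <- sum(abs(Im(ev)) > relTol * max(1, rad))
  new("SpectralSummary", fractionComplex = k / length(ev),
      nEigenvalues = length(ev), tolerance = relTol)
}

#' Ensemble sweep of the eigenvalue diagnostic and the symmetry measure
#'
#' For each pruning level and each ensemble (symmetric, asymmetric with
#' weak-side bound eps, random), generates \code{nNetworks} networks and
#' records mean and standard deviation of both the fraction of complex
#' eigenvalues and the symmetry measure s. Under pruning, the asymmetric
#' and random ensembles overlap substantially in the eigenvalue diagnostic
#' while s keeps them far apart, which is the case for preferring s.
#'
#' @param spec a [NullModelSpec-class]; its \code{pruneP} is ignored, the
#'   sweep grid supplies the pruning levels.
#' @param n network size.
#' @param nNetworks networks per (p, ensemble) cell.
#' @param pGrid pruning levels in \code{[0, 1)}.
#' @param eps weak-side bound of the asymmetric ensemble (default 0.01).
#' @param seed RNG seed.
#' @return data.frame with columns p, ensemble, meanFracComplex,
#'   sdFracComplex, meanS, sdS, nNetworks.
#' @examples
#' spectralSweep(nullModelSpec("uniform"), n = 20, nNetworks = 20,
#'               pGrid = c(0, 0.3), seed = 1)
#' @export
spectralSweep <- function(spec, n, nNetworks, pGrid, eps = 0.01, seed = 1) {
  stopifnot(is(spec, "NullModelSpec"), all(pGrid >= 0 & pGrid < 1),
            nNetworks >= 2)
  set.seed(seed)
  ensembles <- c("symmetric", "asymmetric", "random")
  rows <- vector("list", length(pGrid) * length(ensembles))
  k <- 0
  for (p in pGrid) {
    sp <- nullModelSpec(spec@family, wMin = spec@wMin, wMax = spec@wMax,
                        mu = spec@mu, sigma = spec@sigma, pruneP = p)
    for (ens in ensembles) {
      fc <- numeric(nNetworks)
      sv <- numeric(nNetworks)
      for (m in seq_len(nNetworks)) {
        W <- switch(ens,
          symmetric = symmetricNetwork(n, sp),
          asymmetric = asymmetricNetwork(n, sp, eps = eps),
          random = randomNetwork(n, sp)
        )
        fc[m] <- fractionComplexEigenvalues(W)@fractionComplex
        res <- .sFromMatrix(W@weights)
        sv[m] <- res$s
      }
      k <- k + 1
      rows[[k]] <- data.frame(p = p, ensemble = ens,
                              meanFracComplex = mean(fc),
                              sdFracComplex = stats::sd(fc),
                              meanS = mean(sv, na.rm = TRUE),
                              sdS = stats::sd(sv, na.rm = TRUE),
                              nNetworks = nNetworks)
    }
  }
  do.call(rbind, rows)
}
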