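#' @include AllClasses.R core.R
NULL

# Normalised (continuous, unpruned) single-weight density of a family.
.familyPdf <- function(spec) {
  if (spec@family == "uniform") {
    r <- spec@wMax - spec@wMin
    lo <- spec@wMin
    hi <- spec@wMax
    function(w) ifelse(w >= lo & w <= hi, 1 / r, 0)
  } else {
    zc <- stats::pnorm(spec@wMax, spec@mu, spec@sigma) -
      stats::pnorm(spec@wMin, spec@mu, spec@sigma)
    lo <- spec@wMin
    hi <- spec@wMax
    mu <- spec@mu
    sg <- spec@sigma
    function(w) ifelse(w >= lo & w <= hi, stats::dnorm(w, mu, sg) / zc, 0)
  }
}

# Draw n i.i.d. weights from the (unpruned) family. Truncated Gaussians are
# drawn by rejection from the parent normal; under the narrowness constraint
# the rejection rate is < 1e-4.
.sampleFamily <- function(n, spec) {
  if (spec@family == "uniform") {
    return(stats::runif(n, spec@wMin, spec@wMax))
  }
  x <- stats::rnorm(n, spec@mu, spec@sigma)
  bad <- which(x < spec@wMin | x > spec@wMax)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), spec@mu, spec@sigma)
    bad <- bad[x[bad] < spec@wMin | x[bad] > spec@wMax]
  }
  x
}

#' Null densities of the pair statistics
#'
#' Builds the probability densities of a single weight w, of the pair sum
#' u = w_ij + w_ji, of the absolute difference v = |w_ij - w_ji|, and of the
#' joint (u, v), under the null model, conditioned on the pair having at
#' least one alive weight. With pruning probability p, the pair law is an
#' explicit mixture: with weight (1-p)/(1+p) both weights survive and
#' (u, v) follows the continuous unpruned joint density; with weight
#' 2p/(1+p) exactly one survives, so v = u and the mass sits on that line
#' with the single-weight family density along it. (0,0) pairs are excluded
#' by the conditioning.
#'
#' For the uniform family on \code{[0, 1]} without pruning, u has the
#' symmetric triangular density on \code{[0, 2]} and v has density
#' 2(1 - v). For the truncated-Gaussian family the sum and difference
#' densities are obtained in closed form from products of normal densities.
#'
#' @param spec a [NullModelSpec-class].
#' @return A [DensityBundle-class]. \code{pdfU} and \code{pdfV} are the full
#'   mixture marginals (each integrates to 1); \code{pdfW} is the continuous
#'   part of the single-weight law (integrates to 1 - p, with an atom of
#'   mass p at zero); \code{jointCont} integrates to (1-p)/(1+p) over the
#'   triangle and \code{lineDensity} to 2p/(1+p) along v = u.
#' @examples
#' b <- nullDensities(nullModelSpec("uniform"))
#' b@pdfV(0.5)  # 2 * (1 - 0.5) = 1
#' @export
nullDensities <- function(spec) {
  stopifnot(is(spec, "NullModelSpec"))
  validObject(spec)
  p <- spec@pruneP
  contW <- (1 - p) / (1 + p)
  pruneW <- 2 * p / (1 + p)
  fw <- .familyPdf(spec)
  lo <- spec@wMin
  hi <- spec@wMax

  if (spec@family == "uniform") {
    r <- hi - lo
    fsum <- function(u) {
      ifelse(u >= 2 * lo & u <= lo + hi, (u - 2 * lo) / r^2,
             ifelse(u > lo + hi & u <= 2 * hi, (2 * hi - u) / r^2, 0))
    }
    fdiff <- function(v) ifelse(v >= 0 & v <= r, 2 * (r - v) / r^2, 0)
  } else {
    mu <- spec@mu
    sg <- spec@sigma
    zc <- stats::pnorm(hi, mu, sg) - stats::pnorm(lo, mu, sg)
    s2 <- sg / sqrt(2)
    # f_U(u) = int fW(t) fW(u - t) dt; the product of the two normal
    # densities factorises as N(u; 2 mu, 2 sigma^2) * N(t; u/2, sigma^2/2).
    fsum <- function(u) {
      a <- pmax(lo, u - hi)
      b <- pmin(hi, u - lo)
      out <- stats::dnorm(u, 2 * mu, sqrt(2) * sg) / zc^2 *
        (stats::pnorm(b, u / 2, s2) - stats::pnorm(a, u / 2, s2))
      ifelse(b > a, out, 0)
    }
    # f_V(v) = 2 int fW(t) fW(t + v) dt for v >= 0.
    fdiff <- function(v) {
      ctr <- mu - v / 2
      out <- 2 * stats::dnorm(v, 0, sqrt(2) * sg) / zc^2 *
        (stats::pnorm(hi - v, ctr, s2) - stats::pnorm(lo, ctr, s2))
      ifelse(v >= 0 & v <= hi - lo, pmax(out, 0), 0)
    }
  }

  pdfU <- function(u) contW * fsum(u) + pruneW * fw(u)
  pdfV <- function(v) contW * fdiff(v) + pruneW * fw(v)
  pdfW <- function(w) (1 - p) * fw(w)
  # change of variables (a, b) -> (u, v): two branches, |Jacobian| = 2
  jointCont <- function(u, v) {
    ok <- v >= 0 & v <= u & (u + v) / 2 <= hi & (u - v) / 2 >= lo
    ifelse(ok, contW * fw((u + v) / 2) * fw((u - v) / 2), 0)
  }
  lineDensity <- function(u) pruneW * fw(u)

  new("DensityBundle", pdfW = pdfW, pdfU = pdfU, pdfV = pdfV,
      jointCont = jointCont, lineDensity = lineDensity,
      contWeight = contW, pruneWeight = pruneW,
      wContWeight = 1 - p, wAtomZero = p,
      support = list(w = c(lo, hi), u = c(2 * lo, 2 * hi),
                     v = c(0, hi - lo)),
      spec = spec)
}

# Unpruned moments E[z] and E[z^2] for a family; closed form for the
# uniform family anchored at zero, 2-D quadrature otherwise.
.momentsZ0 <- function(spec, absTol = 1e-10) {
  if (spec@family == "uniform" && spec@wMin == 0) {
    # E|a-b|/(a+b) over the unit square = 2 log 2 - 1 (scale-invariant)
    return(list(m1 = 2 * log(2) - 1, m2 = 3 - 4 * log(2),
                method = "closed_form"))
  }
  fw <- .familyPdf(spec)
  # |a - b| has a kink on the diagonal; integrate over the smooth triangle
  # b < a and double (the integrand is symmetric under swapping a and b)
  f1 <- function(x, y) (x - y) / (x + y) * fw(x) * fw(y)
  f2 <- function(x, y) ((x - y) / (x + y))^2 * fw(x) * fw(y)
  m1 <- pracma::integral2(f1, spec@wMin, spec@wMax, spec@wMin,
                          function(x) x, reltol = 1e-10, abstol = absTol)
  m2 <- pracma::integral2(f2, spec@wMin, spec@wMax, spec@wMin,
                          function(x) x, reltol = 1e-10, abstol = absTol)
  m1$Q <- 2 * m1$Q
  m2$Q <- 2 * m2$Q
  if (!is.finite(m1$Q) || !is.finite(m2$Q)) {
    stop("quadrature for the z moments did not converge (error estimates ",
         m1$error, ", ", m2$error, ")")
  }
  list(m1 = m1$Q, m2 = m2$Q, method = "quadrature")
}

#' Mean and variance of the pair asymmetry z under a null model
#'
#' For the uniform family on \code{[0, wMax]} the unpruned moments have
#' closed forms (E[z] = 2 log 2 - 1, E[z^2] = 3 - 4 log 2); the
#' truncated-Gaussian moments are computed by two-dimensional quadrature of
#' z = |a - b|/(a + b) against the product of the truncated densities.
#' Pruning enters through the exact mixture identity
#' \deqn{E[z; p] = \frac{(1-p) E[z; 0] + 2p}{1 + p}}
#' (and the same identity for E[z^2]): with probability 2p/(1+p) a counted
#' pair has exactly one alive weight and z = 1 exactly.
#'
#' @param spec a [NullModelSpec-class].
#' @return Named list with \code{muZ}, \code{varZ} and \code{method}
#'   ("closed_form" or "quadrature").
#' @examples
#' momentsZ(nullModelSpec("uniform"))$muZ        # 2 log 2 - 1
#' momentsZ(nullModelSpec("uniform", pruneP = 0.5))$muZ
#' @export
momentsZ <- function(spec) {
  stopifnot(is(spec, "NullModelSpec"))
  validObject(spec)
  m0 <- .momentsZ0(spec)
  p <- spec@pruneP
  m1 <- ((1 - p) * m0$m1 + 2 * p) / (1 + p)
  m2 <- ((1 - p) * m0$m2 + 2 * p) / (1 + p)
  list(muZ = m1, varZ = m2 - m1^2, method = m0$method)
}

#' Null statistics of the symmetry measure s
#'
#' Converts the z moments into moments of s for a network of N neurons:
#' mu_s = 1 - mu_z and var_s = var_z / E[P], where
#' E[P] = (1 - p^2) N(N-1)/2 is the expected number of counted pairs (each
#' of the N(N-1)/2 pairs survives the pruning of both its weights with
#' probability 1 - p^2).
#'
#' @param spec a [NullModelSpec-class].
#' @param nNeurons network size N (>= 2).
#' @return A [NullStatistics-class].
#' @examples
#' ns <- momentsS(nullModelSpec("uniform"), 30)
#' muS(ns)          # 2 - 2 log 2, about 0.6137
#' sqrt(varS(ns))   # about 0.0134
#' @export
momentsS <- function(spec, nNeurons) {
  stopifnot(is.numeric(nNeurons), length(nNeurons) == 1, nNeurons >= 2)
  nNeurons <- as.integer(nNeurons)
  mz <- momentsZ(spec)
  p <- spec@pruneP
  ep <- (1 - p^2) * nNeurons * (nNeurons - 1) / 2
  new("NullStatistics", muZ = mz$muZ, varZ = mz$varZ, muS = 1 - mz$muZ,
      varS = mz$varZ / ep, expectedPairs = ep, nNeurons = nNeurons,
      method = mz$method, spec = spec)
}

#' Monte-Carlo null statistics of s
#'
#' Generates independent random networks from the null model (via
#' [randomNetwork()]), evaluates s on each, and returns the sample mean and
#' variance. Useful as an independent check of the analytic moments and for
#' null models without closed forms.
#'
#' @param spec a [NullModelSpec-class].
#' @param nNeurons network size N.
#' @param nNetworks number of networks M (>= 2).
#' @param seed RNG seed (required for reproducibility).
#' @return A [NullStatistics-class] with method "monte_carlo". \code{varZ}
#'   is back-computed as \code{varS * E[P]} and \code{muZ = 1 - muS} so the
#'   object is comparable with analytic ones.
#' @examples
#' mcNullStatistics(nullModelSpec("uniform"), 30, 200, seed = 1)
#' @export
mcNullStatistics <- function(spec, nNeurons, nNetworks, seed) {
  stopifnot(is(spec, "NullModelSpec"))
  validObject(spec)
  stopifnot(nNetworks >= 2, nNeurons >= 2)
  nNeurons <- as.integer(nNeurons)
  nNetworks <- as.integer(nNetworks)
  set.seed(seed)
  svals <- vapply(seq_len(nNetworks), function(k) {
    W <- randomNetwork(nNeurons, spec, seed = NULL)
    res <- .sFromMatrix(W@weights)
    if (is.na(res$s)) {
      stop("a generated network had no counted pairs; ",
           "pruning probability too close to 1 for this network size")
    }
    res$s
  }, numeric(1))
  p <- spec@pruneP
  ep <- (1 - p^2) * nNeurons * (nNeurons - 1) / 2
  m <- mean(svals)
  v <- stats::var(svals)
  new("NullStatistics", muZ = 1 - m, varZ = v * ep, muS = m, varS = v,
      expectedPairs = ep, nNeurons = nNeurons, method = "monte_carlo",
      nNetworks = nNetworks, seed = as.integer(seed), spec = spec)
}

#' Sample correlation between the pair sum u and difference v
#'
#' Draws pairs of weights from the (unpruned) family and returns the
#' Pearson correlation between u = a + b and v = |a - b|. For the
#' truncated-Gaussian family this correlation is negligible, which
#' justifies factorising the bivariate law of (u, v) into a product of
#' marginals; pruning needs no separate treatment since the pruned
#' contribution is described by its own mixture component.
#'
#' @param spec a [NullModelSpec-class] with \code{pruneP = 0}.
#' @param nSamples number of weight pairs (>= 2).
#' @param seed RNG seed.
#' @return Pearson correlation coefficient.
#' @examples
#' correlationUV(nullModelSpec("gaussian"), 1e4, seed = 1)
#' @export
correlationUV <- function(spec, nSamples, seed) {
  stopifnot(is(spec, "NullModelSpec"))
  validObject(spec)
  if (spec@pruneP != 0) {
    stop("correlationUV is defined for the unpruned family (pruneP = 0)")
  }
  if (nSamples < 2) stop("need at least 2 samples")
  set.seed(seed)
  a <- .sampleFamily(nSamples, spec)
  b <- .sampleFamily(nSamples, spec)
  u <- a + b
  v <- abs(a - b)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("correlation undefined: degenerate (constant) weight distribution")
  }
  stats::cor(u, v)
}
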