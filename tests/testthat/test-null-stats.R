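test_that("density bundles are normalised mixtures for both families and all p", {
  for (spec in list(uspec(0), uspec(0.3), uspec(0.6), gspec(0), gspec(0.4))) {
    b <- nullDensities(spec)
    p <- spec@pruneP
    expect_equal(b@contWeight, (1 - p) / (1 + p))
    expect_equal(b@pruneWeight, 2 * p / (1 + p))
    iu <- integrate(b@pdfU, b@support$u[1], b@support$u[2],
                    subdivisions = 400, rel.tol = 1e-9)$value
    iv <- integrate(b@pdfV, b@support$v[1], b@support$v[2],
                    subdivisions = 400, rel.tol = 1e-9)$value
    iw <- integrate(b@pdfW, b@support$w[1], b@support$w[2],
                    subdivisions = 400, rel.tol = 1e-9)$value
    expect_equal(iu, 1, tolerance = 1e-6)
    expect_equal(iv, 1, tolerance = 1e-6)
    expect_equal(iw + b@wAtomZero, 1, tolerance = 1e-6)
    # continuous joint integrates to its mixture weight on the triangle
    # v <= min(u - 2 wMin, 2 wMax - u, wMax - wMin)
    lo <- b@support$w[1]; hi <- b@support$w[2]
    ij <- pracma::integral2(function(u, v) b@jointCont(u, v),
                            b@support$u[1], b@support$u[2], 0,
                            function(u) pmax(0, pmin(u - 2 * lo,
                                                     2 * hi - u, hi - lo)),
                            reltol = 1e-8)$Q
    expect_equal(ij, b@contWeight, tolerance = 1e-5)
    il <- integrate(b@lineDensity, b@support$w[1], b@support$w[2])$value
    expect_equal(il, b@pruneWeight, tolerance = 1e-6)
  }
})

test_that("unpruned uniform densities have their closed forms", {
  b <- nullDensities(uspec(0))
  # triangular sum density peaking at 1
  expect_equal(b@pdfU(1), 1)
  expect_equal(b@pdfU(0.5), 0.5)
  expect_equal(b@pdfU(1.5), 0.5)
  expect_equal(b@pdfU(c(-0.1, 2.1)), c(0, 0))
  # difference density 2(1 - v)
  v <- seq(0, 1, by = 0.1)
  expect_equal(b@pdfV(v), 2 * (1 - v))
  # joint density is flat (= 1) on the triangle
  expect_equal(b@jointCont(0.8, 0.3), 1)
  expect_equal(b@jointCont(0.8, 0.9), 0)  # v > u
  expect_equal(b@jointCont(1.5, 0.8), 0)  # (u+v)/2 > wMax
})

test_that("gaussian sum and difference densities match Monte Carlo histograms", {
  set.seed(3)
  n <- 2e5
  a <- rnorm(n, 0.5, 0.1); b2 <- rnorm(n, 0.5, 0.1)
  keep <- a >= 0 & a <= 1 & b2 >= 0 & b2 <= 1
  u <- (a + b2)[keep]; v <- abs(a - b2)[keep]
  bun <- nullDensities(gspec(0))
  h <- hist(u, breaks = seq(0, 2, by = 0.05), plot = FALSE)
  keepBins <- h$density > 0.2
  expect_equal(h$density[keepBins], bun@pdfU(h$mids)[keepBins],
               tolerance = 0.05)
  h <- hist(v, breaks = seq(0, 1, by = 0.025), plot = FALSE)
  keepBins <- h$density > 0.2
  expect_equal(h$density[keepBins], bun@pdfV(h$mids)[keepBins],
               tolerance = 0.05)
})

test_that("pruning mixture weight vanishes as p tends to zero", {
  b <- nullDensities(uspec(1e-9))
  expect_lt(b@pruneWeight, 1e-8)
  expect_equal(b@pdfV(0.5), nullDensities(uspec(0))@pdfV(0.5),
               tolerance = 1e-7)
})

test_that("uniform z moments match their closed forms and the pruning mixture identity", {
  m <- momentsZ(uspec(0))
  expect_equal(m$muZ, 2 * log(2) - 1, tolerance = 1e-12)
  expect_equal(m$varZ, (3 - 4 * log(2)) - (2 * log(2) - 1)^2,
               tolerance = 1e-12)
  expect_identical(m$method, "closed_form")

  m5 <- momentsZ(uspec(0.5))
  expect_equal(m5$muZ, ((1 - 0.5) * (2 * log(2) - 1) + 2 * 0.5) / 1.5,
               tolerance = 1e-12)
  expect_equal(m5$muZ, 0.7954310, tolerance = 1e-6)
})

test_that("gaussian z moments from quadrature agree with a Monte-Carlo oracle", {
  m <- momentsZ(gspec(0))
  expect_identical(m$method, "quadrature")
  # frozen regression value pinned by the MC oracle below; close to the
  # independence approximation E[v] E[1/u] = (2 sigma / sqrt(pi)) E[1/u]
  expect_equal(m$muZ, 0.115245, tolerance = 1e-4)
  approx <- 2 * 0.1 / sqrt(pi) * (1 + 2 * 0.1^2 + 3 * (2 * 0.1^2)^2)
  expect_equal(m$muZ, approx, tolerance = 2e-3)
  set.seed(5)
  n <- 1e6
  a <- rnorm(n, 0.5, 0.1); b <- rnorm(n, 0.5, 0.1)
  keep <- a >= 0 & a <= 1 & b >= 0 & b <= 1
  z <- (abs(a - b) / (a + b))[keep]
  se <- sd(z) / sqrt(length(z))
  expect_lt(abs(m$muZ - mean(z)), 3 * se)
  expect_lt(abs((m$varZ + m$muZ^2) - mean(z^2)), 3 * sd(z^2) / sqrt(length(z)))
})

test_that("s moments follow from z moments with the expected pair count", {
  ns <- momentsS(uspec(0), 30)
  expect_equal(muS(ns), 2 - 2 * log(2), tolerance = 1e-12)
  expect_equal(ns@expectedPairs, 435)
  expect_equal(sqrt(varS(ns)), 0.013407, tolerance = 1e-4)
  expect_equal(varS(ns), varZ(ns) / ns@expectedPairs, tolerance = 1e-12)

  ns5 <- momentsS(uspec(0.5), 30)
  expect_equal(muS(ns5), (2 - 2 * log(2)) / 3, tolerance = 1e-12)
  expect_equal(ns5@expectedPairs, 0.75 * 435)

  # var_s shrinks monotonically with N
  vs <- sapply(c(10, 30, 100, 300), function(n) varS(momentsS(uspec(0), n)))
  expect_true(all(diff(vs) < 0))

  expect_error(momentsS(uspec(0), 1), "nNeurons")
})

test_that("Monte-Carlo null statistics are deterministic and match closed forms", {
  a <- mcNullStatistics(uspec(0), 30, 300, seed = 9)
  b <- mcNullStatistics(uspec(0), 30, 300, seed = 9)
  expect_identical(reportAsList(a), reportAsList(b))
  expect_identical(a@method, "monte_carlo")
  expect_identical(a@nNetworks, 300L)

  mc <- mcNullStatistics(uspec(0), 30, 2000, seed = 1)
  se <- sqrt(varS(mc) / 2000)
  expect_lt(abs(muS(mc) - (2 - 2 * log(2))), 3 * se)

  # Gaussian weights bias the network toward symmetry
  mg <- mcNullStatistics(gspec(0), 30, 2000, seed = 2)
  expect_gt(muS(mg), muS(mc))
  seg <- sqrt(varS(mg) / 2000)
  expect_lt(abs(muS(mg) - muS(momentsS(gspec(0), 30))), 3 * seg)
})

test_that("analytic mu_s decreases in p and gaussian stays above uniform", {
  grid <- seq(0, 0.9, by = 0.1)
  mu <- sapply(grid, function(p) muS(momentsS(uspec(p), 30)))
  mg <- sapply(grid, function(p) muS(momentsS(gspec(p), 30)))
  expect_true(all(diff(mu) < 0))
  expect_true(all(diff(mg) < 0))
  expect_true(all(mg > mu))
})

test_that("the pruning mixture identity matches Monte Carlo within 3 SE", {
  p <- 0.4
  mc <- mcNullStatistics(uspec(p), 30, 2000, seed = 3)
  an <- momentsS(uspec(p), 30)
  expect_lt(abs(muS(mc) - muS(an)), 3 * sqrt(varS(mc) / 2000))
})

test_that("u and v are uncorrelated for both families", {
  # near-zero correlation justifies factorising the gaussian joint law;
  # for the uniform family it follows from reflection symmetry about the
  # interval midpoint
  expect_lt(abs(correlationUV(gspec(0), 2e5, seed = 1)), 0.01)
  expect_lt(abs(correlationUV(uspec(0), 2e5, seed = 1)), 0.01)
})

test_that("correlationUV rejects pruned, degenerate and tiny inputs", {
  expect_error(correlationUV(uspec(0.5), 100, seed = 1), "pruneP = 0")
  expect_error(correlationUV(uspec(0), 1, seed = 1), "at least 2")
  # a numerically degenerate gaussian gives constant weights
  degen <- nullModelSpec("gaussian", sigma = 1e-300)
  expect_error(correlationUV(degen, 10, seed = 1), "degenerate")
})

test_that("invalid null-model specifications are rejected", {
  expect_error(nullModelSpec("uniform", wMin = 1, wMax = 0), "wMin")
  expect_error(nullModelSpec("uniform", pruneP = 1), "pruneP")
  expect_error(nullModelSpec("gaussian", sigma = 0.4), "too wide")
  expect_error(nullModelSpec("gaussian", mu = 0.7), "midpoint")
})
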