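test_that("all generators produce valid matrices and are seed-deterministic", {
  gens <- list(
    function(seed) randomNetwork(12, uspec(0.3), seed = seed),
    function(seed) symmetricNetwork(12, gspec(0.3), seed = seed),
    function(seed) asymmetricNetwork(12, uspec(0.3), eps = 0.01, seed = seed),
    function(seed) prescribedSNetwork(12, 0.4, uspec(0.3), seed = seed)
  )
  for (gen in gens) {
    a <- gen(5)
    expect_true(validObject(a))
    expect_identical(weights(gen(5)), weights(a))
    expect_false(identical(weights(gen(6)), weights(a)))
  }
})

test_that("symmetric networks are exactly symmetric until pruning breaks them", {
  W <- symmetricNetwork(10, uspec(0), seed = 1)
  expect_identical(weights(W), t(weights(W)))
  expect_equal(sValue(symmetryMeasure(W)), 1)

  W2 <- symmetricNetwork(2, uspec(0), seed = 1)
  expect_equal(pairDecompose(W2)@pairs$z, 0)

  # mean s decreases with pruning: pruning makes symmetry look asymmetric
  meanS <- sapply(c(0.2, 0.5, 0.8), function(p) {
    set.seed(20)
    mean(replicate(200, sValue(symmetryMeasure(
      symmetricNetwork(10, uspec(p))))))
  })
  expect_true(all(meanS < 1))
  expect_true(all(diff(meanS) < 0))
})

test_that("asymmetric networks pin s at (or near) zero regardless of pruning", {
  expect_equal(sValue(symmetryMeasure(
    asymmetricNetwork(10, uspec(0), seed = 2))), 0)
  # pruning cannot raise s above 0 when the weak side is already 0
  expect_equal(sValue(symmetryMeasure(
    asymmetricNetwork(10, uspec(0.5), seed = 2))), 0)

  # with eps = 0.01, 1 - z <= 2 eps / (a + eps) per pair; averaging the
  # bound over a ~ U(0, 1) gives E[1 - z] <= 2 eps log((1 + eps)/eps),
  # about 0.092, so s stays below 0.1
  set.seed(21)
  s <- replicate(100, sValue(symmetryMeasure(
    asymmetricNetwork(30, uspec(0), eps = 0.01))))
  expect_true(all(s > 0 & s < 0.1))

  expect_error(asymmetricNetwork(10, uspec(0), eps = 1), "eps")
})

test_that("prescribed-s networks hit their target", {
  # with a degenerate z spread every pair has z = 1 - s exactly
  W <- prescribedSNetwork(10, 0.5, uspec(0), sigmaZ = 1e-14, seed = 3)
  expect_equal(sValue(symmetryMeasure(W)), 0.5, tolerance = 1e-9)

  set.seed(22)
  for (st in c(0.1, 0.5, 0.9)) {
    s <- replicate(50, sValue(symmetryMeasure(
      prescribedSNetwork(30, st, uspec(0), sigmaZ = 0.05))))
    expect_lt(abs(mean(s) - st), 0.02)
  }

  # the adaptive default spread stays near target across the domain
  # (boundary clipping allows a small pull-off near the extremes)
  set.seed(23)
  for (st in c(0.1, 0.5, 0.9)) {
    s <- replicate(50, sValue(symmetryMeasure(
      prescribedSNetwork(30, st, uspec(0)))))
    expect_lt(abs(mean(s) - st), 0.05)
  }

  # z clipped at 1 gives a zero weight, not a division by zero
  W1 <- prescribedSNetwork(30, 0.02, uspec(0), sigmaZ = 0.05, seed = 4)
  expect_true(all(is.finite(weights(W1))))
  expect_error(prescribedSNetwork(10, 1, uspec(0)), "sTarget")
})

test_that("pruning is Bernoulli per connection and mask is reusable", {
  W <- randomNetwork(10, uspec(0), seed = 6)
  un <- applyPruning(W, 0, seed = 7)
  expect_identical(weights(un$weights), weights(W))
  expect_true(all(!un$mask[row(un$mask) != col(un$mask)]))

  expect_identical(applyPruning(W, 0.5, seed = 8)$mask,
                   applyPruning(W, 0.5, seed = 8)$mask)
  expect_error(applyPruning(W, 1), "\\[0, 1\\)")

  # fraction of zero entries about p
  big <- randomNetwork(101, uspec(0), seed = 9)
  pr <- applyPruning(big, 0.9, seed = 10)
  off <- row(pr$mask) != col(pr$mask)
  ztest <- binom.test(sum(weights(pr$weights)[off] == 0), sum(off), 0.9)
  expect_gt(ztest$p.value, 0.01)

  # fraction of pairs with exactly one side pruned about 2p(1-p)
  sym <- symmetricNetwork(101, uspec(0), seed = 11)
  pr2 <- applyPruning(sym, 0.5, seed = 12)
  w <- weights(pr2$weights)
  ut <- upper.tri(w)
  one <- sum(xor(w[ut] == 0, t(w)[ut] == 0))
  expect_gt(binom.test(one, sum(ut), 0.5)$p.value, 0.01)
})

test_that("random-ensemble s moments match the analytics for both families", {
  for (fam in list(uspec, gspec)) {
    for (p in c(0, 0.4, 0.8)) {
      an <- momentsS(fam(p), 30)
      mc <- mcNullStatistics(fam(p), 30, 1000, seed = 30 + round(10 * p))
      se <- sqrt(varS(mc) / 1000)
      expect_lt(abs(muS(mc) - muS(an)), 3 * se)
    }
  }
})

test_that("extreme ensembles bracket every random network", {
  set.seed(33)
  for (rep in 1:20) {
    sAsym <- sValue(symmetryMeasure(asymmetricNetwork(15, uspec(0))))
    sRand <- sValue(symmetryMeasure(randomNetwork(15, uspec(0))))
    sSym <- sValue(symmetryMeasure(symmetricNetwork(15, uspec(0))))
    expect_lte(sAsym, sRand)
    expect_lte(sRand, sSym)
  }
})
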