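test_that("ACHR iterates on the unit interval are uniform", {
  # pool {0, 1} with center 0.5: the step distribution makes each iterate
  # an independent Uniform(0,1) draw, so the closed-form mean applies
  sp <- boxSpace(1)
  state <- list(current = 0.5, center = 0.5, k = 2,
                pool = matrix(c(0, 1), 2, 1))
  set.seed(42)
  N <- 10000
  xs <- numeric(N)
  for (i in seq_len(N)) {
    state <- achrStep(sp, state)
    xs[i] <- state$current
  }
  expect_lt(abs(mean(xs) - 0.5), 3 * sqrt(1 / 12 / N))
  expect_true(all(xs >= 0 & xs <= 1))
  # the empirical center absorbed every iterate
  expect_equal(state$k, 2 + N)
})

test_that("a collapsed direction pool raises a degenerate-pool error", {
  sp <- boxSpace(2)
  state <- list(current = c(0.5, 0.5), center = c(0.5, 0.5), k = 1,
                pool = matrix(c(0.5, 0.5), 1, 2))
  set.seed(1)
  expect_error(achrStep(sp, state), "degenerate")
})

test_that("sampling is deterministic given the seed, for every mode", {
  sp <- netSpace(5, 10, seed = 3)
  a <- sampleOptGp(sp, 60, 5, 4, seed = 123)
  b <- sampleOptGp(sp, 60, 5, 4, seed = 123)
  expect_identical(samples(a), samples(b))
  g1 <- sampleGp(sp, 25, 10, seed = 9)
  g2 <- sampleGp(sp, 25, 10, seed = 9)
  expect_identical(samples(g1), samples(g2))
  h1 <- sampleHitAndRun(sp, 50, thin = 2, seed = 4)
  h2 <- sampleHitAndRun(sp, 50, thin = 2, seed = 4)
  expect_identical(samples(h1), samples(h2))
  # different seed, different trajectory
  expect_false(identical(samples(a), samples(sampleOptGp(sp, 60, 5, 4, seed = 124))))
})

test_that("thinned-chain bookkeeping follows the allocation rule", {
  sp <- boxSpace(3)
  s <- sampleOptGp(sp, 10, 3, 3, seed = 2)
  expect_equal(provenance(s)$chainSamples, c(4, 3, 3))
  expect_equal(provenance(s)$chainId, rep(1:3, c(4, 3, 3)))  # chain-major

  s2 <- sampleOptGp(sp, 100, 2, 4, seed = 2)
  expect_equal(provenance(s2)$chainSamples, rep(25, 4))
  expect_equal(nrow(samples(s2)), 100)
  expect_equal(provenance(s2)$warmupPoints, 2 * nReactions(sp))

  expect_error(sampleOptGp(sp, 2, 5, 4, seed = 1), "configuration error")
})

test_that("restart-mode warm-up policy matches its definition", {
  sp <- boxSpace(2)
  # stepCount 0 returns the pulled warm-up points themselves
  s0 <- sampleGp(sp, 4, 0, seed = 5)
  expected <- pullToInterior(minmaxWarmup(sp), 0.5)
  expect_equal(samples(s0), warmupPoints(expected))
  # nSamples = 2n exactly: no random-weight LPs executed
  expect_equal(provenance(s0)$randomWeightPoints, 0)
  # beyond 2n the remainder comes from random weightings
  s6 <- sampleGp(sp, 6, 0, seed = 5)
  expect_equal(provenance(s6)$randomWeightPoints, 2)
  expect_equal(provenance(s6)$nChains, 6)   # one chain per sample
})

test_that("every stored sample is feasible in every mode", {
  for (sp in list(boxSpace(3), triangleSpace(), netSpace(5, 10, seed = 3))) {
    expect_feasible(sp, samples(sampleOptGp(sp, 400, 5, 4, seed = 31)))
    expect_feasible(sp, samples(sampleGp(sp, 50, 10, seed = 32)))
    expect_feasible(sp, samples(sampleHitAndRun(sp, 400, thin = 2, seed = 33)))
  }
})

test_that("results are independent of the worker count", {
  sp <- netSpace(5, 10, seed = 3)
  a <- sampleOptGp(sp, 40, 5, 4, seed = 7, workers = 1)
  b <- sampleOptGp(sp, 40, 5, 4, seed = 7, workers = 4)
  expect_identical(samples(a), samples(b))
})

test_that("plain hit-and-run recovers analytic uniform moments", {
  sp1 <- boxSpace(1)
  h <- samples(sampleHitAndRun(sp1, 10000, seed = 6))
  expect_lt(abs(mean(h) - 0.5), 3 * sqrt(1 / 12 / 10000))

  # triangle: exact uniform centroid is (1/3, 1/3); batch-mean standard
  # errors account for chain autocorrelation
  spt <- triangleSpace()
  ht <- samples(sampleHitAndRun(spt, 10000, thin = 5, seed = 61))
  batches <- matrix(ht[, 1], ncol = 20)
  se <- sd(colMeans(batches)) / sqrt(20)
  expect_lt(abs(mean(ht[, 1]) - 1/3), 3 * se + 1e-6)
  expect_lt(abs(mean(ht[, 2]) - 1/3), 3 * se + 1e-6)
})

test_that("hit-and-run and the rejection oracle agree on first two moments", {
  spt <- triangleSpace()
  h <- samples(sampleHitAndRun(spt, 8000, thin = 5, seed = 62))[, 1:2]
  r <- samples(rejectionSample(spt, 8000, seed = 63))[, 1:2]
  seH <- apply(h, 2, function(x) {
    b <- colMeans(matrix(x, ncol = 20)); sd(b) / sqrt(20)
  })
  seR <- apply(r, 2, sd) / sqrt(nrow(r))
  for (j in 1:2) {
    expect_lt(abs(mean(h[, j]) - mean(r[, j])),
              3 * sqrt(seH[j]^2 + seR[j]^2))
  }
  # second moments: uniform-triangle variance 1/18, covariance -1/36
  expect_equal(unname(diag(cov(h))), c(1, 1) / 18, tolerance = 0.08)
  expect_equal(cov(h)[1, 2], -1 / 36, tolerance = 0.15)
})

test_that("ACHR marginals on a box pass a uniformity screen", {
  sp <- boxSpace(2)
  s <- samples(sampleOptGp(sp, 4000, 20, 4, seed = 64))
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(s[, j], "punif"))$statistic
    expect_lt(unname(ks), 3 * 1.36 / sqrt(4000))
  }
})

test_that("run-to-run self-deviation shrinks as the step count grows", {
  sp <- fx$mixnet <- fx$mixnet %||% solutionSpace(
    makeRandomNetwork(1, 10, seed = 7, tightWidth = 0.05, looseWidth = 200,
                      looseFraction = 0.15))
  selfDev <- function(st) {
    runs <- lapply(1:4, function(i) sampleOptGp(sp, 500, st, 4, seed = 700 + 10 * st + i))
    xyDeviation(runs[1:2], runs[3:4], space = sp)@xyDeviation
  }
  d <- vapply(c(1, 10, 100), selfDev, numeric(1))
  # non-increasing in expectation; allow one inversion
  expect_lt(sum(diff(d) > 0), 2)
  expect_gt(d[1], d[3])
})
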