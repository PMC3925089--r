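test_that("Geweke z-scores are near-standard-normal for stationary chains", {
  set.seed(10)
  ch <- matrix(rnorm(10000 * 50), 10000, 50)
  z <- gewekeDiagnostic(ch)
  frac <- mean(abs(z) > 1.96)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
})

test_that("Geweke flags a planted trend and zero-variance columns", {
  set.seed(11)
  ch <- matrix(rnorm(5000 * 3), 5000, 3)
  ch[, 2] <- ch[, 2] + seq(0, 4, length.out = 5000)
  z <- gewekeDiagnostic(ch)
  expect_gt(abs(z[2]), 5)
  expect_lt(abs(z[1]), 4)

  ch[, 3] <- 1
  z2 <- gewekeDiagnostic(ch)
  expect_identical(z2[3], 0)
  expect_true(attr(z2, "degenerate")[3])

  expect_error(gewekeDiagnostic(matrix(rnorm(50), 50, 1)), "N >= 100")
  expect_error(gewekeDiagnostic(ch, fracFirst = 0.6, fracLast = 0.5), "<= 1")
})

test_that("Gelman-Rubin separates mixed from unmixed chains", {
  set.seed(12)
  chains <- lapply(1:4, function(i) matrix(rnorm(5000 * 10), 5000, 10))
  gr <- gelmanRubin(chains)
  expect_true(all(gr$psrf >= 0.99 & gr$psrf <= 1.05))
  expect_lt(gr$mpsrf, 1.05)

  apart <- list(matrix(rnorm(1000), 1000, 1),
                matrix(rnorm(1000, mean = 10), 1000, 1))
  expect_gt(gelmanRubin(apart)$psrf[1], 1.2)

  expect_error(gelmanRubin(chains[1]), "at least 2")
  expect_error(gelmanRubin(list(matrix(1, 5, 1), matrix(1, 5, 1))), "N >= 10")
})

test_that("identical chains give the closed-form floor R = sqrt((N-1)/N)", {
  set.seed(13)
  one <- matrix(rnorm(500 * 3), 500, 3)
  gr <- gelmanRubin(list(one, one, one))
  expect_equal(as.numeric(gr$psrf), rep(sqrt(499 / 500), 3), tolerance = 1e-10)
  expect_lte(max(gr$psrf), 1 + 1e-6)
})

test_that("Heidelberger-Welch passes stationary chains, rejects shifts", {
  set.seed(14)
  ch <- matrix(runif(10000 * 50), 10000, 50)
  hw <- heidelbergerWelch(ch)
  expect_gte(mean(hw), 0.9)

  shifted <- matrix(rnorm(1000), 1000, 1)
  shifted[1:500, 1] <- shifted[1:500, 1] + 5
  hws <- heidelbergerWelch(shifted)
  # fails outright or passes only after discarding at least half the chain
  if (hws[1] == 1) expect_gte(attr(hws, "startFraction")[1], 0.5)

  const <- matrix(1, 1000, 1)
  hwc <- heidelbergerWelch(const)
  expect_identical(hwc[1], 0)
  expect_true(attr(hwc, "degenerate")[1])

  expect_error(heidelbergerWelch(matrix(rnorm(50), 50, 1)), "N >= 100")
})

test_that("all three diagnostics are invariant to affine rescaling", {
  set.seed(15)
  ch <- matrix(rnorm(2000 * 4), 2000, 4)
  chains <- lapply(1:3, function(i) matrix(rnorm(2000 * 4), 2000, 4))
  rescale <- function(m) { m[, 2] <- 5 * m[, 2] - 7; m }

  z1 <- as.numeric(gewekeDiagnostic(ch))
  z2 <- as.numeric(gewekeDiagnostic(rescale(ch)))
  expect_equal(z2, z1, tolerance = 1e-8)

  r1 <- gelmanRubin(chains)$psrf
  r2 <- gelmanRubin(lapply(chains, rescale))$psrf
  expect_equal(as.numeric(r2), as.numeric(r1), tolerance = 1e-8)

  h1 <- as.numeric(heidelbergerWelch(ch))
  h2 <- as.numeric(heidelbergerWelch(rescale(ch)))
  expect_identical(h1, h2)
})

test_that("the Cramer-von Mises CDF matches the classical critical values", {
  # 0.4614 and 0.7435 are the classical 5% and 1% critical points
  expect_equal(fluxsampler:::.pcramer(0.4614), 0.95, tolerance = 1e-3)
  expect_equal(fluxsampler:::.pcramer(0.7435), 0.99, tolerance = 1e-3)
})

test_that("the combined report averages runs and carries thresholds", {
  sp <- boxSpace(2)
  runs <- lapply(1:3, function(i) sampleOptGp(sp, 500, 5, 2, seed = 40 + i))
  rep1 <- convergenceDiagnostics(runs)
  expect_s4_class(rep1, "DiagnosticsReport")
  expect_equal(rep1@hwFraction, mean(rep1@hwPass))
  expect_identical(names(rep1@gewekeZ), reactionIds(sp))
  expect_equal(rep1@thresholds$R_crit, 1.2)
  expect_error(convergenceDiagnostics(runs[1]), ">= 2")
})
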