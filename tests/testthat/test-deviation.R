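test_that("sorting and bound-normalisation behave column-wise", {
  m <- matrix(c(3, 1, 2,
                5, 5, 5), 3, 2)
  out <- sortedNormalized(m, lb = c(0, 0), ub = c(10, 10))
  expect_equal(out[, 1], c(0.1, 0.2, 0.3))
  expect_equal(out[, 2], c(0.5, 0.5, 0.5))     # constant column, ub > lb

  fixed <- sortedNormalized(m, lb = c(0, 2), ub = c(10, 2))
  expect_equal(attr(fixed, "excluded"), 2L)
  expect_equal(fixed[, 2], c(0, 0, 0))

  expect_error(sortedNormalized(matrix(numeric(), 0, 2), c(0, 0), c(1, 1)),
               "empty")
})

test_that("the mean chain averages sorted runs element-wise", {
  a <- matrix(c(0, 1), 2, 1)
  b <- matrix(c(1, 0), 2, 1)
  mc <- meanChain(list(a, b), lb = 0, ub = 1)
  expect_equal(as.numeric(mc), c(0, 1))        # both sort to (0, 1)

  one <- meanChain(list(a), lb = 0, ub = 1)
  expect_equal(as.numeric(one), sortedNormalized(a, 0, 1)[, 1])

  set.seed(3)
  runs <- lapply(1:4, function(i) matrix(runif(20), 10, 2))
  mc4 <- meanChain(runs, lb = c(0, 0), ub = c(1, 1))
  sorted <- lapply(runs, sortedNormalized, lb = c(0, 0), ub = c(1, 1))
  lo <- Reduce(pmin, sorted)
  hi <- Reduce(pmax, sorted)
  expect_true(all(mc4 >= lo - 1e-12 & mc4 <= hi + 1e-12))

  expect_error(meanChain(list(a, matrix(0, 3, 1)), 0, 1), "differing")
})

test_that("xy-deviation hits its exact anchors: 0, 1 and the iid floor", {
  set.seed(4)
  one <- matrix(runif(60), 20, 3)
  dup <- list(one, one, one)               # duplicated identical runs
  same <- xyDeviation(dup, dup, lb = rep(0, 3), ub = rep(1, 3))
  expect_identical(same@xyDeviation, 0)

  zeroes <- matrix(0, 5, 1)
  ones <- matrix(1, 5, 1)
  maximal <- xyDeviation(list(zeroes), list(ones), lb = 0, ub = 1)
  expect_identical(maximal@xyDeviation, 1)
  expect_identical(unname(maximal@perReaction), 1)

  # two samplers both drawing iid Uniform(0,1): expected sorted-chain gap
  # is O(1/sqrt(N)), well under 0.03 at N = 1000
  set.seed(5)
  x <- lapply(1:4, function(i) matrix(runif(1000), 1000, 1))
  y <- lapply(1:4, function(i) matrix(runif(1000), 1000, 1))
  expect_lt(xyDeviation(x, y, lb = 0, ub = 1)@xyDeviation, 0.03)
})

test_that("deviation is bounded, permutation-invariant and scale-equivariant", {
  set.seed(6)
  lb <- c(-2, 0, 1)
  ub <- c(3, 10, 1.5)
  mk <- function() sapply(seq_along(lb), function(j) runif(50, lb[j], ub[j]))
  x <- lapply(1:3, function(i) mk())
  y <- lapply(1:3, function(i) mk())
  rep1 <- xyDeviation(x, y, lb = lb, ub = ub)
  expect_true(all(rep1@perReaction >= 0 & rep1@perReaction <= 1))
  expect_gte(rep1@xyDeviation, 0)
  expect_lte(rep1@xyDeviation, 1)

  shuffled <- lapply(x, function(m) m[sample(nrow(m)), ])
  rep2 <- xyDeviation(shuffled, y, lb = lb, ub = ub)
  expect_equal(rep2@perReaction, rep1@perReaction)

  # scaling one reaction's fluxes AND bounds leaves D_j unchanged
  scale1 <- function(m) { m[, 1] <- m[, 1] * 7; m }
  lb2 <- lb; ub2 <- ub
  lb2[1] <- lb[1] * 7; ub2[1] <- ub[1] * 7
  rep3 <- xyDeviation(lapply(x, scale1), lapply(y, scale1), lb = lb2, ub = ub2)
  expect_equal(rep3@perReaction, rep1@perReaction, tolerance = 1e-12)
})

test_that("misaligned run groups are refused", {
  a <- matrix(runif(10), 5, 2)
  expect_error(xyDeviation(list(a), list(matrix(runif(8), 4, 2)),
                           lb = c(0, 0), ub = c(1, 1)), "same sample count")
  sp <- boxSpace(2)
  s1 <- sampleHitAndRun(sp, 10, seed = 1)
  s2 <- new("FluxSamples", samples = samples(s1),
            reactionIds = c("other", "ids"), meta = list())
  expect_error(xyDeviation(list(s1), list(s2), space = sp), "alignment")
})

test_that("the symmetric variant dominates both directions", {
  set.seed(8)
  x <- list(matrix(runif(100), 100, 1))
  y <- list(matrix(rbeta(100, 2, 5), 100, 1))
  fwd <- xyDeviation(x, y, lb = 0, ub = 1)@xyDeviation
  bwd <- xyDeviation(y, x, lb = 0, ub = 1)@xyDeviation
  sym <- xyDeviation(x, y, lb = 0, ub = 1, symmetric = TRUE)@xyDeviation
  expect_equal(sym, max(fwd, bwd))
})

test_that("reports serialise to JSON and TSV", {
  set.seed(9)
  x <- list(matrix(runif(40), 20, 2))
  rep1 <- xyDeviation(x, x, lb = c(0, 0), ub = c(1, 1))
  d <- withr::local_tempdir()
  jp <- writeDeviationReport(rep1, file.path(d, "r.json"), "json")
  back <- jsonlite::fromJSON(jp)
  expect_equal(back$xy_deviation, 0)
  tp <- writeDeviationReport(rep1, file.path(d, "r.tsv"), "tsv")
  tab <- read.delim(tp)
  expect_equal(nrow(tab), 2)
})
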