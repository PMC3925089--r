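## Deterministic per-chain seed stream derived from the master seed.
## Kept below 2^31 - 1; chain index 0 is reserved for warm-up draws.
.chainSeed <- function(seed, chain) {
  as.integer(((seed %% 2147483647) * 1000003 + chain * 7919) %% 2147483647)
}

.resolveSeed <- function(seed) {
  if (is.null(seed)) sample.int(2147483646L, 1L) else as.integer(seed)
}

#' One artificial-centering hit-and-run iterate
#'
#' The ACHR primitive: draw a point uniformly from the direction pool, take
#' the unit direction from it toward the running empirical center, move a
#' uniform random step along the feasible segment, and absorb the new point
#' into the center. Degenerate draws (pool point at the center, or a
#' zero-length segment) are redrawn up to 10 times before a degenerate-pool
#' error.
#'
#' @param space a [SolutionSpace-class].
#' @param state list with components \code{current} (feasible flux vector),
#'   \code{center} (empirical center), \code{k} (number of points absorbed
#'   into the center) and \code{pool} (matrix of direction-pool points, one
#'   per row).
#' @return the updated state list (same shape; \code{pool} untouched).
#' @examples
#' sp <- solutionSpace(makeBox(2))
#' wu <- pullToInterior(minmaxWarmup(sp))
#' st <- list(current = wu@centroid, center = wu@centroid,
#'            k = nrow(wu@points), pool = wu@points)
#' set.seed(1)
#' st2 <- achrStep(sp, st)
#' isFeasible(sp, st2$current)
#' @export
achrStep <- function(space, state) {
  stopifnot(is.list(state), !is.null(state$current), !is.null(state$pool))
  r <- .achrChainCpp(state$pool, state$current, state$center,
                     as.numeric(state$k), 1L, 1L,
                     space@model@lb, space@model@ub, space@proj,
                     0L, FALSE, space@dirTol, space@boundTol)
  list(current = as.numeric(r$samples[1, ]), center = as.numeric(r$center),
       k = r$k, pool = state$pool)
}

.PROJECT_EVERY <- 100L

#' Sample with long thinned parallel ACHR chains (OptGP scheme)
#'
#' The production sampler. Warm-up: the 2n min/max points, pulled toward the
#' interior. Each of \code{nChains} logical chains starts at a warm-up point
#' chosen uniformly at random and runs continuously, keeping every
#' \code{stepCount}-th ACHR iterate as a sample; stored samples join the
#' chain's direction pool and every iterate (stored or not) updates the
#' empirical center. Chain \code{j} stores \code{floor(nSamples/nChains)}
#' samples plus one extra for the first \code{nSamples %% nChains} chains, so
#' the output has exactly \code{nSamples} rows in chain-major order, the
#' i-th stored sample of a chain having travelled \code{i * stepCount}
#' iterates from its start.
#'
#' Chains are logical, each with its own RNG stream derived from the master
#' seed, so results depend only on \code{nChains} and \code{seed}, never on
#' how execution is scheduled (\code{workers} is accepted for interface
#' compatibility and does not affect the output).
#'
#' @param space a [SolutionSpace-class].
#' @param nSamples total number of samples (>= nChains).
#' @param stepCount thinning interval: ACHR iterates per stored sample.
#' @param nChains number of logical chains; default 4.
#' @param seed master seed; drawn from the session RNG when NULL.
#' @param tau interior-pulling coefficient for the warm-up set.
#' @param workers ignored (sequential-equivalence contract).
#' @return a [FluxSamples-class] with full provenance.
#' @examples
#' sp <- solutionSpace(makeBox(3))
#' s <- sampleOptGp(sp, nSamples = 40, stepCount = 5, nChains = 4, seed = 1)
#' dim(samples(s))
#' @export
sampleOptGp <- function(space, nSamples, stepCount, nChains = 4L,
                        seed = NULL, tau = 0.5, workers = 1L) {
  nSamples <- as.integer(nSamples)
  nChains <- as.integer(nChains)
  stepCount <- as.integer(stepCount)
  if (nSamples < nChains)
    stop("configuration error: nSamples (", nSamples,
         ") must be >= nChains (", nChains, ")")
  if (stepCount < 1L) stop("stepCount must be >= 1")
  seed <- .resolveSeed(seed)
  wu <- pullToInterior(minmaxWarmup(space), tau)
  W <- nrow(wu@points)
  n <- nReactions(space)
  q <- nSamples %/% nChains
  extra <- nSamples %% nChains
  counts <- q + as.integer(seq_len(nChains) <= extra)
  out <- matrix(NA_real_, nSamples, n)
  chainId <- integer(nSamples)
  pos <- 0L
  for (j in seq_len(nChains)) {
    if (counts[j] == 0L) next
    set.seed(.chainSeed(seed, j))
    start <- floor(stats::runif(1) * W) + 1L
    r <- .achrChainCpp(wu@points, wu@points[start, ], wu@centroid,
                       as.numeric(W), counts[j], stepCount,
                       space@model@lb, space@model@ub, space@proj,
                       .PROJECT_EVERY, TRUE, space@dirTol, space@boundTol)
    rows <- pos + seq_len(counts[j])
    out[rows, ] <- r$samples
    chainId[rows] <- j
    pos <- pos + counts[j]
  }
  new("FluxSamples", samples = out, reactionIds = reactionIds(space),
      meta = list(sampler = "optgp", nSamples = nSamples,
                  stepCount = stepCount, nChains = nChains, seed = seed,
                  tau = tau, chainSamples = counts, chainId = chainId,
                  warmupPoints = W,
                  poolPolicy = "warmup+stored"))
}

#' Sample with restart-per-sample short chains (gpSampler scheme)
#'
#' The COBRA-style orchestration: the warm-up set holds one point per
#' requested sample — the 2n min/max points, topped up with random-weight
#' optima when \code{nSamples > 2n} (or truncated to the first
#' \code{nSamples} min/max points otherwise) — pulled toward the interior.
#' Chain i starts at warm-up point i, runs exactly \code{stepCount} ACHR
#' iterates with the full warm-up set as its direction pool and the warm-up
#' centroid as initial center, and returns its end point as the sample.
#' \code{stepCount = 0} returns the pulled warm-up points themselves.
#'
#' @inheritParams sampleOptGp
#' @param stepCount chain length before the end point is returned (>= 0).
#' @return a [FluxSamples-class] with \code{nSamples} rows (one chain each).
#' @export
sampleGp <- function(space, nSamples, stepCount, seed = NULL, tau = 0.5,
                     workers = 1L) {
  nSamples <- as.integer(nSamples)
  stepCount <- as.integer(stepCount)
  if (nSamples < 1L) stop("configuration error: nSamples must be >= 1")
  if (stepCount < 0L) stop("stepCount must be >= 0")
  seed <- .resolveSeed(seed)
  n <- nReactions(space)
  mm <- minmaxWarmup(space)
  nRandom <- max(0L, nSamples - nrow(mm@points))
  pts <- mm@points
  origin <- mm@origin
  if (nRandom > 0L) {
    rw <- randomWeightWarmup(space, nRandom, seed = .chainSeed(seed, 0L))
    pts <- rbind(pts, rw@points)
    origin <- c(origin, rw@origin)
  }
  pts <- pts[seq_len(nSamples), , drop = FALSE]
  origin <- origin[seq_len(nSamples)]
  wu <- pullToInterior(.warmupSet(pts, origin), tau)
  if (stepCount == 0L) {
    out <- wu@points
  } else {
    out <- matrix(NA_real_, nSamples, n)
    for (i in seq_len(nSamples)) {
      set.seed(.chainSeed(seed, i))
      r <- .achrChainCpp(wu@points, wu@points[i, ], wu@centroid,
                         as.numeric(nSamples), 1L, stepCount,
                         space@model@lb, space@model@ub, space@proj,
                         .PROJECT_EVERY, FALSE, space@dirTol, space@boundTol)
      out[i, ] <- r$samples[1, ]
    }
  }
  new("FluxSamples", samples = out, reactionIds = reactionIds(space),
      meta = list(sampler = "gp", nSamples = nSamples, stepCount = stepCount,
                  nChains = nSamples, seed = seed, tau = tau,
                  chainId = seq_len(nSamples),
                  randomWeightPoints = nRandom))
}

#' Plain hit-and-run sampling
#'
#' Uncentered hit-and-run: directions are isotropic in the nullspace of S
#' (standard normal in an orthonormal nullspace basis restricted to non-fixed
#' coordinates, then normalised), the step is uniform on the feasible
#' segment. The chain starts at the centroid of the min/max warm-up set and
#' every \code{thin}-th point is stored.
#'
#' @param space a [SolutionSpace-class] with at least one non-fixed
#'   dimension.
#' @param nSamples number of stored samples.
#' @param thin iterates between stored samples; default 1.
#' @param seed master seed; drawn from the session RNG when NULL.
#' @return a [FluxSamples-class].
#' @export
sampleHitAndRun <- function(space, nSamples, thin = 1L, seed = NULL) {
  nSamples <- as.integer(nSamples)
  thin <- as.integer(thin)
  if (nSamples < 1L) stop("configuration error: nSamples must be >= 1")
  if (thin < 1L) stop("thin must be >= 1")
  seed <- .resolveSeed(seed)
  wu <- minmaxWarmup(space)
  x0 <- correctDrift(space, wu@centroid)
  set.seed(.chainSeed(seed, 1L))
  r <- .hrChainCpp(x0, space@dirBasis, nSamples, thin,
                   space@model@lb, space@model@ub, space@proj,
                   .PROJECT_EVERY, space@dirTol, space@boundTol)
  new("FluxSamples", samples = r$samples, reactionIds = reactionIds(space),
      meta = list(sampler = "hr", nSamples = nSamples, stepCount = thin,
                  nChains = 1L, seed = seed,
                  chainId = rep(1L, nSamples)))
}
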