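#' Hyper-rectangle fixture
#'
#' A model with an empty stoichiometric matrix (no mass-balance rows), whose
#' solution space is the axis-aligned box \eqn{[lb, ub]}. Uniform moments are
#' available in closed form (marginal mean \eqn{(lb+ub)/2}, variance
#' \eqn{(ub-lb)^2/12}), which makes the box the primary oracle for sampler
#' uniformity tests.
#'
#' @param n number of reactions/dimensions.
#' @param lb,ub bounds, recycled to length n; defaults 0 and 1.
#' @return a [MetabolicModel-class].
#' @export
makeBox <- function(n, lb = 0, ub = 1) {
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  if (any(lb >= ub)) stop("box requires lb < ub in every dimension")
  metabolicModel(matrix(0, 0, n), lb = lb, ub = ub)
}

#' Triangle fixture
#'
#' Three reactions x, y and a slack s with one mass-balance row
#' \eqn{x + y + s = 0} and bounds \eqn{x, y \in [0, 1]}, \eqn{s \in [-1, 0]},
#' so the feasible set projects onto \eqn{\{x, y \ge 0,\ x + y \le 1\}}: the
#' unit right triangle, with exact uniform moments (mean 1/3 per coordinate,
#' variance 1/18, covariance -1/36).
#'
#' @return a [MetabolicModel-class] with reactions \code{x}, \code{y},
#'   \code{s}.
#' @export
makeTriangle <- function() {
  metabolicModel(matrix(c(1, 1, 1), 1, 3),
                 lb = c(0, 0, -1), ub = c(1, 1, 0),
                 reactionIds = c("x", "y", "s"),
                 metaboliteIds = "pool")
}

#' Random feasible network fixture
#'
#' Generates a small random metabolic network with known-good geometry:
#' sparse integer stoichiometry of full row rank, and bounds built around a
#' planted flux vector drawn from the nullspace of S, so the model is
#' feasible by construction with the planted vector strictly interior.
#' Bound half-widths are drawn from a mixed tight/loose set, producing the
#' anisotropic, elongated-and-narrow solution spaces typical of real
#' networks where some fluxes are loosely and others tightly constrained.
#'
#' @param m number of metabolites (rows).
#' @param n number of reactions (columns), n > m.
#' @param seed integer seed; generation is deterministic given it.
#' @param density probability of a nonzero stoichiometric entry (> 0); each
#'   row is guaranteed at least two nonzeros.
#' @param tightWidth,looseWidth the two bound half-widths mixed across
#'   reactions; defaults 0.5 and 20.
#' @param looseFraction probability that a reaction receives the loose
#'   width; default 0.5. Small values concentrate the polytope's volume
#'   along a few elongated axes.
#' @return a [MetabolicModel-class]; the planted interior flux vector is
#'   attached as attribute \code{"plantedFlux"}.
#' @export
makeRandomNetwork <- function(m, n, seed = 1L, density = 0.3,
                              tightWidth = 0.5, looseWidth = 20,
                              looseFraction = 0.5) {
  if (n <= m || m < 1) stop("need n > m >= 1")
  if (density <= 0) stop("density must be positive")
  set.seed(as.integer(seed))
  for (attempt in 1:50) {
    S <- matrix(0, m, n)
    nz <- matrix(stats::runif(m * n) < density, m, n)
    S[nz] <- sample(c(-2, -1, 1, 2), sum(nz), replace = TRUE)
    for (i in seq_len(m)) {
      need <- 2L - sum(S[i, ] != 0)
      if (need > 0) {
        cols <- sample(which(S[i, ] == 0), need)
        S[i, cols] <- sample(c(-1, 1), need, replace = TRUE)
      }
    }
    if (qr(S)$rank < m) next
    nb <- .nullBasis(S, n)
    v <- as.numeric(nb %*% stats::runif(ncol(nb), -5, 5))
    w <- ifelse(stats::runif(n) < looseFraction, looseWidth, tightWidth)
    model <- metabolicModel(S, lb = v - w, ub = v + w)
    attr(model, "plantedFlux") <- v
    return(model)
  }
  stop("generation error: no full-rank stoichiometry in 50 attempts; reseed")
}

#' Rejection sampling over the flux polytope (validation oracle)
#'
#' Draws exactly-uniform samples by proposing uniformly inside the bounding
#' box of the polytope expressed in an orthonormal nullspace parameterisation
#' (per-direction extents found by linear programming) and rejecting
#' proposals that violate the flux bounds. Because the proposal volume grows
#' explosively with dimension this is only usable as a ground-truth oracle on
#' low-dimensional fixtures; the effective dimension is capped at 4 and a
#' pilot round aborts when the acceptance rate is below 1e-4.
#'
#' @param space a [SolutionSpace-class] with nullspace dimension <= 4.
#' @param count number of accepted samples to return.
#' @param seed optional integer seed.
#' @return a [FluxSamples-class]; the overall acceptance rate is stored in
#'   the provenance entry \code{acceptanceRate}.
#' @export
rejectionSample <- function(space, count, seed = NULL) {
  B <- space@dirBasis
  k <- ncol(B)
  if (k > 4)
    stop("effective dimension ", k, " > 4: rejection sampling refused")
  if (!is.null(seed)) set.seed(as.integer(seed))
  model <- space@model
  v0 <- space@feasiblePoint
  ## extent of the polytope along each basis direction, by LP
  zlo <- numeric(k)
  zhi <- numeric(k)
  for (d in seq_len(k)) {
    lo <- .lpSolve(model@S, model@lb, model@ub, B[, d], maximise = FALSE)
    hi <- .lpSolve(model@S, model@lb, model@ub, B[, d], maximise = TRUE)
    zlo[d] <- sum(B[, d] * (lo$v - v0))
    zhi[d] <- sum(B[, d] * (hi$v - v0))
  }
  propose <- function(nProp) {
    z <- matrix(stats::runif(nProp * k, rep(zlo, each = nProp),
                             rep(zhi, each = nProp)), nProp, k)
    v <- sweep(z %*% t(B), 2, v0, `+`)
    okLb <- v >= matrix(model@lb, nProp, length(model@lb), byrow = TRUE) - space@boundTol
    okUb <- v <= matrix(model@ub, nProp, length(model@ub), byrow = TRUE) + space@boundTol
    v[rowSums(okLb & okUb) == ncol(v), , drop = FALSE]
  }
  pilot <- propose(1000L)
  rate <- nrow(pilot) / 1000
  if (rate < 1e-4)
    stop("acceptance rate ", rate, " below 1e-4 in pilot: refusing")
  acc <- pilot
  nProposed <- 1000L
  while (nrow(acc) < count) {
    todo <- count - nrow(acc)
    batch <- as.integer(min(2e5, ceiling(todo / max(rate, 1e-3)) + 100))
    acc <- rbind(acc, propose(batch))
    nProposed <- nProposed + batch
  }
  out <- acc[seq_len(count), , drop = FALSE]
  new("FluxSamples", samples = out, reactionIds = model@reactionIds,
      meta = list(sampler = "rejection", nSamples = count,
                  seed = seed, acceptanceRate = nrow(acc) / nProposed,
                  chainId = rep(1L, count)))
}
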