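.warmupSet <- function(points, origin, pulled = FALSE) {
  new("WarmupSet", points = points, origin = origin, pulled = pulled,
      centroid = colMeans(points))
}

#' Min/max warm-up points
#'
#' Generates the 2n warm-up points used to seed the chains: for each reaction
#' in model order, the flux vector attaining its minimum and the one attaining
#' its maximum subject to \eqn{Sv = 0} and the bounds (min first, then max).
#' Linear-program optima lie on the polytope boundary; duplicate optima are
#' kept. Each point is drift-corrected onto the nullspace before being stored.
#'
#' @param space a [SolutionSpace-class].
#' @return a [WarmupSet-class] with W = 2n points.
#' @seealso [pullToInterior()], [randomWeightWarmup()]
#' @export
minmaxWarmup <- function(space) {
  model <- space@model
  n <- nReactions(model)
  pts <- matrix(NA_real_, 2L * n, n)
  for (i in seq_len(n)) {
    r <- tryCatch(.lpMinMaxReaction(model@S, model@lb, model@ub, i),
                  error = function(e) stop("warm-up LP failed for reaction '",
                                           model@reactionIds[i], "': ",
                                           conditionMessage(e), call. = FALSE))
    pts[2L * i - 1L, ] <- correctDrift(space, r$argmin)
    pts[2L * i, ] <- correctDrift(space, r$argmax)
  }
  .warmupSet(pts, rep("minmax", 2L * n))
}

#' Random-weight warm-up points
#'
#' Each point maximizes \eqn{c^T v} with weights \eqn{c} drawn i.i.d.
#' uniformly on \eqn{[-1, 1]^n}. This is the second part of the classic
#' COBRA warm-up procedure, used here only in gpSampler-emulation mode:
#' because the constraints often drive different random weightings to the
#' same optimum, these points add little direction diversity at substantial
#' LP cost, which is why the long-chain mode skips them.
#'
#' @param space a [SolutionSpace-class].
#' @param count number of points (>= 1).
#' @param seed optional integer seed for the weight draws.
#' @return a [WarmupSet-class].
#' @export
randomWeightWarmup <- function(space, count, seed = NULL) {
  if (count < 1) stop("count must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  model <- space@model
  n <- nReactions(model)
  pts <- matrix(NA_real_, count, n)
  for (i in seq_len(count)) {
    w <- stats::runif(n, -1, 1)
    sol <- .lpSolve(model@S, model@lb, model@ub, w, maximise = TRUE)
    pts[i, ] <- correctDrift(space, sol$v)
  }
  .warmupSet(pts, rep("random_weight", count))
}

#' Pull warm-up points toward the interior
#'
#' Linear-program optima sit on the boundary, where feasible step lengths
#' shrink to zero. Blending each point with the set centroid,
#' \eqn{x \mapsto c + \tau (x - c)}, moves the set into the interior while
#' preserving feasibility by convexity. \code{tau = 1} is the identity; as
#' \code{tau} approaches 0 all points collapse onto the centroid.
#'
#' @param wset a [WarmupSet-class] with at least 2 points.
#' @param tau blend coefficient in (0, 1]; default 0.5.
#' @return the pulled [WarmupSet-class] (centroid unchanged).
#' @export
pullToInterior <- function(wset, tau = 0.5) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  ctr <- wset@centroid
  pts <- sweep(sweep(wset@points, 2, ctr, `-`) * tau, 2, ctr, `+`)
  new("WarmupSet", points = pts, origin = wset@origin, pulled = TRUE,
      centroid = colMeans(pts))
}
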