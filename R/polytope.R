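## orthonormal nullspace basis of A (n columns); identity when A has no rows
.nullBasis <- function(A, n, tol = 1e-10) {
  if (is.null(A) || nrow(A) == 0L) return(diag(n))
  sv <- svd(A, nu = 0, nv = n)
  d <- c(sv$d, rep(0, n - length(sv$d)))
  keep <- d <= tol * max(d[1], 1)
  sv$v[, keep, drop = FALSE]
}

#' Build the sampling polytope for a model
#'
#' Validates that the solution space \eqn{\{v : Sv = 0, lb \le v \le ub\}} is
#' non-empty (via a phase-1 linear program) and caches the geometry the
#' samplers use: an orthonormal nullspace basis of S, the orthogonal
#' projector onto it, the mask of fixed reactions, and a direction basis with
#' fixed coordinates pinned to zero.
#'
#' @param model a [MetabolicModel-class].
#' @param feasTol equality residual tolerance (default \code{1e-6}).
#' @param boundTol bound violation tolerance (default \code{1e-6}).
#' @param fixedTol reactions with \code{ub - lb <= fixedTol} are treated as
#'   fixed (default \code{1e-9}).
#' @param dirTol direction components with magnitude below this are ignored
#'   when computing segment limits (default \code{1e-9}).
#' @return a [SolutionSpace-class].
#' @examples
#' sp <- solutionSpace(makeTriangle())
#' isFeasible(sp, sp@feasiblePoint)
#' @export
solutionSpace <- function(model, feasTol = 1e-6, boundTol = 1e-6,
                          fixedTol = 1e-9, dirTol = 1e-9) {
  n <- nReactions(model)
  fp <- tryCatch(.lpFeasiblePoint(model@S, model@lb, model@ub),
                 error = function(e) stop("model is infeasible: ",
                                          conditionMessage(e), call. = FALSE))
  nb <- .nullBasis(model@S, n)
  proj <- nb %*% t(nb)
  fixed <- (model@ub - model@lb) <= fixedTol
  ## directions for plain hit-and-run: null(S) intersected with {d_i = 0, i fixed}
  A <- model@S
  if (any(fixed)) {
    pins <- diag(n)[fixed, , drop = FALSE]
    A <- rbind(model@S, pins)
  }
  db <- .nullBasis(A, n)
  if (ncol(db) < 1)
    stop("solution space has no free directions (all reactions fixed)")
  ## project the feasible point exactly onto null(S)
  fp <- as.numeric(proj %*% fp)
  fp <- pmin(pmax(fp, model@lb), model@ub)
  new("SolutionSpace", model = model, feasTol = feasTol, boundTol = boundTol,
      fixedTol = fixedTol, dirTol = dirTol, fixedMask = fixed,
      nullBasis = nb, proj = proj, dirBasis = db, feasiblePoint = fp)
}

#' Feasibility check with residual report
#'
#' A flux vector (or matrix of row vectors) is feasible when
#' \eqn{\|Sv\|_\infty \le} \code{feasTol} and every component lies within
#' \code{boundTol} of its bounds.
#'
#' @param space a [SolutionSpace-class].
#' @param v length-n numeric vector, or an nPoints x n matrix.
#' @return logical (one per point) with attributes
#'   \code{"equalityResidual"} and \code{"boundViolation"} carrying the worst
#'   residuals per point.
#' @export
isFeasible <- function(space, v) {
  model <- space@model
  n <- ncol(model@S)
  if (is.null(dim(v))) {
    if (length(v) != n)
      stop("dimension error: point has length ", length(v), ", expected ", n)
    v <- matrix(v, 1L)
  }
  if (ncol(v) != n)
    stop("dimension error: points have ", ncol(v), " columns, expected ", n)
  eqRes <- if (nrow(model@S) > 0)
    apply(abs(model@S %*% t(v)), 2, max) else rep(0, nrow(v))
  lbViol <- apply(sweep(v, 2, model@lb, `-`), 1, function(r) max(-r, 0))
  ubViol <- apply(sweep(v, 2, model@ub, `-`), 1, function(r) max(r, 0))
  bViol <- pmax(lbViol, ubViol)
  ok <- eqRes <= space@feasTol & bViol <= space@boundTol
  attr(ok, "equalityResidual") <- eqRes
  attr(ok, "boundViolation") <- bViol
  ok
}

#' Feasible segment along a direction
#'
#' For a feasible point \eqn{v} and a direction \eqn{d} lying (numerically)
#' in the nullspace of S, returns the tightest interval
#' \eqn{[\alpha_{min}, \alpha_{max}]} with \eqn{\alpha_{min} \le 0 \le
#' \alpha_{max}} such that \eqn{v + \alpha d} respects the flux bounds for
#' every \eqn{\alpha} in the interval — the maximum distance the sampler may
#' travel forwards or backwards along \eqn{d}. Components with
#' \eqn{|d_i| \le} \code{dirTol} are ignored. If no constraint is met in one
#' direction the limit is capped at \code{1e6 * (1 + ||v||)}.
#'
#' @param space a [SolutionSpace-class].
#' @param point feasible length-n flux vector.
#' @param direction length-n vector with positive norm and
#'   \eqn{\|Sd\|_\infty \le feasTol (1 + \|d\|)}.
#' @return numeric c(alphaMin, alphaMax).
#' @export
lineLimits <- function(space, point, direction) {
  model <- space@model
  n <- ncol(model@S)
  if (length(point) != n || length(direction) != n)
    stop("dimension error: expected length-", n, " point and direction")
  nd <- sqrt(sum(direction^2))
  if (nd <= space@dirTol)
    stop("degenerate direction: norm is (numerically) zero")
  if (nrow(model@S) > 0) {
    res <- max(abs(model@S %*% direction))
    if (res > space@feasTol * (1 + nd))
      stop("direction is off the nullspace: ||S d|| = ", format(res))
  }
  cap <- 1e6 * (1 + sqrt(sum(point^2)))
  lim <- .lineLimitsCpp(point, direction, model@lb, model@ub,
                        space@dirTol, cap)
  c(max(lim[1], -cap), min(lim[2], cap))
}

#' Project a drifted point back onto the mass-balance subspace
#'
#' Long chains accumulate floating-point drift off \eqn{\{v : Sv = 0\}}.
#' This returns the least-squares (orthogonal) projection of \code{point}
#' onto the nullspace of S, then clamps any residual bound violation up to
#' \code{boundTol} back onto the bound. Points further than
#' \code{driftLimit} from the subspace indicate a corrupted chain and raise
#' an error.
#'
#' @param space a [SolutionSpace-class].
#' @param point length-n numeric vector near the nullspace.
#' @param driftLimit hard limit on \eqn{\|Sv\|_\infty} (scaled by
#'   \code{1 + max|v|}) beyond which the point is rejected; default
#'   \code{1e-3}.
#' @return the corrected flux vector.
#' @export
correctDrift <- function(space, point, driftLimit = 1e-3) {
  model <- space@model
  if (length(point) != ncol(model@S))
    stop("dimension error: expected length-", ncol(model@S), " point")
  if (nrow(model@S) > 0) {
    res <- max(abs(model@S %*% point))
    if (res > driftLimit * (1 + max(abs(point))))
      stop("drift beyond limit (||S v|| = ", format(res),
           "): chain corrupted")
  }
  v <- as.numeric(space@proj %*% point)
  lo <- model@lb
  hi <- model@ub
  below <- v < lo
  above <- v > hi
  v[below & (lo - v) <= space@boundTol] <- lo[below & (lo - v) <= space@boundTol]
  v[above & (v - hi) <= space@boundTol] <- hi[above & (v - hi) <= space@boundTol]
  v
}
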