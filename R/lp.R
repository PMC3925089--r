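## Internal linear-programming layer.
##
## Solves   optimise c'v   s.t.  S v = 0,  lb <= v <= ub
## with boot::simplex (two-phase simplex) after shifting to x = v - lb >= 0:
##   optimise c'x  s.t.  S x = -S lb,  x <= ub - lb,  x >= 0.
## Equality rows with negative right-hand side are sign-flipped so the
## tableau right-hand sides are non-negative.

.lpSolve <- function(S, lb, ub, objective, maximise = FALSE, eps = 1e-10) {
  n <- length(lb)
  stopifnot(length(objective) == n)
  width <- ub - lb
  if (nrow(S) > 0) {
    b3 <- as.numeric(-S %*% lb)
    A3 <- S
    ## orient rows so the tableau right-hand sides are non-negative; rows
    ## with zero rhs and no positive coefficient also need flipping or the
    ## phase-1 pivot in boot::simplex produces NAs
    flip <- b3 < 0 | (b3 == 0 & apply(A3, 1, max) <= 0)
    if (any(flip)) {
      A3[flip, ] <- -A3[flip, , drop = FALSE]
      b3[flip] <- -b3[flip]
    }
    keep <- apply(A3 != 0, 1, any) | b3 != 0
    A3 <- A3[keep, , drop = FALSE]
    b3 <- b3[keep]
    if (nrow(A3) == 0L) { A3 <- NULL; b3 <- NULL }
  } else {
    A3 <- NULL
    b3 <- NULL
  }
  res <- boot::simplex(
    a = objective,
    A1 = diag(n), b1 = width,
    A3 = A3, b3 = b3,
    maxi = maximise,
    n.iter = max(200L, 30L * (n + nrow(S))),
    eps = eps
  )
  if (res$solved == -1)
    stop("linear program infeasible: the model admits no flux vector ",
         "satisfying Sv = 0 within the bounds", call. = FALSE)
  if (res$solved != 1)
    stop("linear program did not converge (simplex iteration limit)",
         call. = FALSE)
  v <- as.numeric(res$soln) + lb
  list(v = v, objval = sum(objective * v))
}

## min and max of v[i] over the polytope; returns list(min=, max=, argmin=, argmax=)
.lpMinMaxReaction <- function(S, lb, ub, i) {
  obj <- numeric(length(lb))
  obj[i] <- 1
  lo <- .lpSolve(S, lb, ub, obj, maximise = FALSE)
  hi <- .lpSolve(S, lb, ub, obj, maximise = TRUE)
  list(min = lo$v[i], max = hi$v[i], argmin = lo$v, argmax = hi$v)
}

## a feasible point: phase-1 only (zero objective)
.lpFeasiblePoint <- function(S, lb, ub) {
  .lpSolve(S, lb, ub, numeric(length(lb)), maximise = FALSE)$v
}
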