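# Shared fixtures, built once per test run. All geometry is defined in code
# so the tests document it.

fx <- new.env()

`%||%` <- function(a, b) if (is.null(a)) b else a

boxSpace <- function(n, lb = 0, ub = 1) {
  key <- paste0("box", n, "_", lb[1], "_", ub[1])
  if (is.null(fx[[key]])) fx[[key]] <- solutionSpace(makeBox(n, lb, ub))
  fx[[key]]
}

triangleSpace <- function() {
  if (is.null(fx$triangle)) fx$triangle <- solutionSpace(makeTriangle())
  fx$triangle
}

netSpace <- function(m = 5, n = 10, seed = 3) {
  key <- paste0("net", m, "_", n, "_", seed)
  if (is.null(fx[[key]]))
    fx[[key]] <- solutionSpace(makeRandomNetwork(m, n, seed = seed))
  fx[[key]]
}

# dead-end model: R1 produces M1, R2 consumes it; R3 consumes M2 which has
# no producer, so R3 can never carry flux
deadEndModel <- function() {
  S <- matrix(c(1, -1, 0,
                0,  0, -1), 2, 3, byrow = TRUE)
  metabolicModel(S, lb = c(0, 0, 0), ub = c(10, 10, 10),
                 reactionIds = c("R1", "R2", "R3"),
                 metaboliteIds = c("M1", "M2"))
}

# two parallel conversions of M1; R2 capped to zero flux
cappedParallelModel <- function() {
  S <- matrix(c(1, -1, -1), 1, 3)
  metabolicModel(S, lb = c(0, 0, 0), ub = c(10, 0, 10),
                 reactionIds = c("in", "capped", "out"),
                 metaboliteIds = "M1")
}

expect_feasible <- function(space, pts) {
  ok <- isFeasible(space, pts)
  expect_true(all(ok),
              info = sprintf("max ||Sv|| = %g, max bound violation = %g",
                             max(attr(ok, "equalityResidual")),
                             max(attr(ok, "boundViolation"))))
}
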