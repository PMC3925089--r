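#' @import methods
NULL

#' Constraint-based metabolic model
#'
#' Holds the stoichiometric matrix \eqn{S} (m metabolites by n reactions)
#' together with per-reaction flux bounds. The feasible flux vectors are
#' \eqn{\{v : Sv = 0,\ lb \le v \le ub\}}: mass balance at steady state plus
#' flux capacity/directionality constraints. Reversibility is encoded purely
#' through the bounds (a negative lower bound allows backward flux); reactions
#' are never split into forward/backward halves.
#'
#' @slot S numeric matrix, m x n stoichiometric coefficients. A positive
#'   entry means the metabolite is produced by the reaction, negative consumed.
#' @slot reactionIds character vector of n unique reaction identifiers.
#' @slot metaboliteIds character vector of m unique metabolite identifiers.
#' @slot lb,ub numeric length-n lower/upper flux bounds
#'   (conventionally mmol/gDW/h). Must be finite with \code{lb <= ub}.
#'
#' @seealso [readModel()], [solutionSpace()], [removeBlockedReactions()]
#' @export
setClass("MetabolicModel",
  representation(
    S = "matrix",
    reactionIds = "character",
    metaboliteIds = "character",
    lb = "numeric",
    ub = "numeric"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  n <- ncol(object@S)
  m <- nrow(object@S)
  if (length(object@reactionIds) != n)
    msg <- c(msg, sprintf("reactionIds length (%d) != ncol(S) (%d)",
                          length(object@reactionIds), n))
  if (length(object@metaboliteIds) != m)
    msg <- c(msg, sprintf("metaboliteIds length (%d) != nrow(S) (%d)",
                          length(object@metaboliteIds), m))
  if (anyDuplicated(object@reactionIds))
    msg <- c(msg, "reaction identifiers must be unique")
  if (m > 0 && anyDuplicated(object@metaboliteIds))
    msg <- c(msg, "metabolite identifiers must be unique")
  if (length(object@lb) != n || length(object@ub) != n)
    msg <- c(msg, "lb and ub must have one entry per reaction")
  if (!all(is.finite(object@lb)) || !all(is.finite(object@ub)))
    msg <- c(msg, "flux bounds must be finite")
  bad <- which(object@lb > object@ub)
  if (length(bad))
    msg <- c(msg, sprintf("lb > ub for reaction(s): %s",
                          paste(object@reactionIds[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Sampling polytope with cached geometry
#'
#' A validated solution space \eqn{\{v : Sv = 0, lb \le v \le ub\}} carrying
#' the numerical tolerances and cached linear algebra the samplers need: an
#' orthonormal basis of the nullspace of S, the orthogonal projector onto it,
#' a direction basis restricted to non-fixed coordinates, a feasible point,
#' and the mask of fixed reactions (ub - lb below \code{fixedTol}).
#'
#' @slot model the [MetabolicModel-class].
#' @slot feasTol equality residual tolerance for \eqn{\|Sv\|_\infty}.
#' @slot boundTol inequality tolerance on the box constraints.
#' @slot fixedTol width below which a reaction counts as fixed.
#' @slot dirTol magnitude below which a direction component is ignored.
#' @slot fixedMask logical length-n, TRUE for fixed reactions.
#' @slot nullBasis n x k orthonormal basis of null(S).
#' @slot proj n x n orthogonal projector onto null(S).
#' @slot dirBasis n x k' orthonormal basis of null(S) with fixed coordinates
#'   pinned to zero (used for plain hit-and-run directions).
#' @slot feasiblePoint a feasible flux vector found by linear programming.
#'
#' @seealso [solutionSpace()], [isFeasible()], [lineLimits()]
#' @export
setClass("SolutionSpace",
  representation(
    model = "MetabolicModel",
    feasTol = "numeric",
    boundTol = "numeric",
    fixedTol = "numeric",
    dirTol = "numeric",
    fixedMask = "logical",
    nullBasis = "matrix",
    proj = "matrix",
    dirBasis = "matrix",
    feasiblePoint = "numeric"
  )
)

setValidity("SolutionSpace", function(object) {
  msg <- character()
  n <- ncol(object@model@S)
  if (length(object@fixedMask) != n)
    msg <- c(msg, "fixedMask must have one entry per reaction")
  if (object@feasTol <= 0 || object@boundTol <= 0)
    msg <- c(msg, "tolerances must be positive")
  if (sum(!object@fixedMask) < 1)
    msg <- c(msg, "solution space must have at least one non-fixed dimension")
  if (length(msg)) msg else TRUE
})

#' Warm-up point set
#'
#' Boundary points of the flux polytope obtained by linear programming
#' (min/max of each reaction flux, or optima of random weightings), optionally
#' pulled toward the interior by blending with the set centroid.
#'
#' @slot points W x n matrix, one warm-up point per row.
#' @slot origin character per point, "minmax" or "random_weight".
#' @slot pulled logical, TRUE after [pullToInterior()].
#' @slot centroid length-n arithmetic mean of the points.
#' @export
setClass("WarmupSet",
  representation(
    points = "matrix",
    origin = "character",
    pulled = "logical",
    centroid = "numeric"
  )
)

setValidity("WarmupSet", function(object) {
  msg <- character()
  if (nrow(object@points) < 2)
    msg <- c(msg, "a warm-up set needs at least 2 points")
  if (length(object@origin) != nrow(object@points))
    msg <- c(msg, "one origin label per point required")
  if (!all(object@origin %in% c("minmax", "random_weight")))
    msg <- c(msg, "origin labels must be 'minmax' or 'random_weight'")
  if (length(object@centroid) != ncol(object@points))
    msg <- c(msg, "centroid length must equal point dimension")
  if (max(abs(object@centroid - colMeans(object@points))) > 1e-8)
    msg <- c(msg, "centroid must be the mean of the points")
  if (length(msg)) msg else TRUE
})

#' Matrix of sampled flux vectors with provenance
#'
#' The output of the samplers: an nSamples x n matrix whose rows are flux
#' vectors, plus a provenance record (sampler mode, step count, chain count,
#' master seed, per-row chain id) sufficient to reproduce the run.
#'
#' @slot samples numeric nSamples x n matrix of flux vectors.
#' @slot reactionIds character, column identifiers.
#' @slot meta list: sampler, nSamples, stepCount, nChains, seed, chainId
#'   (integer per row), and any mode-specific fields.
#' @seealso [sampleOptGp()], [sampleGp()], [sampleHitAndRun()], [writeSamples()]
#' @export
setClass("FluxSamples",
  representation(
    samples = "matrix",
    reactionIds = "character",
    meta = "list"
  )
)

setValidity("FluxSamples", function(object) {
  msg <- character()
  if (ncol(object@samples) != length(object@reactionIds))
    msg <- c(msg, "one reaction id per sample column required")
  if (length(msg)) msg else TRUE
})

#' xy-deviation report
#'
#' Per-reaction deviations \eqn{D_j \in [0,1]} between the sorted,
#' bound-normalised chains of sampler x and the mean sorted chain of sampler
#' y, and their average (the scalar xy-deviation).
#'
#' @slot perReaction named numeric, deviation per included reaction.
#' @slot xyDeviation scalar in [0, 1]; mean of perReaction over included
#'   reactions.
#' @slot excluded character, reaction ids excluded because ub == lb.
#' @slot config list describing the comparison (run counts, N, bounds source).
#' @seealso [xyDeviation()]
#' @export
setClass("DeviationReport",
  representation(
    perReaction = "numeric",
    xyDeviation = "numeric",
    excluded = "character",
    config = "list"
  )
)

#' Convergence diagnostics report
#'
#' Bundles the three empirical convergence diagnostics applied to sampler
#' output: Geweke z-scores (averaged across runs), Gelman-Rubin potential
#' scale reduction factors (per reaction and multivariate), and
#' Heidelberger-Welch stationarity pass indicators, with the conventional
#' decision thresholds attached. The three tests are reported side by side
#' and never aggregated into a single verdict.
#'
#' @slot gewekeZ named numeric, per-reaction z-scores.
#' @slot gelmanR scalar multivariate PSRF.
#' @slot gelmanRPerReaction named numeric, per-reaction PSRF.
#' @slot hwPass named numeric in {0,1}, per-reaction stationarity pass.
#' @slot hwFraction scalar, mean of hwPass.
#' @slot thresholds list(R_crit = 1.2, z_crit = 1.96, hw_alpha = 0.05).
#' @seealso [gewekeDiagnostic()], [gelmanRubin()], [heidelbergerWelch()],
#'   [convergenceDiagnostics()]
#' @export
setClass("DiagnosticsReport",
  representation(
    gewekeZ = "numeric",
    gelmanR = "numeric",
    gelmanRPerReaction = "numeric",
    hwPass = "numeric",
    hwFraction = "numeric",
    thresholds = "list"
  )
)
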