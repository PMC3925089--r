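.runMatrix <- function(run) {
  if (is(run, "FluxSamples")) run@samples else as.matrix(run)
}

#' Sorted, bound-normalised chain
#'
#' Step one of the xy-deviation pipeline: each reaction's column of sampled
#' fluxes is sorted ascending and divided by the width of its flux bounds
#' \code{ub - lb}, putting every reaction on a comparable [0, 1]-width scale.
#' Reactions with \code{ub == lb} cannot be normalised; their columns are set
#' to zero and their ids recorded in the \code{"excluded"} attribute.
#'
#' @param run a [FluxSamples-class] or an N x n numeric matrix.
#' @param lb,ub length-n flux bounds used for normalisation.
#' @return N x n matrix of sorted normalised values, with attribute
#'   \code{"excluded"} (integer column indices).
#' @seealso [xyDeviation()]
#' @export
sortedNormalized <- function(run, lb, ub) {
  m <- .runMatrix(run)
  if (nrow(m) == 0L) stop("empty run: no samples to sort")
  if (ncol(m) != length(lb) || length(lb) != length(ub))
    stop("dimension error: bounds do not match the sample columns")
  width <- ub - lb
  excluded <- which(width <= 0)
  out <- apply(m, 2, sort)
  out <- sweep(out, 2, ifelse(width > 0, width, 1), `/`)
  out[, excluded] <- 0
  attr(out, "excluded") <- excluded
  out
}

#' Mean chain of a run group
#'
#' Element-wise arithmetic mean of the sorted, bound-normalised matrices of
#' r runs — the reference profile that the other sampler's runs are compared
#' against.
#'
#' @param runs list of [FluxSamples-class] objects (or matrices), all with
#'   the same number of samples N and the same reactions.
#' @param lb,ub bounds for normalisation.
#' @return N x n matrix, with attribute \code{"excluded"}.
#' @export
meanChain <- function(runs, lb, ub) {
  if (!length(runs)) stop("empty run group")
  mats <- lapply(runs, sortedNormalized, lb = lb, ub = ub)
  Ns <- vapply(mats, nrow, integer(1))
  if (length(unique(Ns)) != 1L)
    stop("dimension error: runs have differing sample counts (",
         paste(unique(Ns), collapse = ", "), ")")
  out <- Reduce(`+`, mats) / length(mats)
  attr(out, "excluded") <- attr(mats[[1]], "excluded")
  out
}

#' xy-deviation between two sampler run groups
#'
#' Quantifies how samples generated by sampler x deviate from those of
#' sampler y. Each run is sorted per reaction and normalised by the bound
#' width; the r_y runs of y are averaged into a mean chain; then for each
#' reaction j the deviation
#' \deqn{D_j = \frac{1}{r_x N} \sum_{runs}\sum_{i=1}^{N} |\hat x_{ij} - \bar y_{ij}|}
#' is the mean absolute deviation of the x-chains from the mean y-chain at
#' aligned order statistics. The scalar xy-deviation is the average of
#' \eqn{D_j} over included reactions; it lies in [0, 1] and can be read as a
#' percentage. Mean absolute deviation is used rather than a standard
#' deviation for robustness to occasional aberrant values. The measure is
#' asymmetric (y provides the reference chain); \code{symmetric = TRUE}
#' additionally computes the reversed direction and reports the maximum of
#' the two — a convenience variant, not part of the original definition.
#'
#' @param xRuns,yRuns lists of [FluxSamples-class] objects (or N x n
#'   matrices); all runs must share reactions and sample count N.
#' @param lb,ub length-n flux bounds for normalisation. May be omitted when
#'   \code{space} is given.
#' @param space optional [SolutionSpace-class] or [MetabolicModel-class]
#'   supplying bounds and reaction ids.
#' @param symmetric if TRUE report max(dev(x|y), dev(y|x)).
#' @return a [DeviationReport-class].
#' @examples
#' sp <- solutionSpace(makeBox(2))
#' a <- sampleOptGp(sp, 50, 5, 2, seed = 1)
#' xyDeviation(list(a), list(a), space = sp)@xyDeviation  # exactly 0
#' @export
xyDeviation <- function(xRuns, yRuns, lb = NULL, ub = NULL, space = NULL,
                        symmetric = FALSE) {
  if (!is.null(space)) {
    mdl <- if (is(space, "SolutionSpace")) space@model else space
    lb <- mdl@lb
    ub <- mdl@ub
    rids <- mdl@reactionIds
  } else rids <- NULL
  if (is.null(lb) || is.null(ub))
    stop("provide flux bounds via lb/ub or space=")
  if (is(xRuns, "FluxSamples") || is.matrix(xRuns)) xRuns <- list(xRuns)
  if (is(yRuns, "FluxSamples") || is.matrix(yRuns)) yRuns <- list(yRuns)
  rx <- lapply(xRuns, .runMatrix)
  if (is.null(rids)) {
    first <- xRuns[[1]]
    rids <- if (is(first, "FluxSamples")) first@reactionIds
            else paste0("R", seq_along(lb))
  }
  idSets <- lapply(c(xRuns, yRuns), function(r)
    if (is(r, "FluxSamples")) r@reactionIds else NULL)
  idSets <- Filter(Negate(is.null), idSets)
  if (length(idSets) && !all(vapply(idSets, identical, logical(1), y = rids)))
    stop("alignment error: runs do not share the same reaction set/order")
  Ns <- vapply(c(rx, lapply(yRuns, .runMatrix)), nrow, integer(1))
  if (length(unique(Ns)) != 1L)
    stop("dimension error: all runs must have the same sample count")

  ybar <- meanChain(yRuns, lb, ub)
  xs <- lapply(xRuns, sortedNormalized, lb = lb, ub = ub)
  excluded <- attr(ybar, "excluded")
  N <- nrow(ybar)
  D <- Reduce(`+`, lapply(xs, function(m) colSums(abs(m - ybar)))) /
    (length(xs) * N)
  included <- setdiff(seq_along(lb), excluded)
  names(D) <- rids
  xy <- mean(D[included])
  if (symmetric) {
    rev <- xyDeviation(yRuns, xRuns, lb = lb, ub = ub, symmetric = FALSE)
    xy <- max(xy, rev@xyDeviation)
    D <- pmax(D, rev@perReaction)
  }
  new("DeviationReport",
      perReaction = D[included], xyDeviation = xy,
      excluded = rids[excluded],
      config = list(rX = length(xRuns), rY = length(yRuns), N = N,
                    symmetric = symmetric))
}

#' Serialise a deviation report
#'
#' Writes the scalar xy-deviation and configuration as JSON, or the
#' per-reaction deviations as a two-column TSV.
#'
#' @param report a [DeviationReport-class].
#' @param path output file.
#' @param format "json" or "tsv".
#' @return invisibly, \code{path}.
#' @export
writeDeviationReport <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(xy_deviation = report@xyDeviation,
           per_reaction = as.list(report@perReaction),
           excluded = report@excluded,
           config = report@config),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(
      data.frame(reaction_id = names(report@perReaction),
                 D = as.numeric(report@perReaction)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
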