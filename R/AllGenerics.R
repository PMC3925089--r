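#' @rdname MetabolicModel-class
#' @param object,x a \code{MetabolicModel}, \code{FluxSamples} or related object
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("lowerBounds", function(x) standardGeneric("lowerBounds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("upperBounds", function(x) standardGeneric("upperBounds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("nullspaceDim", function(x) standardGeneric("nullspaceDim"))

#' @rdname FluxSamples-class
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname FluxSamples-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname WarmupSet-class
#' @export
setGeneric("warmupPoints", function(x) standardGeneric("warmupPoints"))


## ---- accessors -------------------------------------------------------------

#' @rdname MetabolicModel-class
setMethod("reactionIds", "MetabolicModel", function(x) x@reactionIds)
#' @rdname MetabolicModel-class
setMethod("metaboliteIds", "MetabolicModel", function(x) x@metaboliteIds)
#' @rdname MetabolicModel-class
setMethod("stoichiometry", "MetabolicModel", function(x) x@S)
#' @rdname MetabolicModel-class
setMethod("lowerBounds", "MetabolicModel", function(x) x@lb)
#' @rdname MetabolicModel-class
setMethod("upperBounds", "MetabolicModel", function(x) x@ub)
#' @rdname MetabolicModel-class
setMethod("nReactions", "MetabolicModel", function(x) ncol(x@S))
#' @rdname MetabolicModel-class
setMethod("nMetabolites", "MetabolicModel", function(x) nrow(x@S))
#' @rdname MetabolicModel-class
setMethod("nullspaceDim", "MetabolicModel", function(x) {
  if (nrow(x@S) == 0L) return(ncol(x@S))
  ncol(x@S) - qr(x@S)$rank
})

#' @rdname SolutionSpace-class
#' @param x a \code{SolutionSpace}
setMethod("reactionIds", "SolutionSpace", function(x) x@model@reactionIds)
#' @rdname SolutionSpace-class
setMethod("lowerBounds", "SolutionSpace", function(x) x@model@lb)
#' @rdname SolutionSpace-class
setMethod("upperBounds", "SolutionSpace", function(x) x@model@ub)
#' @rdname SolutionSpace-class
setMethod("nReactions", "SolutionSpace", function(x) ncol(x@model@S))

#' @rdname FluxSamples-class
#' @param x a \code{FluxSamples}
setMethod("samples", "FluxSamples", function(x) x@samples)
#' @rdname FluxSamples-class
setMethod("reactionIds", "FluxSamples", function(x) x@reactionIds)
#' @rdname FluxSamples-class
setMethod("provenance", "FluxSamples", function(x) x@meta)

#' @rdname WarmupSet-class
#' @param x a \code{WarmupSet}
setMethod("warmupPoints", "WarmupSet", function(x) x@points)

#' @rdname FluxSamples-class
#' @param object a \code{FluxSamples}
setMethod("dim", "FluxSamples", function(x) dim(x@samples))


## ---- show methods ----------------------------------------------------------

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d metabolites x %d reactions\n",
              nrow(object@S), ncol(object@S)))
  nrev <- sum(object@lb < 0 & object@ub > 0)
  cat(sprintf("  reversible (lb < 0 < ub): %d\n", nrev))
  cat(sprintf("  bound range: [%g, %g]\n", min(object@lb), max(object@ub)))
})

setMethod("show", "SolutionSpace", function(object) {
  cat(sprintf("SolutionSpace on %d reactions (nullspace dim %d, %d fixed)\n",
              ncol(object@model@S), ncol(object@nullBasis),
              sum(object@fixedMask)))
  cat(sprintf("  feasTol %g, boundTol %g\n", object@feasTol, object@boundTol))
})

setMethod("show", "WarmupSet", function(object) {
  cat(sprintf("WarmupSet: %d points in %d dimensions (%s)\n",
              nrow(object@points), ncol(object@points),
              if (object@pulled) "pulled toward interior" else "on boundary"))
  tab <- table(object@origin)
  cat("  origin:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FluxSamples", function(object) {
  cat(sprintf("FluxSamples: %d samples x %d reactions\n",
              nrow(object@samples), ncol(object@samples)))
  m <- object@meta
  cat(sprintf("  sampler=%s stepCount=%s chains=%s seed=%s\n",
              m$sampler %||% "?", m$stepCount %||% "?",
              m$nChains %||% "?", m$seed %||% "?"))
})

setMethod("show", "DeviationReport", function(object) {
  cat(sprintf("DeviationReport: xy-deviation = %.4f (%.2f%%) over %d reactions\n",
              object@xyDeviation, 100 * object@xyDeviation,
              length(object@perReaction)))
  if (length(object@excluded))
    cat("  excluded (ub == lb):", paste(object@excluded, collapse = ", "), "\n")
})

setMethod("show", "DiagnosticsReport", function(object) {
  cat("DiagnosticsReport\n")
  cat(sprintf("  Gelman-Rubin multivariate R = %.4f (criterion < %.2f)\n",
              object@gelmanR, object@thresholds$R_crit))
  cat(sprintf("  Geweke max |z| = %.3f, fraction |z| > %.2f = %.3f\n",
              max(abs(object@gewekeZ)), object@thresholds$z_crit,
              mean(abs(object@gewekeZ) > object@thresholds$z_crit)))
  cat(sprintf("  Heidelberger-Welch pass fraction = %.3f (alpha = %.2f)\n",
              object@hwFraction, object@thresholds$hw_alpha))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
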