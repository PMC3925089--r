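#' Construct a metabolic model
#'
#' Low-level constructor assembling a [MetabolicModel-class] from a
#' stoichiometric matrix and flux bounds. Most users will instead read a model
#' with [readModel()] or generate one with [makeBox()], [makeTriangle()] or
#' [makeRandomNetwork()].
#'
#' @param S m x n numeric matrix of stoichiometric coefficients.
#' @param lb,ub length-n numeric flux bounds, \code{lb <= ub}, finite.
#' @param reactionIds,metaboliteIds identifiers; defaults \code{R1..Rn},
#'   \code{M1..Mm}.
#' @return a validated [MetabolicModel-class].
#' @examples
#' m <- metabolicModel(matrix(c(1, -1), 1, 2), lb = c(0, 0), ub = c(10, 10))
#' nReactions(m)
#' @export
metabolicModel <- function(S, lb, ub,
                           reactionIds = NULL, metaboliteIds = NULL) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  n <- ncol(S)
  m <- nrow(S)
  if (is.null(reactionIds))
    reactionIds <- if (!is.null(colnames(S))) colnames(S) else paste0("R", seq_len(n))
  if (is.null(metaboliteIds))
    metaboliteIds <- if (!is.null(rownames(S))) rownames(S) else
      (if (m > 0) paste0("M", seq_len(m)) else character())
  dimnames(S) <- list(metaboliteIds, reactionIds)
  new("MetabolicModel", S = S, reactionIds = as.character(reactionIds),
      metaboliteIds = as.character(metaboliteIds),
      lb = as.numeric(lb), ub = as.numeric(ub))
}

.DEFAULT_LB <- -1000
.DEFAULT_UB <- 1000

#' Read a metabolic model
#'
#' Reads a constraint-based model from one of three dialects:
#' \describe{
#'   \item{\code{tsv}}{two tab-separated files: a matrix file (metabolites in
#'     rows, reactions in columns, with an id header row and id first column)
#'     and a bounds file with columns \code{reaction_id}, \code{lb},
#'     \code{ub}. The bounds file defaults to the matrix path with a
#'     \code{"_bounds"} suffix.}
#'   \item{\code{json}}{cobra-style JSON:
#'     \code{reactions[\{id, lower_bound, upper_bound, metabolites\{\}\}]}.}
#'   \item{\code{sbml}}{SBML Level 3 with FBC flux bounds (reaction-level
#'     \code{fbc:lowerFluxBound}/\code{fbc:upperFluxBound} parameter
#'     references). Reactions without resolvable bounds fall back to
#'     (-1000, 1000) with a warning, the conventional "arbitrarily large"
#'     capacity used when measurements are unavailable; non-finite bound
#'     values are treated the same way.}
#' }
#' Boundary/external species (SBML \code{boundaryCondition="true"}) are
#' excluded from the mass-balance rows.
#'
#' @param path path to the model file (for tsv: the matrix file).
#' @param format one of \code{"tsv"}, \code{"json"}, \code{"sbml"}; default
#'   guessed from the file extension.
#' @param boundsPath tsv dialect only: path to the bounds file.
#' @return a validated [MetabolicModel-class].
#' @export
readModel <- function(path, format = c("guess", "tsv", "json", "sbml"),
                      boundsPath = NULL) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
                     "tsv" = "tsv", "txt" = "tsv",
                     "json" = "json",
                     "xml" = "sbml", "sbml" = "sbml",
                     stop("cannot guess model format from extension of ", path))
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         tsv = .readModelTsv(path, boundsPath),
         json = .readModelJson(path),
         sbml = .readModelSbml(path))
}

.readModelTsv <- function(path, boundsPath = NULL) {
  if (is.null(boundsPath)) {
    base <- tools::file_path_sans_ext(path)
    boundsPath <- paste0(base, "_bounds.", tools::file_ext(path))
  }
  if (!file.exists(boundsPath))
    stop("bounds file not found: ", boundsPath)
  mat <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  S <- as.matrix(mat)
  if (nrow(S) == 0L) {
    S <- matrix(numeric(), 0, ncol(mat), dimnames = list(NULL, colnames(mat)))
  } else if (!is.numeric(S)) {
    stop("format error in ", path, ": non-numeric stoichiometric entries")
  }
  bounds <- utils::read.table(boundsPath, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("reaction_id", "lb", "ub")
  if (!all(need %in% names(bounds)))
    stop("format error in ", boundsPath, ": need columns ",
         paste(need, collapse = ", "))
  miss <- setdiff(colnames(S), bounds$reaction_id)
  if (length(miss))
    stop("bounds file missing reaction(s): ", paste(miss, collapse = ", "))
  idx <- match(colnames(S), bounds$reaction_id)
  metabolicModel(S, lb = bounds$lb[idx], ub = bounds$ub[idx],
                 reactionIds = colnames(S), metaboliteIds = rownames(S))
}

.readModelJson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rxns <- doc$reactions
  if (is.null(rxns) || !length(rxns))
    stop("format error in ", path, ": no 'reactions' array")
  rids <- vapply(rxns, function(r) as.character(r$id), character(1))
  lb <- vapply(rxns, function(r) as.numeric(r$lower_bound %||% .DEFAULT_LB),
               numeric(1))
  ub <- vapply(rxns, function(r) as.numeric(r$upper_bound %||% .DEFAULT_UB),
               numeric(1))
  mids <- unique(unlist(lapply(rxns, function(r) names(r$metabolites))))
  S <- matrix(0, length(mids), length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(rxns)) {
    met <- rxns[[j]]$metabolites
    if (length(met))
      S[names(met), j] <- vapply(met, as.numeric, numeric(1))
  }
  metabolicModel(S, lb = lb, ub = ub, reactionIds = rids, metaboliteIds = mids)
}

.readModelSbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error parsing SBML ", path,
                                           ": ", conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing"))
    stop("format error in ", path, ": no <model> element")

  ## global parameters (FBC bounds reference these by id)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parVal <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sid <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mids <- sid[!boundary]

  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rnodes)) stop("format error in ", path, ": no reactions")
  rids <- xml2::xml_attr(rnodes, "id")

  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  lb <- numeric(length(rids))
  ub <- numeric(length(rids))
  defaulted <- character()
  for (j in seq_along(rnodes)) {
    rn <- rnodes[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rn, sprintf("./s:%s/s:speciesReference", side), ns)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (sp %in% mids) S[sp, j] <- S[sp, j] + sgn * st
      }
    }
    lbRef <- xml2::xml_attr(rn, "lowerFluxBound")
    ubRef <- xml2::xml_attr(rn, "upperFluxBound")
    lbj <- if (!is.na(lbRef) && lbRef %in% names(parVal)) parVal[[lbRef]] else NA_real_
    ubj <- if (!is.na(ubRef) && ubRef %in% names(parVal)) parVal[[ubRef]] else NA_real_
    if (!is.finite(lbj)) { lbj <- .DEFAULT_LB; defaulted <- c(defaulted, rids[j]) }
    if (!is.finite(ubj)) { ubj <- .DEFAULT_UB; defaulted <- c(defaulted, rids[j]) }
    lb[j] <- lbj
    ub[j] <- ubj
  }
  if (length(defaulted))
    warning("no finite FBC bounds for reaction(s) ",
            paste(unique(defaulted), collapse = ", "),
            "; default bounds (", .DEFAULT_LB, ", ", .DEFAULT_UB, ") applied",
            call. = FALSE)
  metabolicModel(S, lb = lb, ub = ub, reactionIds = rids, metaboliteIds = mids)
}

#' Write a model in the tsv dialect
#'
#' Writes the matrix and bounds files read back by
#' \code{readModel(format = "tsv")}. Numeric values use the 17-significant-
#' digit shortest round-trip representation so fixtures diff cleanly.
#'
#' @param model a [MetabolicModel-class].
#' @param path matrix file path; the bounds file is written alongside with a
#'   \code{"_bounds"} suffix unless \code{boundsPath} is given.
#' @param boundsPath optional explicit bounds file path.
#' @return invisibly, the two paths written.
#' @export
writeModel <- function(model, path, boundsPath = NULL) {
  if (is.null(boundsPath)) {
    base <- tools::file_path_sans_ext(path)
    ext <- tools::file_ext(path)
    if (!nzchar(ext)) ext <- "tsv"
    boundsPath <- paste0(base, "_bounds.", ext)
  }
  S <- model@S
  lines <- c(paste(c("metabolite_id", model@reactionIds), collapse = "\t"))
  for (i in seq_len(nrow(S)))
    lines <- c(lines, paste(c(model@metaboliteIds[i],
                              format(S[i, ], digits = 17, trim = TRUE)),
                            collapse = "\t"))
  writeLines(lines, path)
  blines <- c("reaction_id\tlb\tub",
              paste(model@reactionIds,
                    format(model@lb, digits = 17, trim = TRUE),
                    format(model@ub, digits = 17, trim = TRUE), sep = "\t"))
  writeLines(blines, boundsPath)
  invisible(c(path, boundsPath))
}

#' Flux variability analysis
#'
#' Computes, by linear programming, the minimum and maximum attainable flux
#' of each reaction subject to \eqn{Sv = 0} and the bounds.
#'
#' @param model a [MetabolicModel-class] (or [SolutionSpace-class]).
#' @return data.frame with columns \code{reaction_id}, \code{min}, \code{max}.
#' @seealso [removeBlockedReactions()]
#' @export
fluxVariability <- function(model) {
  if (is(model, "SolutionSpace")) model <- model@model
  n <- nReactions(model)
  mn <- numeric(n)
  mx <- numeric(n)
  for (i in seq_len(n)) {
    r <- tryCatch(.lpMinMaxReaction(model@S, model@lb, model@ub, i),
                  error = function(e) stop("FVA failed for reaction '",
                                           model@reactionIds[i], "': ",
                                           conditionMessage(e), call. = FALSE))
    mn[i] <- r$min
    mx[i] <- r$max
  }
  data.frame(reaction_id = model@reactionIds, min = mn, max = mx,
             stringsAsFactors = FALSE)
}

#' Remove reactions that cannot carry flux
#'
#' Standard preprocessing before sampling: flux variability analysis
#' identifies reactions whose attainable flux range is confined to
#' \code{[-fluxTol, fluxTol]} ("blocked" reactions); these and any metabolites
#' left with all-zero stoichiometric rows are removed. The operation is
#' idempotent and does not change the attainable flux ranges of surviving
#' reactions.
#'
#' @param model a [MetabolicModel-class]; must be feasible.
#' @param fluxTol absolute flux tolerance below which a reaction counts as
#'   blocked; default \code{1e-9}.
#' @return a new [MetabolicModel-class]; removed reaction and metabolite ids
#'   are attached as attributes \code{"removedReactions"} and
#'   \code{"removedMetabolites"}.
#' @examples
#' m <- makeBox(3)
#' identical(dim(stoichiometry(removeBlockedReactions(m))),
#'           dim(stoichiometry(m)))
#' @export
removeBlockedReactions <- function(model, fluxTol = 1e-9) {
  fva <- fluxVariability(model)
  blocked <- abs(fva$min) <= fluxTol & abs(fva$max) <= fluxTol
  keep <- !blocked
  S2 <- model@S[, keep, drop = FALSE]
  keepMet <- if (nrow(S2) > 0) rowSums(abs(S2) > 0) > 0 else logical(0)
  out <- metabolicModel(S2[keepMet, , drop = FALSE],
                        lb = model@lb[keep], ub = model@ub[keep],
                        reactionIds = model@reactionIds[keep],
                        metaboliteIds = model@metaboliteIds[keepMet])
  attr(out, "removedReactions") <- model@reactionIds[blocked]
  attr(out, "removedMetabolites") <- model@metaboliteIds[!keepMet]
  out
}

#' Write and read sampled flux matrices
#'
#' \code{writeSamples} stores a [FluxSamples-class] as a tab-separated table
#' (header row of reaction ids, 17 significant digits, lossless to the last
#' ulp in practice) plus a JSON provenance sidecar at \code{<path>.meta.json}.
#' \code{readSamples} reverses it.
#'
#' @param x a non-empty [FluxSamples-class].
#' @param path output path.
#' @param format only \code{"tsv"} is supported.
#' @return \code{writeSamples}: invisibly, \code{path}. \code{readSamples}:
#'   a [FluxSamples-class].
#' @export
writeSamples <- function(x, path, format = c("tsv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("hdf5 output is not supported by this build; use format = 'tsv'")
  if (nrow(x@samples) == 0)
    stop("refusing to write an empty sample matrix")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(x@reactionIds, collapse = "\t"), con)
  utils::write.table(format(x@samples, digits = 17, trim = TRUE), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(x@meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeSamples
#' @export
readSamples <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  mat <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                                     skip = 1L, colClasses = "numeric"))
  dimnames(mat) <- NULL
  meta <- list()
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp))
    meta <- jsonlite::fromJSON(mp, simplifyVector = TRUE)
  new("FluxSamples", samples = mat, reactionIds = header,
      meta = as.list(meta))
}
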