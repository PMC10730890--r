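#' @import methods
#' @importFrom stats rexp runif rnorm quantile median sd cor wilcox.test
#'   p.adjust pchisq optim cutree hclust as.dist cophenetic setNames
#'   coef predict
#' @importFrom utils read.csv write.csv head
#' @importFrom grDevices chull
NULL

#' Phenotype palette
#'
#' Maps each cellular phenotype label to one of the three tissue
#' compartments: \code{immune}, \code{stromal} or \code{epithelial}.
#' The default palette (\code{\link{defaultPalette}}) carries 6 immune,
#' 7 stromal and 14 epithelial phenotypes (27 in total), the class split
#' used throughout for the CP/TMI/TCI feature taxonomy.
#'
#' @slot phenotypes character vector of phenotype labels.
#' @slot classes named character vector, one of
#'   \code{c("immune","stromal","epithelial")} per phenotype.
#' @exportClass PhenotypePalette
setClass("PhenotypePalette",
  representation(phenotypes = "character", classes = "character"))

setValidity("PhenotypePalette", function(object) {
  msg <- character()
  if (length(object@phenotypes) == 0L)
    msg <- c(msg, "palette must contain at least one phenotype")
  if (anyDuplicated(object@phenotypes))
    msg <- c(msg, "duplicated phenotype labels")
  if (!identical(sort(names(object@classes)), sort(object@phenotypes)))
    msg <- c(msg, "every phenotype must have exactly one class")
  bad <- setdiff(unique(object@classes), c("immune", "stromal", "epithelial"))
  if (length(bad))
    msg <- c(msg, paste0("unknown class(es): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a phenotype palette
#'
#' @param phenotypes character vector of phenotype labels.
#' @param classes character vector (same length or named by phenotype)
#'   assigning each phenotype to \code{immune}, \code{stromal} or
#'   \code{epithelial}.
#' @return A \code{PhenotypePalette}.
#' @examples
#' PhenotypePalette(c("Tcell", "Fibro"), c("immune", "stromal"))
#' @export
PhenotypePalette <- function(phenotypes, classes) {
  if (is.null(names(classes))) names(classes) <- phenotypes
  new("PhenotypePalette", phenotypes = as.character(phenotypes),
      classes = classes[phenotypes])
}

#' @describeIn PhenotypePalette-class phenotype labels.
#' @param x,object a \code{PhenotypePalette}.
#' @aliases phenotypes
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @export
setMethod("phenotypes", "PhenotypePalette", function(x) x@phenotypes)

#' @describeIn PhenotypePalette-class class (compartment) of each phenotype.
#' @aliases phenotypeClass
#' @export
setGeneric("phenotypeClass", function(x) standardGeneric("phenotypeClass"))

#' @export
setMethod("phenotypeClass", "PhenotypePalette", function(x) x@classes)

setMethod("show", "PhenotypePalette", function(object) {
  tab <- table(factor(object@classes,
                      levels = c("immune", "stromal", "epithelial")))
  cat("PhenotypePalette with", length(object@phenotypes), "phenotypes (",
      paste(tab, names(tab), collapse = ", "), ")\n")
})

#' Segmented single-cell image of one patient
#'
#' Holds the segmented cell table of one patient image: cell identifiers,
#' centroid coordinates in micrometres and phenotype labels, together with
#' the total tissue area (used to normalize densities and interaction
#' scores) and the neighborhood radius defining direct cell-cell contact.
#'
#' @slot patientId scalar character.
#' @slot cells data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{phenotype}.
#' @slot areaUm2 total area in square micrometres; \code{NA_real_} means
#'   "fall back to the convex hull of the centroids".
#' @slot neighborRadius direct-neighbor distance threshold in micrometres
#'   (default 4, i.e. 4 pixels at 1 um/pixel).
#' @exportClass PatientImage
setClass("PatientImage",
  representation(patientId = "character", cells = "data.frame",
                 areaUm2 = "numeric", neighborRadius = "numeric"))

setValidity("PatientImage", function(object) {
  msg <- character()
  need <- c("cell_id", "x_um", "y_um", "phenotype")
  if (!all(need %in% names(object@cells)))
    msg <- c(msg, paste("cells must have columns", paste(need, collapse = ", ")))
  else if (nrow(object@cells) > 0 &&
           !all(is.finite(object@cells$x_um) & is.finite(object@cells$y_um)))
    msg <- c(msg, "cell coordinates must be finite")
  if (!is.na(object@areaUm2) && object@areaUm2 <= 0)
    msg <- c(msg, "areaUm2 must be positive")
  if (object@neighborRadius <= 0)
    msg <- c(msg, "neighborRadius must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a PatientImage
#'
#' @param patientId patient identifier.
#' @param cells data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{phenotype}.
#' @param areaUm2 total image area (um^2); \code{NA} to use the convex
#'   hull of the cell centroids.
#' @param neighborRadius neighbor distance threshold in um.
#' @return A \code{PatientImage}.
#' @export
PatientImage <- function(patientId, cells, areaUm2 = NA_real_,
                         neighborRadius = 4) {
  cells$phenotype <- as.character(cells$phenotype)
  cells$cell_id <- as.character(cells$cell_id)
  new("PatientImage", patientId = as.character(patientId), cells = cells,
      areaUm2 = as.numeric(areaUm2), neighborRadius = as.numeric(neighborRadius))
}

#' @describeIn PatientImage-class number of cells.
#' @param object,x a \code{PatientImage}.
#' @aliases nCells
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @export
setMethod("nCells", "PatientImage", function(x) nrow(x@cells))

#' @describeIn PatientImage-class cell table.
#' @aliases cellTable
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @export
setMethod("cellTable", "PatientImage", function(x) x@cells)

#' Effective image area
#'
#' Returns the stored total area, or the convex-hull area of the cell
#' centroids when no area was recorded. The "total area occupied by all
#' the cells" is not operationally pinned down by segmentation output
#' alone, so the hull is the documented fallback.
#'
#' @param x a \code{PatientImage}.
#' @return area in square micrometres.
#' @aliases imageArea
#' @export
setGeneric("imageArea", function(x) standardGeneric("imageArea"))

#' @export
setMethod("imageArea", "PatientImage", function(x) {
  if (!is.na(x@areaUm2)) return(x@areaUm2)
  pts <- cbind(x@cells$x_um, x@cells$y_um)
  if (nrow(pts) < 3) stop("cannot infer area from fewer than 3 cells; supply areaUm2")
  hull <- grDevices::chull(pts)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (a <= 0) stop("degenerate (collinear) cell positions; supply areaUm2")
  a
})

setMethod("show", "PatientImage", function(object) {
  cat("PatientImage", object@patientId, "with", nrow(object@cells), "cells;",
      "radius", object@neighborRadius, "um\n")
})

#' Right-censored survival outcome
#'
#' @slot patientId character vector.
#' @slot time positive follow-up times (months).
#' @slot event 0/1 event indicator (1 = death observed).
#' @exportClass SurvivalOutcome
setClass("SurvivalOutcome",
  representation(patientId = "character", time = "numeric", event = "integer"))

setValidity("SurvivalOutcome", function(object) {
  msg <- character()
  n <- length(object@patientId)
  if (length(object@time) != n || length(object@event) != n)
    msg <- c(msg, "patientId, time and event must have equal length")
  if (any(!is.finite(object@time)) || any(object@time <= 0))
    msg <- c(msg, "times must be positive and finite")
  if (!all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Construct a SurvivalOutcome
#' @param patientId patient identifiers.
#' @param time follow-up times in months.
#' @param event 0/1 (or logical) event indicators.
#' @return A \code{SurvivalOutcome}.
#' @export
SurvivalOutcome <- function(patientId, time, event) {
  new("SurvivalOutcome", patientId = as.character(patientId),
      time = as.numeric(time), event = as.integer(event))
}

#' @describeIn SurvivalOutcome-class follow-up times.
#' @param x,object a \code{SurvivalOutcome}.
#' @aliases survTime
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @export
setMethod("survTime", "SurvivalOutcome", function(x) setNames(x@time, x@patientId))

#' @describeIn SurvivalOutcome-class event indicators.
#' @aliases survEvent
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' @export
setMethod("survEvent", "SurvivalOutcome", function(x) setNames(x@event, x@patientId))

#' @describeIn SurvivalOutcome-class patient identifiers.
#' @aliases patientIds
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @export
setMethod("patientIds", "SurvivalOutcome", function(x) x@patientId)

setMethod("show", "SurvivalOutcome", function(object) {
  cat("SurvivalOutcome:", length(object@time), "patients,",
      sum(object@event), "events, median follow-up",
      round(median(object@time), 1), "months\n")
})

#' Subset a SurvivalOutcome by index or patient id
#' @param x a \code{SurvivalOutcome}.
#' @param i integer, logical or character (patient id) index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SurvivalOutcome", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@patientId)
  SurvivalOutcome(x@patientId[i], x@time[i], x@event[i])
})

#' One-hidden-layer Cox proportional-hazards network
#'
#' A neural Cox model with a single hidden layer: the prognostic index is
#' \eqn{\beta^T \tanh(W x + b)}, fitted by maximizing the Breslow partial
#' log-likelihood with an L2 penalty. The hidden width is
#' \code{\link{hiddenSize}(p)} = ceiling(sqrt(p)).
#'
#' @slot W hidden-by-input weight matrix (h x p).
#' @slot b hidden bias (length h).
#' @slot beta hidden-to-risk coefficients (length h).
#' @slot activation activation tag (currently \code{"tanh"}).
#' @slot l2 L2 penalty weight used in the fit.
#' @slot featureNames input column names (length p).
#' @slot center,scale per-column standardization applied before the net.
#' @slot logLik penalized partial log-likelihood at the optimum.
#' @slot converged logical from the optimizer.
#' @exportClass CoxNet
setClass("CoxNet",
  representation(W = "matrix", b = "numeric", beta = "numeric",
                 activation = "character", l2 = "numeric",
                 featureNames = "character", center = "numeric",
                 scale = "numeric", logLik = "numeric",
                 converged = "logical"))

setValidity("CoxNet", function(object) {
  h <- nrow(object@W); p <- ncol(object@W)
  msg <- character()
  if (length(object@b) != h || length(object@beta) != h)
    msg <- c(msg, "b and beta must have length nrow(W)")
  if (length(object@featureNames) != p)
    msg <- c(msg, "featureNames must have length ncol(W)")
  if (!all(is.finite(object@W)) || !all(is.finite(object@beta)))
    msg <- c(msg, "parameters must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoxNet", function(object) {
  cat("CoxNet:", ncol(object@W), "inputs ->", nrow(object@W),
      "hidden (", object@activation, "), l2 =", object@l2,
      ", logLik =", round(object@logLik, 3), "\n")
})

#' Two-stage Cox network
#'
#' Composite survival model: one \code{CoxNet} per feature set (CP, TMI,
#' TCI) is trained first; their hidden-layer activations are concatenated
#' and a second-stage \code{CoxNet} is trained on the concatenation. The
#' first-stage models are frozen before stage-2 training.
#'
#' @slot stage1 named list of fitted \code{CoxNet} models.
#' @slot stage2 the second-stage \code{CoxNet}.
#' @exportClass TwoStageModel
setClass("TwoStageModel",
  representation(stage1 = "list", stage2 = "CoxNet"))

setValidity("TwoStageModel", function(object) {
  widths <- vapply(object@stage1, function(m) nrow(m@W), integer(1))
  if (ncol(object@stage2@W) != sum(widths))
    return("stage-2 input width must equal the sum of stage-1 hidden widths")
  TRUE
})

setMethod("show", "TwoStageModel", function(object) {
  widths <- vapply(object@stage1, function(m) nrow(m@W), integer(1))
  cat("TwoStageModel: stage-1 hidden widths",
      paste(names(widths), widths, sep = "=", collapse = ", "),
      "-> stage-2 CoxNet on", sum(widths), "inputs\n")
})

#' Consensus NMF subtyping result
#'
#' @slot rank chosen number of subtypes K.
#' @slot labels named integer vector, subtype index 1..K per patient,
#'   1 = best survival after \code{\link{orderBySurvival}}.
#' @slot consensus n x n co-assignment frequency matrix in [0,1].
#' @slot quality data.frame with one row per candidate rank: \code{K},
#'   \code{cophenetic}, \code{silhouette}.
#' @exportClass SubtypeResult
setClass("SubtypeResult",
  representation(rank = "integer", labels = "integer",
                 consensus = "matrix", quality = "data.frame"))

setValidity("SubtypeResult", function(object) {
  msg <- character()
  cm <- object@consensus
  if (nrow(cm) != ncol(cm) || max(abs(cm - t(cm))) > 1e-8)
    msg <- c(msg, "consensus must be symmetric")
  if (any(cm < -1e-8) || any(cm > 1 + 1e-8))
    msg <- c(msg, "consensus entries must lie in [0,1]")
  if (nrow(cm) > 0 && max(abs(diag(cm) - 1)) > 1e-8)
    msg <- c(msg, "consensus diagonal must be 1")
  if (length(object@labels) != nrow(cm))
    msg <- c(msg, "labels must cover all patients")
  if (length(msg)) msg else TRUE
})

#' @describeIn SubtypeResult-class subtype labels (1 = best survival).
#' @param x,object a \code{SubtypeResult}.
#' @aliases subtypeLabels
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' @export
setMethod("subtypeLabels", "SubtypeResult", function(x) x@labels)

#' @describeIn SubtypeResult-class consensus co-assignment matrix.
#' @aliases consensusMatrix
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' @export
setMethod("consensusMatrix", "SubtypeResult", function(x) x@consensus)

setMethod("show", "SubtypeResult", function(object) {
  cat("SubtypeResult: K =", object@rank, "subtypes over",
      length(object@labels), "patients\n")
  print(table(subtype = object@labels))
})

#' Cross-cohort patient matching result
#'
#' @slot pairs data.frame with columns \code{source}, \code{target},
#'   \code{distance} for every retained cross-cohort pair.
#' @slot cutoff similarity quantile used (e.g. 0.995 keeps the 0.5\%
#'   closest cross pairs).
#' @slot cutoffDistance the realized distance threshold.
#' @exportClass MatchResult
setClass("MatchResult",
  representation(pairs = "data.frame", cutoff = "numeric",
                 cutoffDistance = "numeric"))

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult:", nrow(object@pairs), "pairs at similarity cutoff",
      object@cutoff, "(distance <=", signif(object@cutoffDistance, 4), ")\n")
})

#' @describeIn MatchResult-class retained (source, target, distance) pairs.
#' @param x,object a \code{MatchResult}.
#' @aliases matchedPairs
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @export
setMethod("matchedPairs", "MatchResult", function(x) x@pairs)
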