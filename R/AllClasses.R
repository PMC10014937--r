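#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.EXPR_UNITS <- c("FPKM", "TPM", "LOG2TPM")

#' Gene-by-sample expression container with a declared unit
#'
#' `BrainExpression` extends [SummarizedExperiment::SummarizedExperiment]
#' with a single assay (`"exprs"`), a declared abundance unit (one of
#' `"FPKM"`, `"TPM"`, `"LOG2TPM"`, where `LOG2TPM` means `log2(TPM + 1)`)
#' and a per-sample cohort label in `colData(x)$dataset`. Values are
#' finite and nonnegative in every unit; gene symbols (rownames) and
#' sample ids (colnames) are unique.
#'
#' @slot unit character(1), one of `"FPKM"`, `"TPM"`, `"LOG2TPM"`.
#'
#' @seealso [readExpressionMatrix()], [fpkmToTpm()], [log2Transform()],
#'   [intersectAndMerge()]
#' @export
setClass("BrainExpression",
  contains = "SummarizedExperiment",
  slots = c(unit = "character")
)

setValidity("BrainExpression", function(object) {
  msgs <- character()
  if (length(object@unit) != 1L || !object@unit %in% .EXPR_UNITS)
    msgs <- c(msgs, sprintf("unit must be one of %s",
                            paste(.EXPR_UNITS, collapse = ", ")))
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'exprs' is required")
  else {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!all(is.finite(v)))
      msgs <- c(msgs, "expression values must be finite")
    # abundances are nonnegative; log2(TPM+1) is too on construction,
    # but batch-adjusted log values may dip slightly below zero
    else if (object@unit != "LOG2TPM" && any(v < 0))
      msgs <- c(msgs, "expression values must be nonnegative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene symbols (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample ids (colnames) must be present and unique")
  if (!"dataset" %in% colnames(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must contain a 'dataset' column")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BrainExpression object
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param unit abundance unit, one of `"FPKM"`, `"TPM"`, `"LOG2TPM"`.
#' @param dataset cohort label: a single string recycled over samples, or
#'   one label per sample.
#' @return A [BrainExpression-class] object.
#' @examples
#' m <- matrix(c(1, 1, 2, 4, 3, 1), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("S1", "S2")))
#' be <- BrainExpression(m, unit = "FPKM", dataset = "toy")
#' exprUnit(be)
#' @export
BrainExpression <- function(values, unit = c("FPKM", "TPM", "LOG2TPM"),
                            dataset = "cohort") {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(dataset) == 1L) dataset <- rep(dataset, ncol(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(dataset = as.character(dataset),
                                   row.names = colnames(values))
  )
  new("BrainExpression", se, unit = unit)
}

#' @describeIn BrainExpression the expression matrix (genes x samples).
#' @param x,object a `BrainExpression` object.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn BrainExpression the declared unit.
#' @export
exprUnit <- function(x) x@unit

#' @describeIn BrainExpression per-sample cohort labels.
#' @export
sampleDatasets <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$dataset),
                  colnames(x))
}

#' @export
setMethod("show", "BrainExpression", function(object) {
  cat(sprintf("BrainExpression: %d genes x %d samples [unit: %s]\n",
              nrow(object), ncol(object), object@unit))
  ds <- table(SummarizedExperiment::colData(object)$dataset)
  cat("datasets:", paste(sprintf("%s (%d)", names(ds), ds), collapse = ", "),
      "\n")
})

#' Low-dimensional landscape coordinates
#'
#' Per-sample 2-D or 3-D coordinates of the reference landscape together
#' with the seed and hyperparameters that produced them, so an embedding
#' is reproducible from its own record.
#'
#' @slot coords numeric matrix, samples x d (d = 2 or 3), rownames are
#'   sample ids.
#' @slot seed integer seed used for the stochastic optimizer.
#' @slot params list with `n_components`, `n_neighbors`, `min_dist`,
#'   `metric` (see [embedParams()]).
#' @export
setClass("LandscapeEmbedding",
  slots = c(coords = "matrix", seed = "integer", params = "list")
)

setValidity("LandscapeEmbedding", function(object) {
  msgs <- character()
  d <- ncol(object@coords)
  if (!d %in% c(2L, 3L)) msgs <- c(msgs, "coords must have 2 or 3 columns")
  if (!all(is.finite(object@coords))) msgs <- c(msgs, "coords must be finite")
  if (is.null(rownames(object@coords)))
    msgs <- c(msgs, "coords must carry sample ids as rownames")
  if (!is.null(object@params$n_components) &&
      d != object@params$n_components)
    msgs <- c(msgs, "coords dimensionality disagrees with params")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn LandscapeEmbedding coordinates matrix (samples x d).
#' @param x,object a `LandscapeEmbedding`.
#' @export
embeddingCoords <- function(x) x@coords

#' @describeIn LandscapeEmbedding sample ids, in row order.
#' @export
embeddingSamples <- function(x) rownames(x@coords)

#' @export
setMethod("show", "LandscapeEmbedding", function(object) {
  cat(sprintf("LandscapeEmbedding: %d samples in %d-D (seed %d)\n",
              nrow(object@coords), ncol(object@coords), object@seed))
  p <- object@params
  cat(sprintf("params: n_neighbors=%d, min_dist=%g, metric=%s\n",
              p$n_neighbors, p$min_dist, p$metric))
})

#' Kaplan-Meier curve
#'
#' Product-limit survival estimate: distinct observed times in ascending
#' order with the estimated survival probability, at-risk count and event
#' count at each. `S` is non-increasing with `S(0) = 1` implicitly.
#'
#' @slot time ascending observed times (years).
#' @slot surv survival probabilities after each time.
#' @slot nRisk number at risk just before each time.
#' @slot nEvent number of events at each time (0 for censoring-only times).
#' @seealso [kmCurve()], [kmMedian()]
#' @export
setClass("KMCurve",
  slots = c(time = "numeric", surv = "numeric",
            nRisk = "numeric", nEvent = "numeric")
)

setValidity("KMCurve", function(object) {
  msgs <- character()
  n <- length(object@time)
  if (length(object@surv) != n || length(object@nRisk) != n ||
      length(object@nEvent) != n)
    msgs <- c(msgs, "time, surv, nRisk, nEvent must share length")
  if (is.unsorted(object@time)) msgs <- c(msgs, "times must be ascending")
  if (n && (any(object@surv > 1 + 1e-12) || any(object@surv < -1e-12)))
    msgs <- c(msgs, "surv must lie in [0, 1]")
  if (n && is.unsorted(rev(object@surv)))
    msgs <- c(msgs, "surv must be non-increasing")
  if (length(msgs)) msgs else TRUE
})

#' @export
setMethod("show", "KMCurve", function(object) {
  ev <- sum(object@nEvent)
  cat(sprintf("KMCurve: %d time points, %d events, final S = %.3f\n",
              length(object@time), ev,
              if (length(object@surv)) min(object@surv) else 1))
})

#' Pathway-by-sample enrichment scores
#'
#' Single-sample gene-set variation scores bounded in [-1, 1]: a score
#' near 1 means the set's genes rank among the most expressed genes of
#' that sample, a score near -1 among the least expressed.
#'
#' @slot scores numeric matrix, pathways x samples, values in [-1, 1].
#' @seealso [gsvaScores()], [moderatedTTest()]
#' @export
setClass("PathwayScores", slots = c(scores = "matrix"))

setValidity("PathwayScores", function(object) {
  msgs <- character()
  s <- object@scores
  if (!all(is.finite(s))) msgs <- c(msgs, "scores must be finite")
  else if (any(s > 1 + 1e-9) || any(s < -1 - 1e-9))
    msgs <- c(msgs, "scores must lie in [-1, 1]")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msgs <- c(msgs, "scores must carry pathway and sample names")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PathwayScores the score matrix (pathways x samples).
#' @param x,object a `PathwayScores` object.
#' @export
pathwayScores <- function(x) x@scores

#' @export
setMethod("show", "PathwayScores", function(object) {
  cat(sprintf("PathwayScores: %d pathways x %d samples, range [%.3f, %.3f]\n",
              nrow(object@scores), ncol(object@scores),
              min(object@scores), max(object@scores)))
})
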