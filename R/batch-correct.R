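#' Remove cohort batch effects from a log-expression matrix
#'
#' Empirical-Bayes location/scale adjustment (the ComBat model): each
#' gene is standardized, additive (per-batch mean) and multiplicative
#' (per-batch variance) batch effects are estimated and shrunk toward
#' parametric batch-level priors fitted by moments, then removed, and the
#' grand mean and pooled scale are restored. In `mean_only` mode the
#' multiplicative effect is fixed at 1 and only batch means are aligned.
#' The `location_scale_eb` mode is backed by `sva::ComBat` (parametric
#' priors); `mean_only` performs exact per-gene batch-mean centering
#' (no shrinkage), which equalizes per-gene batch means exactly.
#' Degenerate cases are handled around the estimator: a single batch
#' returns the input unchanged, and genes whose variance is zero
#' (overall, or within a batch in `location_scale_eb` mode) pass through
#' unadjusted with a message rather than being dropped. After
#' adjustment each gene is re-centered to its original grand mean, so
#' correction changes within-gene contrasts between batches but never
#' the gene's overall level.
#'
#' @param x a [BrainExpression-class] object, unit `"LOG2TPM"` (batch
#'   correction is performed on the log scale).
#' @param batch batch labels: a vector named by sample id, an unnamed
#'   vector aligned with `colnames(x)`, or a data.frame with columns
#'   `sample_id`, `batch`.
#' @param mode `"location_scale_eb"` (default) or `"mean_only"`.
#' @return A [BrainExpression-class] object, same dimensions, unit and
#'   gene/sample order as the input.
#' @export
combatAdjust <- function(x, batch,
                         mode = c("location_scale_eb", "mean_only")) {
  mode <- match.arg(mode)
  stopifnot(is(x, "BrainExpression"))
  batch <- .resolveBatch(batch, colnames(x))
  v <- exprValues(x)
  if (length(unique(batch)) == 1L) return(x)
  tab <- table(batch)
  if (mode == "location_scale_eb" && any(tab < 2L))
    stop("batch(es) with a single sample in location_scale_eb mode: ",
         paste(names(tab)[tab < 2L], collapse = ", "))

  keep <- .adjustableGenes(v, batch, mode)
  if (!all(keep))
    message(sum(!keep), " zero-variance gene(s) left unadjusted")
  out <- v
  if (any(keep)) {
    sub <- v[keep, , drop = FALSE]
    adj <- if (mode == "mean_only") {
      .meanCenterBatches(sub, batch)
    } else {
      suppressMessages(
        sva::ComBat(dat = sub, batch = batch, mean.only = FALSE,
                    par.prior = TRUE, prior.plots = FALSE))
    }
    # restore each gene's grand mean exactly (EB residuals shift it
    # slightly; downstream contrasts rely on stable per-gene levels)
    adj <- adj - rowMeans(adj) + rowMeans(sub)
    out[keep, ] <- adj
  }
  # adjusted log values may dip slightly below 0 near the zero floor;
  # they are kept as-is (clamping would shift per-gene grand means)
  BrainExpression(out, unit = exprUnit(x), dataset = sampleDatasets(x))
}

# subtract per-gene batch means, add back the per-gene grand mean
.meanCenterBatches <- function(v, batch) {
  out <- v
  gm <- rowMeans(v)
  for (b in unique(batch)) {
    idx <- batch == b
    out[, idx] <- v[, idx, drop = FALSE] -
      rowMeans(v[, idx, drop = FALSE]) + gm
  }
  out
}

.resolveBatch <- function(batch, samples) {
  if (is.data.frame(batch)) {
    stopifnot(all(c("sample_id", "batch") %in% colnames(batch)))
    batch <- stats::setNames(as.character(batch$batch), batch$sample_id)
  }
  if (!is.null(names(batch))) {
    miss <- setdiff(samples, names(batch))
    if (length(miss))
      stop("no batch label for sample(s): ", paste(miss, collapse = ", "))
    batch <- batch[samples]
  } else if (length(batch) != length(samples)) {
    stop("unnamed batch vector must match the number of samples")
  }
  as.character(batch)
}

.adjustableGenes <- function(v, batch, mode) {
  overall <- apply(v, 1L, stats::var) > 0
  if (mode == "mean_only") return(overall)
  within <- rep(TRUE, nrow(v))
  for (b in unique(batch)) {
    vb <- v[, batch == b, drop = FALSE]
    within <- within & (apply(vb, 1L, stats::var) > 0)
  }
  overall & within
}

#' Read a batch design CSV (sample_id, batch)
#'
#' @param path CSV with columns `sample_id` and `batch`.
#' @return named character vector (names = sample ids).
#' @export
readBatchDesign <- function(path) {
  if (!file.exists(path)) stop("batch design file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "batch") %in% colnames(df)))
  stats::setNames(as.character(df$batch), df$sample_id)
}

#' Batch separability as mean silhouette width over principal directions
#'
#' A quality-control statistic for batch correction: samples are
#' projected onto the top principal components of the (gene x sample)
#' matrix and the mean silhouette width of the batch labeling is
#' computed. Values near 0 (or below) mean batches are not separable;
#' values near 1 mean strong batch structure. Correction should drive
#' this down on batch-confounded data.
#'
#' @param x a [BrainExpression-class] object or a numeric genes x samples
#'   matrix.
#' @param batch batch labels (same forms as in [combatAdjust()]).
#' @param nPCs number of principal directions to use (default 10, capped
#'   by the available rank).
#' @return mean silhouette width (numeric scalar).
#' @export
batchSilhouette <- function(x, batch, nPCs = 10L) {
  v <- if (is(x, "BrainExpression")) exprValues(x) else as.matrix(x)
  batch <- .resolveBatch(batch, colnames(v))
  if (length(unique(batch)) < 2L)
    stop("silhouette needs at least two batches")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  k <- min(nPCs, ncol(pc$x))
  sil <- cluster::silhouette(as.integer(factor(batch)),
                             stats::dist(pc$x[, seq_len(k), drop = FALSE]))
  mean(sil[, "sil_width"])
}
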