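#' Embedding hyperparameters
#'
#' Defaults follow the published UMAP defaults: 15 neighbors, minimum
#' distance 0.1, Euclidean metric, 2 output components. The 2-D
#' embedding is the canonical analysis surface (survival annotation,
#' label transfer); 3-D is export-only.
#'
#' @param n_components 2 or 3.
#' @param n_neighbors positive integer, local neighborhood size.
#' @param min_dist minimum embedded distance, in `[0, 1)`.
#' @param metric distance metric name (passed to the optimizer).
#' @return list of validated parameters.
#' @export
embedParams <- function(n_components = 2L, n_neighbors = 15L,
                        min_dist = 0.1, metric = "euclidean") {
  n_components <- as.integer(n_components)
  n_neighbors <- as.integer(n_neighbors)
  min_dist <- as.numeric(min_dist)
  stopifnot(n_components %in% c(2L, 3L), n_neighbors >= 1L,
            min_dist >= 0, min_dist < 1, is.character(metric))
  list(n_components = n_components, n_neighbors = n_neighbors,
       min_dist = min_dist, metric = metric)
}

#' Embed corrected expression into landscape coordinates
#'
#' Runs UMAP (via `uwot`) on the samples of a log2(TPM+1) matrix using
#' all genes as features. The run is deterministic given the input,
#' parameters and seed: single-threaded optimization with the seed set
#' immediately before the call, so the same call yields bit-identical
#' coordinates.
#'
#' @param x a [BrainExpression-class] object (samples become embedding
#'   points; typically unit `"LOG2TPM"` after [combatAdjust()]).
#' @param params hyperparameters from [embedParams()].
#' @param seed integer seed.
#' @return A [LandscapeEmbedding-class] object.
#' @export
embedLandscape <- function(x, params = embedParams(), seed = 1L) {
  stopifnot(is(x, "BrainExpression"))
  v <- exprValues(x)
  if (!all(is.finite(v))) stop("non-finite input")
  n <- ncol(v)
  if (n < params$n_neighbors + 1L)
    stop("need at least n_neighbors + 1 = ", params$n_neighbors + 1L,
         " samples, got ", n)
  seed <- as.integer(seed)
  set.seed(seed)
  coords <- uwot::umap(t(v),
                       n_neighbors = params$n_neighbors,
                       n_components = params$n_components,
                       min_dist = params$min_dist,
                       metric = params$metric,
                       n_threads = 1, n_sgd_threads = 0,
                       verbose = FALSE)
  coords <- matrix(as.numeric(coords), nrow(coords), ncol(coords))
  rownames(coords) <- colnames(v)
  colnames(coords) <- c("x", "y", "z")[seq_len(params$n_components)]
  new("LandscapeEmbedding", coords = coords, seed = seed, params = params)
}

#' Transfer labels to unlabeled samples via embedding neighbors
#'
#' Each unlabeled sample receives the majority label among its `k`
#' nearest labeled samples (Euclidean distance in the embedding). Ties
#' are broken by the label of the single nearest labeled neighbor.
#' Labeled samples keep their labels unchanged. This is the label
#' transfer used to assign, e.g., a medulloblastoma subtype to
#' unclassified samples from where they sit on the landscape.
#'
#' @param e a [LandscapeEmbedding-class].
#' @param labels named character vector mapping a subset of sample ids
#'   to labels; samples absent (or `NA`) are imputed.
#' @param k positive integer, at most the number of labeled samples.
#' @return named character vector: a label for every sample in `e`.
#' @export
knnLabelImpute <- function(e, labels, k = 15L) {
  stopifnot(is(e, "LandscapeEmbedding"))
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("no labeled samples")
  coords <- embeddingCoords(e)
  unknown <- setdiff(rownames(coords), names(labels))
  extra <- setdiff(names(labels), rownames(coords))
  if (length(extra))
    stop("labeled sample(s) absent from embedding: ",
         paste(extra, collapse = ", "))
  k <- as.integer(k)
  if (k < 1L || k > length(labels))
    stop("k must be in [1, number of labeled samples]")
  out <- stats::setNames(rep(NA_character_, nrow(coords)), rownames(coords))
  out[names(labels)] <- unname(labels)
  lab_coords <- coords[names(labels), , drop = FALSE]
  for (s in unknown) {
    d <- sqrt(colSums((t(lab_coords) - coords[s, ])^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    out[s] <- if (length(top) == 1L) top else unname(labels[nn[1L]])
  }
  out
}

#' Write an embedding as CSV plus a JSON sidecar
#'
#' CSV columns `sample_id, x, y[, z]`; the sidecar records the seed and
#' hyperparameters so the embedding can be regenerated.
#'
#' @param e a [LandscapeEmbedding-class].
#' @param path CSV output path; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(e, path) {
  co <- embeddingCoords(e)
  df <- data.frame(sample_id = rownames(co), co, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = e@seed, params = e@params),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an embedding written by [writeEmbedding()]
#'
#' @param path CSV path (sidecar expected at `paste0(path, ".json")`).
#' @return A [LandscapeEmbedding-class].
#' @export
readEmbedding <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  co <- as.matrix(df[, setdiff(colnames(df), "sample_id"), drop = FALSE])
  rownames(co) <- df$sample_id
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else list(seed = NA_integer_, params = embedParams(ncol(co)))
  new("LandscapeEmbedding", coords = co,
      seed = as.integer(meta$seed),
      params = embedParams(meta$params$n_components,
                           meta$params$n_neighbors,
                           meta$params$min_dist, meta$params$metric))
}
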