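#' Read a gene-by-sample expression TSV
#'
#' Expects a tab-separated file whose first column (`gene`) holds gene
#' symbols and whose remaining columns are samples, one header row of
#' sample ids. Duplicate gene symbols are collapsed by keeping the row
#' with the highest mean expression (a message reports how many rows were
#' dropped), the common practice when multiple probes/transcript rows map
#' to one symbol.
#'
#' @param path path to the TSV file.
#' @param unit declared unit of the values (`"FPKM"`, `"TPM"`, `"LOG2TPM"`).
#' @param dataset cohort label attached to every sample.
#' @return A [BrainExpression-class] object.
#' @export
readExpressionMatrix <- function(path, unit = c("FPKM", "TPM", "LOG2TPM"),
                                 dataset = "cohort") {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("zero genes in expression file: ", path)
  if (ncol(df) < 2L) stop("zero samples in expression file: ", path)
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric cell(s) in expression body of ", path)
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  vals <- collapseDuplicateGenes(vals)
  BrainExpression(vals, unit = unit, dataset = dataset)
}

# keep, per duplicated symbol, the row with the highest mean
collapseDuplicateGenes <- function(vals) {
  dup <- duplicated(rownames(vals)) | duplicated(rownames(vals),
                                                 fromLast = TRUE)
  if (!any(dup)) return(vals)
  means <- rowMeans(vals)
  ord <- order(rownames(vals), -means)
  keep <- ord[!duplicated(rownames(vals)[ord])]
  keep <- sort(keep)  # preserve original row order
  message(sum(dup) - length(unique(rownames(vals)[dup])),
          " duplicate gene row(s) collapsed by highest mean")
  vals[keep, , drop = FALSE]
}

#' Write a BrainExpression object as a TSV
#'
#' Inverse of [readExpressionMatrix()]: first column `gene`, one column
#' per sample. Full double precision is retained so a read/write/read
#' round trip reproduces values exactly.
#'
#' @param x a [BrainExpression-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  v <- exprValues(x)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM abundances to TPM
#'
#' Per sample `j`, `TPM_ij = FPKM_ij / sum_i(FPKM_ij) * 1e6`, so every
#' column of the result sums to one million. Within-sample relative
#' abundances are unchanged; only the per-sample scale differs between
#' the two units.
#'
#' @param x a [BrainExpression-class] object with unit `"FPKM"`.
#' @return A [BrainExpression-class] object with unit `"TPM"`.
#' @export
fpkmToTpm <- function(x) {
  stopifnot(is(x, "BrainExpression"))
  if (exprUnit(x) != "FPKM") stop("fpkmToTpm requires unit FPKM, got ",
                                  exprUnit(x))
  v <- exprValues(x)
  cs <- colSums(v)
  bad <- colnames(v)[cs <= 0]
  if (length(bad))
    stop("all-zero sample column(s): ", paste(bad, collapse = ", "))
  tpm <- sweep(v, 2L, cs, "/") * 1e6
  BrainExpression(tpm, unit = "TPM", dataset = sampleDatasets(x))
}

#' Read a protein-coding gene space (one symbol per line)
#'
#' @param path text file, one gene symbol per line.
#' @return character vector of unique symbols.
#' @export
readGeneSpace <- function(path) {
  if (!file.exists(path)) stop("gene-space file not found: ", path)
  sym <- readLines(path)
  sym <- sym[nzchar(trimws(sym))]
  sym <- unique(trimws(sym))
  if (!length(sym)) stop("empty gene space: ", path)
  sym
}

#' Intersect gene spaces and merge cohorts into one matrix
#'
#' Restricts every cohort matrix to the genes shared by all cohorts and
#' by the supplied gene space (typically the protein-coding symbols),
#' then binds samples. The merged gene order is lexicographic so the
#' result does not depend on input order; per-sample cohort labels are
#' carried in `colData(x)$dataset`.
#'
#' @param matrices list of [BrainExpression-class] objects, all unit
#'   `"TPM"`, with globally unique sample ids.
#' @param space character vector of admissible gene symbols (see
#'   [readGeneSpace()]); `NULL` uses the plain intersection.
#' @return A merged [BrainExpression-class] object (unit `"TPM"`).
#' @export
intersectAndMerge <- function(matrices, space = NULL) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, is, logical(1), "BrainExpression")))
  units <- vapply(matrices, exprUnit, character(1))
  if (!all(units == "TPM"))
    stop("all matrices must be TPM; got: ", paste(units, collapse = ", "))
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (!is.null(space)) common <- intersect(common, space)
  if (!length(common)) stop("empty gene intersection")
  common <- sort(common)
  ids <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) across cohorts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- do.call(cbind, lapply(matrices, function(m)
    exprValues(m)[common, , drop = FALSE]))
  ds <- unlist(lapply(matrices, function(m) unname(sampleDatasets(m))))
  BrainExpression(vals, unit = "TPM", dataset = ds)
}

#' Log-transform a TPM matrix
#'
#' Elementwise `log2(TPM + 1)`. The pseudocount keeps zeros at zero and
#' makes the transform defined on the whole nonnegative range; it is
#' strictly increasing, so within-sample gene ranking is preserved.
#'
#' @param x a [BrainExpression-class] object with unit `"TPM"`.
#' @return A [BrainExpression-class] object with unit `"LOG2TPM"`.
#' @export
log2Transform <- function(x) {
  stopifnot(is(x, "BrainExpression"))
  if (exprUnit(x) != "TPM") stop("log2Transform requires unit TPM, got ",
                                 exprUnit(x))
  v <- exprValues(x)
  if (any(v < 0)) stop("negative input value")
  BrainExpression(log2(v + 1), unit = "LOG2TPM",
                  dataset = sampleDatasets(x))
}

.SAMPLE_TYPES <- c("primary", "recurrent", "secondary", "normal")

#' Read per-sample clinical/molecular metadata
#'
#' CSV with columns `sample_id, patient_id, dataset, disease_label,
#' sample_type, age_years, sex, survival_years, event`; empty strings are
#' treated as missing. `event` is coerced to logical, survival times to
#' years (numeric).
#'
#' @param path CSV path.
#' @return data.frame, one row per sample.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validateSampleMetadata(df)
}

#' Validate a sample-metadata table
#'
#' Checks the column contract used throughout the pipeline: unique
#' `sample_id`, known `sample_type` levels, nonnegative ages/survival
#' times, and `survival_years` present wherever `event` is present.
#'
#' @param df data.frame of per-sample metadata.
#' @return the validated (type-coerced) data.frame.
#' @export
validateSampleMetadata <- function(df) {
  need <- c("sample_id", "patient_id", "dataset", "disease_label",
            "sample_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(stats::na.omit(unique(df$sample_type)), .SAMPLE_TYPES)
  if (length(bad)) stop("unknown sample_type value(s): ",
                        paste(bad, collapse = ", "))
  for (col in c("age_years", "survival_years")) {
    if (!col %in% colnames(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE)) stop(col, " must be nonnegative")
  }
  if (!"event" %in% colnames(df)) df$event <- NA
  df$event <- as.logical(df$event)
  if (any(!is.na(df$event) & is.na(df$survival_years)))
    stop("survival_years must be present wherever event is present")
  df
}
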