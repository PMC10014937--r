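#' Read a minimal MAF-like variant TSV
#'
#' Columns `Tumor_Sample_Barcode, Hugo_Symbol, Start_Position,
#' Tumor_Seq_Allele2, Variant_Classification, caller` are mapped to the
#' internal columns `sample_id, gene, position, alt, variant_class,
#' caller`. Already-internal column names are accepted as-is.
#'
#' @param path TSV path.
#' @return data.frame variant table.
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  map <- c(Tumor_Sample_Barcode = "sample_id", Hugo_Symbol = "gene",
           Start_Position = "position", Tumor_Seq_Allele2 = "alt",
           Variant_Classification = "variant_class")
  hit <- colnames(df) %in% names(map)
  colnames(df)[hit] <- map[colnames(df)[hit]]
  stopifnot(all(c("sample_id", "gene") %in% colnames(df)))
  if (!"caller" %in% colnames(df)) df$caller <- "unknown"
  if (any(!nzchar(df$sample_id)) || any(!nzchar(df$gene)))
    stop("empty sample_id or gene in variant table")
  df
}

#' Read a fusion TSV (sample, gene5, gene3, confidence, caller)
#'
#' @param path TSV path; columns `sample_id` (or `sample`),
#'   `gene_5prime`/`gene5`, `gene_3prime`/`gene3`, `confidence`,
#'   `caller`.
#' @return data.frame fusion table.
#' @export
readFusionTable <- function(path) {
  if (!file.exists(path)) stop("fusion file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  map <- c(sample = "sample_id", gene5 = "gene_5prime",
           gene3 = "gene_3prime")
  hit <- colnames(df) %in% names(map)
  colnames(df)[hit] <- map[colnames(df)[hit]]
  need <- c("sample_id", "gene_5prime", "gene_3prime", "confidence")
  stopifnot(all(need %in% colnames(df)))
  if (!"caller" %in% colnames(df)) df$caller <- "unknown"
  bad <- setdiff(unique(df$confidence), c("high", "medium", "low"))
  if (length(bad)) stop("unknown confidence level(s): ",
                        paste(bad, collapse = ", "))
  df
}

#' Read a GISTIC-thresholded gene-level copy-number TSV
#'
#' Gene x sample matrix with integer calls in \{-2, -1, 0, 1, 2\}
#' (deep loss ... high gain); first column holds gene symbols.
#'
#' @param path TSV path.
#' @return integer matrix, genes x samples.
#' @export
readCopyNumberMatrix <- function(path) {
  if (!file.exists(path)) stop("copy-number file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "integer"
  validateCopyNumber(m)
}

#' Validate a copy-number call matrix
#'
#' @param m integer matrix of GISTIC-thresholded calls.
#' @return `m`, invisibly validated.
#' @export
validateCopyNumber <- function(m) {
  if (!all(m %in% -2:2)) stop("copy-number values must be in {-2..2}")
  m
}

#' Merge variant tables from multiple callers
#'
#' Union of records, deduplicated on (sample_id, gene, position, alt)
#' where position/alt are available, otherwise on (sample_id, gene,
#' variant_class). The `caller` field of a merged record becomes the
#' sorted, comma-separated list of supporting callers.
#'
#' @param tables list of variant data.frames (see [readVariantTable()]).
#' @return merged variant data.frame.
#' @export
mergeVariantCallers <- function(tables) {
  stopifnot(length(tables) >= 1L)
  df <- do.call(rbind, lapply(tables, function(tb) {
    for (col in c("position", "alt", "variant_class"))
      if (!col %in% colnames(tb)) tb[[col]] <- NA
    tb[, c("sample_id", "gene", "position", "alt", "variant_class",
           "caller")]
  }))
  if (nrow(df) == 0L) return(df)
  key <- ifelse(!is.na(df$position) & !is.na(df$alt),
                paste(df$sample_id, df$gene, df$position, df$alt,
                      sep = "\r"),
                paste(df$sample_id, df$gene, df$variant_class,
                      sep = "\r"))
  callers <- vapply(split(df$caller, key), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  out <- df[!duplicated(key), , drop = FALSE]
  out$caller <- unname(callers[key[!duplicated(key)]])
  rownames(out) <- NULL
  out
}

#' Point-mutation burden per sample
#'
#' Number of (deduplicated) variant records per sample; samples listed
#' in `samples` but absent from the table count 0.
#'
#' @param v variant data.frame.
#' @param samples character vector of sample ids to report.
#' @return named integer vector over `samples`.
#' @export
mutationBurden <- function(v, samples) {
  counts <- table(factor(v$sample_id, levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' Gene-fusion burden per sample (high-confidence filter)
#'
#' Fusion calls from the Arriba-style caller are first restricted to
#' high confidence (other callers are not confidence-filtered); the
#' burden is the number of remaining calls per sample.
#'
#' @param f fusion data.frame (see [readFusionTable()]).
#' @param samples character vector of sample ids to report.
#' @param filter_caller caller name whose calls are confidence-filtered
#'   (default `"arriba"`, matched case-insensitively).
#' @return named integer vector over `samples`.
#' @export
fusionBurden <- function(f, samples, filter_caller = "arriba") {
  f <- filterHighConfidence(f, filter_caller)
  counts <- table(factor(f$sample_id, levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' @describeIn fusionBurden the filtering step alone: drops non-high
#'   confidence rows of the named caller.
#' @export
filterHighConfidence <- function(f, filter_caller = "arriba") {
  drop <- tolower(f$caller) == tolower(filter_caller) &
    f$confidence != "high"
  f[!drop, , drop = FALSE]
}

#' Copy-number gain/loss counts per sample
#'
#' Per sample: number of genes with a gained call (> 0) and with a lost
#' call (< 0) in the GISTIC-thresholded matrix.
#'
#' @param cn integer genes x samples matrix with values in \{-2..2\}.
#' @return data.frame with columns `sample_id`, `genes_gained`,
#'   `genes_lost`.
#' @export
cnGainLossCounts <- function(cn) {
  validateCopyNumber(cn)
  data.frame(sample_id = colnames(cn),
             genes_gained = as.integer(colSums(cn > 0)),
             genes_lost = as.integer(colSums(cn < 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fusion frequency of a gene per sample group
#'
#' Percentage of samples in each group carrying at least one fusion with
#' the gene as either the 5' or 3' partner (partner-agnostic, matching
#' how "fusions involving" a gene are counted). The table should already
#' be high-confidence filtered (see [filterHighConfidence()]).
#'
#' @param f fusion data.frame.
#' @param groups named character vector: sample id -> group label.
#' @param gene gene symbol to look up.
#' @return named numeric vector of percentages (0-100) per group.
#' @export
fusionFrequencyByGroup <- function(f, groups, gene) {
  if (!length(groups)) stop("empty group assignment")
  carriers <- unique(f$sample_id[f$gene_5prime == gene |
                                   f$gene_3prime == gene])
  out <- vapply(split(names(groups), unname(groups)), function(ss) {
    if (!length(ss)) stop("empty group")
    100 * sum(ss %in% carriers) / length(ss)
  }, numeric(1))
  out
}

#' Single-gene multi-omic panel
#'
#' For one gene, a per-sample record across all expression samples:
#' expression value, whether the sample has a variant in the gene,
#' its copy-number call, and whether it carries a fusion involving the
#' gene. Samples missing from a source default to mutated = FALSE,
#' fused = FALSE, cn_call = 0, with per-source coverage flags recording
#' whether the sample was assayed by that source at all.
#'
#' @param gene gene symbol; must be present in the expression matrix.
#' @param x a [BrainExpression-class] object.
#' @param v variant data.frame (or `NULL`).
#' @param f fusion data.frame, already confidence-filtered (or `NULL`).
#' @param cn copy-number matrix (or `NULL`).
#' @return data.frame with one row per expression sample: `sample_id`,
#'   `expression`, `mutated`, `cn_call`, `fused`, and coverage flags
#'   `covered_variants`, `covered_fusions`, `covered_cn`.
#' @export
genePanel <- function(gene, x, v = NULL, f = NULL, cn = NULL) {
  stopifnot(is(x, "BrainExpression"))
  if (!gene %in% rownames(x))
    stop("gene absent from expression matrix: ", gene)
  samples <- colnames(x)
  mutated <- if (!is.null(v)) samples %in% v$sample_id[v$gene == gene]
             else rep(FALSE, length(samples))
  fused <- if (!is.null(f))
    samples %in% f$sample_id[f$gene_5prime == gene |
                               f$gene_3prime == gene]
    else rep(FALSE, length(samples))
  cn_call <- rep(0L, length(samples))
  if (!is.null(cn) && gene %in% rownames(cn)) {
    hit <- samples %in% colnames(cn)
    cn_call[hit] <- cn[gene, samples[hit]]
  }
  data.frame(sample_id = samples,
             expression = exprValues(x)[gene, ],
             mutated = mutated, cn_call = cn_call, fused = fused,
             covered_variants = if (is.null(v)) FALSE
                                else samples %in% unique(v$sample_id),
             covered_fusions = if (is.null(f)) FALSE
                               else samples %in% unique(f$sample_id),
             covered_cn = if (is.null(cn)) FALSE
                          else samples %in% colnames(cn),
             row.names = NULL, stringsAsFactors = FALSE)
}
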