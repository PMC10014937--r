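#' Restrict survival records to one primary sample per patient
#'
#' Reproduces the inclusion rule used for survival analyses: samples
#' labeled recurrent, secondary or normal tissue are removed, and each
#' patient is represented by exactly one sample. When a patient has
#' several primary samples, the lexicographically smallest sample id is
#' kept (a deterministic tie-break).
#'
#' @param records data.frame of survival records with columns
#'   `sample_id`, `patient_id`, `time_years`, `event`, plus any label
#'   columns (`subtype`, `dataset`).
#' @param meta sample metadata (see [readSampleMetadata()]) supplying
#'   `sample_type` per `sample_id`; records without metadata are
#'   dropped.
#' @return filtered data.frame of records.
#' @export
filterPrimaryUnique <- function(records, meta) {
  stopifnot(all(c("sample_id", "patient_id") %in% colnames(records)))
  type <- stats::setNames(meta$sample_type, meta$sample_id)
  keep <- !is.na(type[records$sample_id]) &
    type[records$sample_id] == "primary"
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$sample_id), , drop = FALSE]
  out <- out[!duplicated(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit curve
#'
#' Standard product-limit estimate over a set of (possibly censored)
#' survival records, computed with `survival::survfit`. Censored times
#' reduce the at-risk count without stepping the curve down.
#'
#' @param records data.frame with numeric `time_years` (nonnegative) and
#'   logical/0-1 `event` (`TRUE` = death observed).
#' @return A [KMCurve-class] object.
#' @export
kmCurve <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time_years", "event") %in% colnames(records)))
  if (nrow(records) == 0L) stop("empty input: no survival records")
  t <- as.numeric(records$time_years)
  ev <- as.integer(as.logical(records$event))
  if (any(is.na(t)) || any(is.na(ev)))
    stop("missing time or event in survival records")
  if (any(t < 0)) stop("time_years must be nonnegative")
  fit <- survival::survfit(survival::Surv(t, ev) ~ 1)
  new("KMCurve", time = as.numeric(fit$time), surv = as.numeric(fit$surv),
      nRisk = as.numeric(fit$n.risk), nEvent = as.numeric(fit$n.event))
}

#' Kaplan-Meier median survival
#'
#' The smallest event time at which the survival estimate drops to 0.5
#' or below. Undefined (returns `NA`) when the curve never reaches 0.5
#' -- e.g. when too few deaths are observed -- which is exactly why the
#' landscape annotation can leave samples uncolored.
#'
#' @param curve a [KMCurve-class] object.
#' @return numeric scalar, or `NA_real_` when the median is undefined.
#' @export
kmMedian <- function(curve) {
  stopifnot(is(curve, "KMCurve"))
  at <- curve@nEvent > 0 & curve@surv <= 0.5 + 1e-12
  if (!any(at)) return(NA_real_)
  min(curve@time[at])
}

#' Parameters of the nearest-neighbor survival annotation
#'
#' @param radius neighborhood radius in embedding units (default 2).
#' @param cohort_fraction fraction of the same-(subtype, dataset) sample
#'   count used as the neighbor cohort size (default 0.25).
#' @param min_cohort minimum cohort size required to annotate a sample
#'   (default 10).
#' @param order whether the radius constraint is applied before taking
#'   the k nearest neighbors (`"radius_then_k"`, default) or the k
#'   nearest are taken first and then restricted to the radius
#'   (`"k_then_radius"`).
#' @return validated parameter list.
#' @export
nnSurvivalParams <- function(radius = 2, cohort_fraction = 0.25,
                             min_cohort = 10L,
                             order = c("radius_then_k", "k_then_radius")) {
  order <- match.arg(order)
  radius <- as.numeric(radius)
  cohort_fraction <- as.numeric(cohort_fraction)
  stopifnot(radius > 0, cohort_fraction > 0, cohort_fraction <= 1,
            min_cohort >= 1)
  list(radius = radius, cohort_fraction = cohort_fraction,
       min_cohort = as.integer(min_cohort), order = order)
}

# round half away from zero (round() rounds half to even)
roundHalfUp <- function(x) floor(x + 0.5)

#' Nearest-neighbor median-survival annotation of the landscape
#'
#' Annotates each sample with the Kaplan-Meier median survival of a
#' local cohort of landscape neighbors: samples of the same subtype and
#' dataset, within a fixed Euclidean radius in the 2-D embedding, the
#' sample itself excluded. The cohort size is `cohort_fraction` of the
#' total number of same-(subtype, dataset) samples (rounded half away
#' from zero); if fewer neighbors qualify inside the radius the smaller
#' cohort is used. A sample is left unannotated (`NA`) when the cohort
#' has fewer than `min_cohort` members or its Kaplan-Meier median is
#' undefined.
#'
#' @param e a [LandscapeEmbedding-class]; only the first two coordinates
#'   are used (the 2-D landscape is the canonical analysis surface).
#' @param records survival records (data.frame with `sample_id`,
#'   `time_years`, `event`, `subtype`, `dataset`), already filtered by
#'   [filterPrimaryUnique()]; every record's sample must be present in
#'   the embedding.
#' @param params parameters from [nnSurvivalParams()].
#' @return data.frame with columns `sample_id`,
#'   `median_survival_years` (`NA` where unannotated), one row per
#'   record.
#' @export
nnSurvivalAnnotate <- function(e, records, params = nnSurvivalParams()) {
  stopifnot(is(e, "LandscapeEmbedding"),
            all(c("sample_id", "time_years", "event", "subtype",
                  "dataset") %in% colnames(records)))
  co <- embeddingCoords(e)[, 1:2, drop = FALSE]
  miss <- setdiff(records$sample_id, rownames(co))
  if (length(miss))
    stop("record sample(s) missing from embedding: ",
         paste(miss, collapse = ", "))
  ann <- rep(NA_real_, nrow(records))
  grp <- interaction(records$subtype, records$dataset, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    n_gd <- length(idx)
    k <- roundHalfUp(params$cohort_fraction * n_gd)
    if (k < 1L) next
    pts <- co[records$sample_id[idx], , drop = FALSE]
    dm <- as.matrix(stats::dist(pts))
    for (i in seq_len(n_gd)) {
      d <- dm[i, -i]
      others <- idx[-i]
      if (params$order == "radius_then_k") {
        inr <- d <= params$radius
        cand <- others[inr][order(d[inr])]
        cohort <- cand[seq_len(min(k, length(cand)))]
      } else {
        nearest <- others[order(d)][seq_len(min(k, length(others)))]
        dn <- sort(d)[seq_len(min(k, length(others)))]
        cohort <- nearest[dn <= params$radius]
      }
      if (length(cohort) < params$min_cohort) next
      med <- kmMedian(kmCurve(records[cohort, , drop = FALSE]))
      if (!is.na(med)) ann[idx[i]] <- med
    }
  }
  data.frame(sample_id = records$sample_id,
             median_survival_years = ann, stringsAsFactors = FALSE)
}

#' Build survival records from metadata and subtype calls
#'
#' Joins per-sample survival fields from the metadata table with the
#' subtype (for classified tumor samples) or the disease label (for all
#' other samples), producing the record table consumed by [kmCurve()]
#' and [nnSurvivalAnnotate()]. Samples without both a survival time and
#' an event indicator are dropped.
#'
#' @param meta sample metadata (see [readSampleMetadata()]).
#' @param subtypeCalls optional data.frame from [classifyWhoCns5()]
#'   (`sample_id`, `subtype`); where present and not `UNCLASSIFIED`, the
#'   subtype is used as the record's group label.
#' @return data.frame of survival records.
#' @export
makeSurvivalRecords <- function(meta, subtypeCalls = NULL) {
  keep <- !is.na(meta$survival_years) & !is.na(meta$event)
  df <- meta[keep, , drop = FALSE]
  label <- df$disease_label
  if (!is.null(subtypeCalls)) {
    st <- stats::setNames(as.character(subtypeCalls$subtype),
                          subtypeCalls$sample_id)
    hit <- df$sample_id %in% names(st) &
      st[df$sample_id] != "UNCLASSIFIED"
    label[hit] <- st[df$sample_id[hit]]
  }
  data.frame(sample_id = df$sample_id, patient_id = df$patient_id,
             time_years = df$survival_years, event = df$event,
             subtype = label, dataset = df$dataset,
             stringsAsFactors = FALSE)
}
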