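.GLIOMA_SUBTYPES <- c("OLIGODENDROGLIOMA_IDH_MUT_CODEL",
                      "ASTROCYTOMA_IDH_MUT",
                      "GLIOBLASTOMA_IDH_WT",
                      "UNCLASSIFIED")

#' WHO-CNS5 rule-based classification of adult diffuse gliomas
#'
#' Classifies each sample from its molecular marker calls using the
#' WHO-CNS5 decision rule driven by IDH status (IDH1/IDH2 combined) and
#' 1p/19q codeletion:
#' \itemize{
#'   \item IDH mutant + 1p/19q codeleted: oligodendroglioma
#'     (`OLIGODENDROGLIOMA_IDH_MUT_CODEL`)
#'   \item IDH mutant + 1p/19q intact: IDH-mutant astrocytoma
#'     (`ASTROCYTOMA_IDH_MUT`)
#'   \item IDH wildtype: IDH-wildtype glioblastoma
#'     (`GLIOBLASTOMA_IDH_WT`), regardless of 1p/19q or grade
#'   \item anything else (IDH unknown, or IDH mutant with unknown
#'     1p/19q): `UNCLASSIFIED` -- missing primary markers are never
#'     imputed.
#' }
#' TP53/ATRX mutation and chromosome 7 gain / 10 loss are corroborating
#' annotations of the subtypes (astrocytomas typically TP53/ATRX mutant,
#' IDH-wt glioblastomas typically +7/-10); they never override the
#' IDH/1p19q rule. A `flag` column marks IDH-wildtype tumors recorded
#' with grade below 4, which are still grouped with glioblastoma
#' transcriptionally.
#'
#' @param markers data.frame with columns `idh_status`
#'   (`"mutant"|"wildtype"|"unknown"`), `codel_1p19q`
#'   (`"codel"|"intact"|"unknown"`) and optionally `sample_id`,
#'   `tp53_mut`, `atrx_mut`, `chr7_gain`, `chr10_loss`, `grade`.
#'   Missing optional columns are tolerated; `NA` is treated as unknown.
#' @return data.frame with columns `sample_id`, `subtype` (factor with
#'   the four levels above) and `flag` (character, `""` or
#'   `"idh_wt_grade_lt_4"`).
#' @export
classifyWhoCns5 <- function(markers) {
  stopifnot(is.data.frame(markers),
            all(c("idh_status", "codel_1p19q") %in% colnames(markers)))
  idh <- as.character(markers$idh_status)
  codel <- as.character(markers$codel_1p19q)
  idh[is.na(idh)] <- "unknown"
  codel[is.na(codel)] <- "unknown"
  bad <- setdiff(unique(idh), c("mutant", "wildtype", "unknown"))
  if (length(bad)) stop("unknown idh_status value(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(codel), c("codel", "intact", "unknown"))
  if (length(bad)) stop("unknown codel_1p19q value(s): ",
                        paste(bad, collapse = ", "))

  subtype <- rep("UNCLASSIFIED", nrow(markers))
  subtype[idh == "wildtype"] <- "GLIOBLASTOMA_IDH_WT"
  subtype[idh == "mutant" & codel == "codel"] <-
    "OLIGODENDROGLIOMA_IDH_MUT_CODEL"
  subtype[idh == "mutant" & codel == "intact"] <- "ASTROCYTOMA_IDH_MUT"

  grade <- if ("grade" %in% colnames(markers))
    suppressWarnings(as.integer(markers$grade)) else rep(NA_integer_,
                                                         nrow(markers))
  flag <- ifelse(subtype == "GLIOBLASTOMA_IDH_WT" & !is.na(grade) &
                   grade < 4L, "idh_wt_grade_lt_4", "")
  ids <- if ("sample_id" %in% colnames(markers))
    as.character(markers$sample_id) else as.character(seq_len(nrow(markers)))
  data.frame(sample_id = ids,
             subtype = factor(subtype, levels = .GLIOMA_SUBTYPES),
             flag = flag, stringsAsFactors = FALSE)
}

#' Read a molecular-marker CSV
#'
#' Columns: `sample_id, idh_status, codel_1p19q, tp53_mut, atrx_mut,
#' chr7_gain, chr10_loss, grade` (logical columns as true/false, empty =
#' missing).
#'
#' @param path CSV path.
#' @return data.frame of marker calls.
#' @export
readMarkers <- function(path) {
  if (!file.exists(path)) stop("markers file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  stopifnot(all(c("sample_id", "idh_status", "codel_1p19q") %in%
                  colnames(df)))
  for (col in c("tp53_mut", "atrx_mut", "chr7_gain", "chr10_loss"))
    if (col %in% colnames(df)) df[[col]] <- as.logical(df[[col]])
  df
}
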