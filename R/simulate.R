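.DRIVER_GENES <- c("IDH1", "TP53", "ATRX", "EGFR", "PTEN", "CIC",
                   "BRAF", "KIAA1549", "PSPHP1", "RELA", "C11orf95",
                   "NF2", "YAP1")

#' Specify a sample group for the simulator
#'
#' A group is a disease entity (or normal-brain region) with its own
#' expression shift profile, subtype markers, survival distribution and
#' omics rates.
#'
#' @param label group label (used as disease label in metadata).
#' @param n_samples number of samples.
#' @param kind `"tumor_adult"`, `"tumor_pediatric"` or `"normal"`.
#' @param subtype for adult tumors, the true WHO-CNS5 subtype label
#'   (`NA` otherwise).
#' @param shift log2 expression up-shift applied to this group's gene
#'   block (default 2).
#' @param frac_shifted fraction of genes in the group's block
#'   (default 0.05).
#' @param median_survival true median survival in years (`NA` for no
#'   survival records).
#' @param censor_frac fraction of censored survival records, in
#'   `[0, 1)`.
#' @param mutation_rate mean somatic variants per sample (Poisson).
#' @param fusions list of recurrent fusions, each
#'   `list(gene5 =, gene3 =, rate =)`.
#' @param cn_gain,cn_loss driver genes whose copy-number block is gained
#'   / lost in ~90% of the group's samples.
#' @return group spec list.
#' @export
simGroup <- function(label, n_samples, kind = "tumor_adult",
                     subtype = NA_character_, shift = 2,
                     frac_shifted = 0.05, median_survival = NA_real_,
                     censor_frac = 0.3, mutation_rate = 20,
                     fusions = list(), cn_gain = character(),
                     cn_loss = character()) {
  stopifnot(n_samples >= 1, kind %in% c("tumor_adult", "tumor_pediatric",
                                        "normal"),
            censor_frac >= 0, censor_frac < 1, mutation_rate >= 0)
  list(label = label, n_samples = as.integer(n_samples), kind = kind,
       subtype = subtype, shift = shift, frac_shifted = frac_shifted,
       median_survival = median_survival, censor_frac = censor_frac,
       mutation_rate = mutation_rate, fusions = fusions,
       cn_gain = cn_gain, cn_loss = cn_loss)
}

.defaultGroups <- function() list(
  simGroup("glioblastoma", 120, "tumor_adult", "GLIOBLASTOMA_IDH_WT",
           median_survival = 1.2, mutation_rate = 40,
           fusions = list(list(gene5 = "EGFR", gene3 = "PSPHP1",
                               rate = 0.18)),
           cn_gain = "EGFR", cn_loss = "PTEN"),
  simGroup("astrocytoma", 80, "tumor_adult", "ASTROCYTOMA_IDH_MUT",
           median_survival = 6, mutation_rate = 25),
  simGroup("oligodendroglioma", 60, "tumor_adult",
           "OLIGODENDROGLIOMA_IDH_MUT_CODEL",
           median_survival = 12, mutation_rate = 20,
           cn_loss = "CIC"),
  simGroup("pediatric_lgg", 80, "tumor_pediatric",
           mutation_rate = 10,
           fusions = list(list(gene5 = "KIAA1549", gene3 = "BRAF",
                               rate = 0.32))),
  simGroup("medulloblastoma", 80, "tumor_pediatric",
           mutation_rate = 15),
  simGroup("normal_brain", 160, "normal", mutation_rate = 0)
)

#' Simulation configuration
#'
#' Defines the multi-cohort study the generator emulates: group
#' structure with subtype-specific expression, markers, survival and
#' omics, plus cohort-level batch effects in the ComBat form (additive
#' shift gamma, multiplicative noise scale delta on the log2 scale).
#' The defaults describe a scaled-down brain-tumor landscape: three
#' adult diffuse-glioma subtypes, two pediatric tumor groups and normal
#' brain, split over two cohorts processed by different pipelines.
#'
#' @param n_genes number of genes (driver symbols are placed first,
#'   synthetic symbols fill the rest).
#' @param groups list of [simGroup()] specs.
#' @param cohorts list of cohort specs `list(label =, gamma =, delta =,
#'   prob =)`; `prob` is each sample's chance of being assigned to the
#'   cohort (normalized internally).
#' @param noise_sd within-group log2 expression noise sd (default 1).
#' @param marker_noise probability a primary marker call (IDH, 1p/19q)
#'   is flipped (default 0: markers match truth exactly).
#' @param dup_patient_frac fraction of tumor patients given an extra
#'   recurrent sample (exercises the primary/unique filter).
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @return config list.
#' @export
simConfig <- function(n_genes = 1000L, groups = .defaultGroups(),
                      cohorts = list(
                        list(label = "recount", gamma = 0, delta = 1,
                             prob = 0.5),
                        list(label = "cbtn", gamma = 1, delta = 1.3,
                             prob = 0.5)),
                      noise_sd = 1, marker_noise = 0,
                      dup_patient_frac = 0.05, seed = 1L) {
  stopifnot(n_genes >= length(.DRIVER_GENES) + 10L,
            length(groups) >= 1L, length(cohorts) >= 1L, noise_sd > 0,
            marker_noise >= 0, marker_noise <= 1)
  for (co in cohorts) stopifnot(co$delta > 0, co$prob > 0)
  list(n_genes = as.integer(n_genes), groups = groups,
       cohorts = cohorts, noise_sd = noise_sd,
       marker_noise = marker_noise,
       dup_patient_frac = dup_patient_frac, seed = as.integer(seed))
}

#' Simulate a multi-cohort bundle with known ground truth
#'
#' Generates, from one seed, everything the pipeline consumes: FPKM
#' expression matrices per cohort, sample metadata, molecular markers,
#' survival records, variant/fusion/copy-number tables, and the truth
#' labels. Log2-scale expression is `gene mean + group shift + cohort
#' gamma + delta * N(0, noise_sd)`, exponentiated to FPKM-like
#' positives. Survival is exponential with the group's configured
#' median; censored records have their time truncated uniformly.
#' With `marker_noise = 0`, [classifyWhoCns5()] on the marker table
#' recovers the true subtype of every adult tumor sample.
#'
#' @param cfg a config from [simConfig()].
#' @return a list of class `brainscapeBundle` with elements
#'   `expression` (list of [BrainExpression-class], FPKM, one per
#'   cohort), `metadata`, `markers`, `survival`, `variants`, `fusions`,
#'   `copynumber`, `batch` (named vector) and `truth` (group, subtype,
#'   cohort per sample plus the config).
#' @export
simulateCohort <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  p <- cfg$n_genes
  genes <- c(.DRIVER_GENES,
             sprintf("G%05d", seq_len(p - length(.DRIVER_GENES))))
  mu <- stats::runif(p, 2, 8)
  names(mu) <- genes

  # non-overlapping up-shifted gene blocks per group (drivers excluded)
  free <- setdiff(seq_len(p), seq_along(.DRIVER_GENES))
  blocks <- list()
  cursor <- 1L
  for (g in cfg$groups) {
    nb <- max(1L, round(g$frac_shifted * p))
    if (cursor + nb - 1L > length(free))
      stop("too many shifted genes for n_genes")
    blocks[[g$label]] <- free[cursor:(cursor + nb - 1L)]
    cursor <- cursor + nb
  }

  cohort_labels <- vapply(cfg$cohorts, `[[`, character(1), "label")
  cohort_prob <- vapply(cfg$cohorts, `[[`, numeric(1), "prob")
  cohort_prob <- cohort_prob / sum(cohort_prob)
  gamma <- stats::setNames(vapply(cfg$cohorts, `[[`, numeric(1),
                                  "gamma"), cohort_labels)
  delta <- stats::setNames(vapply(cfg$cohorts, `[[`, numeric(1),
                                  "delta"), cohort_labels)

  meta <- list(); markers <- list(); surv <- list()
  variants <- list(); fusions <- list()
  expr_cols <- list(); cn_cols <- list()
  truth_group <- character(); truth_subtype <- character()
  batch <- character()

  for (g in cfg$groups) {
    for (i in seq_len(g$n_samples)) {
      sid <- sprintf("%s_S%03d", toupper(g$label), i)
      pid <- sprintf("%s_P%03d", toupper(g$label), i)
      co <- sample(cohort_labels, 1L, prob = cohort_prob)
      batch[sid] <- co
      truth_group[sid] <- g$label
      is_tumor <- g$kind != "normal"

      logx <- mu + gamma[co] + delta[co] * stats::rnorm(p, 0,
                                                        cfg$noise_sd)
      logx[blocks[[g$label]]] <- logx[blocks[[g$label]]] + g$shift
      expr_cols[[sid]] <- 2^logx

      age <- switch(g$kind,
                    tumor_adult = stats::rnorm(1, 55, 12),
                    tumor_pediatric = stats::rnorm(1, 8, 4),
                    normal = stats::rnorm(1, 50, 15))
      st <- if (g$kind == "normal") "normal" else "primary"
      tm <- ev <- NA
      if (!is.na(g$median_survival)) {
        lam <- log(2) / g$median_survival
        tt <- stats::rexp(1, rate = lam)
        if (g$censor_frac > 0) {
          # independent uniform censoring C ~ U(0, u), u chosen so that
          # P(C < T) equals censor_frac (keeps the KM estimate unbiased)
          u <- .uniformCensorBound(lam, g$censor_frac)
          cc <- stats::runif(1, 0, u)
          ev <- tt <= cc
          tm <- min(tt, cc)
        } else {
          ev <- TRUE
          tm <- tt
        }
      }
      meta[[sid]] <- data.frame(
        sample_id = sid, patient_id = pid, dataset = co,
        disease_label = g$label, sample_type = st,
        age_years = max(0, round(age, 1)),
        sex = sample(c("male", "female"), 1L),
        survival_years = if (is.na(tm)) NA_real_ else round(tm, 4),
        event = ev, stringsAsFactors = FALSE)

      if (g$kind == "tumor_adult" && !is.na(g$subtype)) {
        truth_subtype[sid] <- g$subtype
        markers[[sid]] <- .drawMarkers(sid, g$subtype,
                                       cfg$marker_noise)
      }
      if (!is.na(g$median_survival))
        surv[[sid]] <- data.frame(
          sample_id = sid, patient_id = pid, time_years = round(tm, 4),
          event = ev,
          subtype = if (!is.na(g$subtype)) g$subtype else g$label,
          dataset = co, stringsAsFactors = FALSE)

      if (is_tumor) {
        variants[[sid]] <- .drawVariants(sid, g, genes)
        fusions[[sid]] <- .drawFusions(sid, g, genes)
        cn_cols[[sid]] <- .drawCopyNumber(g, genes)
      }
    }
  }

  # a few recurrent duplicate samples per tumor patient
  meta_df <- do.call(rbind, meta)
  tum <- meta_df$sample_id[meta_df$sample_type == "primary"]
  ndup <- round(cfg$dup_patient_frac * length(tum))
  if (ndup > 0) {
    for (sid in sample(tum, ndup)) {
      rid <- paste0(sid, "R")
      row <- meta_df[meta_df$sample_id == sid, ]
      row$sample_id <- rid
      row$sample_type <- "recurrent"
      meta_df <- rbind(meta_df, row)
      co <- batch[sid]
      batch[rid] <- co
      truth_group[rid] <- truth_group[sid]
      g <- cfg$groups[[which(vapply(cfg$groups, `[[`, character(1),
                                    "label") ==
                               row$disease_label)]]
      logx <- mu + gamma[co] + delta[co] * stats::rnorm(p, 0,
                                                        cfg$noise_sd)
      logx[blocks[[g$label]]] <- logx[blocks[[g$label]]] + g$shift
      expr_cols[[rid]] <- 2^logx
      if (!is.na(row$survival_years))
        surv[[rid]] <- data.frame(
          sample_id = rid, patient_id = row$patient_id,
          time_years = row$survival_years, event = row$event,
          subtype = if (!is.na(g$subtype)) g$subtype else g$label,
          dataset = co, stringsAsFactors = FALSE)
    }
  }
  rownames(meta_df) <- NULL

  used <- cohort_labels[cohort_labels %in% batch]
  exprs <- lapply(used, function(co) {
    ids <- names(batch)[batch == co]
    m <- do.call(cbind, expr_cols[ids])
    rownames(m) <- genes
    colnames(m) <- ids
    BrainExpression(m, unit = "FPKM", dataset = co)
  })
  names(exprs) <- used

  cn <- if (length(cn_cols)) {
    m <- do.call(cbind, cn_cols)
    rownames(m) <- genes
    colnames(m) <- names(cn_cols)
    storage.mode(m) <- "integer"
    m
  } else NULL

  bundle <- list(
    expression = exprs,
    metadata = validateSampleMetadata(meta_df),
    markers = if (length(markers)) do.call(rbind, markers) else NULL,
    survival = if (length(surv)) do.call(rbind, surv) else NULL,
    variants = do.call(rbind, variants),
    fusions = do.call(rbind, fusions),
    copynumber = cn,
    batch = batch,
    truth = list(group = truth_group, subtype = truth_subtype,
                 cohort = batch, config = cfg))
  for (nm in c("markers", "survival", "variants", "fusions"))
    if (!is.null(bundle[[nm]])) rownames(bundle[[nm]]) <- NULL
  class(bundle) <- "brainscapeBundle"
  bundle
}

# upper bound u of U(0, u) censoring s.t. P(C < T) = frac for
# T ~ exp(lam): P(C < T) = (1 - exp(-lam u)) / (lam u)
.uniformCensorBound <- function(lam, frac) {
  f <- function(u) (1 - exp(-lam * u)) / (lam * u) - frac
  stats::uniroot(f, interval = c(1e-8 / lam, 1e6 / lam),
                 tol = 1e-10)$root
}

.drawMarkers <- function(sid, subtype, noise) {
  idh <- switch(subtype,
                GLIOBLASTOMA_IDH_WT = "wildtype",
                ASTROCYTOMA_IDH_MUT = ,
                OLIGODENDROGLIOMA_IDH_MUT_CODEL = "mutant")
  codel <- if (subtype == "OLIGODENDROGLIOMA_IDH_MUT_CODEL") "codel"
           else "intact"
  if (noise > 0) {
    if (stats::runif(1) < noise)
      idh <- sample(c("mutant", "wildtype", "unknown"), 1L)
    if (stats::runif(1) < noise)
      codel <- sample(c("codel", "intact", "unknown"), 1L)
  }
  is_astro <- subtype == "ASTROCYTOMA_IDH_MUT"
  is_gbm <- subtype == "GLIOBLASTOMA_IDH_WT"
  data.frame(
    sample_id = sid, idh_status = idh, codel_1p19q = codel,
    tp53_mut = stats::runif(1) < if (is_astro) 0.9 else 0.2,
    atrx_mut = stats::runif(1) < if (is_astro) 0.85 else 0.1,
    chr7_gain = stats::runif(1) < if (is_gbm) 0.9 else 0.1,
    chr10_loss = stats::runif(1) < if (is_gbm) 0.9 else 0.1,
    grade = switch(subtype,
                   GLIOBLASTOMA_IDH_WT = 4L,
                   ASTROCYTOMA_IDH_MUT = sample(2:4, 1L),
                   OLIGODENDROGLIOMA_IDH_MUT_CODEL = sample(2:3, 1L)),
    stringsAsFactors = FALSE)
}

.drawVariants <- function(sid, g, genes) {
  n <- stats::rpois(1, g$mutation_rate)
  drivers <- switch(g$subtype %||% "none",
    GLIOBLASTOMA_IDH_WT = c("EGFR", "PTEN"),
    ASTROCYTOMA_IDH_MUT = c("IDH1", "TP53", "ATRX"),
    OLIGODENDROGLIOMA_IDH_MUT_CODEL = c("IDH1", "CIC"),
    character())
  drivers <- drivers[stats::runif(length(drivers)) < 0.8]
  gn <- c(drivers, if (n > 0) sample(genes, n, replace = TRUE))
  if (!length(gn)) return(NULL)
  data.frame(
    sample_id = sid, gene = gn,
    position = sample.int(1e8, length(gn), replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), length(gn), replace = TRUE),
    variant_class = "Missense_Mutation",
    caller = sample(c("mutect2", "varscan2"), length(gn),
                    replace = TRUE),
    stringsAsFactors = FALSE)
}

.drawFusions <- function(sid, g, genes) {
  rows <- list()
  for (fu in g$fusions) {
    if (stats::runif(1) < fu$rate)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, gene_5prime = fu$gene5,
        gene_3prime = fu$gene3, confidence = "high",
        caller = "arriba", stringsAsFactors = FALSE)
  }
  nbg <- stats::rpois(1, 0.3)
  if (nbg > 0) {
    gn <- matrix(sample(genes, 2 * nbg, replace = TRUE), ncol = 2)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, gene_5prime = gn[, 1], gene_3prime = gn[, 2],
      confidence = sample(c("high", "medium", "low"), nbg,
                          replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      caller = "arriba", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

.drawCopyNumber <- function(g, genes) {
  cn <- integer(length(genes))
  names(cn) <- genes
  noise_idx <- stats::runif(length(genes)) < 0.01
  cn[noise_idx] <- sample(c(-1L, 1L), sum(noise_idx), replace = TRUE)
  for (gg in g$cn_gain)
    if (stats::runif(1) < 0.9) cn[gg] <- sample(1:2, 1L, prob = c(.7, .3))
  for (gg in g$cn_loss)
    if (stats::runif(1) < 0.9) cn[gg] <- sample(-(1:2), 1L,
                                                prob = c(.7, .3))
  cn
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @export
print.brainscapeBundle <- function(x, ...) {
  n <- length(x$batch)
  cat(sprintf("brainscapeBundle: %d samples, %d genes, %d cohort(s)\n",
              n, nrow(exprValues(x$expression[[1L]])),
              length(x$expression)))
  cat("groups:", paste(sort(unique(x$truth$group)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a simulated bundle to disk in pipeline input formats
#'
#' Produces exactly the files [runPipeline()] reads: one expression TSV
#' per cohort, `metadata.csv`, `markers.csv`, `batch.csv`,
#' `variants.tsv`, `fusions.tsv`, `copynumber.tsv`, `gene_space.txt`,
#' and `truth.json` with the generator's ground-truth labels.
#'
#' @param bundle a `brainscapeBundle` from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (co in names(bundle$expression)) {
    pth <- file.path(dir, sprintf("expression_%s.tsv", co))
    writeExpressionMatrix(bundle$expression[[co]], pth)
    paths[paste0("expression_", co)] <- pth
  }
  utils::write.csv(bundle$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  paths["metadata"] <- file.path(dir, "metadata.csv")
  if (!is.null(bundle$markers)) {
    utils::write.csv(bundle$markers, file.path(dir, "markers.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    paths["markers"] <- file.path(dir, "markers.csv")
  }
  utils::write.csv(
    data.frame(sample_id = names(bundle$batch),
               batch = unname(bundle$batch)),
    file.path(dir, "batch.csv"), row.names = FALSE, quote = FALSE)
  paths["batch"] <- file.path(dir, "batch.csv")
  for (nm in c("variants", "fusions")) {
    if (is.null(bundle[[nm]])) next
    pth <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(bundle[[nm]], pth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[nm] <- pth
  }
  if (!is.null(bundle$copynumber)) {
    pth <- file.path(dir, "copynumber.tsv")
    df <- data.frame(gene = rownames(bundle$copynumber),
                     bundle$copynumber, check.names = FALSE)
    utils::write.table(df, pth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["copynumber"] <- pth
  }
  writeLines(rownames(exprValues(bundle$expression[[1L]])),
             file.path(dir, "gene_space.txt"))
  paths["gene_space"] <- file.path(dir, "gene_space.txt")
  jsonlite::write_json(bundle$truth[c("group", "subtype", "cohort")],
                       file.path(dir, "truth.json"), auto_unbox = FALSE)
  paths["truth"] <- file.path(dir, "truth.json")
  invisible(paths)
}
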