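# Fixture builders and independent oracles shared across tests.
# Oracles are deliberately written as plain loops, separate from the
# package implementations they check.

writeToyExpressionTsv <- function(path, genes, samples, values) {
  df <- data.frame(gene = genes,
                   matrix(values, nrow = length(genes),
                          dimnames = list(NULL, samples)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toyFusionTable <- function() {
  data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S3", "S3"),
    gene_5prime = c("EGFR", "EGFR", "NF2", "KIAA1549", "EGFR", "A1"),
    gene_3prime = c("PSPHP1", "SEPT14", "YAP1", "BRAF", "VOPP1", "B1"),
    confidence = c("high", "high", "low", "high", "medium", "high"),
    caller = c("arriba", "arriba", "arriba", "arriba", "arriba",
               "starfusion"),
    stringsAsFactors = FALSE)
}

toyVariantTable <- function(caller = "mutect2") {
  data.frame(
    sample_id = c("S1", "S1", "S1", "S2"),
    gene = c("TP53", "EGFR", "PTEN", "IDH1"),
    position = c(7577120L, 55249071L, 89692905L, 208248389L),
    alt = c("T", "A", "G", "A"),
    variant_class = "Missense_Mutation",
    caller = caller,
    stringsAsFactors = FALSE)
}

# independent product-limit estimator: plain loop over sorted times,
# events at a time precede censorings at the same time
handKM <- function(time, event) {
  ord <- order(time, -as.integer(event))
  time <- time[ord]; event <- as.logical(event[ord])
  at_risk <- length(time)
  s <- 1
  out_t <- numeric(0); out_s <- numeric(0)
  for (tt in unique(time)) {
    d <- sum(time == tt & event)
    c <- sum(time == tt & !event)
    if (d > 0) {
      s <- s * (1 - d / at_risk)
      out_t <- c(out_t, tt); out_s <- c(out_s, s)
    }
    at_risk <- at_risk - d - c
  }
  list(time = out_t, surv = out_s)
}

handKMMedian <- function(time, event) {
  km <- handKM(time, event)
  hit <- km$surv <= 0.5 + 1e-12
  if (!any(hit)) NA_real_ else min(km$time[hit])
}

# brute-force NN survival annotation: full distance matrix, explicit
# constraint filtering, hand product-limit median
oracleNNAnnotate <- function(coords, rec, radius = 2, frac = 0.25,
                             minc = 10) {
  out <- rep(NA_real_, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    same <- which(rec$subtype == rec$subtype[i] &
                    rec$dataset == rec$dataset[i])
    k <- floor(frac * length(same) + 0.5)
    cand <- setdiff(same, i)
    if (!length(cand) || k < 1) next
    ci <- coords[rec$sample_id[i], 1:2]
    d <- apply(coords[rec$sample_id[cand], 1:2, drop = FALSE], 1,
               function(r) sqrt(sum((r - ci)^2)))
    keep <- d <= radius
    cand <- cand[keep][order(d[keep])]
    cohort <- cand[seq_len(min(k, length(cand)))]
    if (length(cohort) < minc) next
    out[i] <- handKMMedian(rec$time_years[cohort], rec$event[cohort])
  }
  out
}

# random synthetic landscape + survival records for oracle comparisons
randomSurvivalLandscape <- function(seed, n_per_group = 60,
                                    groups = c("GBM", "ASTRO"),
                                    datasets = c("tcga", "cgga")) {
  set.seed(seed)
  rec <- expand.grid(subtype = groups, dataset = datasets,
                     stringsAsFactors = FALSE)
  rec <- rec[rep(seq_len(nrow(rec)), each = n_per_group), ]
  n <- nrow(rec)
  rec$sample_id <- sprintf("S%04d", seq_len(n))
  rec$patient_id <- rec$sample_id
  rec$time_years <- rexp(n, rate = log(2) / 3)
  rec$event <- runif(n) < 0.7
  rownames(rec) <- NULL
  coords <- matrix(runif(2 * n, 0, 8), n, 2,
                   dimnames = list(rec$sample_id, c("x", "y")))
  e <- new("LandscapeEmbedding", coords = coords, seed = as.integer(seed),
           params = embedParams())
  list(embedding = e, records = rec)
}

# brute-force k-NN majority label transfer with nearest tie-break
oracleKnnImpute <- function(coords, labels, k) {
  out <- setNames(rep(NA_character_, nrow(coords)), rownames(coords))
  out[names(labels)] <- labels
  for (s in setdiff(rownames(coords), names(labels))) {
    d <- apply(coords[names(labels), , drop = FALSE], 1,
               function(r) sqrt(sum((r - coords[s, ])^2)))
    nn <- names(sort(d))[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    out[s] <- if (length(top) == 1L) top else labels[[names(sort(d))[1L]]]
  }
  out
}

smallSimConfig <- function(seed = 1L, n_genes = 200L,
                           gbm = 40L, astro = 30L, oligo = 30L,
                           normal = 40L, ...) {
  grp <- list(
      simGroup("glioblastoma", gbm, "tumor_adult",
               "GLIOBLASTOMA_IDH_WT", median_survival = 1.2,
               mutation_rate = 40,
               fusions = list(list(gene5 = "EGFR", gene3 = "PSPHP1",
                                   rate = 0.18)),
               cn_gain = "EGFR", cn_loss = "PTEN"),
      simGroup("astrocytoma", astro, "tumor_adult",
               "ASTROCYTOMA_IDH_MUT", median_survival = 6),
      simGroup("oligodendroglioma", oligo, "tumor_adult",
               "OLIGODENDROGLIOMA_IDH_MUT_CODEL",
               median_survival = 12),
      if (normal > 0) simGroup("normal_brain", normal, "normal",
                               mutation_rate = 0))
  grp <- Filter(Negate(is.null), grp)
  simConfig(n_genes = n_genes, groups = grp, seed = seed, ...)
}
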