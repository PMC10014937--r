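#' Assemble a pipeline configuration
#'
#' @param expression named list/vector: cohort label -> expression TSV
#'   path (unit given by `units`, default FPKM for every cohort).
#' @param metadata path to the sample-metadata CSV.
#' @param batch path to the batch-design CSV (sample_id, batch); when
#'   `NULL` the metadata `dataset` column is used as the batch.
#' @param gene_space optional path to a protein-coding gene list.
#' @param markers optional path to the molecular-markers CSV.
#' @param gmt optional path to a GMT gene-set file (enables the pathway
#'   stage).
#' @param variants,fusions,copynumber optional overlay input paths.
#' @param units named character vector cohort -> unit (default
#'   `"FPKM"`).
#' @param comparisons optional list of `list(name =, a =, b =)` where
#'   `a`/`b` are disease labels (or subtype labels) defining
#'   differential pathway comparisons.
#' @param panel_genes optional gene symbols for single-gene panels.
#' @param embed_params from [embedParams()].
#' @param nn_params from [nnSurvivalParams()].
#' @param combat_mode `"location_scale_eb"` or `"mean_only"`.
#' @param gsva_min_size,gsva_max_size gene-set size window.
#' @param seed integer seed (embedding and any other randomness).
#' @param outdir output directory.
#' @param stages character vector of stages to run, a subset of
#'   `c("harmonize", "correct", "embed", "classify",
#'   "survival-annotate", "pathways", "overlays")`; stages whose inputs
#'   are not configured are skipped.
#' @return config list of class `brainscapeConfig`.
#' @export
pipelineConfig <- function(expression, metadata, batch = NULL,
                           gene_space = NULL, markers = NULL,
                           gmt = NULL, variants = NULL, fusions = NULL,
                           copynumber = NULL, units = NULL,
                           comparisons = NULL, panel_genes = NULL,
                           embed_params = embedParams(),
                           nn_params = nnSurvivalParams(),
                           combat_mode = "location_scale_eb",
                           gsva_min_size = 5L, gsva_max_size = 500L,
                           seed = 1L, outdir = "brainscape_out",
                           stages = c("harmonize", "correct", "embed",
                                      "classify", "survival-annotate",
                                      "pathways", "overlays")) {
  cfg <- list(expression = as.list(expression), metadata = metadata,
              batch = batch, gene_space = gene_space, markers = markers,
              gmt = gmt, variants = variants, fusions = fusions,
              copynumber = copynumber, units = units,
              comparisons = comparisons, panel_genes = panel_genes,
              embed_params = embed_params, nn_params = nn_params,
              combat_mode = combat_mode,
              gsva_min_size = gsva_min_size,
              gsva_max_size = gsva_max_size,
              seed = as.integer(seed), outdir = outdir, stages = stages)
  class(cfg) <- "brainscapeConfig"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields mirror the arguments of
#'   [pipelineConfig()].
#' @return config list of class `brainscapeConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- js[intersect(names(js), names(formals(pipelineConfig)))]
  ep <- js$embed_params
  if (!is.null(ep))
    args$embed_params <- do.call(embedParams, as.list(ep))
  np <- js$nn_params
  if (!is.null(np))
    args$nn_params <- do.call(nnSurvivalParams, as.list(np))
  if (is.data.frame(args$comparisons))
    args$comparisons <- lapply(seq_len(nrow(args$comparisons)),
                               function(i) as.list(args$comparisons[i, ]))
  do.call(pipelineConfig, args)
}

#' Run the landscape pipeline end to end
#'
#' Executes the configured stages in order -- harmonize (units, gene
#' intersection, merge, log2), batch-correct, embed, classify subtypes,
#' nearest-neighbor survival annotation, pathway scoring and
#' differential testing, multi-omic overlays -- writing each stage's
#' outputs under `cfg$outdir` before the next stage runs. A rerun with
#' the same config and seed is bit-identical except for the manifest
#' timestamp. A stage failure aborts with the stage name and cause.
#'
#' @param cfg a `brainscapeConfig` (see [pipelineConfig()],
#'   [readPipelineConfig()]).
#' @return invisibly, a list with the in-memory stage results
#'   (`merged`, `corrected`, `embedding`, `subtypes`, `survival`,
#'   `pathway_scores`, `diff_tables`, `overlays`) and `files` (paths
#'   written).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "brainscapeConfig"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(files = character())
  stage <- function(name, enabled, fn) {
    if (!name %in% cfg$stages || !enabled) return(invisible(NULL))
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- function(...) file.path(cfg$outdir, ...)

  meta <- readSampleMetadata(cfg$metadata)

  stage("harmonize", TRUE, function() {
    mats <- lapply(names(cfg$expression), function(co) {
      unit <- if (!is.null(cfg$units) && co %in% names(cfg$units))
        cfg$units[[co]] else "FPKM"
      m <- readExpressionMatrix(cfg$expression[[co]], unit = unit,
                                dataset = co)
      if (exprUnit(m) == "FPKM") m <- fpkmToTpm(m)
      m
    })
    space <- if (!is.null(cfg$gene_space)) readGeneSpace(cfg$gene_space)
    merged <- log2Transform(intersectAndMerge(mats, space))
    res$merged <<- merged
    writeExpressionMatrix(merged, out("merged_log2tpm.tsv"))
    res$files["merged"] <<- out("merged_log2tpm.tsv")
  })

  stage("correct", !is.null(res$merged), function() {
    batch <- if (!is.null(cfg$batch)) readBatchDesign(cfg$batch)
             else stats::setNames(meta$dataset, meta$sample_id)
    corrected <- combatAdjust(res$merged, batch, mode = cfg$combat_mode)
    res$corrected <<- corrected
    writeExpressionMatrix(corrected, out("corrected_log2tpm.tsv"))
    res$files["corrected"] <<- out("corrected_log2tpm.tsv")
  })

  expr_for_embed <- function() {
    if (!is.null(res$corrected)) res$corrected else res$merged
  }

  stage("embed", !is.null(res$merged), function() {
    emb <- embedLandscape(expr_for_embed(), params = cfg$embed_params,
                          seed = cfg$seed)
    res$embedding <<- emb
    writeEmbedding(emb, out("embedding.csv"))
    res$files["embedding"] <<- out("embedding.csv")
  })

  stage("classify", !is.null(cfg$markers), function() {
    calls <- classifyWhoCns5(readMarkers(cfg$markers))
    res$subtypes <<- calls
    utils::write.csv(calls, out("subtypes.csv"), row.names = FALSE,
                     quote = FALSE)
    res$files["subtypes"] <<- out("subtypes.csv")
  })

  stage("survival-annotate", !is.null(res$embedding), function() {
    records <- makeSurvivalRecords(meta, res$subtypes)
    records <- filterPrimaryUnique(records, meta)
    ann <- nnSurvivalAnnotate(res$embedding, records,
                              params = cfg$nn_params)
    res$survival <<- ann
    utils::write.csv(ann, out("survival_annotation.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    res$files["survival"] <<- out("survival_annotation.csv")
  })

  stage("pathways", !is.null(cfg$gmt) && !is.null(res$merged),
        function() {
    sets <- readGmt(cfg$gmt)
    sc <- gsvaScores(expr_for_embed(), sets,
                     min_size = cfg$gsva_min_size,
                     max_size = cfg$gsva_max_size)
    res$pathway_scores <<- sc
    writePathwayScores(sc, out("pathway_scores.tsv"))
    res$files["pathway_scores"] <<- out("pathway_scores.tsv")
    if (!is.null(cfg$comparisons)) {
      lab <- stats::setNames(meta$disease_label, meta$sample_id)
      if (!is.null(res$subtypes)) {
        st <- stats::setNames(as.character(res$subtypes$subtype),
                              res$subtypes$sample_id)
        hit <- names(lab) %in% names(st) &
          st[names(lab)] != "UNCLASSIFIED"
        lab[hit] <- st[names(lab)[hit]]
      }
      lab <- lab[names(lab) %in%
                   colnames(pathwayScores(sc))]
      tables <- list()
      for (cmp in cfg$comparisons) {
        ga <- names(lab)[lab == cmp$a]
        gb <- names(lab)[lab == cmp$b]
        tb <- moderatedTTest(sc, ga, gb)
        tables[[cmp$name]] <- tb
        pth <- out(sprintf("diff_pathways_%s.csv", cmp$name))
        utils::write.csv(tb, pth, row.names = FALSE)
        res$files[paste0("diff_", cmp$name)] <<- pth
      }
      res$diff_tables <<- tables
    }
  })

  stage("overlays", !is.null(cfg$variants) || !is.null(cfg$fusions) ||
          !is.null(cfg$copynumber), function() {
    samples <- meta$sample_id
    ov <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
    v <- f <- cn <- NULL
    if (!is.null(cfg$variants)) {
      v <- mergeVariantCallers(list(readVariantTable(cfg$variants)))
      ov$mutation_burden <- mutationBurden(v, samples)
    }
    if (!is.null(cfg$fusions)) {
      f <- filterHighConfidence(readFusionTable(cfg$fusions))
      ov$fusion_burden <- fusionBurden(f, samples)
    }
    if (!is.null(cfg$copynumber)) {
      cn <- readCopyNumberMatrix(cfg$copynumber)
      gl <- cnGainLossCounts(cn)
      idx <- match(samples, gl$sample_id)
      ov$genes_gained <- ifelse(is.na(idx), 0L, gl$genes_gained[idx])
      ov$genes_lost <- ifelse(is.na(idx), 0L, gl$genes_lost[idx])
    }
    res$overlays <<- ov
    utils::write.csv(ov, out("overlays.csv"), row.names = FALSE,
                     quote = FALSE)
    res$files["overlays"] <<- out("overlays.csv")
    if (!is.null(cfg$panel_genes) && !is.null(res$merged)) {
      for (gene in cfg$panel_genes) {
        pan <- genePanel(gene, expr_for_embed(), v, f, cn)
        pth <- out(sprintf("gene_panel_%s.csv", gene))
        utils::write.csv(pan, pth, row.names = FALSE, quote = FALSE)
        res$files[paste0("panel_", gene)] <<- pth
      }
    }
  })

  manifest <- list(
    package = "brainscape",
    version = as.character(utils::packageVersion("brainscape")),
    seed = cfg$seed,
    embed_params = cfg$embed_params,
    nn_params = cfg$nn_params,
    combat_mode = cfg$combat_mode,
    stages = cfg$stages,
    files = as.list(res$files),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
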