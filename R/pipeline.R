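#' Default pipeline configuration
#'
#' Nested settings list for [runPipeline()], mirroring the committed
#' YAML in \code{inst/extdata/default_config.yaml}. One global seed
#' propagates to per-stage child seeds by fixed offsets.
#'
#' @param seed global seed, default 7.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 7L) {
  list(
    seed = as.integer(seed),
    signatures = list(n_top = 100L),
    ssgsea = list(weight = 0.75, min_overlap = 5L),
    association = list(target_group = "dualpos", n_permutations = 1000L),
    nmf = list(k = 3L, n_restarts = 20L),
    oncogps = list(k_nodes = 9L, n_states = 3L, pull_exponent = 2,
                   n_restarts = 10L, plant_state = 2L, plant_scale = 2),
    diffexp = list(group_a = "dualpos", group_b = "typeII"),
    cells = list(n_cells = 100000L,
                 fractions = list(typeI = 0.324, typeII = 0.650,
                                  dualpos = 0.026)),
    ct = list(fold_changes = list(Rage = 4, Aqp5 = 2.5, Sftpc = 1.8),
              noise_sd = 0))
}

validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopIfNot(is.list(config), "config must be a list or a YAML path")
  default <- defaultPipelineConfig()
  merged <- utils::modifyList(default, config)
  stopIfNot(is.numeric(merged$seed), "config: seed must be numeric")
  stopIfNot(merged$signatures$n_top >= 1,
            "config: signatures$n_top must be >= 1")
  stopIfNot(merged$ssgsea$weight >= 0,
            "config: ssgsea$weight must be >= 0")
  stopIfNot(merged$association$n_permutations >= 100,
            "config: association$n_permutations must be >= 100")
  stopIfNot(merged$nmf$k >= 1, "config: nmf$k must be >= 1")
  stopIfNot(merged$oncogps$k_nodes >= 2,
            "config: oncogps$k_nodes must be >= 2")
  fr <- unlist(merged$cells$fractions)
  stopIfNot(abs(sum(fr) - 1) < 1e-9,
            "config: cells$fractions must sum to 1")
  stopIfNot(all(unlist(merged$ct$fold_changes) > 0),
            "config: ct$fold_changes must be positive")
  merged
}

#' Run the full synthetic end-to-end analysis pipeline
#'
#' Generates the synthetic study, reference panels and cell-line
#' module panel, then runs every downstream stage in dependency order:
#' signature derivation, ssGSEA scoring, information-coefficient
#' association against the dual-positive group, NMF sample clustering,
#' Onco-GPS map construction and study projection, differential
#' expression, and the gating / delta-delta-CT quantifications. All
#' stage outputs are TSV/GMT/JSON files in \code{outDir}; a JSON
#' manifest records every file with its MD5 hash and the stage
#' parameters. Reruns with an identical config are byte-identical.
#'
#' @param config configuration list or YAML path (see
#'   [defaultPipelineConfig()]); validated before any compute.
#' @param outDir output directory (created if needed). Required.
#' @param verbose log per-stage messages to stderr, default TRUE.
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        verbose = TRUE) {
  cfg <- validateConfig(config)
  if (missing(outDir) || is.null(outDir))
    stop("config error: output directory is required", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (verbose) message("[", stage, "] ", ...)
  }
  manifest <- list(config = cfg, files = list())
  record <- function(stage, path, params = NULL) {
    manifest$files[[basename(path)]] <<- list(
      stage = stage, md5 = unname(tools::md5sum(path)),
      params = params)
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      partial <- file.path(outDir, "manifest_partial.json")
      manifest$failed_stage <- stage
      jsonlite::write_json(manifest, partial, auto_unbox = TRUE,
                           digits = NA, force = TRUE)
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), " (partial manifest at ", partial, ")",
           call. = FALSE)
    })
  }
  seed <- cfg$seed

  runStage("simulate", {
    say("simulate", "study matrix and annotation")
    design <- defaultStudyDesign(seed = childSeed(seed, 1))
    study <- simulateStudy(design)
    writeExpression(study$matrix, file.path(outDir, "study_expression.tsv"))
    writeSampleAnnotation(study$annotation,
                          file.path(outDir, "study_annotation.tsv"))
    record("simulate", file.path(outDir, "study_expression.tsv"),
           list(n_genes = design@nGenes, seed = design@seed))
    record("simulate", file.path(outDir, "study_annotation.tsv"))
    panels <- simulateReferencePanels(seed = childSeed(seed, 2))
    for (pn in names(panels)) {
      mp <- file.path(outDir, paste0("panel_", pn, "_expression.tsv"))
      ap <- file.path(outDir, paste0("panel_", pn, "_annotation.tsv"))
      writeExpression(panels[[pn]]$matrix, mp)
      writeSampleAnnotation(panels[[pn]]$annotation, ap)
      record("simulate", mp); record("simulate", ap)
    }
    kras <- simulateKrasPanel(seed = childSeed(seed, 3))
    writeExpression(kras$matrix, file.path(outDir, "kras_panel.tsv"))
    writeGmt(GeneSetCollection(list(kras$module)),
             file.path(outDir, "kras_module.gmt"))
    record("simulate", file.path(outDir, "kras_panel.tsv"))
    record("simulate", file.path(outDir, "kras_module.gmt"))
  })

  runStage("signatures", {
    say("signatures", "top-", cfg$signatures$n_top, " SNR per cell type")
    sigs <- deriveAll(panels, nTop = cfg$signatures$n_top)
    writeGmt(sigs, file.path(outDir, "signatures.gmt"))
    record("signatures", file.path(outDir, "signatures.gmt"),
           cfg$signatures)
  })

  runStage("ssgsea", {
    say("ssgsea", "scoring ", length(sigs), " sets x ",
        length(sampleIds(study$matrix)), " samples")
    scores <- scoreCollection(study$matrix, sigs,
                              w = cfg$ssgsea$weight,
                              minOverlap = cfg$ssgsea$min_overlap)
    writeTsvMatrix(enrichmentScores(scores),
                   file.path(outDir, "ssgsea_scores.tsv"), "set_name")
    record("ssgsea", file.path(outDir, "ssgsea_scores.tsv"), cfg$ssgsea)
  })

  runStage("association", {
    say("association", "IC vs ", cfg$association$target_group,
        " indicator, ", cfg$association$n_permutations, " permutations")
    pheno <- stats::setNames(
      as.numeric(study$annotation$group == cfg$association$target_group),
      study$annotation$sample_id)
    assoc <- suppressMessages(associateCollection(
      scores, pheno, nPermutations = cfg$association$n_permutations,
      seed = childSeed(seed, 4)))
    utils::write.table(assoc, file.path(outDir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("association", file.path(outDir, "association.tsv"),
           cfg$association)
  })

  runStage("nmf", {
    say("nmf", "rank-", cfg$nmf$k, " factorization, ",
        cfg$nmf$n_restarts, " restarts")
    model <- suppressMessages(fitNmf(study$matrix, cfg$nmf$k,
                                     nRestarts = cfg$nmf$n_restarts,
                                     seed = childSeed(seed, 5)))
    writeTsvMatrix(basisMatrix(model), file.path(outDir, "nmf_W.tsv"),
                   "gene_id")
    writeTsvMatrix(coefMatrix(model), file.path(outDir, "nmf_H.tsv"),
                   "factor")
    clusters <- assignClusters(model)
    utils::write.table(
      data.frame(sample_id = names(clusters), factor = clusters),
      file.path(outDir, "nmf_clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (f in c("nmf_W.tsv", "nmf_H.tsv", "nmf_clusters.tsv"))
      record("nmf", file.path(outDir, f), cfg$nmf)
  })

  runStage("oncogps", {
    say("oncogps", cfg$oncogps$k_nodes, "-node map, ",
        cfg$oncogps$n_states, " states")
    map <- suppressMessages(buildMap(
      kras$matrix, kras$module, kNodes = cfg$oncogps$k_nodes,
      nStates = cfg$oncogps$n_states,
      pullExponent = cfg$oncogps$pull_exponent,
      nRestarts = cfg$oncogps$n_restarts,
      seed = childSeed(seed, 6)))
    writeOncoGPSMap(map, file.path(outDir, "oncogps_map.json"))
    planted <- addStateActivity(
      study$matrix, study$annotation$sample_id[
        study$annotation$group == cfg$association$target_group],
      kras, cfg$oncogps$plant_state, scale = cfg$oncogps$plant_scale)
    proj <- suppressWarnings(projectSamples(map, planted))
    utils::write.table(proj, file.path(outDir, "oncogps_projection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("oncogps", file.path(outDir, "oncogps_map.json"), cfg$oncogps)
    record("oncogps", file.path(outDir, "oncogps_projection.tsv"),
           cfg$oncogps)
  })

  runStage("diffexp", {
    say("diffexp", cfg$diffexp$group_a, " vs ", cfg$diffexp$group_b)
    de <- differentialExpression(study$matrix, study$annotation,
                                 cfg$diffexp$group_a,
                                 cfg$diffexp$group_b)
    utils::write.table(de, file.path(outDir, "differential_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("diffexp", file.path(outDir, "differential_expression.tsv"),
           cfg$diffexp)
  })

  runStage("quantification", {
    say("quantification", "gated fractions and fold changes")
    spec <- epithelialPopulationSpec(
      nCells = cfg$cells$n_cells,
      fractions = unlist(cfg$cells$fractions),
      seed = childSeed(seed, 8))
    pops <- gateCells(simulateCells(spec), epithelialGate())
    utils::write.table(pops, file.path(outDir, "populations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ct <- simulateCtTable(unlist(cfg$ct$fold_changes),
                          noiseSd = cfg$ct$noise_sd,
                          seed = childSeed(seed, 9))
    fc <- foldChange(ct, names(unlist(cfg$ct$fold_changes)))
    utils::write.table(
      data.frame(gene_id = names(fc), fold_change = formatNum(fc)),
      file.path(outDir, "fold_changes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    record("quantification", file.path(outDir, "populations.tsv"),
           cfg$cells)
    record("quantification", file.path(outDir, "fold_changes.tsv"),
           cfg$ct)
  })

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  say("done", length(manifest$files), " artifacts in ", outDir)
  invisible(manifest)
}
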