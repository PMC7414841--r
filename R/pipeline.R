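# End-to-end orchestration: proximity -> DIAMOnD -> validation/stop ->
# enrichment map -> perturbation -> robustness (-> ssGSEA), driven by a
# config list or YAML file, with a reproducibility manifest.

pipelineDefaults <- list(
  n_random = 300L, min_bin_size = 100L, diamond_iterations = 150L,
  window_size = NULL, p_threshold = 0.05, patience = NULL,
  jaccard_cutoff = 0.1, z_significant = -1.645, z_probable = -1.282,
  n_sim = 200L, ssgsea_tau = 0.25, seed = 1L, out_dir = "netmodule_out")

#' Validate and complete a pipeline configuration
#'
#' Fills defaults, checks that thresholds are finite, \code{n_random}
#' is at least 2, and that every referenced input file exists.
#' Required entries: \code{network}, \code{seeds}, \code{drugs},
#' \code{gene_sets} (paths); optional: \code{validation_genes},
#' \code{expression}, \code{pairing}.
#'
#' @param config named list, or path to a YAML file.
#' @return the completed config list.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (k in names(pipelineDefaults))
    if (is.null(config[[k]])) config[[k]] <- pipelineDefaults[[k]]
  for (k in c("network", "seeds", "drugs", "gene_sets")) {
    if (is.null(config[[k]])) stop("config is missing required path: ", k)
    if (!file.exists(config[[k]]))
      stop("config ", k, " file does not exist: ", config[[k]])
  }
  for (k in c("validation_genes", "expression", "pairing")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop("config ", k, " file does not exist: ", config[[k]])
  }
  if (config$n_random < 2) stop("n_random must be >= 2")
  for (k in c("p_threshold", "jaccard_cutoff", "z_significant",
              "z_probable"))
    if (!is.finite(config[[k]])) stop("config ", k, " must be finite")
  config
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full drug-effect pipeline
#'
#' Executes, in order: drug-disease proximity, drug-pathway proximity,
#' DIAMOnD ranking, validation scoring with the sliding-window stopping
#' rule, module assembly, functional enrichment of the module with
#' enrichment-map construction, per-drug perturbation profiling of the
#' map, attack-vulnerability analysis of the map network, and — when
#' expression and pairing inputs are present — ssGSEA with paired
#' treatment deltas (skipped with a logged reason otherwise).  Every
#' stage writes a TSV into the output directory; a final
#' \code{manifest.json} records the config, seeds, package versions,
#' per-stage row counts and md5 hashes, so a rerun with the same config
#' is verifiably identical.  A stage failure aborts with the stage name;
#' the outputs of completed stages are retained.
#'
#' @param config list or YAML path, see \code{\link{pipelineConfig}}.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  config <- pipelineConfig(config)
  outDir <- config$out_dir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manifest <- list(config = config,
                   versions = list(
                     netmodule = as.character(utils::packageVersion("netmodule")),
                     igraph = as.character(utils::packageVersion("igraph")),
                     R = paste(R.version$major, R.version$minor, sep = ".")),
                   stages = list())
  files <- character(0)
  stage <- function(name, expr) {
    logMsg("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  record <- function(name, rows, file = NULL) {
    manifest$stages[[name]] <<- list(rows = rows, file = file)
    if (!is.null(file)) files <<- c(files, file)
  }

  graph <- stage("load", loadEdgeList(config$network))
  seeds <- stage("load", readGeneList(config$seeds))
  drugs <- stage("load", readDrugTargets(config$drugs))
  sets <- stage("load", readGmt(config$gene_sets))
  bins <- stage("binning", buildDegreeBins(graph, config$min_bin_size))

  prox <- stage("proximity", {
    mat <- proximityMatrix(graph, drugs, list(disease = seeds), bins,
                           nRandom = config$n_random,
                           rngSeed = deriveSeed(config$seed, "proximity"))
    writeTsv(mat$results, file.path(outDir, "drug_disease_proximity.tsv"))
    mat
  })
  record("proximity", nrow(prox$results),
         file.path(outDir, "drug_disease_proximity.tsv"))

  pathProx <- stage("pathway_proximity", {
    mat <- proximityMatrix(graph, drugs, sets, bins,
                           nRandom = config$n_random,
                           rngSeed = deriveSeed(config$seed, "pathway"))
    writeTsv(mat$results, file.path(outDir, "drug_pathway_proximity.tsv"))
    mat
  })
  record("pathway_proximity", nrow(pathProx$results),
         file.path(outDir, "drug_pathway_proximity.tsv"))

  ranking <- stage("diamond", {
    r <- runDiamond(graph, seeds, config$diamond_iterations)
    writeTsv(r, file.path(outDir, "diamond_ranking.tsv"))
    r
  })
  record("diamond", nrow(ranking),
         file.path(outDir, "diamond_ranking.tsv"))

  valStage <- stage("validation", {
    valSets <- sets
    if (!is.null(config$validation_genes))
      valSets$expression_derived <- readGeneList(config$validation_genes)
    hits <- scoreHits(ranking, valSets)
    unionMembers <- unique(unlist(valSets, use.names = FALSE))
    bg <- mean(igraph::V(graph)$name %in% unionMembers)
    w <- config$window_size %||% length(intersect(seeds,
                                                  igraph::V(graph)$name))
    ws <- slidingWindowStats(hits, windowSize = w, backgroundRate = bg,
                             mode = "binomial")
    stopIter <- stoppingIteration(ws, config$p_threshold,
                                  config$patience %||% w)
    out <- merge(hits, ws, by = "iteration")
    writeTsv(out, file.path(outDir, "validation_windows.tsv"))
    list(windows = out, stop = stopIter, background = bg)
  })
  record("validation", nrow(valStage$windows),
         file.path(outDir, "validation_windows.tsv"))

  module <- stage("module", {
    nKeep <- if (valStage$stop > 0) valStage$stop else nrow(ranking)
    m <- assembleModule(graph, seeds, ranking, nKeep)
    writeTsv(data.frame(gene = moduleMembers(m),
                        in_lcc = moduleMembers(m) %in% lccMembers(m),
                        is_seed = moduleMembers(m) %in% seedGenes(m)),
             file.path(outDir, "disease_module.tsv"))
    m
  })
  record("module", length(moduleMembers(module)),
         file.path(outDir, "disease_module.tsv"))

  emap <- stage("enrichment_map", {
    enr <- fisherEnrichment(moduleMembers(module), sets,
                            background = igraph::V(graph)$name,
                            mode = "ease")
    writeTsv(enr, file.path(outDir, "enrichment.tsv"))
    sig <- filterSignificant(enr)
    termIds <- if (nrow(sig) > 0) sig$term_id else {
      logMsg("no term passed the significance filter; mapping all terms")
      enr$term_id
    }
    map <- buildEnrichmentMap(sets[termIds], config$jaccard_cutoff)
    writeTsv(nodeTable(map), file.path(outDir, "map_nodes.tsv"))
    writeTsv(edgeTable(map), file.path(outDir, "map_edges.tsv"))
    map
  })
  record("enrichment_map", nrow(nodeTable(emap)),
         file.path(outDir, "map_nodes.tsv"))

  perturb <- stage("perturbation", {
    profs <- lapply(names(drugs), function(d)
      perturbationProfile(graph, drugs[[d]], emap, bins,
                          nRandom = config$n_random,
                          rngSeed = deriveSeed(config$seed,
                                               paste0("perturb_", d)),
                          drugId = d,
                          zThreshold = config$z_probable))
    names(profs) <- names(drugs)
    summary <- do.call(rbind, lapply(profs, function(p) data.frame(
      drug_id = p@drugId, n_perturbed = p@nPerturbed,
      n_nodes = p@nNodes, ratio = p@ratio, stringsAsFactors = FALSE)))
    writeTsv(summary, file.path(outDir, "perturbation.tsv"))
    profs
  })
  record("perturbation", length(perturb),
         file.path(outDir, "perturbation.tsv"))

  robust <- stage("robustness", {
    mapGraph <- igraph::graph_from_data_frame(
      edgeTable(emap)[, 1:2], directed = FALSE,
      vertices = nodeTable(emap)["term_id"])
    curve <- randomFailureCurve(mapGraph, nSim = config$n_sim,
                                rngSeed = deriveSeed(config$seed,
                                                     "robustness"))
    writeTsv(attackTable(curve), file.path(outDir, "attack_curve.tsv"))
    drugRows <- do.call(rbind, lapply(names(perturb), function(d) {
      pn <- nodeTable(perturb[[d]])
      hitNodes <- pn$term_id[!is.na(pn$perturbed) & pn$perturbed]
      data.frame(drug_id = d, n_removed = length(hitNodes),
                 remaining_lcc_fraction =
                   targetedAttack(mapGraph, hitNodes),
                 stringsAsFactors = FALSE)
    }))
    writeTsv(drugRows, file.path(outDir, "targeted_attack.tsv"))
    list(curve = curve, half_collapse = halfCollapseFraction(curve),
         targeted = drugRows)
  })
  record("robustness", length(robust$curve@fractionsRemoved),
         file.path(outDir, "attack_curve.tsv"))

  if (!is.null(config$expression) && !is.null(config$pairing)) {
    ssg <- stage("ssgsea", {
      expr <- readExpression(config$expression)
      pairing <- readPairing(config$pairing)
      scores <- ssgseaScore(expr, sets, tau = config$ssgsea_tau)
      writeTsv(data.frame(gene_set = rownames(scores), scores,
                          check.names = FALSE),
               file.path(outDir, "ssgsea_scores.tsv"))
      deltas <- pairedDelta(scores, pairing)
      writeTsv(deltas, file.path(outDir, "ssgsea_deltas.tsv"))
      deltas
    })
    record("ssgsea", nrow(ssg), file.path(outDir, "ssgsea_deltas.tsv"))
  } else {
    logMsg("ssgsea stage skipped: no expression/pairing input")
    manifest$stages$ssgsea <- list(skipped = "no expression/pairing input")
  }

  manifest$half_collapse_fraction <- robust$half_collapse
  manifest$stopping_iteration <- valStage$stop
  manifest$hashes <- as.list(tools::md5sum(files))
  names(manifest$hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
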