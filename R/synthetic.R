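# Synthetic data with planted ground truth: interactome + dense module,
# proximal/distal drugs, enriched/null gene sets, and paired treatment
# expression.  All randomness flows from per-stage seeds; simulateBundle
# derives named substreams from one master seed so every stage can be
# regenerated independently and byte-identically.

#' Simulate a scale-free interactome with a planted disease module
#'
#' Grows a preferential-attachment backbone (heavy-tailed degrees, as in
#' real interactomes), then plants a disease module: a random subset of
#' genes receiving extra within-module edges with probability
#' \code{moduleDensityBoost} per pair, so the module is denser than the
#' background (\code{boost = 0} is the negative control where the module
#' is indistinguishable).  A subset of module genes is designated as the
#' known disease seeds.
#'
#' @param nNodes number of genes.
#' @param attachmentM edges added per new node in the backbone.
#' @param moduleSize number of planted module genes
#'   (< \code{nNodes}).
#' @param moduleDensityBoost probability of an extra edge per
#'   within-module pair.
#' @param nSeeds number of module genes labelled as disease seeds.
#' @param rngSeed integer seed.
#' @return list with \code{graph} (\code{igraph}) and \code{truth}, a
#'   list recording every parameter plus \code{module_genes} and
#'   \code{seed_genes}.
#' @export
simulateInteractome <- function(nNodes = 1000L, attachmentM = 2L,
                                moduleSize = 60L,
                                moduleDensityBoost = 0.15,
                                nSeeds = 25L, rngSeed = NULL) {
  stopifnot(moduleSize < nNodes, attachmentM >= 1, nSeeds <= moduleSize,
            moduleDensityBoost >= 0, moduleDensityBoost <= 1)
  withSeed(rngSeed, {
    g <- igraph::sample_pa(nNodes, power = 1, m = attachmentM,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("G%04d", seq_len(nNodes))
    moduleGenes <- sort(sample(igraph::V(g)$name, moduleSize))
    if (moduleDensityBoost > 0 && moduleSize >= 2) {
      pairs <- utils::combn(moduleGenes, 2)
      pick <- stats::runif(ncol(pairs)) < moduleDensityBoost
      if (any(pick)) {
        g <- igraph::add_edges(g, as.vector(pairs[, pick, drop = FALSE]))
        g <- igraph::simplify(g)
      }
    }
    seedGenes <- sort(sample(moduleGenes, nSeeds))
    truth <- list(
      params = list(n_nodes = nNodes, attachment_m = attachmentM,
                    module_size = moduleSize,
                    module_density_boost = moduleDensityBoost,
                    n_seeds = nSeeds, rng_seed = rngSeed),
      module_genes = moduleGenes,
      seed_genes = seedGenes)
    list(graph = g, truth = truth)
  })
}

#' Simulate drugs with graph-proximal and graph-distal targets
#'
#' Proximal drugs draw their targets from nodes at distance at most
#' \code{dNear} from the planted module (with the default
#' \code{dNear = 0}, from the module itself, the d_c = 0 regime);
#' distal drugs from nodes at distance at least \code{dNear + 2}.
#'
#' @param graph \code{igraph} from \code{\link{simulateInteractome}}.
#' @param truth its truth record.
#' @param nProximal,nDistal drug counts per class.
#' @param targetsPerDrug targets drawn per drug (without replacement).
#' @param dNear proximity radius of the proximal stratum.
#' @param rngSeed integer seed.
#' @return list with \code{drugs} (named list of target vectors) and the
#'   updated \code{truth} carrying \code{drug_labels}.
#' @export
simulateDrugs <- function(graph, truth, nProximal = 3L, nDistal = 3L,
                          targetsPerDrug = 5L, dNear = 0L,
                          rngSeed = NULL) {
  dmin <- apply(igraph::distances(graph, v = truth$module_genes), 2, min)
  nearPool <- names(dmin)[dmin <= dNear]
  farPool <- names(dmin)[is.finite(dmin) & dmin >= dNear + 2]
  if (length(nearPool) < targetsPerDrug)
    stop("too few nodes within distance ", dNear, " of the module")
  if (length(farPool) < targetsPerDrug)
    stop("too few nodes at distance >= ", dNear + 2, " from the module")
  withSeed(rngSeed, {
    drugs <- list()
    for (i in seq_len(nProximal))
      drugs[[sprintf("proximal_%02d", i)]] <-
        sort(sample(nearPool, targetsPerDrug))
    for (i in seq_len(nDistal))
      drugs[[sprintf("distal_%02d", i)]] <-
        sort(sample(farPool, targetsPerDrug))
    truth$drug_params <- list(n_proximal = nProximal, n_distal = nDistal,
                              targets_per_drug = targetsPerDrug,
                              d_near = dNear, rng_seed = rngSeed)
    truth$drug_labels <- stats::setNames(
      rep(c("proximal", "distal"), c(nProximal, nDistal)), names(drugs))
    truth$drugs <- drugs
    list(drugs = drugs, truth = truth)
  })
}

#' Simulate gene-set collections enriched (or not) in the module
#'
#' Enriched terms draw a fraction \code{overlapFrac} of their members
#' from the planted module genes and the rest uniformly from the other
#' genes; null terms are drawn fully uniformly, so their enrichment
#' p-values are calibrated.
#'
#' @param graph \code{igraph}.
#' @param truth truth record with \code{module_genes}.
#' @param nTerms total number of terms.
#' @param enrichedFraction fraction of terms that are module-enriched.
#' @param overlapFrac fraction of an enriched term drawn from the
#'   module.
#' @param sizeRange integer length-2, inclusive term-size bounds.
#' @param rngSeed integer seed.
#' @return list with \code{sets} (named list, GMT-compatible) and the
#'   updated \code{truth} carrying \code{enriched_terms}.
#' @export
simulateGeneSets <- function(graph, truth, nTerms = 20L,
                             enrichedFraction = 0.3, overlapFrac = 0.6,
                             sizeRange = c(10L, 40L), rngSeed = NULL) {
  nodes <- igraph::V(graph)$name
  module <- truth$module_genes
  offModule <- setdiff(nodes, module)
  nEnr <- round(nTerms * enrichedFraction)
  withSeed(rngSeed, {
    sets <- list()
    for (i in seq_len(nEnr)) {
      s <- sample(seq(sizeRange[1], sizeRange[2]), 1)
      nOv <- min(round(overlapFrac * s), length(module))
      members <- sort(c(sample(module, nOv), sample(offModule, s - nOv)))
      attr(members, "description") <- "module-enriched synthetic term"
      sets[[sprintf("term_enr_%02d", i)]] <- members
    }
    for (i in seq_len(nTerms - nEnr)) {
      s <- sample(seq(sizeRange[1], sizeRange[2]), 1)
      members <- sort(sample(nodes, s))
      attr(members, "description") <- "background synthetic term"
      sets[[sprintf("term_null_%02d", i)]] <- members
    }
    truth$gene_set_params <- list(n_terms = nTerms,
                                  enriched_fraction = enrichedFraction,
                                  overlap_frac = overlapFrac,
                                  size_range = sizeRange,
                                  rng_seed = rngSeed)
    truth$enriched_terms <- grep("^term_enr_", names(sets), value = TRUE)
    list(sets = sets, truth = truth)
  })
}

#' Simulate paired before/after treatment expression
#'
#' Log-scale expression: every gene gets a subject-independent baseline
#' mean plus Gaussian noise per sample.  In the "after" sample of
#' improver subjects, genes belonging to \code{setsToShift} are reduced
#' by \code{deltaTx} (treatment suppressing the disease-associated
#' programs); non-improvers are unshifted by construction.
#'
#' @param genes character vector of gene symbols to simulate.
#' @param nSubjects number of paired subjects.
#' @param setsToShift named list of gene sets that respond to
#'   treatment.
#' @param deltaTx treatment effect size (log-scale shift).
#' @param noiseSd per-sample Gaussian noise SD.
#' @param improverFraction fraction of subjects that respond.
#' @param rngSeed integer seed.
#' @return list with \code{expr} (genes x samples matrix),
#'   \code{pairing} (\code{data.frame}: sample, subject, timepoint,
#'   group) and a \code{truth} record of the parameters.
#' @export
simulateExpression <- function(genes, nSubjects = 20L,
                               setsToShift = list(), deltaTx = 1,
                               noiseSd = 0.3, improverFraction = 0.5,
                               rngSeed = NULL) {
  genes <- unique(genes)
  nG <- length(genes)
  shiftGenes <- intersect(genes,
                          unique(unlist(setsToShift, use.names = FALSE)))
  withSeed(rngSeed, {
    mu <- stats::rnorm(nG, mean = 6, sd = 1.5)
    names(mu) <- genes
    nImp <- round(nSubjects * improverFraction)
    improver <- rep(c(TRUE, FALSE), c(nImp, nSubjects - nImp))
    subjects <- sprintf("S%02d", seq_len(nSubjects))
    samples <- c(paste0(subjects, "_before"), paste0(subjects, "_after"))
    expr <- matrix(NA_real_, nG, 2 * nSubjects,
                   dimnames = list(genes, samples))
    for (i in seq_len(nSubjects)) {
      expr[, i] <- mu + stats::rnorm(nG, 0, noiseSd)
      after <- mu + stats::rnorm(nG, 0, noiseSd)
      if (improver[i]) after[shiftGenes] <- after[shiftGenes] - deltaTx
      expr[, nSubjects + i] <- after
    }
    pairing <- data.frame(
      sample = samples,
      subject = rep(subjects, 2),
      timepoint = rep(c("before", "after"), each = nSubjects),
      group = rep(ifelse(improver, "improver", "non_improver"), 2),
      stringsAsFactors = FALSE)
    truth <- list(n_subjects = nSubjects, delta_tx = deltaTx,
                  noise_sd = noiseSd,
                  improver_fraction = improverFraction,
                  shifted_sets = names(setsToShift),
                  improver_subjects = subjects[improver],
                  rng_seed = rngSeed)
    list(expr = expr, pairing = pairing, truth = truth)
  })
}

#' Generate a complete synthetic study bundle
#'
#' Runs the four generators with substream seeds derived from one master
#' seed (streams: interactome, drugs, sets, expression) and returns
#' everything a full pipeline run needs.  The treatment shifts the
#' module-enriched gene sets in improver subjects.
#'
#' @param masterSeed integer master seed.
#' @param nNodes,attachmentM,moduleSize,moduleDensityBoost,nSeeds
#'   passed to \code{\link{simulateInteractome}}.
#' @param nProximal,nDistal,targetsPerDrug,dNear passed to
#'   \code{\link{simulateDrugs}}.
#' @param nTerms,enrichedFraction,overlapFrac,sizeRange passed to
#'   \code{\link{simulateGeneSets}}.
#' @param nSubjects,deltaTx,noiseSd,improverFraction passed to
#'   \code{\link{simulateExpression}}.
#' @return list with \code{graph}, \code{truth}, \code{drugs},
#'   \code{sets}, \code{expr}, \code{pairing}.
#' @export
simulateBundle <- function(masterSeed,
                           nNodes = 1000L, attachmentM = 2L,
                           moduleSize = 60L, moduleDensityBoost = 0.15,
                           nSeeds = 25L,
                           nProximal = 3L, nDistal = 3L,
                           targetsPerDrug = 5L, dNear = 0L,
                           nTerms = 20L, enrichedFraction = 0.3,
                           overlapFrac = 0.6, sizeRange = c(10L, 40L),
                           nSubjects = 20L, deltaTx = 1,
                           noiseSd = 0.3, improverFraction = 0.5) {
  net <- simulateInteractome(nNodes, attachmentM, moduleSize,
                             moduleDensityBoost, nSeeds,
                             rngSeed = deriveSeed(masterSeed, "interactome"))
  dr <- simulateDrugs(net$graph, net$truth, nProximal, nDistal,
                      targetsPerDrug, dNear,
                      rngSeed = deriveSeed(masterSeed, "drugs"))
  gs <- simulateGeneSets(net$graph, dr$truth, nTerms, enrichedFraction,
                         overlapFrac, sizeRange,
                         rngSeed = deriveSeed(masterSeed, "sets"))
  shifted <- gs$sets[gs$truth$enriched_terms]
  ex <- simulateExpression(igraph::V(net$graph)$name, nSubjects, shifted,
                           deltaTx, noiseSd, improverFraction,
                           rngSeed = deriveSeed(masterSeed, "expression"))
  truth <- gs$truth
  truth$expression <- ex$truth
  truth$master_seed <- masterSeed
  list(graph = net$graph, truth = truth, drugs = dr$drugs,
       sets = gs$sets, expr = ex$expr, pairing = ex$pairing)
}

#' Write a synthetic bundle to plain-text files
#'
#' Emits \code{edges.tsv}, \code{seeds.txt}, \code{drugs.tsv},
#' \code{sets.gmt}, \code{expr.tsv}, \code{pairing.tsv} and
#' \code{truth.json} into a directory.  Identical bundles produce
#' byte-identical files.
#'
#' @param bundle list from \code{\link{simulateBundle}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  el <- igraph::as_edgelist(bundle$graph)
  utils::write.table(el, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(bundle$truth$seed_genes, file.path(dir, "seeds.txt"))
  writeDrugTargets(bundle$drugs, file.path(dir, "drugs.tsv"))
  writeGmt(bundle$sets, file.path(dir, "sets.gmt"))
  exprDf <- data.frame(gene = rownames(bundle$expr), bundle$expr,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(exprDf, file.path(dir, "expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$pairing, file.path(dir, "pairing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
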