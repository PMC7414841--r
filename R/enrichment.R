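# Local functional enrichment (Fisher / EASE), significance filtering,
# enrichment-map construction and per-drug perturbation profiling.

#' Over-representation test of a query gene set against term sets
#'
#' One-sided hypergeometric (Fisher exact) over-representation test of
#' \code{query} in every term, against a fixed background universe.  The
#' EASE variant recomputes the tail after removing one overlapping gene
#' (overlap - 1, floored at 0) — a deliberately conservative penalty for
#' small overlaps.  Both p-values are always reported; \code{mode}
#' selects which one populates \code{p} and the \code{ease_score}
#' (-log10 p).  Optionally a Benjamini-Hochberg adjusted column is added;
#' the default filtering path (see \code{\link{filterSignificant}}) uses
#' raw p-values.
#'
#' @param query character vector of genes; members outside the
#'   background are dropped with a message.
#' @param terms named list of character vectors; each term is
#'   intersected with the background.
#' @param background character vector, the gene universe.
#' @param mode \code{"fisher"} (default) or \code{"ease"}.
#' @param adjust add a BH-adjusted \code{p_adjusted} column (default
#'   FALSE).
#' @return \code{data.frame}, one row per term: \code{term_id},
#'   \code{term_name}, \code{overlap_count}, \code{query_size},
#'   \code{term_size}, \code{background_size}, \code{fold_enrichment},
#'   \code{p_fisher}, \code{p_ease}, \code{p}, \code{ease_score},
#'   \code{overlap_genes} (comma-separated).
#' @export
fisherEnrichment <- function(query, terms, background,
                             mode = c("fisher", "ease"),
                             adjust = FALSE) {
  mode <- match.arg(mode)
  background <- unique(background)
  B <- length(background)
  if (B == 0) stop("empty background universe")
  stopifnot(is.list(terms), length(terms) >= 1, !is.null(names(terms)))
  q <- intersect(unique(query), background)
  nDropped <- length(unique(query)) - length(q)
  if (nDropped > 0)
    logMsg(nDropped, " query gene(s) outside the background, dropped")
  if (length(q) == 0) stop("no query gene maps to the background")
  rows <- lapply(names(terms), function(id) {
    t <- intersect(unique(terms[[id]]), background)
    ovGenes <- intersect(q, t)
    ov <- length(ovGenes)
    nt <- length(t)
    pFisher <- stats::phyper(ov - 1L, nt, B - nt, length(q),
                             lower.tail = FALSE)
    ovE <- max(ov - 1L, 0L)
    pEase <- stats::phyper(ovE - 1L, nt, B - nt, length(q),
                           lower.tail = FALSE)
    fe <- if (ov == 0 || nt == 0) 0 else (ov / length(q)) / (nt / B)
    data.frame(
      term_id = id,
      term_name = attr(terms[[id]], "description") %||% id,
      overlap_count = ov, query_size = length(q), term_size = nt,
      background_size = B, fold_enrichment = fe,
      p_fisher = pFisher, p_ease = pEase,
      p = if (mode == "fisher") pFisher else pEase,
      ease_score = -log10(if (mode == "fisher") pFisher else pEase),
      overlap_genes = paste(sort(ovGenes), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Filter enrichment results on the significance triple
#'
#' Keeps a term iff p < 0.01, overlap count > 3, and fold enrichment
#' > 1.5 — all strict inequalities.
#'
#' @param results \code{data.frame} from \code{\link{fisherEnrichment}}
#'   (needs columns \code{p}, \code{overlap_count},
#'   \code{fold_enrichment}).
#' @param pMax,minCount,minFoldEnrichment the three strict bounds.
#' @return the filtered \code{data.frame}.
#' @export
filterSignificant <- function(results, pMax = 0.01, minCount = 3L,
                              minFoldEnrichment = 1.5) {
  keep <- results$p < pMax & results$overlap_count > minCount &
    results$fold_enrichment > minFoldEnrichment
  results[keep, , drop = FALSE]
}

#' Build an enrichment map from term gene sets
#'
#' Gene-set similarity graph: one node per term, an undirected edge
#' between two terms whenever their Jaccard coefficient
#' |A intersect B| / |A union B| strictly exceeds the cutoff (default
#' 0.1, i.e. "overlap by more than 10 percent").
#'
#' @param termSets named list of character vectors.
#' @param jaccardCutoff strict edge threshold in [0, 1).
#' @return an \linkS4class{EnrichmentMap}.
#' @export
buildEnrichmentMap <- function(termSets, jaccardCutoff = 0.1) {
  stopifnot(is.list(termSets), length(termSets) >= 1,
            !is.null(names(termSets)))
  ids <- names(termSets)
  sets <- lapply(termSets, unique)
  n <- length(ids)
  ea <- character(0); eb <- character(0); jc <- numeric(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        inter <- length(intersect(sets[[i]], sets[[j]]))
        if (inter == 0) next
        jac <- inter / length(union(sets[[i]], sets[[j]]))
        if (jac > jaccardCutoff) {
          ea <- c(ea, ids[i]); eb <- c(eb, ids[j]); jc <- c(jc, jac)
        }
      }
    }
  }
  edgeTable <- data.frame(term_a = ea, term_b = eb, jaccard = jc,
                          stringsAsFactors = FALSE)
  nodeTable <- data.frame(term_id = ids, size = lengths(sets),
                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edgeTable[, 1:2], directed = FALSE,
                                     vertices = nodeTable["term_id"])
  lccSize <- if (n == 0) 0L else max(igraph::components(g)$csize)
  new("EnrichmentMap", termSets = sets, nodeTable = nodeTable,
      edgeTable = edgeTable, jaccardCutoff = jaccardCutoff,
      lccSize = as.integer(lccSize))
}

#' Perturbation profile of a drug over an enrichment map
#'
#' For every map node (term gene set), computes the proximity z of the
#' drug's targets to the node's genes with the same degree-matched null
#' used for disease and pathway proximity; a node is perturbed when
#' z <= -1.282 (probable proximity or stronger).  Nodes whose proximity
#' computation fails or is degenerate are logged and excluded from the
#' denominator.
#'
#' @param graph undirected \code{igraph}.
#' @param drugTargets character vector of target genes.
#' @param map \linkS4class{EnrichmentMap}.
#' @param binning \linkS4class{DegreeBins}.
#' @param nRandom null draws per node.
#' @param rngSeed master seed; per-node substreams derived from it.
#' @param drugId label stored in the profile.
#' @param zThreshold perturbation threshold (default -1.282).
#' @return a \linkS4class{PerturbationProfile}.
#' @export
perturbationProfile <- function(graph, drugTargets, map, binning,
                                nRandom = 1000L, rngSeed = NULL,
                                drugId = "drug", zThreshold = -1.282) {
  stopifnot(is(map, "EnrichmentMap"))
  ids <- names(map@termSets)
  if (length(ids) == 0) stop("empty enrichment map")
  rows <- lapply(ids, function(id) {
    nodeSeed <- if (is.null(rngSeed)) NULL else deriveSeed(rngSeed, id)
    res <- tryCatch(
      proximityZ(graph, map@termSets[[id]], drugTargets, binning,
                 nRandom = nRandom, rngSeed = nodeSeed),
      error = function(e) conditionMessage(e),
      warning = function(w) "degenerate null")
    if (is.character(res)) {
      logMsg("map node ", id, " excluded: ", res)
      return(data.frame(term_id = id, d_c = NA_real_, z = NA_real_,
                        p_one_sided = NA_real_, perturbed = NA,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    data.frame(term_id = id, d_c = res@dC, z = res@z,
               p_one_sided = res@pOneSided,
               perturbed = res@z <= zThreshold,
               degenerate = res@degenerate, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  usable <- !tab$degenerate & !is.na(tab$z)
  nNodes <- sum(usable)
  nPert <- sum(tab$perturbed[usable])
  new("PerturbationProfile", drugId = drugId, nodeTable = tab,
      nPerturbed = as.integer(nPert), nNodes = as.integer(nNodes),
      ratio = if (nNodes == 0) 0 else nPert / nNodes)
}
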