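#' Load an interactome from a two-column edge list
#'
#' Reads a tab- (or whitespace-) separated edge list of gene symbols into a
#' simple undirected \code{igraph}.  Self-loops and duplicate edges
#' (including reversed duplicates) are collapsed silently, with counts
#' reported through \code{message()}: the proximity and module-detection
#' maths assume a simple graph.  Lines starting with \code{#} are comments.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator; \code{NULL} (default) splits on any
#'   run of spaces/tabs.
#' @return an undirected simple \code{igraph} whose vertex names are the
#'   gene symbols (treated as case-sensitive opaque strings).
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "B\tB", "B\tC"), f)
#' g <- loadEdgeList(f)
#' igraph::vcount(g)  # 3
#' @export
loadEdgeList <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty graph: no edges in ", path)
  parts <- if (is.null(delimiter)) {
    strsplit(trimws(lines), "[ \t]+")
  } else {
    strsplit(lines, delimiter, fixed = TRUE)
  }
  nf <- lengths(parts)
  if (any(nf < 2)) {
    bad <- lineNo[which(nf < 2)[1]]
    stop("malformed edge list line ", bad, " in ", path,
         ": fewer than 2 fields")
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  nSelf <- sum(a == b)
  ok <- a != b
  a <- a[ok]; b <- b[ok]
  # canonical unordered pair for dedup (reversed duplicates included)
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key)
  nDup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  if (length(a) == 0) stop("empty graph: only self-loops in ", path)
  if (nSelf > 0 || nDup > 0)
    logMsg("dropped ", nSelf, " self-loop(s) and ", nDup,
           " duplicate edge(s) while loading ", basename(path))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE)
  logMsg("loaded interactome: ", igraph::vcount(g), " nodes, ",
         igraph::ecount(g), " edges")
  g
}

#' Decompose a gene list over the interactome into LCC / small / isolated
#'
#' Restricts \code{genes} to the graph, takes the induced subgraph, and
#' partitions the mapped genes into the largest connected component, the
#' members of smaller components of size >= 2 ("paired off"), and isolated
#' genes.  Genes absent from the graph are reported as \code{unmapped},
#' never an error.
#'
#' @param graph undirected \code{igraph}.
#' @param genes character vector of gene symbols.
#' @return an \linkS4class{LccDecomposition}.
#' @export
decomposeLcc <- function(graph, genes) {
  genes <- unique(genes)
  nodes <- igraph::V(graph)$name
  mapped <- intersect(genes, nodes)
  unmapped <- setdiff(genes, nodes)
  if (length(mapped) == 0) {
    return(new("LccDecomposition", lcc = character(0), small = character(0),
               isolated = character(0), unmapped = unmapped))
  }
  sub <- igraph::induced_subgraph(graph, mapped)
  comp <- igraph::components(sub)
  nm <- igraph::V(sub)$name
  sizes <- comp$csize[comp$membership]
  # deterministic LCC pick on ties: the component containing the
  # lexicographically smallest gene among the maximal ones
  maxSize <- max(comp$csize)
  maxComps <- which(comp$csize == maxSize)
  if (length(maxComps) > 1) {
    firstGene <- vapply(maxComps, function(ci) min(nm[comp$membership == ci]),
                        character(1))
    lccComp <- maxComps[order(firstGene)[1]]
  } else {
    lccComp <- maxComps
  }
  lcc <- nm[comp$membership == lccComp]
  isolated <- setdiff(nm[sizes == 1], lcc)
  small <- setdiff(nm[sizes >= 2], lcc)
  new("LccDecomposition", lcc = lcc, small = small,
      isolated = isolated, unmapped = unmapped)
}

#' Build ascending degree bins for degree-matched sampling
#'
#' Greedy binning of all graph nodes by degree: walk degree values from
#' lowest to highest, accumulating whole degree classes, and close a bin
#' once it holds at least \code{minBinSize} nodes.  A trailing undersized
#' bin is merged into its predecessor, so every bin meets the minimum
#' (except when the whole graph is smaller than one bin).  The default of
#' 100 follows the published closest-proximity protocol; small synthetic
#' graphs simply fall back to fewer, broader bins.
#'
#' @param graph undirected \code{igraph}.
#' @param minBinSize positive integer, minimum nodes per bin.
#' @return a \linkS4class{DegreeBins}.
#' @export
buildDegreeBins <- function(graph, minBinSize = 100L) {
  minBinSize <- as.integer(minBinSize)
  if (minBinSize < 1) stop("minBinSize must be >= 1")
  deg <- igraph::degree(graph)
  n <- length(deg)
  if (minBinSize > n)
    stop("minBinSize (", minBinSize, ") exceeds node count (", n, ")")
  degVals <- sort(unique(deg))
  bins <- list(); lo <- integer(0); hi <- integer(0)
  cur <- character(0); curLo <- NA_integer_
  for (d in degVals) {
    nodes_d <- names(deg)[deg == d]
    if (length(cur) == 0) curLo <- d
    cur <- c(cur, nodes_d)
    if (length(cur) >= minBinSize) {
      bins[[length(bins) + 1L]] <- cur
      lo <- c(lo, curLo); hi <- c(hi, d)
      cur <- character(0)
    }
  }
  if (length(cur) > 0) {
    if (length(bins) == 0) {
      bins[[1L]] <- cur
      lo <- curLo; hi <- degVals[length(degVals)]
    } else {
      k <- length(bins)
      bins[[k]] <- c(bins[[k]], cur)
      hi[k] <- degVals[length(degVals)]
    }
  }
  binOf <- integer(n)
  names(binOf) <- names(deg)
  for (i in seq_along(bins)) binOf[bins[[i]]] <- i
  new("DegreeBins", minBinSize = minBinSize, bins = bins,
      degreeLo = as.integer(lo), degreeHi = as.integer(hi), binOf = binOf)
}

#' Draw a degree-matched random gene set
#'
#' For every gene of \code{reference}, draws one node uniformly at random,
#' without replacement, from that gene's degree bin — producing a random
#' set of the same size and degree profile as the reference, the null
#' model behind all proximity z-scores.
#'
#' @param graph undirected \code{igraph} (used only to verify mapping).
#' @param binning \linkS4class{DegreeBins} built on \code{graph}.
#' @param reference character vector of genes, all present in the graph.
#' @param rngSeed optional integer seed; the draw is deterministic given
#'   the seed.
#' @return character vector of sampled genes, \code{length(reference)}.
#' @export
sampleDegreeMatched <- function(graph, binning, reference, rngSeed = NULL) {
  stopifnot(is(binning, "DegreeBins"))
  reference <- as.character(reference)
  missing <- setdiff(reference, names(binning@binOf))
  if (length(missing) > 0)
    stop("reference genes not in the graph/binning: ",
         paste(utils::head(missing, 5), collapse = ", "))
  refBins <- binning@binOf[reference]
  need <- table(refBins)
  withSeed(rngSeed, {
    out <- character(0)
    for (b in names(need)) {
      pool <- binning@bins[[as.integer(b)]]
      k <- as.integer(need[[b]])
      if (k > length(pool))
        stop("degree bin ", b, " exhausted (", k, " needed, ",
             length(pool), " available); rebuild with a larger minBinSize")
      out <- c(out, sample(pool, k, replace = FALSE))
    }
    out
  })
}
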