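# DIAMOnD: iterative disease-module growth by connectivity significance.
# At each step the candidate whose links to the current module are most
# surprising under a hypergeometric null is absorbed into the module.

# Internal weighted hypergeometric tail.  ksSeed/s0Seed carry the seed
# portion of the links/module so alpha > 1 can up-weight seed evidence
# consistently (links, degree, module size and universe all inflated by
# (alpha - 1) per seed link / seed gene); at alpha = 1 this is the plain
# hypergeometric upper tail.
diamondPvalue <- function(N, s0, k, ks, ksSeed = ks, s0Seed = s0,
                          alpha = 1) {
  w <- alpha - 1
  ksEff <- ks + w * ksSeed
  kEff <- k + w * ksSeed
  s0Eff <- s0 + w * s0Seed
  nEff <- N + w * s0Seed
  stats::phyper(ksEff - 1, s0Eff, nEff - s0Eff, kEff,
                lower.tail = FALSE)
}

#' Connectivity p-value of a candidate node
#'
#' Probability that a node of degree \code{k} has \code{ks} or more links
#' into a module of \code{s0} genes, when its neighbours are drawn
#' uniformly from a network of \code{N} nodes: the hypergeometric upper
#' tail \eqn{\sum_{i=ks}^{\min(k,s0)} \binom{s0}{i}\binom{N-s0}{k-i} /
#' \binom{N}{k}}.  With \code{alpha > 1}, module links are treated as
#' seed links and up-weighted by \code{alpha} (link count, degree, module
#' size and universe each inflated by \code{alpha - 1} per seed
#' link/gene), following the module-detection algorithm's seed-weighting
#' convention.
#'
#' @param N network size (node count).
#' @param s0 current module size.
#' @param k candidate degree.
#' @param ks candidate links into the module.
#' @param alpha seed weight, integer >= 1 (default 1: unweighted).
#' @return p-value in (0, 1]; vectorized over \code{k}/\code{ks}.
#' @examples
#' connectivityPvalue(N = 10, s0 = 3, k = 4, ks = 2)  # 1/3
#' @export
connectivityPvalue <- function(N, s0, k, ks, alpha = 1L) {
  if (alpha < 1) stop("alpha must be >= 1")
  if (any(ks < 0) || any(ks > pmin(k, s0)) || s0 > N || any(k > N - 1))
    stop("argument bounds violated: need 0 <= ks <= min(k, s0) and k < N >= s0")
  diamondPvalue(N, s0, k, ks, alpha = alpha)
}

#' Rank candidate disease genes by connectivity significance (DIAMOnD)
#'
#' Starting from the seed genes, repeatedly evaluates every node adjacent
#' to the current module (nodes with no module link cannot be selected),
#' computes each candidate's connectivity p-value against the full
#' network (\code{N} stays the total node count throughout), and adds the
#' candidate with the smallest p-value; ties are broken deterministically
#' by the lexicographically smallest gene symbol.  The ranking order is
#' the module-membership priority of every non-seed gene.
#'
#' @param graph undirected \code{igraph}.
#' @param seeds character vector of seed genes; unmapped seeds are
#'   dropped with a message.
#' @param nIterations number of genes to rank.  If the reachable
#'   candidate pool is exhausted earlier the ranking is truncated with a
#'   warning.
#' @param alpha seed weight (>= 1), default 1.
#' @return \code{data.frame} with columns \code{iteration}, \code{gene},
#'   \code{degree_k}, \code{seed_links_ks} (links into the module at
#'   selection time), \code{p_conn}.
#' @export
runDiamond <- function(graph, seeds, nIterations, alpha = 1L) {
  nIterations <- as.integer(nIterations)
  if (nIterations < 1) stop("nIterations must be >= 1")
  nodes <- igraph::V(graph)$name
  N <- length(nodes)
  seedIdx <- which(nodes %in% seeds)
  nUnmapped <- length(setdiff(unique(seeds), nodes))
  if (nUnmapped > 0)
    logMsg(nUnmapped, " seed gene(s) absent from the graph, dropped")
  if (length(seedIdx) == 0) stop("no seed gene maps to the graph")
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  deg <- lengths(adj)
  inModule <- logical(N)
  inModule[seedIdx] <- TRUE
  ks <- integer(N)
  ksSeed <- integer(N)
  for (s in seedIdx) {
    ks[adj[[s]]] <- ks[adj[[s]]] + 1L
    ksSeed[adj[[s]]] <- ksSeed[adj[[s]]] + 1L
  }
  s0 <- length(seedIdx)
  s0Seed <- s0
  out <- vector("list", nIterations)
  for (it in seq_len(nIterations)) {
    cand <- which(!inModule & ks > 0L)
    if (length(cand) == 0) {
      warning("candidate pool exhausted after ", it - 1L,
              " iterations (requested ", nIterations, ")")
      out <- out[seq_len(it - 1L)]
      break
    }
    p <- diamondPvalue(N, s0, deg[cand], ks[cand], ksSeed[cand],
                       s0Seed, alpha)
    best <- cand[order(p, nodes[cand])[1L]]
    out[[it]] <- data.frame(
      iteration = it, gene = nodes[best], degree_k = deg[best],
      seed_links_ks = ks[best], p_conn = p[which(cand == best)],
      stringsAsFactors = FALSE)
    inModule[best] <- TRUE
    s0 <- s0 + 1L
    nb <- adj[[best]]
    ks[nb] <- ks[nb] + 1L
  }
  do.call(rbind, out)
}

#' Assemble a disease module from seeds and a DIAMOnD ranking
#'
#' Takes the union of the mapped seed genes and the first \code{nKeep}
#' ranked genes, extracts the largest connected component of the induced
#' subgraph, and reports which seeds outside the seed-only LCC were
#' reconnected into the module LCC by the added genes.
#'
#' @param graph undirected \code{igraph}.
#' @param seeds character vector of seed genes.
#' @param ranking a \code{data.frame} from \code{\link{runDiamond}} (or a
#'   character vector of ranked genes).
#' @param nKeep how many ranked genes to retain (0 reproduces the
#'   seed-only module).
#' @return a \linkS4class{DiseaseModule}.
#' @export
assembleModule <- function(graph, seeds, ranking, nKeep) {
  genes <- if (is.data.frame(ranking)) ranking$gene else as.character(ranking)
  nKeep <- as.integer(nKeep)
  if (nKeep < 0 || nKeep > length(genes))
    stop("nKeep must be between 0 and the ranking length (",
         length(genes), ")")
  nodes <- igraph::V(graph)$name
  seedsMapped <- intersect(unique(seeds), nodes)
  kept <- genes[seq_len(nKeep)]
  members <- union(seedsMapped, kept)
  moduleLcc <- lccMembers(decomposeLcc(graph, members))
  seedLcc <- lccMembers(decomposeLcc(graph, seedsMapped))
  reconnected <- setdiff(intersect(seedsMapped, moduleLcc), seedLcc)
  new("DiseaseModule", seedGenes = seedsMapped, diamondGenes = kept,
      members = members, moduleLcc = moduleLcc,
      reconnectedIsolatedSeeds = reconnected)
}
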