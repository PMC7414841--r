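# Attack-vulnerability analysis: evolution of the largest connected
# component under random node failure or targeted removal.

# Trajectory of LCC size under a removal order, computed by reverse
# percolation: nodes are re-added in reverse order with a union-find,
# so the whole n-step trajectory costs near-linear time instead of n
# component recomputations.
percolationTrajectory <- function(adjIdx, removalOrder) {
  n <- length(adjIdx)
  parent <- seq_len(n)
  sz <- integer(n)
  active <- logical(n)
  lccAfter <- integer(n + 1L)  # [k+1] = LCC size after k removals
  maxComp <- 0L
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  addOrder <- rev(removalOrder)
  for (j in seq_len(n)) {
    v <- addOrder[j]
    active[v] <- TRUE
    sz[v] <- 1L
    for (u in adjIdx[[v]]) {
      if (active[u]) {
        ru <- find(u)
        rv <- find(v)
        if (ru != rv) {
          if (sz[ru] < sz[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
          parent[rv] <- ru
          sz[ru] <- sz[ru] + sz[rv]
        }
      }
    }
    rv <- find(v)
    if (sz[rv] > maxComp) maxComp <- sz[rv]
    lccAfter[n - j + 1L] <- maxComp
  }
  lccAfter
}

#' LCC decay under random node failure
#'
#' Each simulation deletes the nodes one at a time in a uniformly random
#' order and records the size of the largest connected component after
#' every deletion, normalized by the intact LCC size.  The returned
#' curve is the mean over simulations on the exact grid of one point per
#' removed node; per-run trajectories are retained in the object.
#'
#' @param network undirected \code{igraph}.
#' @param nSim number of random removal orders (1000 in the published
#'   protocol).
#' @param rngSeed optional integer seed; curves are reproducible
#'   bit-for-bit given the seed.
#' @return an \linkS4class{AttackCurve} with \code{mode = "random"}.
#' @export
randomFailureCurve <- function(network, nSim = 1000L, rngSeed = NULL) {
  n <- igraph::vcount(network)
  if (n == 0) stop("empty network")
  nSim <- as.integer(nSim)
  adjIdx <- lapply(igraph::as_adj_list(network), as.integer)
  intactLcc <- max(igraph::components(network)$csize)
  runs <- withSeed(rngSeed, {
    t(vapply(seq_len(nSim), function(i) {
      percolationTrajectory(adjIdx, sample.int(n)) / intactLcc
    }, numeric(n + 1L)))
  })
  new("AttackCurve", nNodes = as.integer(n),
      fractionsRemoved = (0:n) / n,
      lccFraction = colMeans(runs), runs = runs,
      nSim = nSim, mode = "random")
}

#' Remaining LCC after simultaneous targeted removal
#'
#' Removes the given nodes at once (nodes absent from the network are
#' ignored with a message) and returns the LCC size of the remainder as
#' a fraction of the intact LCC.
#'
#' @param network undirected \code{igraph}.
#' @param nodeSet character vector of node names to delete.
#' @return numeric in [0, 1].
#' @export
targetedAttack <- function(network, nodeSet) {
  nodes <- igraph::V(network)$name
  hit <- intersect(unique(nodeSet), nodes)
  absent <- length(unique(nodeSet)) - length(hit)
  if (absent > 0)
    logMsg(absent, " attack node(s) absent from the network, ignored")
  intactLcc <- max(igraph::components(network)$csize)
  if (length(hit) == length(nodes)) return(0)
  rest <- igraph::delete_vertices(network, hit)
  max(igraph::components(rest)$csize) / intactLcc
}

#' LCC trajectory under sequential targeted removal
#'
#' Deletes the given nodes one at a time in the supplied order and
#' records the normalized LCC after each deletion — the sequential
#' counterpart of \code{\link{targetedAttack}}.
#'
#' @param network undirected \code{igraph}.
#' @param nodeOrder character vector, removal order; names absent from
#'   the network are skipped with a message.
#' @return an \linkS4class{AttackCurve} with \code{mode = "targeted"}
#'   whose grid stops after the last listed node.
#' @export
targetedAttackCurve <- function(network, nodeOrder) {
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  ord <- unique(nodeOrder)
  keep <- ord %in% nodes
  if (any(!keep))
    logMsg(sum(!keep), " attack node(s) absent from the network, skipped")
  ord <- ord[keep]
  adjIdx <- lapply(igraph::as_adj_list(network), as.integer)
  intactLcc <- max(igraph::components(network)$csize)
  # complete the order with the surviving nodes so the reverse
  # percolation runs over the full graph, then truncate the trajectory
  full <- c(match(ord, nodes), setdiff(seq_len(n), match(ord, nodes)))
  traj <- percolationTrajectory(adjIdx, full) / intactLcc
  k <- length(ord)
  new("AttackCurve", nNodes = as.integer(n),
      fractionsRemoved = (0:k) / n,
      lccFraction = traj[seq_len(k + 1L)],
      runs = matrix(numeric(0), 0, 0),
      nSim = 1L, mode = "targeted")
}

#' Half-collapse fraction of an attack curve
#'
#' Smallest fraction of removed nodes at which the mean LCC fraction
#' falls to one half or below.  Returns 1.0 with a warning when the
#' curve never crosses 0.5.
#'
#' @param curve an \linkS4class{AttackCurve}.
#' @return numeric fraction in [0, 1].
#' @export
halfCollapseFraction <- function(curve) {
  stopifnot(is(curve, "AttackCurve"))
  idx <- which(curve@lccFraction <= 0.5)
  if (length(idx) == 0) {
    warning("curve never falls to half of the intact LCC; returning 1.0")
    return(1.0)
  }
  curve@fractionsRemoved[idx[1]]
}
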