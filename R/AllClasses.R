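#' @import methods
NULL

#' Largest-connected-component decomposition of a gene list
#'
#' Partition of the genes of interest, restricted to the interactome, into
#' the largest connected component of their induced subgraph, smaller
#' connected components (size >= 2), and isolated genes.  Genes absent from
#' the graph are kept separately in \code{unmapped}.
#'
#' @slot lcc character, members of the largest connected component.
#' @slot small character, members of non-LCC components of size >= 2.
#' @slot isolated character, mapped genes with no mapped neighbour.
#' @slot unmapped character, genes not present in the graph.
#' @exportClass LccDecomposition
setClass("LccDecomposition",
  representation(
    lcc = "character",
    small = "character",
    isolated = "character",
    unmapped = "character"
  )
)

setValidity("LccDecomposition", function(object) {
  cats <- list(object@lcc, object@small, object@isolated)
  all_mapped <- unlist(cats)
  if (anyDuplicated(all_mapped) > 0)
    return("lcc/small/isolated must be disjoint")
  if (length(intersect(all_mapped, object@unmapped)) > 0)
    return("unmapped genes cannot also be mapped")
  TRUE
})

#' Degree bins for degree-preserving node sampling
#'
#' Nodes of the interactome grouped into contiguous ascending degree
#' intervals, each holding at least \code{minBinSize} nodes (except where a
#' trailing undersized bin was merged into its predecessor).  Used to draw
#' random node sets with the same degree profile as an observed set.
#'
#' @slot minBinSize integer(1), requested minimum bin occupancy.
#' @slot bins list of character vectors, the nodes of each bin.
#' @slot degreeLo,degreeHi integer, inclusive degree bounds per bin.
#' @slot binOf named integer, bin index of every node.
#' @exportClass DegreeBins
setClass("DegreeBins",
  representation(
    minBinSize = "integer",
    bins = "list",
    degreeLo = "integer",
    degreeHi = "integer",
    binOf = "integer"
  )
)

setValidity("DegreeBins", function(object) {
  nb <- length(object@bins)
  if (length(object@degreeLo) != nb || length(object@degreeHi) != nb)
    return("degree bounds must match number of bins")
  if (nb > 1 && any(diff(object@degreeLo) <= 0))
    return("degree intervals must be sorted ascending and disjoint")
  if (any(object@degreeHi < object@degreeLo))
    return("each degree interval must be non-empty")
  if (sum(lengths(object@bins)) != length(object@binOf))
    return("bins must partition the node set")
  TRUE
})

#' Network proximity of a target set to a gene set
#'
#' Result of comparing the observed closest distance \eqn{d_c} between a
#' target set and a gene set with a reference distribution of distances
#' between degree-matched random node sets.
#'
#' @slot dC observed closest distance (mean over targets of the shortest
#'   path to the nearest gene-set member).
#' @slot nullMean,nullSd mean and standard deviation of the reference
#'   distribution.
#' @slot z standardized distance \code{(dC - nullMean)/nullSd}; \code{NA}
#'   when the null is degenerate.
#' @slot pOneSided lower-tail normal probability of \code{z}.
#' @slot pEmpirical empirical lower-tail rank of \code{dC} in the null
#'   (diagnostic).
#' @slot nRandom number of null draws.
#' @slot nTargetsUsed number of mapped, connected targets entering
#'   \code{dC}.
#' @slot classification one of \code{"significant"}, \code{"probable"},
#'   \code{"not_proximal"}.
#' @slot degenerate TRUE when the null standard deviation was zero.
#' @exportClass ProximityResult
setClass("ProximityResult",
  representation(
    dC = "numeric",
    nullMean = "numeric",
    nullSd = "numeric",
    z = "numeric",
    pOneSided = "numeric",
    pEmpirical = "numeric",
    nRandom = "integer",
    nTargetsUsed = "integer",
    classification = "character",
    degenerate = "logical"
  )
)

setValidity("ProximityResult", function(object) {
  if (object@dC < 0) return("dC must be non-negative")
  if (!object@classification %in%
      c("significant", "probable", "not_proximal"))
    return("unknown classification")
  if (!object@degenerate && is.finite(object@z) && object@nullSd > 0) {
    if (abs(object@z - (object@dC - object@nullMean) / object@nullSd) > 1e-8)
      return("z inconsistent with dC, nullMean, nullSd")
  }
  TRUE
})

#' Disease module assembled from seeds and DIAMOnD genes
#'
#' @slot seedGenes character, mapped seed genes.
#' @slot diamondGenes character, ranked genes retained from the DIAMOnD
#'   iteration, in selection order.
#' @slot members union of seeds and retained DIAMOnD genes.
#' @slot moduleLcc largest connected component of the subgraph induced by
#'   \code{members}.
#' @slot reconnectedIsolatedSeeds seeds outside the seed-only LCC that the
#'   DIAMOnD genes reconnected into \code{moduleLcc}.
#' @exportClass DiseaseModule
setClass("DiseaseModule",
  representation(
    seedGenes = "character",
    diamondGenes = "character",
    members = "character",
    moduleLcc = "character",
    reconnectedIsolatedSeeds = "character"
  )
)

setValidity("DiseaseModule", function(object) {
  if (!setequal(object@members,
                union(object@seedGenes, object@diamondGenes)))
    return("members must equal seeds + DIAMOnD genes")
  if (!all(object@moduleLcc %in% object@members))
    return("moduleLcc must be a subset of members")
  if (!all(object@reconnectedIsolatedSeeds %in% object@seedGenes))
    return("reconnected seeds must be seeds")
  TRUE
})

#' Enrichment map: gene-set similarity graph
#'
#' Nodes are gene sets (enriched terms); an undirected edge joins two
#' nodes whenever their Jaccard overlap exceeds the cutoff.
#'
#' @slot termSets named list of character vectors, the node gene sets.
#' @slot nodeTable data.frame with columns \code{term_id}, \code{size}.
#' @slot edgeTable data.frame with columns \code{term_a}, \code{term_b},
#'   \code{jaccard}.
#' @slot jaccardCutoff numeric(1), strict lower bound for an edge.
#' @slot lccSize integer(1), node count of the map's largest component.
#' @exportClass EnrichmentMap
setClass("EnrichmentMap",
  representation(
    termSets = "list",
    nodeTable = "data.frame",
    edgeTable = "data.frame",
    jaccardCutoff = "numeric",
    lccSize = "integer"
  )
)

setValidity("EnrichmentMap", function(object) {
  if (is.null(names(object@termSets)))
    return("termSets must be named")
  if (nrow(object@edgeTable) > 0) {
    if (any(object@edgeTable$jaccard <= object@jaccardCutoff))
      return("all edges must exceed the Jaccard cutoff")
    if (any(object@edgeTable$term_a == object@edgeTable$term_b))
      return("no self-edges allowed")
  }
  if (object@lccSize > nrow(object@nodeTable))
    return("lccSize cannot exceed node count")
  TRUE
})

#' Per-drug perturbation profile over an enrichment map
#'
#' One proximity z per map node; a node counts as perturbed when its z is
#' at or below the probable-proximity threshold (-1.282).
#'
#' @slot drugId character(1).
#' @slot nodeTable data.frame with columns \code{term_id}, \code{d_c},
#'   \code{z}, \code{p_one_sided}, \code{perturbed}, \code{degenerate}.
#' @slot nPerturbed,nNodes integer counts (degenerate nodes excluded from
#'   the denominator).
#' @slot ratio nPerturbed / nNodes.
#' @exportClass PerturbationProfile
setClass("PerturbationProfile",
  representation(
    drugId = "character",
    nodeTable = "data.frame",
    nPerturbed = "integer",
    nNodes = "integer",
    ratio = "numeric"
  )
)

setValidity("PerturbationProfile", function(object) {
  if (object@nNodes > 0 &&
      abs(object@ratio - object@nPerturbed / object@nNodes) > 1e-12)
    return("ratio inconsistent with counts")
  if (object@nPerturbed > object@nNodes)
    return("nPerturbed cannot exceed nNodes")
  TRUE
})

#' Attack-vulnerability curve
#'
#' Evolution of the largest connected component under node removal,
#' normalized by the intact LCC size.  For \code{mode = "random"} the
#' per-run trajectories of every simulation are retained alongside their
#' mean.
#'
#' @slot nNodes integer(1), node count of the intact network.
#' @slot fractionsRemoved numeric grid in [0, 1] (one point per removed
#'   node, starting at 0).
#' @slot lccFraction mean LCC fraction at each grid point.
#' @slot runs numeric matrix (nSim x grid) of per-run trajectories, or a
#'   0-row matrix in targeted mode.
#' @slot nSim integer(1), number of simulations.
#' @slot mode \code{"random"} or \code{"targeted"}.
#' @exportClass AttackCurve
setClass("AttackCurve",
  representation(
    nNodes = "integer",
    fractionsRemoved = "numeric",
    lccFraction = "numeric",
    runs = "matrix",
    nSim = "integer",
    mode = "character"
  )
)

setValidity("AttackCurve", function(object) {
  if (length(object@fractionsRemoved) != length(object@lccFraction))
    return("grid and curve lengths differ")
  if (abs(object@lccFraction[1] - 1) > 1e-12)
    return("curve must start at 1 with nothing removed")
  if (any(object@lccFraction < -1e-12 | object@lccFraction > 1 + 1e-12))
    return("LCC fractions must lie in [0, 1]")
  if (is.unsorted(object@fractionsRemoved))
    return("fractionsRemoved must be increasing")
  if (!object@mode %in% c("random", "targeted"))
    return("unknown mode")
  TRUE
})
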