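# Accessor generics: user code should read slots through these, not with @.

#' Accessors for netmodule result objects
#'
#' Small family of read-only accessors for the S4 containers returned by
#' the package: LCC decompositions, disease modules, proximity results,
#' enrichment maps, perturbation profiles and attack curves.
#'
#' @param x an object of the matching class.
#' @return A character vector of gene symbols, a numeric scalar, or a
#'   \code{data.frame}, depending on the accessor.
#' @name accessors
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C, D - E, F)
#' dec <- decomposeLcc(g, LETTERS[1:6])
#' lccMembers(dec)
#' isolatedMembers(dec)
NULL

#' @rdname accessors
#' @export
setGeneric("lccMembers", function(x) standardGeneric("lccMembers"))
#' @rdname accessors
#' @export
setMethod("lccMembers", "LccDecomposition", function(x) x@lcc)
#' @rdname accessors
#' @export
setMethod("lccMembers", "DiseaseModule", function(x) x@moduleLcc)

#' @rdname accessors
#' @export
setGeneric("smallComponentMembers",
           function(x) standardGeneric("smallComponentMembers"))
#' @rdname accessors
#' @export
setMethod("smallComponentMembers", "LccDecomposition", function(x) x@small)

#' @rdname accessors
#' @export
setGeneric("isolatedMembers", function(x) standardGeneric("isolatedMembers"))
#' @rdname accessors
#' @export
setMethod("isolatedMembers", "LccDecomposition", function(x) x@isolated)

#' @rdname accessors
#' @export
setGeneric("unmappedMembers", function(x) standardGeneric("unmappedMembers"))
#' @rdname accessors
#' @export
setMethod("unmappedMembers", "LccDecomposition", function(x) x@unmapped)

#' @rdname accessors
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))
#' @rdname accessors
#' @export
setMethod("moduleMembers", "DiseaseModule", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))
#' @rdname accessors
#' @export
setMethod("seedGenes", "DiseaseModule", function(x) x@seedGenes)

#' @rdname accessors
#' @export
setGeneric("diamondGenes", function(x) standardGeneric("diamondGenes"))
#' @rdname accessors
#' @export
setMethod("diamondGenes", "DiseaseModule", function(x) x@diamondGenes)

#' @rdname accessors
#' @export
setGeneric("reconnectedSeeds",
           function(x) standardGeneric("reconnectedSeeds"))
#' @rdname accessors
#' @export
setMethod("reconnectedSeeds", "DiseaseModule",
          function(x) x@reconnectedIsolatedSeeds)

#' @rdname accessors
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))
#' @rdname accessors
#' @export
setMethod("zScore", "ProximityResult", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))
#' @rdname accessors
#' @export
setMethod("classification", "ProximityResult", function(x) x@classification)

#' @rdname accessors
#' @export
setGeneric("proximityTable", function(x) standardGeneric("proximityTable"))

#' @rdname accessors
#' @export
setMethod("proximityTable", "ProximityResult", function(x) {
  data.frame(
    d_c = x@dC, null_mean = x@nullMean, null_sd = x@nullSd, z = x@z,
    p_one_sided = x@pOneSided, p_empirical = x@pEmpirical,
    n_random = x@nRandom, n_targets_used = x@nTargetsUsed,
    classification = x@classification, degenerate = x@degenerate,
    stringsAsFactors = FALSE
  )
})

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
#' @rdname accessors
#' @export
setMethod("nodeTable", "EnrichmentMap", function(x) x@nodeTable)
#' @rdname accessors
#' @export
setMethod("nodeTable", "PerturbationProfile", function(x) x@nodeTable)

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setMethod("edgeTable", "EnrichmentMap", function(x) x@edgeTable)

#' @rdname accessors
#' @export
setGeneric("termSets", function(x) standardGeneric("termSets"))
#' @rdname accessors
#' @export
setMethod("termSets", "EnrichmentMap", function(x) x@termSets)

#' @rdname accessors
#' @export
setGeneric("perturbationRatio",
           function(x) standardGeneric("perturbationRatio"))
#' @rdname accessors
#' @export
setMethod("perturbationRatio", "PerturbationProfile", function(x) x@ratio)

#' @rdname accessors
#' @export
setGeneric("attackTable", function(x) standardGeneric("attackTable"))

#' @rdname accessors
#' @export
setMethod("attackTable", "AttackCurve", function(x) {
  data.frame(fraction_removed = x@fractionsRemoved,
             lcc_fraction = x@lccFraction)
})
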