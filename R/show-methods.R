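#' @describeIn LccDecomposition-class Compact category summary.
#' @param object object to display.
#' @export
setMethod("show", "LccDecomposition", function(object) {
  cat("LccDecomposition:",
      length(object@lcc), "in LCC,",
      length(object@small), "in small components,",
      length(object@isolated), "isolated,",
      length(object@unmapped), "unmapped\n")
})

#' @describeIn DegreeBins-class Bin layout summary.
#' @param object object to display.
#' @export
setMethod("show", "DegreeBins", function(object) {
  cat("DegreeBins:", length(object@bins), "bins over",
      length(object@binOf), "nodes (minBinSize =",
      object@minBinSize, ")\n")
  lo <- object@degreeLo
  hi <- object@degreeHi
  for (i in seq_along(object@bins)) {
    cat(sprintf("  bin %d: degree %d-%d, %d nodes\n",
                i, lo[i], hi[i], length(object@bins[[i]])))
  }
})

#' @describeIn ProximityResult-class One-line result summary.
#' @param object object to display.
#' @export
setMethod("show", "ProximityResult", function(object) {
  cat(sprintf(
    "ProximityResult: d_c = %.4g, null %.4g +/- %.4g, z = %.4g (p = %.4g), %s%s\n",
    object@dC, object@nullMean, object@nullSd, object@z,
    object@pOneSided, object@classification,
    if (object@degenerate) " [degenerate null]" else ""))
})

#' @describeIn DiseaseModule-class Membership summary.
#' @param object object to display.
#' @export
setMethod("show", "DiseaseModule", function(object) {
  cat("DiseaseModule:", length(object@members), "members (",
      length(object@seedGenes), "seeds +",
      length(object@diamondGenes), "DIAMOnD genes ); module LCC",
      length(object@moduleLcc), "genes;",
      length(object@reconnectedIsolatedSeeds),
      "isolated seeds reconnected\n")
})

#' @describeIn EnrichmentMap-class Node/edge/LCC summary.
#' @param object object to display.
#' @export
setMethod("show", "EnrichmentMap", function(object) {
  cat("EnrichmentMap:", nrow(object@nodeTable), "nodes,",
      nrow(object@edgeTable), "edges (Jaccard >",
      object@jaccardCutoff, "), LCC", object@lccSize, "nodes\n")
})

#' @describeIn PerturbationProfile-class Perturbation-ratio summary.
#' @param object object to display.
#' @export
setMethod("show", "PerturbationProfile", function(object) {
  cat(sprintf("PerturbationProfile[%s]: %d / %d nodes perturbed (%.1f%%)\n",
              object@drugId, object@nPerturbed, object@nNodes,
              100 * object@ratio))
})

#' @describeIn AttackCurve-class Curve summary.
#' @param object object to display.
#' @export
setMethod("show", "AttackCurve", function(object) {
  cat(sprintf("AttackCurve (%s): %d nodes, %d simulation%s, %d grid points\n",
              object@mode, object@nNodes, object@nSim,
              if (object@nSim == 1) "" else "s",
              length(object@fractionsRemoved)))
})
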