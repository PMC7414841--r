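test_that("backbone edge count follows preferential-attachment arithmetic", {
  sim <- simulateInteractome(nNodes = 1000, attachmentM = 2,
                             moduleSize = 60, moduleDensityBoost = 0,
                             nSeeds = 25, rngSeed = 1)
  expect_equal(igraph::vcount(sim$graph), 1000)
  # n*m - m(m+1)/2 edges, up to one collapsed duplicate
  expect_gte(igraph::ecount(sim$graph), 1997)
  expect_lte(igraph::ecount(sim$graph), 1998)
  expect_true(igraph::is_connected(sim$graph))
  expect_true(all(sim$truth$seed_genes %in% sim$truth$module_genes))
})

test_that("the planted module is denser than background iff boosted", {
  withinDeg <- function(sim) {
    sub <- igraph::induced_subgraph(sim$graph, sim$truth$module_genes)
    mean(igraph::degree(sub))
  }
  boosted <- vapply(1:10, function(s)
    withinDeg(simulateInteractome(600, 2, 50, 0.15, 20, rngSeed = s)),
    numeric(1))
  control <- vapply(1:10, function(s)
    withinDeg(simulateInteractome(600, 2, 50, 0, 20, rngSeed = s)),
    numeric(1))
  expect_true(all(boosted > control))
  # boosted within-module degree far exceeds the backbone's contribution
  expect_gt(mean(boosted), mean(control) + 3)
})

test_that("proximal drugs sit inside the module when dNear = 0", {
  sim <- simulateInteractome(500, 2, 40, 0.15, 15, rngSeed = 4)
  dr <- simulateDrugs(sim$graph, sim$truth, nProximal = 2, nDistal = 2,
                      targetsPerDrug = 4, dNear = 0, rngSeed = 5)
  for (d in names(dr$drugs)[startsWith(names(dr$drugs), "proximal")]) {
    expect_true(all(dr$drugs[[d]] %in% sim$truth$module_genes))
    expect_equal(closestDistance(sim$graph, sim$truth$module_genes,
                                 dr$drugs[[d]])$d_c, 0)
  }
  for (d in names(dr$drugs)[startsWith(names(dr$drugs), "distal")]) {
    expect_gte(closestDistance(sim$graph, sim$truth$module_genes,
                               dr$drugs[[d]])$d_c, 2)
  }
  # singleton target sets are legal
  one <- simulateDrugs(sim$graph, sim$truth, 1, 1, targetsPerDrug = 1,
                       rngSeed = 6)
  expect_length(one$drugs$proximal_01, 1)
})

test_that("gene-set plants respect overlap and size contracts", {
  sim <- simulateInteractome(500, 2, 40, 0.15, 15, rngSeed = 9)
  gs <- simulateGeneSets(sim$graph, sim$truth, nTerms = 10,
                         enrichedFraction = 0.5, overlapFrac = 1,
                         sizeRange = c(10, 30), rngSeed = 2)
  for (id in gs$truth$enriched_terms)
    expect_true(all(gs$sets[[id]] %in% sim$truth$module_genes))
  expect_true(all(lengths(gs$sets) >= 10 & lengths(gs$sets) <= 30))
})

test_that("null terms have approximately uniform enrichment p-values", {
  ps <- unlist(lapply(1:8, function(s) {
    sim <- simulateInteractome(400, 2, 40, 0.15, 15, rngSeed = 700 + s)
    gs <- simulateGeneSets(sim$graph, sim$truth, nTerms = 12,
                           enrichedFraction = 0, overlapFrac = 0.6,
                           rngSeed = 800 + s)
    enr <- fisherEnrichment(sim$truth$module_genes, gs$sets,
                            igraph::V(sim$graph)$name)
    enr$p_fisher
  }))
  # discrete and conservative, so only a coarse calibration bound:
  # small p-values are not over-produced
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps > 0.5), 0.25)
})

test_that("regeneration from the same master seed is byte-identical", {
  d1 <- file.path(tempdir(), "bundleA")
  d2 <- file.path(tempdir(), "bundleB")
  writeBundle(simulateBundle(77, nNodes = 300, moduleSize = 30,
                             nSeeds = 12, nSubjects = 4), d1)
  writeBundle(simulateBundle(77, nNodes = 300, moduleSize = 30,
                             nSeeds = 12, nSubjects = 4), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the interactome
  d3 <- file.path(tempdir(), "bundleC")
  writeBundle(simulateBundle(78, nNodes = 300, moduleSize = 30,
                             nSeeds = 12, nSubjects = 4), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "edges.tsv"))),
    unname(tools::md5sum(file.path(d3, "edges.tsv")))))
})

test_that("bundle files round-trip through the package readers", {
  d <- file.path(tempdir(), "bundleRT")
  b <- simulateBundle(13, nNodes = 300, moduleSize = 30, nSeeds = 12,
                      nSubjects = 4)
  writeBundle(b, d)
  g <- suppressMessages(loadEdgeList(file.path(d, "edges.tsv")))
  expect_equal(igraph::vcount(g), igraph::vcount(b$graph))
  expect_equal(igraph::ecount(g), igraph::ecount(b$graph))
  expect_setequal(readGeneList(file.path(d, "seeds.txt")),
                  b$truth$seed_genes)
  drugs <- readDrugTargets(file.path(d, "drugs.tsv"))
  expect_equal(drugs[order(names(drugs))],
               b$drugs[order(names(b$drugs))])
  sets <- readGmt(file.path(d, "sets.gmt"))
  expect_equal(lapply(sets, as.character),
               lapply(b$sets, as.character))
  expr <- suppressMessages(readExpression(file.path(d, "expr.tsv")))
  expect_equal(dim(expr), dim(b$expr))
  expect_equal(expr[5, 3], b$expr[5, 3], tolerance = 1e-9)
})
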