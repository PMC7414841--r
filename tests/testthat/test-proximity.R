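test_that("closest distance matches hand-worked path-graph cases", {
  g <- pathGraph5()
  r <- closestDistance(g, disease = "A", targets = c("C", "E"))
  expect_equal(r$d_c, 3)            # (2 + 4) / 2
  expect_equal(r$n_targets_used, 2L)
  expect_equal(closestDistance(g, c("A", "E"), "C")$d_c, 2)
  # targets inside the disease set sit at distance zero
  expect_equal(closestDistance(g, c("A", "B"), c("A", "B"))$d_c, 0)
})

test_that("closest distance distinguishes unmapped from disconnected", {
  g <- igraph::make_graph(~ A - B, C - D)
  expect_error(closestDistance(g, "X", "A"), "unmapped")
  expect_error(closestDistance(g, "A", "Y"), "unmapped")
  expect_error(closestDistance(g, "A", "C"), "disconnected")
  # a disconnected target is excluded, not fatal, when another connects
  r <- closestDistance(g, "A", c("B", "C"))
  expect_equal(r$d_c, 1)
  expect_equal(r$n_targets_used, 1L)
})

test_that("closest distance agrees with a Floyd-Warshall oracle on random graphs", {
  for (s in 1:40) {
    g <- randomTestGraph(sample(8:30, 1), runif(1, 0.1, 0.35), seed = s)
    nodes <- igraph::V(g)$name
    S <- sample(nodes, sample(2:5, 1))
    T <- sample(nodes, sample(2:5, 1))
    got <- tryCatch(closestDistance(g, S, T), error = function(e) NULL)
    want <- oracleClosestDistance(g, S, T)
    if (is.null(got)) {
      expect_true(is.nan(want$d_c) || want$n == 0)
    } else {
      expect_identical(got$d_c, want$d_c)
      expect_identical(got$n_targets_used, as.integer(want$n))
    }
  }
})

test_that("d_c is monotone non-increasing as disease genes are added", {
  for (s in 1:15) {
    g <- randomTestGraph(20, 0.25, seed = 200 + s)
    nodes <- igraph::V(g)$name
    S <- sample(nodes, 3)
    T <- sample(nodes, 3)
    d1 <- closestDistance(g, S, T)$d_c
    S2 <- union(S, sample(setdiff(nodes, S), 3))
    d2 <- closestDistance(g, S2, T)$d_c
    expect_lte(d2, d1)
  }
})

test_that("proximity classification thresholds are inclusive", {
  expect_equal(classifyProximity(-1.70), "significant")
  expect_equal(classifyProximity(-1.645), "significant")
  expect_equal(classifyProximity(-1.40), "probable")
  expect_equal(classifyProximity(-1.282), "probable")
  expect_equal(classifyProximity(-1.281), "not_proximal")
  expect_equal(classifyProximity(0.3), "not_proximal")
  expect_error(classifyProximity(NaN), "finite")
  expect_error(classifyProximity(Inf), "finite")
})

test_that("one-sided p at the thresholds recovers the nominal levels", {
  expect_equal(pnorm(-1.645), 0.05, tolerance = 5e-4 / 0.05)
  expect_equal(pnorm(-1.282), 0.10, tolerance = 5e-4 / 0.10)
})

test_that("proximity z is the standardized distance and is reproducible", {
  g <- randomTestGraph(120, 0.05, seed = 31)
  bins <- buildDegreeBins(g, minBinSize = 25)
  nodes <- igraph::V(g)$name
  S <- sample(nodes, 10)
  T <- sample(nodes, 4)
  r1 <- proximityZ(g, S, T, bins, nRandom = 50, rngSeed = 11)
  r2 <- proximityZ(g, S, T, bins, nRandom = 50, rngSeed = 11)
  expect_identical(proximityTable(r1), proximityTable(r2))
  expect_equal(r1@z, (r1@dC - r1@nullMean) / r1@nullSd)
  expect_equal(r1@pOneSided, pnorm(r1@z))
  expect_equal(classification(r1), classifyProximity(r1@z))
})

test_that("a degenerate null is flagged instead of dividing by zero", {
  # disease set = every node, so d_c is identically zero in all draws
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- LETTERS[1:6]
  bins <- buildDegreeBins(k6, minBinSize = 2)
  expect_warning(
    r <- proximityZ(k6, LETTERS[1:6], "C", bins, nRandom = 20,
                    rngSeed = 1, randomize = "targets"),
    "degenerate")
  expect_true(r@degenerate)
  expect_true(is.na(zScore(r)))
  expect_equal(classification(r), "not_proximal")
})

test_that("proximity matrix has full shape, per-pair seeds, and planted minimum", {
  g <- randomTestGraph(100, 0.06, seed = 55)
  bins <- buildDegreeBins(g, minBinSize = 20)
  nodes <- igraph::V(g)$name
  pw <- list(P1 = sample(nodes, 12), P2 = sample(nodes, 12),
             P3 = sample(nodes, 12))
  drugs <- list(dInside = sample(pw$P1, 4),  # targets inside pathway P1
                dRandom = sample(nodes, 4))
  m1 <- proximityMatrix(g, drugs, pw, bins, nRandom = 40, rngSeed = 7)
  expect_equal(dim(m1$z), c(2L, 3L))
  expect_equal(nrow(m1$results), 6L)
  # planted containment: d_c = 0 and the row minimum z at (dInside, P1)
  row <- m1$results[m1$results$target_set_id == "dInside" &
                      m1$results$gene_set_id == "P1", ]
  expect_equal(row$d_c, 0)
  expect_equal(which.min(m1$z["dInside", ]), c(P1 = 1L))
  # reproducible
  m2 <- proximityMatrix(g, drugs, pw, bins, nRandom = 40, rngSeed = 7)
  expect_identical(m1$z, m2$z)
  expect_identical(m1$results, m2$results)
})

test_that("pair failures become annotated missing cells, not errors", {
  g <- igraph::make_graph(~ A - B - C)
  bins <- buildDegreeBins(g, minBinSize = 1)
  m <- proximityMatrix(g, list(bad = "ZZZ", ok = "A"),
                       list(gs = c("B", "C")), bins,
                       nRandom = 10, rngSeed = 1)
  expect_equal(nrow(m$results), 2L)
  bad <- m$results[m$results$target_set_id == "bad", ]
  expect_true(is.na(bad$z))
  expect_match(bad$note, "unmapped")
})
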