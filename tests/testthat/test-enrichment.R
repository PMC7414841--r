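makeUniverse <- function(n) sprintf("U%03d", seq_len(n))

test_that("over-representation test matches the worked example", {
  bg <- makeUniverse(100)
  term <- bg[1:20]
  query <- c(bg[1:5], bg[21:25])   # overlap 5 of query 10
  r <- fisherEnrichment(query, list(t1 = term), bg)
  expect_equal(r$overlap_count, 5L)
  expect_equal(r$fold_enrichment, (5 / 10) / (20 / 100))
  expect_equal(r$p_fisher, oracleHyperTail(100, 20, 10, 5),
               tolerance = 1e-12)
  # and against R's own Fisher test as an independent cross-check
  ft <- fisher.test(matrix(c(5, 5, 15, 75), 2), alternative = "greater")
  expect_equal(r$p_fisher, ft$p.value, tolerance = 1e-9)
})

test_that("Fisher tail matches the hypergeometric-sum oracle exhaustively", {
  set.seed(12)
  for (rep in 1:30) {
    B <- sample(15:50, 1)
    bg <- makeUniverse(B)
    q <- sample(bg, sample(3:10, 1))
    t <- sample(bg, sample(3:15, 1))
    r <- fisherEnrichment(q, list(t = t), bg)
    expect_equal(r$p_fisher,
                 oracleHyperTail(B, length(t), length(q),
                                 length(intersect(q, t))),
                 tolerance = 1e-12)
  }
})

test_that("zero overlap and the EASE penalty corners behave as defined", {
  bg <- makeUniverse(50)
  r0 <- fisherEnrichment(bg[1:5], list(t = bg[40:50]), bg)
  expect_equal(r0$p_fisher, 1)          # P(X >= 0)
  expect_equal(r0$fold_enrichment, 0)
  # overlap 1 recomputed at 0 gives p_ease = 1
  r1 <- fisherEnrichment(bg[1:5], list(t = bg[5:10]), bg, mode = "ease")
  expect_equal(r1$overlap_count, 1L)
  expect_equal(r1$p_ease, 1)
  expect_equal(r1$ease_score, 0)
})

test_that("EASE p-value is never smaller than the Fisher p-value", {
  set.seed(33)
  for (rep in 1:20) {
    bg <- makeUniverse(40)
    q <- sample(bg, 8)
    t <- sample(bg, 10)
    r <- fisherEnrichment(q, list(t = t), bg)
    expect_gte(r$p_ease, r$p_fisher)
  }
})

test_that("significance filter applies the strict triple", {
  res <- data.frame(
    p = c(0.005, 0.005, 0.02, 0.005, 0.0099),
    overlap_count = c(4L, 3L, 10L, 4L, 4L),
    fold_enrichment = c(2.0, 2.0, 3.0, 1.5, 1.51))
  kept <- filterSignificant(res)
  expect_equal(rownames(kept), c("1", "5"))
  # boundary: p exactly 0.01 is excluded ("less than")
  expect_equal(nrow(filterSignificant(
    data.frame(p = 0.01, overlap_count = 5L, fold_enrichment = 2))), 0L)
})

test_that("enrichment map applies the strict Jaccard rule", {
  sets <- list(a = c("A", "B", "C"), b = c("B", "C", "D"),
               c = c("X", "Y", "Z"),
               # jaccard(d, e) = 1/10 exactly: must NOT create an edge
               d = c("E", "F", "G", "H", "I"),
               e = c("I", "J", "K", "L", "M", "N"))
  map <- buildEnrichmentMap(sets, jaccardCutoff = 0.1)
  et <- edgeTable(map)
  expect_equal(nrow(et), 1L)
  expect_setequal(c(et$term_a, et$term_b), c("a", "b"))
  expect_equal(et$jaccard, 0.5)
  expect_equal(nrow(nodeTable(map)), 5L)
  expect_equal(map@lccSize, 2L)
})

test_that("map edges are invariant to term ordering and jaccard is symmetric", {
  set.seed(66)
  sets <- lapply(1:8, function(i) sample(makeUniverse(40), 12))
  names(sets) <- paste0("t", 1:8)
  m1 <- buildEnrichmentMap(sets, 0.1)
  m2 <- buildEnrichmentMap(rev(sets), 0.1)
  key <- function(m) {
    et <- edgeTable(m)
    sort(paste(pmin(et$term_a, et$term_b), pmax(et$term_a, et$term_b),
               round(et$jaccard, 12)))
  }
  expect_identical(key(m1), key(m2))
  expect_true(all(edgeTable(m1)$jaccard > 0.1 &
                    edgeTable(m1)$jaccard <= 1))
})

test_that("perturbation profile flags planted containment and counts ratios", {
  b <- simulateBundle(31, nNodes = 500, moduleSize = 40, nSeeds = 15,
                      nTerms = 8)
  bins <- buildDegreeBins(b$graph, 50)
  map <- buildEnrichmentMap(b$sets[1:4], 0.1)
  # drug targeting one node's own genes: that node must be perturbed
  nodeGenes <- map@termSets[[1]]
  prof <- suppressMessages(perturbationProfile(
    b$graph, nodeGenes[1:5], map, bins, nRandom = 60, rngSeed = 3,
    drugId = "self"))
  tab <- nodeTable(prof)
  expect_equal(tab$d_c[1], 0)
  expect_true(tab$perturbed[1])
  expect_equal(perturbationRatio(prof),
               prof@nPerturbed / prof@nNodes)
  # relaxing the threshold can only increase the perturbed count
  prof2 <- suppressMessages(perturbationProfile(
    b$graph, nodeGenes[1:5], map, bins, nRandom = 60, rngSeed = 3,
    drugId = "self", zThreshold = 0))
  expect_gte(prof2@nPerturbed, prof@nPerturbed)
})
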