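test_that("edge-list loading collapses self-loops and duplicate edges", {
  f <- edgeFileFixture(c("# comment", "A B", "B A", "B B", "B C"))
  g <- suppressMessages(loadEdgeList(f))
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_true(igraph::are_adjacent(g, "B", "C"))
})

test_that("edge-list loading rejects empty and malformed input", {
  expect_error(suppressMessages(loadEdgeList(edgeFileFixture(character(0)))),
               "empty graph")
  expect_error(suppressMessages(loadEdgeList(edgeFileFixture("# only comments"))),
               "empty graph")
  expect_error(suppressMessages(loadEdgeList(edgeFileFixture(c("A B", "Conly")))),
               "line 2")
})

test_that("LCC decomposition separates path, pair and isolated genes", {
  g <- igraph::make_graph(~ A - B - C, D - E, F)
  dec <- decomposeLcc(g, LETTERS[1:6])
  expect_setequal(lccMembers(dec), c("A", "B", "C"))
  expect_setequal(smallComponentMembers(dec), c("D", "E"))
  expect_setequal(isolatedMembers(dec), "F")
  expect_length(unmappedMembers(dec), 0)
})

test_that("LCC decomposition handles complete and absent gene sets", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  dec <- decomposeLcc(k4, LETTERS[1:4])
  expect_setequal(lccMembers(dec), LETTERS[1:4])
  expect_length(smallComponentMembers(dec), 0)
  expect_length(isolatedMembers(dec), 0)

  none <- decomposeLcc(k4, c("X", "Y"))
  expect_length(lccMembers(none), 0)
  expect_setequal(unmappedMembers(none), c("X", "Y"))
})

test_that("LCC categories partition the mapped genes on random graphs", {
  for (s in 1:20) {
    g <- randomTestGraph(25, 0.08, seed = s)
    genes <- sample(c(igraph::V(g)$name, paste0("X", 1:5)), 15)
    dec <- decomposeLcc(g, genes)
    mapped <- intersect(genes, igraph::V(g)$name)
    cats <- c(lccMembers(dec), smallComponentMembers(dec),
              isolatedMembers(dec))
    expect_setequal(cats, mapped)
    expect_equal(anyDuplicated(cats), 0)
    expect_setequal(unmappedMembers(dec),
                    setdiff(genes, igraph::V(g)$name))
    # LCC is at least as large as any other component
    if (length(smallComponentMembers(dec)) > 0) {
      sub <- igraph::induced_subgraph(g, mapped)
      comp <- igraph::components(sub)
      expect_equal(length(lccMembers(dec)), max(comp$csize))
    }
  }
})

test_that("greedy degree binning follows the accumulate-and-close rule", {
  # degrees: A,B,C have 1; D,E have 2; F has 3 via a tailored graph
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C", "D", "E"),
               to   = c("F", "F", "D", "E", "F")),
    directed = FALSE)
  deg <- igraph::degree(g)
  expect_setequal(names(deg)[deg == 1], c("A", "B", "C"))
  expect_setequal(names(deg)[deg == 2], c("D", "E"))
  expect_equal(unname(deg["F"]), 3)
  bins <- buildDegreeBins(g, minBinSize = 3)
  expect_length(bins@bins, 2)
  expect_setequal(bins@bins[[1]], c("A", "B", "C"))
  expect_setequal(bins@bins[[2]], c("D", "E", "F"))
  expect_equal(bins@degreeLo, c(1L, 2L))
  expect_equal(bins@degreeHi, c(1L, 3L))
})

test_that("degree binning corner cases: per-degree bins and single bin", {
  g <- randomTestGraph(30, 0.15, seed = 3)
  b1 <- buildDegreeBins(g, minBinSize = 1)
  expect_length(b1@bins, length(unique(igraph::degree(g))))

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- LETTERS[1:5]
  ball <- buildDegreeBins(k5, minBinSize = 2)
  expect_length(ball@bins, 1)
  expect_setequal(ball@bins[[1]], LETTERS[1:5])

  expect_error(buildDegreeBins(k5, minBinSize = 6), "exceeds node count")
})

test_that("degree bins partition the node set", {
  for (s in 1:10) {
    g <- randomTestGraph(40, 0.1, seed = 100 + s)
    bins <- buildDegreeBins(g, minBinSize = 7)
    expect_setequal(unlist(bins@bins), igraph::V(g)$name)
    expect_equal(sum(lengths(bins@bins)), igraph::vcount(g))
    expect_true(all(lengths(bins@bins) >= 7))
  }
})

test_that("degree-matched sampling preserves bin labels and is seeded", {
  g <- randomTestGraph(60, 0.1, seed = 9)
  bins <- buildDegreeBins(g, minBinSize = 10)
  ref <- sample(igraph::V(g)$name, 8)
  s1 <- sampleDegreeMatched(g, bins, ref, rngSeed = 42)
  s2 <- sampleDegreeMatched(g, bins, ref, rngSeed = 42)
  expect_identical(s1, s2)
  expect_length(s1, length(ref))
  expect_equal(anyDuplicated(s1), 0)
  # multiset of bin labels preserved exactly, for several seeds
  for (seed in 1:5) {
    s <- sampleDegreeMatched(g, bins, ref, rngSeed = seed)
    expect_equal(sort(unname(table(bins@binOf[s]))),
                 sort(unname(table(bins@binOf[ref]))))
  }
  expect_error(sampleDegreeMatched(g, bins, c(ref, "NOPE")),
               "not in the graph")
})

test_that("within-bin sampling frequencies are uniform", {
  g <- randomTestGraph(200, 0.05, seed = 77)
  bins <- buildDegreeBins(g, minBinSize = 40)
  ref <- bins@bins[[1]][1]  # one reference gene from bin 1
  pool <- bins@bins[[bins@binOf[ref]]]
  draws <- vapply(seq_len(1000), function(i)
    sampleDegreeMatched(g, bins, ref, rngSeed = 5000 + i), character(1))
  counts <- table(factor(draws, levels = pool))
  # 99% binomial bounds for 1000 draws of 1-of-|pool|
  p <- 1 / length(pool)
  bound <- qbinom(c(0.005, 0.995), 1000, p)
  expect_gt(min(counts), bound[1] - 1)
  expect_lt(max(counts), bound[2] + 1)
})
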