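test_that("GAL neighbor lists parse, symmetrize and report components", {
  path <- writeGalFixture(list(a = "b", b = c("a", "c"), c = "b"),
                          tempfile(fileext = ".gal"))
  g <- readNeighborList(path)
  expect_s4_class(g, "AreaGraph")
  expect_identical(unname(degrees(g)), c(1L, 2L, 1L))
  expect_identical(nComponents(g), 1L)

  # asymmetric entry: a lists b, b does not list a
  asym <- writeGalFixture(list(a = "b", b = character(0)),
                          tempfile(fileext = ".gal"))
  expect_warning(g2 <- readNeighborList(asym), "symmetrized")
  expect_identical(unname(degrees(g2)), c(1L, 1L))

  # two components from a 4-area file with edges {1-2}, {3-4}
  two <- writeGalFixture(list(a = "b", b = "a", c = "d", d = "c"),
                         tempfile(fileext = ".gal"))
  g3 <- readNeighborList(two)
  expect_identical(nComponents(g3), 2L)
  expect_identical(unname(componentLabels(g3)),
                   bfsComponents(adjacencyList(g3)))
})

test_that("GAL parse errors name the offending record", {
  bad <- writeGalFixture(list(a = "zz", zzz = character(0)),
                         tempfile(fileext = ".gal"))
  expect_error(readNeighborList(bad), "unknown neighbor")
  dup <- tempfile(fileext = ".gal")
  writeLines(c("2", "a 0", "a 0"), dup)
  expect_error(readNeighborList(dup), "duplicate area id")
})

test_that("addEdges bridges components, is idempotent, validates endpoints", {
  g <- AreaGraph(letters[1:4], cbind(c("a", "c"), c("b", "d")))
  expect_identical(nComponents(g), 2L)
  g2 <- addEdges(g, cbind("b", "c"))
  expect_identical(nComponents(g2), 1L)
  # adding an existing edge changes nothing
  g3 <- addEdges(g2, cbind("a", "b"))
  expect_identical(adjacencyList(g3), adjacencyList(g2))
  expect_error(addEdges(g, cbind("a", "nope")), "not in graph")

  # isolated node gains degree 1 through an extra edge
  g10 <- AreaGraph(letters[1:10],
                   cbind(letters[1:8], letters[2:9]))  # j isolated
  expect_identical(min(degrees(g10)), 0L)
  g11 <- addEdges(g10, cbind("j", "a"))
  expect_identical(min(degrees(g11)), 1L)
  expect_identical(unname(degrees(g11))["j" == areaIds(g11)], 1L)
})

test_that("validateGraph reports isolation, components, degrees", {
  rep1 <- validateGraph(AreaGraph(c("a", "b", "c"),
                                  cbind(c("a", "b"), c("b", "c"))))
  expect_identical(rep1$isolated, character(0))
  expect_identical(rep1$nComponents, 1L)

  expect_warning(
    rep2 <- validateGraph(AreaGraph(c("a", "b", "c"), cbind("a", "b"))),
    "isolated"
  )
  expect_identical(rep2$isolated, "c")

  lat <- makeLattice(20, 20)
  rep3 <- validateGraph(lat)
  expect_identical(rep3$nAreas, 400L)
  expect_equal(rep3$nEdges, 760)
  expect_identical(rep3$nComponents, 1L)
  expect_identical(max(as.integer(names(rep3$degreeDistribution))), 4L)
})

test_that("aggregateAreas merges neighbors and sums tables exactly", {
  # merge two adjacent areas: counts 3 + 4 -> 7, no self-loop
  g <- AreaGraph(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
  tab <- matrix(c(3, 4, 5), ncol = 1,
                dimnames = list(c("a", "b", "c"), "count"))
  res <- aggregateAreas(g, c(a = "ab", b = "ab"), list(tab))
  expect_identical(areaIds(res$graph), c("ab", "c"))
  expect_identical(unname(degrees(res$graph)), c(1L, 1L))
  expect_equal(res$tables[[1]]["ab", "count"], 7)
  expect_equal(sum(res$tables[[1]]), sum(tab))

  # empty merge map is the identity
  res0 <- aggregateAreas(g, character(0), list(tab))
  expect_identical(areaIds(res0$graph), areaIds(g))
  expect_equal(res0$tables[[1]], tab[areaIds(g), , drop = FALSE])

  expect_error(aggregateAreas(g, c(zz = "g1")), "unknown area")
})

test_that("aggregation drops area count by the summed group excess", {
  # three merge groups of sizes 4, 3, 5 shrink 20 areas by 9 -> 11
  g <- makeLattice(4, 5)
  ids <- areaIds(g)
  mm <- c(setNames(rep("g1", 4), ids[1:4]),
          setNames(rep("g2", 3), ids[5:7]),
          setNames(rep("g3", 5), ids[8:12]))
  tab <- matrix(seq_len(20), ncol = 1, dimnames = list(ids, "n"))
  res <- aggregateAreas(g, mm, list(tab))
  expect_identical(length(res$graph), 20L - 9L)
  expect_equal(sum(res$tables[[1]]), sum(tab))
})

test_that("random graphs keep symmetry and match the BFS oracle", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(5:40, 1)
    ids <- sprintf("n%02d", seq_len(n))
    g <- AreaGraph(ids, randomEdges(n, runif(1, 0.02, 0.2), ids))
    adj <- adjacencyList(g)
    for (i in seq_len(n)) {
      expect_false(i %in% adj[[i]])
      for (j in adj[[i]]) expect_true(i %in% adj[[j]])
    }
    expect_identical(unname(componentLabels(g)), bfsComponents(adj))
  }
  # scale check: 100x100 lattice = 1e4 nodes, one component
  big <- makeLattice(100, 100)
  expect_identical(unname(componentLabels(big)),
                   bfsComponents(adjacencyList(big)))
})

test_that("neighbor lists round-trip through write + read", {
  g <- makeLattice(4, 4, islands = 1)
  path <- tempfile(fileext = ".gal")
  writeNeighborList(g, path)
  g2 <- readNeighborList(path)
  expect_identical(areaIds(g2), areaIds(g))
  expect_identical(adjacencyList(g2), adjacencyList(g))
})
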