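test_that("small-graph centralities match hand enumeration", {
  # path a-b-c
  path3 <- netFromGraph(igraph::make_graph(~ a - b, b - c))
  t3 <- computeCentralities(path3)
  expect_equal(t3$degree[t3$key == "b"], 2)
  expect_equal(t3$betweenness[t3$key == "b"], 1)
  expect_equal(t3$betweenness[t3$key == "a"], 0)

  # star K1,5: center closeness 1, betweenness C(5,2)=10, leaves 5/9
  star <- netFromGraph(igraph::make_star(6, mode = "undirected", center = 1))
  ts <- computeCentralities(star)
  expect_equal(ts$closeness[1], 1)
  expect_equal(ts$betweenness[1], 10)
  expect_equal(ts$closeness[-1], rep(5 / 9, 5))

  # dyad: both ends have Burt constraint 1
  dyad <- netFromGraph(igraph::make_graph(~ a - b))
  expect_equal(computeCentralities(dyad)$burt_constraint, c(1, 1))

  # complete graph: betweenness 0, closeness 1 everywhere
  k5 <- netFromGraph(igraph::make_full_graph(5))
  tk <- computeCentralities(k5)
  expect_equal(tk$betweenness, rep(0, 5))
  expect_equal(tk$closeness, rep(1, 5))
})

test_that("all seven measures match brute-force oracles on a seeded random graph", {
  er <- seededER(25, 0.15, seed = 42)
  tab <- computeCentralities(er$net)
  A <- er$A
  expect_equal(tab$degree, unname(rowSums(A)))
  expect_equal(tab$betweenness, oracleBetweenness(A), tolerance = 1e-8)
  expect_equal(tab$closeness, oracleCloseness(A), tolerance = 1e-8)
  expect_equal(tab$burt_constraint, oracleBurt(A), tolerance = 1e-8)
  expect_equal(tab$pagerank, oraclePagerank(A, 0.85), tolerance = 1e-8)
  expect_equal(tab$kcore, oracleKcore(A))
  expect_equal(tab$authority, oracleAuthority(A), tolerance = 1e-8)
  # structural invariants
  expect_equal(sum(tab$degree), 2 * igraph::ecount(networkGraph(er$net)))
  expect_equal(sum(tab$pagerank), 1, tolerance = 1e-9)
  expect_equal(max(tab$authority), 1)
  expect_true(all(tab$kcore <= tab$degree))
})

test_that("degenerate graphs follow the stated conventions", {
  # graph with an isolated node
  g <- igraph::make_graph(~ a - b, b - c) + igraph::vertices("z")
  tab <- computeCentralities(netFromGraph(g))
  z <- tab[tab$key == "z", ]
  expect_equal(z$degree, 0)
  expect_equal(z$closeness, 0)
  expect_true(is.na(z$burt_constraint))
  expect_equal(z$kcore, 0)
  expect_equal(sum(tab$pagerank), 1, tolerance = 1e-9)
  expect_error(computeCentralities(netFromGraph(igraph::make_empty_graph(0, directed = FALSE))),
               "empty")
  expect_error(computeCentralities(netFromGraph(igraph::make_ring(4)), damping = 1.5),
               "damping")
})

test_that("adding an edge never decreases degree or k-core", {
  er <- seededER(18, 0.12, seed = 7)
  g <- networkGraph(er$net)
  t1 <- computeCentralities(er$net)
  nonEdges <- which(er$A == 0 & upper.tri(er$A), arr.ind = TRUE)
  set.seed(1)
  for (r in sample(nrow(nonEdges), 5)) {
    g2 <- igraph::add_edges(g, c(nonEdges[r, 1], nonEdges[r, 2]))
    t2 <- computeCentralities(netFromGraph(g2))
    expect_true(all(t2$degree >= t1$degree))
    expect_true(all(t2$kcore >= t1$kcore))
  }
})

test_that("measure correlations form a proper Pearson matrix", {
  er <- seededER(25, 0.15, seed = 42)
  tab <- computeCentralities(er$net)
  r <- measureCorrelations(tab)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  expect_true(all(abs(r[!is.na(r)]) <= 1 + 1e-12))
  # one-line covariance oracle for degree vs kcore
  keep <- complete.cases(tab[, c("degree", "kcore", "burt_constraint")])
  x <- tab$degree[keep]; y <- tab$kcore[keep]
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["degree", "kcore"], rOracle, tolerance = 1e-12)
  # antisymmetry
  tab$neg <- -tab$degree
  r2 <- measureCorrelations(tab, c("degree", "neg"))
  expect_equal(r2["degree", "neg"], -1)
  # zero variance flagged
  tab$flat <- 1
  expect_warning(r3 <- measureCorrelations(tab, c("degree", "flat")), "zero-variance")
  expect_true(is.na(r3["flat", "degree"]))
})

test_that("betweenness matches the path-counting oracle across many graphs", {
  for (seed in 1:8) {
    n <- 10 + 4 * seed
    er <- seededER(n, 0.12, seed = 100 + seed)
    tab <- computeCentralities(er$net)
    expect_equal(tab$betweenness, oracleBetweenness(er$A), tolerance = 1e-8,
                 info = paste("seed", seed))
  }
})
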