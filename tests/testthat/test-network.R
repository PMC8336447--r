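test_that("validation accepts valid networks and names violations", {
  g <- caterpillar5()
  expect_valid(g)

  fx <- make_m1()
  expect_valid(fx$graph)

  # two-cycle between internal vertices
  bad <- g
  bad$edges <- rbind(bad$edges, c(3L, 2L), c(2L, 3L))
  chk <- validate_directed(bad)
  expect_false(chk$ok)
  expect_true(any(grepl("cycle|non-binary", chk$violations)))

  # internal vertex with in-degree 2 and out-degree 2
  bad2 <- graph_from_names(
    parent = c("r", "r", "x", "y", "m", "m", "x", "y"),
    child  = c("x", "y", "m", "m", "A", "B", "C", "D"))
  chk2 <- validate_directed(bad2)
  expect_false(chk2$ok)
  expect_true(any(grepl("non-binary", chk2$violations)))
})

test_that("edge count identity |E| = |V| - 1 + h holds for valid networks", {
  for (seed in 1:10) {
    fx <- random_graph(5 + seed %% 4, seed %% 3, seed = seed)
    g <- fx$graph
    expect_valid(g)
    nv <- length(unique(c(as.integer(g$edges), g$root)))
    expect_equal(nrow(g$edges), nv - 1L + n_admixture(g))
  }
})

test_that("undirecting suppresses the root and drops exactly one edge", {
  g <- caterpillar5()
  u <- to_undirected(g)
  expect_equal(nrow(u$edges), nrow(g$edges) - 1L)
  expect_true(all(tabulate(as.integer(u$edges)) %in% c(1L, 3L)))

  fx <- make_m1()
  u2 <- to_undirected(fx$graph)
  deg <- tabulate(as.integer(u2$edges))
  expect_equal(deg[u2$admix], 3L)          # former admixture node has degree 3
  expect_equal(sum(deg == 1L), 5L)
})

test_that("undirected isomorphism is reflexive, label-aware, and id-blind", {
  g <- caterpillar5()
  u <- to_undirected(g)
  expect_true(is_isomorphic(u, u))

  # same topology written in another creation order (permuted internal ids)
  g2 <- graph_from_names(
    parent = c("t1", "t1", "t2", "t2", "t3", "t3", "q", "q"),
    child  = c("A", "B", "t1", "C", "t2", "D", "t3", "E"))
  expect_true(is_isomorphic(to_undirected(g2), u))

  a <- to_undirected(balanced4())
  b <- to_undirected(caterpillar4_acbd())
  expect_false(is_isomorphic(a, b))   # different splits
})

test_that("orientations of one undirected network are unrooted-isomorphic", {
  fx <- make_m1()
  u <- to_undirected(fx$graph)
  ors <- enumerate_orientations(fx$graph, outgroup = "E")
  expect_true(length(ors) >= 2L)
  for (o in ors) expect_true(is_isomorphic(to_undirected(o), u))
})

test_that("directed isomorphism distinguishes rootings but unrooted does not", {
  fx <- make_m1()
  g <- fx$graph
  u <- to_undirected(g)
  # reroot on B's pendant edge with same admixture set
  bid <- which(!is.na(u$labels) & u$labels == "B")
  ri <- which(u$edges[, 1] == bid | u$edges[, 2] == bid)
  g2 <- orient(u, orientation_spec(u$edges[ri, ], u$admix))
  expect_valid(g2)
  expect_false(is_isomorphic_directed(g, g2))
  expect_true(is_isomorphic_unrooted(g, g2))
})
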