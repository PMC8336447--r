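test_that("neighbor joining recovers additive (tree) f2 inputs", {
  for (seed in c(2, 4, 6, 8)) {
    fx <- random_graph(6, 0, seed = seed)
    u <- nj_tree(fx$data)
    expect_true(is_isomorphic(u, to_undirected(fx$graph)))
  }
})

test_that("starting-tree modes agree with the generating tree on tree data", {
  fx <- random_graph(5, 0, seed = 11)
  og <- populations(fx$graph)[1]
  for (mode in c("nj", "exact_ml")) {
    cfg <- search_config(0L, og, start = mode)
    t <- starting_tree(fx$data, cfg)
    expect_true(is_isomorphic_unrooted(t, fx$graph))
  }
  # random addition is seed-reproducible
  cfg1 <- search_config(0L, og, start = "random_addition", seed = 7L)
  t1 <- starting_tree(fx$data, cfg1)
  t2 <- starting_tree(fx$data, cfg1)
  expect_true(is_isomorphic_directed(t1, t2))
  expect_true(is_isomorphic_unrooted(t1, fx$graph))
})

test_that("on the case-study data the NJ tree is also the exact ML tree", {
  fx <- make_m1()
  cfg_nj <- search_config(1L, "E", start = "nj")
  cfg_ml <- search_config(1L, "E", start = "exact_ml")
  n0_nj <- starting_tree(fx$data, cfg_nj)
  n0_ml <- starting_tree(fx$data, cfg_ml)
  expect_true(is_isomorphic_unrooted(n0_nj, n0_ml))
  expect_false(is_base_tree(n0_nj, fx$graph))
})

test_that("hill climbing from one tail move away recovers the truth on tree data", {
  fx <- random_graph(5, 0, seed = 21)
  cfg <- search_config(0L, populations(fx$graph)[1])
  start <- enumerate_tail_moves(fx$graph)[[2]]$graph
  hc <- hill_climb(start, fx$data, cfg)
  expect_true(is_isomorphic_unrooted(hc$network, fx$graph))
  expect_equal(hc$fit$loglik, perfect_fit_loglik(fx$data), tolerance = 1e-6)
  # a network at its optimum is left unchanged
  hc2 <- hill_climb(fx$graph, fx$data, cfg)
  expect_equal(hc2$steps, 0L)
})

test_that("a zero-admixture search returns the starting tree fit", {
  fx <- random_graph(5, 0, seed = 31)
  out <- run_search(fx$data, search_config(0L, populations(fx$graph)[1]))
  expect_true(is_isomorphic_unrooted(out$network, fx$graph))
  expect_equal(out$trace$stage, "starting_tree")
})

test_that("starting from a base tree, edge addition alone recovers the truth", {
  # given a base tree of the true network as the starting tree, the best
  # gene-flow edge addition reaches the true topology without any
  # reorientation step
  fx <- random_graph(5, 1, seed = 17)
  bt <- base_trees(fx$graph)[[1]]
  cfg <- search_config(1L, populations(fx$graph)[1], mlno = FALSE)
  st <- add_admixture_step(bt, rep(0L, nrow(bt$edges)), fx$data, cfg)
  expect_equal(st$fit$loglik, perfect_fit_loglik(fx$data), tolerance = 0.5)
  expect_true(is_isomorphic_unrooted(st$network, fx$graph))
})

test_that("trace log-likelihoods never decrease across stages", {
  fx <- random_graph(6, 1, seed = 23)
  out <- run_search(fx$data, search_config(1L, populations(fx$graph)[1],
                                           mlno = TRUE))
  ll <- out$trace$loglik
  expect_true(all(diff(ll) > -1e-6))
})
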