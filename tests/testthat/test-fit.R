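test_that("branch lengths of a tree are recovered exactly from its own f2", {
  for (seed in c(1, 2, 3)) {
    fx <- random_graph(6, 0, seed = seed)
    fit <- fit_params(fx$graph, fx$data, "treemix")
    expect_true(fit$converged)
    expect_equal(fit$loglik, perfect_fit_loglik(fx$data), tolerance = 1e-8)
    # identifiable lengths: all except the two root edges (only their sum is)
    rootrows <- which(fx$graph$edges[, 1] == fx$graph$root)
    other <- setdiff(seq_len(nrow(fx$graph$edges)), rootrows)
    expect_equal(fit$params$lengths[other], fx$params$lengths[other],
                 tolerance = 1e-6)
    expect_equal(sum(fit$params$lengths[rootrows]),
                 sum(fx$params$lengths[rootrows]), tolerance = 1e-6)
  }
})

test_that("the true admixture topology reaches the perfect-fit score under both conventions", {
  fx <- make_m1()
  tm <- score_graph(fx$graph, fx$data, "treemix")
  ag <- fit_params(fx$graph, fx$data, "admixturegraph")
  expect_equal(round(tm$loglik), 83)
  expect_equal(round(ag$loglik), 83)
  expect_equal(tm$loglik, perfect_fit_loglik(fx$data), tolerance = 1e-4)
  # per-labeling scores are near-identical even though admixture-edge
  # parameters differ between labelings
  expect_length(tm$scores, 2L)
  expect_lt(diff(range(tm$scores)), 1e-3)
  # gamma recovered
  expect_equal(unname(tm$params$gamma), 0.45, tolerance = 1e-3)
  # fixed-to-zero edges are exactly zero
  fixed <- admixorient:::fixed_zero_edges(fx$graph, tm$labeling, "treemix")
  expect_equal(unname(tm$params$lengths[fixed]), rep(0, length(fixed)))
})

test_that("a wrong topology scores strictly below the truth on admixed data", {
  fx <- make_m1()
  wrong <- caterpillar5()            # a base tree, no admixture edge
  fit <- fit_params(wrong, fx$data, "treemix")
  expect_lt(fit$loglik, perfect_fit_loglik(fx$data) - 100)
})

test_that("fitting is a fixed point and never exceeds the perfect-fit bound", {
  fx <- random_graph(5, 1, seed = 9)
  fit1 <- fit_params(fx$graph, fx$data, "treemix")
  expect_lte(fit1$loglik, perfect_fit_loglik(fx$data) + 1e-6)
  fit2 <- fit_params(fx$graph, fx$data, "treemix", labeling = fit1$labeling)
  expect_lt(abs(fit2$loglik - fit1$loglik), 1e-8)
})

test_that("score_graph maximizes over labelings (brute-force cross-check)", {
  fx <- random_graph(6, 2, seed = 4)
  best <- score_graph(fx$graph, fx$data, "treemix")
  labs <- enumerate_labelings(fx$graph)
  brute <- max(vapply(labs, function(l)
    fit_params(fx$graph, fx$data, "treemix", labeling = l)$loglik, numeric(1)))
  expect_equal(best$loglik, brute, tolerance = 1e-8)
  expect_length(best$scores, length(labs))

  # tree: single fit, identical to fit_params
  tr <- random_graph(5, 0, seed = 4)
  expect_equal(score_graph(tr$graph, tr$data, "treemix")$loglik,
               fit_params(tr$graph, tr$data, "treemix")$loglik)
})
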