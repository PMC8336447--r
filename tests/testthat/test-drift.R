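test_that("path weights on trees are 0/1 indicators of the root path", {
  g <- caterpillar5()
  params <- drift_params(g, 0.1)
  P <- path_weights(g, params)
  expect_true(all(P %in% c(0, 1)))
  # pendant edge indicators
  for (lab in c("A", "B", "C", "D", "E")) {
    lv <- which(!is.na(g$labels) & g$labels == lab)
    pend <- which(g$edges[, 2] == lv)
    expect_equal(unname(P[lab, pend]), 1)
    expect_equal(sum(P[lab, g$edges[, 2] %in%
                         which(!is.na(g$labels) & g$labels != lab)]), 0)
  }
})

test_that("admixture splits path weights by gamma and f2 follows", {
  half <- admixed3(0.5)
  P <- path_weights(half$graph, half$params)
  # B traverses each side's top edge with probability 1/2
  expect_equal(unname(P["B", 1:2]), c(0.5, 0.5))
  expect_equal(unname(P["B", 7]), 1)

  quarter <- admixed3(0.25)   # gamma on the u (A-side) incoming edge
  P2 <- path_weights(quarter$graph, quarter$params)
  expect_equal(unname(P2["B", 1]), 0.25)

  y <- expected_f2(half$graph, half$params)
  expect_equal(unname(y["A|B"]), 0.25 * (0.1 + 0.1) + 0.3 + 0.1)  # 0.45
  expect_equal(unname(y["A|C"]), 0.1 + 0.1 + 0.3 + 0.4)           # 0.9
  # flow conservation: inflow = outflow at internal vertices
  g <- half$graph
  for (v in setdiff(unique(as.integer(g$edges)), c(g$root, leaves(g)))) {
    inflow <- sum(P["B", which(g$edges[, 2] == v)])
    outflow <- sum(P["B", which(g$edges[, 1] == v)])
    expect_equal(inflow, outflow)
  }
})

test_that("expected f2 equals path distance on trees (independent oracle)", {
  for (seed in 1:5) {
    fx <- random_graph(6, 0, seed = seed)
    y <- expected_f2(fx$graph, fx$params)
    oracle <- tree_path_f2_oracle(fx$graph, fx$params$lengths)
    expect_equal(y[names(oracle)], oracle, tolerance = 1e-12)
  }
})

test_that("expected f2 matches a Monte-Carlo Brownian drift simulation", {
  fx <- admixed3(0.3)
  set.seed(42)
  g <- fx$graph
  reps <- 1e5
  # simulate zero-mean Gaussian increments with variance c_e per edge; the
  # admixed population's allele frequency is the gamma-weighted average of
  # its two parents' frequencies plus its own drift
  m <- admixture_nodes(g)
  des <- fx$params$gamma_parent[[as.character(m)]]
  gam <- fx$params$gamma[[as.character(m)]]
  inc <- matrix(stats::rnorm(reps * nrow(g$edges)), reps) *
    rep(sqrt(fx$params$lengths), each = reps)
  # vertex ids: leaves by label, internal by structure
  eidx <- function(p, c) which(g$edges[, 1] == p & g$edges[, 2] == c)
  idA <- which(!is.na(g$labels) & g$labels == "A")
  idB <- which(!is.na(g$labels) & g$labels == "B")
  idC <- which(!is.na(g$labels) & g$labels == "C")
  idu <- g$edges[g$edges[, 2] == idA, 1]   # A's parent
  idv <- g$edges[g$edges[, 2] == idC, 1]   # C's parent
  A <- inc[, eidx(g$root, idu)] + inc[, eidx(idu, idA)]
  C <- inc[, eidx(g$root, idv)] + inc[, eidx(idv, idC)]
  B_side_u <- inc[, eidx(g$root, idu)] + inc[, eidx(idu, m)]
  B_side_v <- inc[, eidx(g$root, idv)] + inc[, eidx(idv, m)]
  w_u <- if (des == idu) gam else 1 - gam
  B <- w_u * B_side_u + (1 - w_u) * B_side_v + inc[, eidx(m, idB)]
  emp <- c(`A|B` = mean((A - B)^2), `A|C` = mean((A - C)^2), `B|C` = mean((B - C)^2))
  y <- expected_f2(g, fx$params)
  # mean of squared differences: SE of each estimate ~ sqrt(2/reps) * Y
  for (k in names(emp))
    expect_lt(abs(emp[[k]] - y[[k]]), 3 * sqrt(2 / reps) * y[[k]] + 3e-4)
})

test_that("the likelihood takes its closed perfect-fit values", {
  fx <- make_m1()
  y <- expected_f2(fx$graph, fx$params)
  ll <- log_likelihood(fx$data, y)
  expect_equal(ll, -(10 / 2) * (2 * log(1e-4) + log(2 * pi)), tolerance = 1e-12)
  expect_equal(round(ll), 83)
  expect_equal(ll, perfect_fit_loglik(fx$data))

  # 15 pairs at the same scale
  fx6 <- random_graph(6, 1, seed = 2)
  expect_equal(round(perfect_fit_loglik(fx6$data)), 124)

  # single pair with X - Y = Z contributes -(1/2)(1 + 2 log Z + log 2pi)
  d1 <- fx$data[fx$data$pop1 == "A" & fx$data$pop2 == "B", , drop = FALSE]
  class(d1) <- class(fx$data)
  y1 <- c(`A|B` = d1$f2 - d1$se)
  expect_equal(log_likelihood(d1, y1),
               -0.5 * (1 + 2 * log(d1$se) + log(2 * pi)))
})

test_that("residuals are zero at a perfect fit and localized otherwise", {
  fx <- make_m1()
  y <- expected_f2(fx$graph, fx$params)
  r <- f2_residuals(fx$data, y)
  expect_equal(r$raw, rep(0, 10))
  y2 <- y; y2["B|C"] <- y2["B|C"] + 1e-3
  r2 <- f2_residuals(fx$data, y2)
  expect_equal(sum(r2$raw != 0), 1L)
  expect_equal(r2$raw[r2$pop1 == "B" & r2$pop2 == "C"], -1e-3)
})

test_that("expected f2 is invariant to relocating the root above admixture", {
  fx <- make_m1()
  y0 <- expected_f2(fx$graph, fx$params)
  # reroot on the other root-incident edge side: orientation of the same
  # undirected network with root on v3-v2 edge (still ancestral to t)
  u <- to_undirected(fx$graph)
  fit0 <- fit_params(fx$graph, fx$data, "admixturegraph")
  for (o in enumerate_orientations(fx$graph, "E", all_roots = TRUE)) {
    if (!is_isomorphic_unrooted(o, fx$graph)) next
    fit <- fit_params(o, fx$data, "admixturegraph")
    expect_equal(fit$loglik, fit0$loglik, tolerance = 1e-6)
  }
})
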