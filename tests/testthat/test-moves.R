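test_that("the case-study network arises by edge addition on the caterpillar", {
  g <- caterpillar5()
  # e = pendant edge of D, f = pendant edge of A
  e <- g$edges[g$edges[, 2] == which(!is.na(g$labels) & g$labels == "D"), ]
  f <- g$edges[g$edges[, 2] == which(!is.na(g$labels) & g$labels == "A"), ]
  g2 <- apply_edge_addition(g, e, f)
  expect_valid(g2)
  expect_equal(n_admixture(g2), 1L)
  expect_equal(nrow(g2$edges), nrow(g$edges) + 3L)
  expect_true(is_isomorphic_unrooted(g2, make_m1()$graph))
  # A's parent is the admixture node
  m <- admixture_nodes(g2)
  expect_equal(g2$labels[admixorient:::ag_children(g2, m)], "A")

  expect_error(apply_edge_addition(g, e, e), "distinct")
})

test_that("reachability index equals a per-pair DFS oracle", {
  dfs_reaches <- function(g, u, v) {
    stack <- u; seen <- integer(0)
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      if (x == v) return(TRUE)
      if (x %in% seen) next
      seen <- c(seen, x)
      stack <- c(admixorient:::ag_children(g, x), stack)
    }
    FALSE
  }
  for (seed in c(2, 5)) {
    fx <- random_graph(6, 1, seed = seed)
    R <- build_reachability(fx$graph)
    vs <- sort(unique(c(as.integer(fx$graph$edges), fx$graph$root)))
    for (u in vs) for (v in vs)
      expect_equal(R[u, v], dfs_reaches(fx$graph, u, v))
    expect_true(all(R[fx$graph$root, vs]))   # root reaches everything
  }
})

test_that("edge-addition legality equals the apply-and-validate oracle", {
  for (seed in c(1, 6)) {
    fx <- random_graph(5, seed %% 2, seed = seed)
    g <- fx$graph
    listed <- enumerate_edge_additions(g)
    keys <- vapply(listed, function(cd)
      paste(paste(cd$e, collapse = ","), paste(cd$f, collapse = ","),
            sep = ";"), character(1))
    ne <- nrow(g$edges)
    brute <- character(0)
    for (i in seq_len(ne)) for (j in seq_len(ne)) {
      if (i == j) next
      g2 <- apply_edge_addition(g, g$edges[i, ], g$edges[j, ])
      if (admixorient:::ag_is_valid(g2))
        brute <- c(brute, paste(paste(g$edges[i, ], collapse = ","),
                                paste(g$edges[j, ], collapse = ","), sep = ";"))
    }
    expect_setequal(keys, brute)
    expect_lte(length(listed), ne * (ne - 1))
    for (cd in listed) expect_valid(cd$graph)
  }
})

test_that("tail moves are reversible and neighborhoods are symmetric", {
  fx <- random_graph(5, 1, seed = 3)
  g <- fx$graph
  nbrs <- enumerate_tail_moves(g)
  expect_true(length(nbrs) > 0)
  for (nb in nbrs[seq_len(min(8, length(nbrs)))]) {
    expect_valid(nb$graph)
    # symmetric: g is in the tail-move neighborhood of the neighbor
    # (modulo root position)
    back <- enumerate_tail_moves(nb$graph)
    found <- any(vapply(back, function(x)
      is_isomorphic_unrooted(x$graph, g), logical(1)))
    expect_true(found)
  }
})

test_that("head moves preserve the admixture count and are legal", {
  fx <- random_graph(5, 1, seed = 8)
  nbrs <- enumerate_head_moves(fx$graph)
  expect_true(length(nbrs) > 0)
  for (nb in nbrs) {
    expect_valid(nb$graph)
    expect_equal(n_admixture(nb$graph), 1L)
  }
})

test_that("move distance is 0 for isomorphic networks and 1 after one move", {
  fx <- random_graph(5, 1, seed = 12)
  g <- fx$graph
  expect_equal(move_distance(g, g), 0L)
  nb <- enumerate_tail_moves(g)[[1]]$graph
  d <- move_distance(g, nb, cap = 2L)
  expect_lte(d, 1L)   # 0 if the move was a rerooting-equivalent
})
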