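# Small fixture constructors shared across test files.

# Rooted caterpillar ((((A,B),C),D),E) rooted on E's pendant edge.
caterpillar5 <- function() {
  graph_from_names(
    parent = c("r", "r", "v3", "v3", "v2", "v2", "v1", "v1"),
    child  = c("E", "v3", "D", "v2", "C", "v1", "A", "B"))
}

# Three-leaf graph with B admixed between the A-side and C-side internal
# vertices: rho->u (0.1), rho->v (0.1), u->A (0.3), v->C (0.4),
# u->m, v->m (0), m->B (0.1).
admixed3 <- function(gamma_u = 0.5) {
  g <- graph_from_names(
    parent = c("rho", "rho", "u", "v", "u", "v", "m"),
    child  = c("u", "v", "A", "C", "m", "m", "B"))
  params <- drift_params(g, c(0.1, 0.1, 0.3, 0.4, 0, 0, 0.1),
                         stats::setNames(gamma_u, as.character(admixture_nodes(g))),
                         stats::setNames(2L, as.character(admixture_nodes(g))))
  list(graph = g, params = params)
}

# Balanced 4-leaf rooted tree ((A,B),(C,D)).
balanced4 <- function() {
  graph_from_names(parent = c("r", "r", "u", "u", "w", "w"),
                   child  = c("u", "w", "A", "B", "C", "D"))
}

# 4-leaf caterpillar (((A,C),B),D).
caterpillar4_acbd <- function() {
  graph_from_names(parent = c("r", "r", "u", "u", "w", "w"),
                   child  = c("D", "u", "B", "w", "A", "C"))
}

expect_valid <- function(g) {
  chk <- validate_directed(g)
  testthat::expect_true(chk$ok, info = paste(chk$violations, collapse = "; "))
}

# The case-study local optimum N1 (best gene-flow addition from the NJ
# starting tree), memoized across test files.
.m1_cache <- new.env(parent = emptyenv())
m1_local_optimum <- function() {
  if (is.null(.m1_cache$n1)) {
    fx <- make_m1()
    cfg <- search_config(1L, "E", mlno = FALSE)
    n0 <- starting_tree(fx$data, cfg)
    st <- add_admixture_step(n0, rep(0L, nrow(n0$edges)), fx$data, cfg)
    .m1_cache$n0 <- n0
    .m1_cache$n1 <- st$network
    .m1_cache$n1_fit <- st$fit
  }
  list(n0 = .m1_cache$n0, n1 = .m1_cache$n1, fit = .m1_cache$n1_fit)
}

# Independent pairwise path-length oracle for trees: undirected Dijkstra
# over the tree's edge lengths.
tree_path_f2_oracle <- function(g, lengths) {
  nv <- max(g$edges, g$root)
  W <- matrix(Inf, nv, nv)
  diag(W) <- 0
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, 1]; b <- g$edges[i, 2]
    W[a, b] <- W[b, a] <- lengths[i]
  }
  for (k in seq_len(nv)) for (i in seq_len(nv)) for (j in seq_len(nv))
    if (W[i, k] + W[k, j] < W[i, j]) W[i, j] <- W[i, k] + W[k, j]
  lv <- leaves(g)
  labs <- g$labels[lv]
  cmb <- utils::combn(order(labs), 2)
  y <- numeric(ncol(cmb))
  names(y) <- apply(cmb, 2, function(ix)
    paste(sort(labs[ix]), collapse = "|"))
  for (k in seq_len(ncol(cmb)))
    y[k] <- W[lv[cmb[1, k]], lv[cmb[2, k]]]
  y
}
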