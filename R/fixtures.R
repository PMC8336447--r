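## Model fixtures and the f2 simulator.
##
## The five-population case-study fixture ("m1") is a caterpillar tree on
## A..E rooted at the outgroup E, with one edge addition between the edges
## pendant to D and to A, so that A is admixed.  Its numerical parameters
## are package constants chosen so that the fixture reproduces the
## phenomenology that motivates the orientation search: the NJ/ML starting
## tree is not a base tree of the true network, the best edge addition from
## that tree makes the outgroup E admixed, and the true network is the
## unique global optimum among all one-admixture topologies (see
## validate_m1()).

#' Construct the five-population case-study fixture
#'
#' @param se standard error attached to every f2 entry (default 1e-4).
#' @return list of class `model_fixture` with `name`, `graph`, `params`,
#'   `data` (the exact f2 implied by the model).
#' @export
make_m1 <- function(se = 1e-4) {
  ## ids: 1 r, 2 v3, 3 v2, 4 v1, 5 E, 6 D, 7 C, 8 A, 9 B, 10 s, 11 t
  edges <- rbind(c(1L, 5L),   # r  -> E
                 c(1L, 2L),   # r  -> v3
                 c(2L, 10L),  # v3 -> s
                 c(10L, 6L),  # s  -> D
                 c(2L, 3L),   # v3 -> v2
                 c(3L, 7L),   # v2 -> C
                 c(3L, 4L),   # v2 -> v1
                 c(4L, 11L),  # v1 -> t   (base-tree side of the admixture)
                 c(11L, 8L),  # t  -> A
                 c(4L, 9L),   # v1 -> B
                 c(10L, 11L)) # s  -> t   (gene-flow arc)
  labels <- c(NA, NA, NA, NA, "E", "D", "C", "A", "B", NA, NA)
  g <- admix_graph(edges, labels, 1L)
  lengths <- c(0.150,  # r->E   (long outgroup pendant)
               0.020,  # r->v3
               0.020,  # v3->s
               0.040,  # s->D
               0.020,  # v3->v2
               0.060,  # v2->C
               0.020,  # v2->v1
               0.000,  # v1->t
               0.050,  # t->A
               0.060,  # v1->B
               0.000)  # s->t
  params <- drift_params(g, lengths, gamma = c(`11` = 0.45))
  structure(list(name = "m1", graph = g, params = params,
                 data = f2_from_model(g, params, se)),
            class = "model_fixture")
}

#' @export
print.model_fixture <- function(x, ...) {
  cat(sprintf("Model fixture '%s': %d populations, h = %d, %d f2 pairs\n",
              x$name, length(populations(x$graph)), n_admixture(x$graph),
              nrow(x$data)))
  invisible(x)
}

#' Random admixture-graph fixture
#'
#' A random rooted binary tree (stepwise leaf insertion at uniformly chosen
#' edges) followed by `h` random legal gene-flow edge additions.  Branch
#' lengths are Uniform(0.01, 0.5) drift units on edges not incident to an
#' admixture node and 0 on admixture-incident edges (so the exact f2 data
#' are reproducible under either fitting convention); admixture proportions
#' are Uniform(0.1, 0.9).
#'
#' @param n_pops number of populations (2..26; labeled A, B, ...).
#' @param h number of admixture events, `h <= n_pops - 2`.
#' @param seed integer seed (fixture is reproducible).
#' @param se standard error attached to every f2 entry.
#' @return a `model_fixture`.
#' @export
random_graph <- function(n_pops, h = 0L, seed = 1L, se = 1e-4) {
  stopifnot(n_pops >= 2L, n_pops <= 26L, h >= 0L, h <= n_pops - 2L)
  set.seed(seed)
  labs <- LETTERS[seq_len(n_pops)]
  g <- graph_from_names(parent = c("r", "r"), child = labs[1:2])
  for (lab in labs[-(1:2)]) {
    i <- sample.int(nrow(g$edges), 1L)
    s1 <- ag_subdivide(g, g$edges[i, 1L], g$edges[i, 2L])
    g <- s1$graph
    lf <- ag_nv(g) + 1L
    g$edges <- rbind(g$edges, c(s1$new, lf))
    g$labels <- c(g$labels, rep(NA_character_, lf - 1L - length(g$labels)), lab)
    g <- ag_compact(g)
  }
  labeling <- rep(0L, nrow(g$edges))
  for (k in seq_len(h)) {
    cands <- enumerate_edge_additions(g, labeling, gene_flow_only = TRUE)
    if (!length(cands)) stop("no legal gene-flow edge addition remains")
    pick <- cands[[sample.int(length(cands), 1L)]]
    g <- pick$graph; labeling <- pick$labeling
  }
  am <- admixture_nodes(g)
  incident <- g$edges[, 1L] %in% am | g$edges[, 2L] %in% am
  lengths <- ifelse(incident, 0, stats::runif(nrow(g$edges), 0.01, 0.5))
  gamma <- stats::runif(length(am), 0.1, 0.9)
  names(gamma) <- as.character(am)
  params <- drift_params(g, lengths, gamma)
  structure(list(name = sprintf("random_n%d_h%d_s%d", n_pops, h, seed),
                 graph = g, params = params,
                 data = f2_from_model(g, params, se)),
            class = "model_fixture")
}

#' Simulate noisy f2-statistics from a fixture
#'
#' Each observed statistic is the model expectation plus independent
#' Gaussian noise of standard deviation `se`; the reported standard error
#' equals `se`.
#'
#' @param fixture a `model_fixture`.
#' @param se noise standard deviation (`> 0`).
#' @param seed integer seed.
#' @return an `f2_dataset`.
#' @export
simulate_f2 <- function(fixture, se, seed = 1L) {
  stopifnot(se > 0)
  set.seed(seed)
  y <- expected_f2(fixture$graph, fixture$params)
  pp <- do.call(rbind, strsplit(names(y), "|", fixed = TRUE))
  f2_dataset(pp[, 1L], pp[, 2L],
             unname(y) + se * stats::rnorm(length(y)), se)
}

#' All one-admixture networks on a population set
#'
#' Every legal gene-flow edge addition applied to every rooted tree
#' topology, deduplicated by isomorphism modulo the root position.  Used
#' for brute-force global-optimum checks on small fixtures.
#'
#' @param pops character vector of population names (guarded at 6).
#' @return list of `admix_graph`s.
#' @export
all_one_admixture_networks <- function(pops) {
  if (length(pops) > 6L) stop("brute-force enumeration guarded at 6 populations")
  out <- list(); seen <- new_net_set()
  for (t in all_rooted_trees(sort(pops))) {
    for (cd in enumerate_edge_additions(t, rep(0L, nrow(t$edges)),
                                        gene_flow_only = TRUE)) {
      if (net_set_add(seen, cd$graph))
        out[[length(out) + 1L]] <- cd$graph
    }
  }
  out
}

#' Validate the case-study fixture's phenomenology
#'
#' Brute-force checks mirroring the construction of the case study:
#' (i) the true network is the unique global optimum (up to isomorphism)
#' among all one-admixture networks on its populations; (ii) the NJ/ML
#' starting tree is not a base tree of the truth; (iii) the best gene-flow
#' edge addition from the starting tree yields a network in which the
#' outgroup E is admixed.
#'
#' @param fx a `model_fixture` from [make_m1()].
#' @param convention fitting convention used for scoring.
#' @return list with logical fields `unique_optimum`, `nj_not_base_tree`,
#'   `best_addition_admixes_outgroup`, plus supporting details.
#' @export
validate_m1 <- function(fx, convention = "admixturegraph") {
  data <- fx$data
  nets <- all_one_admixture_networks(populations(fx$graph))
  ## coarse profile scores rank all classes; the leaders are refit exactly
  coarse <- vapply(nets, function(n)
    fit_quick(n, data, convention)$loglik, numeric(1))
  top <- order(-coarse)[seq_len(min(8L, length(nets)))]
  scores <- coarse
  scores[top] <- vapply(top, function(i)
    score_graph(nets[[i]], data, convention)$loglik, numeric(1))
  best <- which.max(scores)
  second <- max(scores[-best])
  unique_optimum <- is_isomorphic_unrooted(nets[[best]], fx$graph) &&
    scores[best] > second + 1
  cfg <- search_config(1L, "E", mlno = FALSE)
  n0 <- starting_tree(data, cfg)
  nj_not_base <- !is_base_tree(n0, fx$graph)
  st <- add_admixture_step(n0, rep(0L, nrow(n0$edges)), data, cfg)
  m <- admixture_nodes(st$network)
  admixed_pop <- st$network$labels[ag_children(st$network, m[1L])]
  list(unique_optimum = unique_optimum,
       nj_not_base_tree = nj_not_base,
       best_addition_admixes_outgroup = identical(admixed_pop, "E"),
       n0 = n0, n1 = st$network, scores = scores,
       best_score = scores[best], second_score = second)
}
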