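## Full starting-tree-based maximum likelihood (STB-ML) search driver:
## starting tree, iterated gene-flow edge addition, tail-move hill
## climbing, and (optionally) an exhaustive maximum likelihood network
## orientation after every edge addition.

#' Search configuration
#'
#' @param num_admixture number of admixture events to add (`h >= 0`).
#' @param outgroup population fixing the root.
#' @param start starting-tree mode: `"nj"` (neighbor joining, default,
#'   deterministic), `"exact_ml"` (brute force over all rooted topologies,
#'   guarded at 8 populations), or `"random_addition"` (stepwise maximum
#'   likelihood leaf insertion in seed-shuffled order, then tail-move
#'   climbing).
#' @param exhaustive_edge_addition score every legal gene-flow edge
#'   addition; when `FALSE`, only candidate edges implicated by the largest
#'   scaled residuals are tried.
#' @param mlno run the exhaustive orientation search after each addition.
#' @param candidate_k number of worst-residual pairs feeding the heuristic
#'   candidate edge set.
#' @param seed integer seed for the random-addition order.
#' @param tol minimum log-likelihood improvement accepted during hill
#'   climbing.
#' @param convention fitting convention, see [fit_params()].
#' @param mlno_all_roots,mlno_max_h passed to [mlno()].
#' @return list of class `search_config`.
#' @export
search_config <- function(num_admixture, outgroup, start = "nj",
                          exhaustive_edge_addition = TRUE, mlno = TRUE,
                          candidate_k = 5L, seed = NULL, tol = 1e-6,
                          convention = "treemix",
                          mlno_all_roots = FALSE, mlno_max_h = 6L) {
  stopifnot(num_admixture >= 0, tol > 0)
  start <- match.arg(start, c("nj", "exact_ml", "random_addition"))
  structure(list(num_admixture = as.integer(num_admixture),
                 outgroup = outgroup, start = start,
                 exhaustive_edge_addition = exhaustive_edge_addition,
                 mlno = mlno, candidate_k = as.integer(candidate_k),
                 seed = seed, tol = tol, convention = convention,
                 mlno_all_roots = mlno_all_roots,
                 mlno_max_h = as.integer(mlno_max_h)),
            class = "search_config")
}

## f2 data as a symmetric matrix (distance-like input to neighbor joining).
f2_matrix <- function(data) {
  pops <- sort(unique(c(data$pop1, data$pop2)))
  M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(nrow(data))) {
    M[data$pop1[i], data$pop2[i]] <- data$f2[i]
    M[data$pop2[i], data$pop1[i]] <- data$f2[i]
  }
  M
}

## Convert an unrooted binary ape::phylo into an admix_ugraph.
phylo_to_ugraph <- function(tr) {
  nt <- length(tr$tip.label)
  labels <- c(tr$tip.label, rep(NA_character_, tr$Nnode))
  structure(list(edges = cbind(tr$edge[, 1L], tr$edge[, 2L]),
                 labels = labels, admix = integer(0)),
            class = "admix_ugraph")
}

#' Neighbor-joining tree from f2-statistics
#'
#' Standard neighbor joining (via \pkg{ape}) on the pairwise f2 matrix;
#' recovers the generating topology exactly on additive (tree) inputs.
#'
#' @param data an `f2_dataset` with at least 3 populations.
#' @return an unrooted tree as `admix_ugraph`.
#' @export
nj_tree <- function(data) {
  M <- f2_matrix(data)
  if (nrow(M) < 3L) stop("neighbor joining needs at least 3 populations")
  phylo_to_ugraph(ape::unroot(ape::nj(stats::as.dist(M))))
}

root_at_outgroup <- function(u, outgroup) {
  og <- which(!is.na(u$labels) & u$labels == outgroup)
  if (!length(og)) stop("unknown outgroup ", outgroup)
  ri <- which(u$edges[, 1L] == og | u$edges[, 2L] == og)
  g <- orient(u, orientation_spec(u$edges[ri[1L], ], u$admix))
  if (is.null(g)) stop("could not root the network at ", outgroup)
  g
}

## All rooted binary tree topologies on a label set (stepwise enumeration:
## each later leaf inserted into every edge or above the root).
all_rooted_trees <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("need at least two labels")
  base <- graph_from_names(parent = c("r", "r"),
                           child = labels[1:2])
  trees <- list(base)
  for (lab in labels[-(1:2)]) {
    nxt <- list()
    for (t in trees) {
      for (i in seq_len(nrow(t$edges))) {
        s1 <- ag_subdivide(t, t$edges[i, 1L], t$edges[i, 2L])
        g <- s1$graph
        lf <- ag_nv(g) + 1L
        g$edges <- rbind(g$edges, c(s1$new, lf))
        g$labels <- c(g$labels, rep(NA_character_, lf - 1L - length(g$labels)), lab)
        nxt[[length(nxt) + 1L]] <- ag_compact(g)
      }
      ## new root above the old root
      nr <- ag_nv(t) + 1L; lf <- nr + 1L
      g <- t
      g$edges <- rbind(g$edges, c(nr, g$root), c(nr, lf))
      g$labels <- c(g$labels, NA_character_, lab)
      g$root <- nr
      nxt[[length(nxt) + 1L]] <- ag_compact(g)
    }
    trees <- nxt
  }
  trees
}

#' Compute the starting tree of a search
#'
#' @param data an `f2_dataset`.
#' @param config a [search_config()].
#' @return a rooted tree (`admix_graph`, h = 0) rooted at the outgroup.
#' @export
starting_tree <- function(data, config) {
  pops <- sort(unique(c(data$pop1, data$pop2)))
  og <- config$outgroup
  if (!(og %in% pops)) stop("outgroup not present in the data")
  switch(config$start,
    nj = root_at_outgroup(nj_tree(data), og),
    exact_ml = {
      if (length(pops) > 8L)
        stop("exact ML starting tree guarded at 8 populations")
      cands <- lapply(all_rooted_trees(setdiff(pops, og)), function(t) {
        nr <- ag_nv(t) + 1L; lf <- nr + 1L
        t$edges <- rbind(t$edges, c(nr, t$root), c(nr, lf))
        t$labels <- c(t$labels, NA_character_, og)
        t$root <- nr
        ag_compact(t)
      })
      scores <- vapply(cands, function(t)
        fit_params(t, data, config$convention)$loglik, numeric(1))
      cands[[which.max(scores)]]
    },
    random_addition = {
      if (!is.null(config$seed)) set.seed(config$seed)
      others <- sample(setdiff(pops, og))
      g <- graph_from_names(parent = c("r", "r", "v", "v"),
                            child = c(og, "v", others[1L], others[2L]))
      for (lab in others[-(1:2)]) {
        cands <- list()
        for (i in seq_len(nrow(g$edges))) {
          s1 <- ag_subdivide(g, g$edges[i, 1L], g$edges[i, 2L])
          g2 <- s1$graph
          lf <- ag_nv(g2) + 1L
          g2$edges <- rbind(g2$edges, c(s1$new, lf))
          g2$labels <- c(g2$labels, rep(NA_character_, lf - 1L - length(g2$labels)), lab)
          cands[[length(cands) + 1L]] <- ag_compact(g2)
        }
        sub <- f2_subset(data, c(populations(cands[[1L]])))
        scores <- vapply(cands, function(t)
          fit_params(t, sub, config$convention)$loglik, numeric(1))
        g <- cands[[which.max(scores)]]
      }
      hill_climb(g, data, config)$network
    })
}

## Restriction of a dataset to a population subset.
f2_subset <- function(data, pops) {
  d <- data[data$pop1 %in% pops & data$pop2 %in% pops, , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("f2_dataset", "data.frame")
  d
}

## Edges on the root-to-leaf paths of the given populations.
root_path_edges <- function(g, pops) {
  R <- build_reachability(g)
  lv <- which(!is.na(g$labels) & g$labels %in% pops)
  rows <- logical(nrow(g$edges))
  for (i in seq_len(nrow(g$edges)))
    rows[i] <- any(R[g$edges[i, 2L], lv])
  which(rows)
}

#' One gene-flow edge addition step
#'
#' Scores legal gene-flow edge additions and returns the best resulting
#' network.  In exhaustive mode every legal pair of base-tree edges is
#' scored; in heuristic mode only pairs of edges lying on root paths of the
#' populations in the `candidate_k` worst-residual pairs are scored.
#'
#' @param g current network.
#' @param labeling current tree-based labeling.
#' @param data an `f2_dataset`.
#' @param config a [search_config()].
#' @return list with `network`, `labeling`, `fit`.
#' @export
add_admixture_step <- function(g, labeling, data, config) {
  cands <- enumerate_edge_additions(g, labeling, gene_flow_only = TRUE)
  if (!length(cands)) stop("empty legal edge addition neighborhood")
  if (!config$exhaustive_edge_addition) {
    cur <- fit_params(g, data, config$convention, labeling = labeling)
    res <- cur$residuals
    worst <- res[order(-abs(res$scaled)), ][seq_len(min(config$candidate_k,
                                                        nrow(res))), ]
    keep <- root_path_edges(g, unique(c(worst$pop1, worst$pop2)))
    sel <- vapply(cands, function(cd) {
      edge_row(g, cd$e) %in% keep && edge_row(g, cd$f) %in% keep
    }, logical(1))
    if (any(sel)) cands <- cands[sel]
  }
  ## coarse ranking pass, then exact refits of the leaders
  coarse <- vapply(cands, function(cd)
    fit_quick(cd$graph, data, config$convention, cd$labeling)$loglik,
    numeric(1))
  top <- order(-coarse)[seq_len(min(5L, length(cands)))]
  fits <- lapply(top, function(i)
    fit_params(cands[[i]]$graph, data, config$convention,
               labeling = cands[[i]]$labeling))
  best <- top[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]
  fit <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  list(network = cands[[best]]$graph, labeling = cands[[best]]$labeling,
       fit = fit)
}

#' Steepest-ascent hill climbing over tail moves
#'
#' Repeatedly scores every legal tail move (each candidate refit under a
#' freshly computed tree-based labeling) and takes the best one, stopping
#' when no neighbor improves the log-likelihood by more than `config$tol`.
#'
#' @param g current network.
#' @param data an `f2_dataset`.
#' @param config a [search_config()].
#' @return list with `network`, `fit`, `labeling`, `steps` (number of moves
#'   taken).
#' @export
hill_climb <- function(g, data, config) {
  labeling <- find_tree_based_labeling(g)
  cur <- fit_params(g, data, config$convention, labeling = labeling)
  steps <- 0L
  repeat {
    nbrs <- enumerate_tail_moves(g)
    labs <- lapply(nbrs, function(nb) find_tree_based_labeling(nb$graph))
    keep <- if (config$convention == "treemix")
      which(!vapply(labs, is.null, logical(1))) else seq_along(nbrs)
    if (!length(keep)) break
    coarse <- vapply(keep, function(i)
      fit_quick(nbrs[[i]]$graph, data, config$convention, labs[[i]])$loglik,
      numeric(1))
    top <- keep[order(-coarse)[seq_len(min(5L, length(keep)))]]
    fits <- lapply(top, function(i)
      fit_params(nbrs[[i]]$graph, data, config$convention,
                 labeling = labs[[i]]))
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    if (max(lls) <= cur$loglik + config$tol) break
    i <- top[which.max(lls)]
    g <- nbrs[[i]]$graph; labeling <- labs[[i]]; cur <- fits[[which.max(lls)]]
    steps <- steps + 1L
  }
  list(network = g, fit = cur, labeling = labeling, steps = steps)
}

#' Run the full admixture-graph search
#'
#' Step 1 builds the starting tree rooted at the outgroup.  Then for each
#' admixture event: (2a) the best gene-flow edge addition, (2b) tail-move
#' hill climbing, and (2c, optional) an exhaustive maximum likelihood
#' network orientation.  With `config$mlno = FALSE` this is the plain
#' starting-tree-based baseline.
#'
#' @param data an `f2_dataset`.
#' @param config a [search_config()].
#' @return list with `network`, `fit`, `trace` (data.frame of per-stage
#'   log-likelihoods), and `config`.
#' @export
run_search <- function(data, config) {
  g <- starting_tree(data, config)
  labeling <- rep(0L, nrow(g$edges))
  fit <- fit_params(g, data, config$convention, labeling = labeling)
  trace <- data.frame(iteration = 0L, stage = "starting_tree",
                      loglik = fit$loglik, stringsAsFactors = FALSE)
  add_rec <- function(it, stage, ll)
    rbind(trace, data.frame(iteration = it, stage = stage, loglik = ll,
                            stringsAsFactors = FALSE))
  h <- config$num_admixture
  if (h > 0L) {
    for (i in seq_len(h)) {
      st <- add_admixture_step(g, labeling, data, config)
      g <- st$network; labeling <- st$labeling; fit <- st$fit
      trace <- add_rec(i, "edge_addition", fit$loglik)
      hc <- hill_climb(g, data, config)
      g <- hc$network; labeling <- hc$labeling; fit <- hc$fit
      trace <- add_rec(i, "tail_moves", fit$loglik)
      if (config$mlno) {
        mo <- mlno(g, data, config$convention, config$outgroup,
                   max_h = config$mlno_max_h,
                   all_roots = config$mlno_all_roots)
        g <- mo$network; fit <- mo$fit
        labeling <- fit$labeling
        trace <- add_rec(i, "mlno", fit$loglik)
      }
    }
  }
  list(network = g, fit = fit, trace = trace, config = config)
}
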