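## Orienting undirected networks.  Specifying the root edge and the set of
## admixture nodes determines at most one valid orientation of a binary
## undirected network; it is found here by constraint propagation on
## required in-degrees.  On top of this sit the (outgroup-rooted)
## orientation neighborhood and the exhaustive maximum likelihood network
## orientation (MLNO) search.

#' Orientation specification
#'
#' @param root_edge length-2 integer vector, an edge of the undirected
#'   network to be subdivided by the root.
#' @param admix_set integer ids of the internal vertices designated as
#'   admixture nodes.
#' @return list of class `orientation_spec`.
#' @export
orientation_spec <- function(root_edge, admix_set = integer(0)) {
  structure(list(root_edge = as.integer(root_edge),
                 admix_set = sort(as.integer(admix_set))),
            class = "orientation_spec")
}

#' Orient an undirected network
#'
#' Subdivides the root edge with a new root vertex, directs both root edges
#' outward, and propagates direction constraints: every vertex has a
#' required in-degree (root 0, admixture nodes 2, all others 1).  Whenever
#' a vertex has received its full in-degree its remaining edges point
#' outward; whenever its undirected edges are exactly its in-degree deficit
#' they point inward.  Returns `NULL` if propagation stalls, overshoots, or
#' the completed graph is not a valid directed network; otherwise the
#' unique valid orientation.
#'
#' @param u an `admix_ugraph`.
#' @param spec an [orientation_spec()].
#' @return an `admix_graph`, or `NULL` when no orientation exists.
#' @export
orient <- function(u, spec) {
  deg <- ug_degree(u)
  nv0 <- length(deg)
  lv <- which(deg == 1L)
  if (any(spec$admix_set %in% lv) || any(spec$admix_set > nv0))
    stop("admixture set must be internal vertices of the network")
  ri <- which((u$edges[, 1L] == spec$root_edge[1L] &
               u$edges[, 2L] == spec$root_edge[2L]) |
              (u$edges[, 1L] == spec$root_edge[2L] &
               u$edges[, 2L] == spec$root_edge[1L]))
  if (!length(ri)) stop("root edge not found in the network")
  ## parallel copies (an undirected "bubble" under the old root) are
  ## interchangeable: subdividing either gives isomorphic orientations
  ri <- ri[1L]
  rho <- nv0 + 1L
  E <- rbind(u$edges[-ri, , drop = FALSE],
             c(rho, u$edges[ri, 1L]),
             c(rho, u$edges[ri, 2L]))
  ne <- nrow(E)
  ## dir: 0 unknown, 1 = E[i,1] -> E[i,2], -1 = reverse
  dir <- integer(ne)
  dir[ne - 1L] <- 1L; dir[ne] <- 1L
  req_in <- rep(1L, rho)
  req_in[rho] <- 0L
  req_in[spec$admix_set] <- 2L
  degs <- tabulate(as.integer(E), rho)
  req_out <- degs - req_in
  inc <- lapply(seq_len(rho), function(v) which(E[, 1L] == v | E[, 2L] == v))
  repeat {
    changed <- FALSE
    for (v in seq_len(rho)) {
      rows <- inc[[v]]
      into <- (E[rows, 1L] == v & dir[rows] == -1L) |
              (E[rows, 2L] == v & dir[rows] == 1L)
      outof <- (E[rows, 1L] == v & dir[rows] == 1L) |
               (E[rows, 2L] == v & dir[rows] == -1L)
      unk <- rows[dir[rows] == 0L]
      n_in <- sum(into); n_out <- sum(outof)
      if (n_in > req_in[v] || n_out > req_out[v]) return(NULL)
      if (!length(unk)) next
      if (n_in == req_in[v]) {
        dir[unk] <- ifelse(E[unk, 1L] == v, 1L, -1L); changed <- TRUE
      } else if (n_in + length(unk) == req_in[v] || n_out == req_out[v]) {
        dir[unk] <- ifelse(E[unk, 2L] == v, 1L, -1L); changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (any(dir == 0L)) return(NULL)
  from <- ifelse(dir == 1L, E[, 1L], E[, 2L])
  to   <- ifelse(dir == 1L, E[, 2L], E[, 1L])
  g <- admix_graph(cbind(from, to),
                   c(u$labels[seq_len(nv0)], NA_character_), rho)
  if (!ag_is_valid(g)) return(NULL)
  ag_compact(g)
}

#' Enumerate the (outgroup-rooted) orientation neighborhood
#'
#' All valid orientations of the undirected version of `g` having the same
#' number of admixture nodes, with the root on the outgroup's pendant edge
#' (or on every edge when `all_roots`), over all ways of choosing the
#' admixture vertex set among internal vertices.  Contains a network
#' isomorphic to `g` itself; deduplicated by isomorphism; deterministic
#' order.
#'
#' @param g a valid `admix_graph`.
#' @param outgroup population name fixing the root edge.
#' @param all_roots consider every root edge, not just the outgroup pendant
#'   edge.
#' @return list of `admix_graph`s.
#' @export
enumerate_orientations <- function(g, outgroup, all_roots = FALSE) {
  u <- to_undirected(g)
  if (!(outgroup %in% populations(g))) stop("unknown outgroup ", outgroup)
  h <- n_admixture(g)
  deg <- ug_degree(u)
  internal <- which(deg >= 3L)
  og <- which(!is.na(u$labels) & u$labels == outgroup)
  root_rows <- if (all_roots) seq_len(nrow(u$edges)) else
    which(u$edges[, 1L] == og | u$edges[, 2L] == og)
  sets <- if (h == 0L) list(integer(0)) else
    utils::combn(internal, h, simplify = FALSE)
  out <- list(); seen <- character(0)
  for (ri in root_rows) {
    for (am in sets) {
      n2 <- orient(u, orientation_spec(u$edges[ri, ], am))
      if (is.null(n2)) next
      key <- ag_canonical(n2)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- n2
    }
  }
  out
}

#' Maximum likelihood network orientation (MLNO)
#'
#' Scores every member of the outgroup-rooted orientation neighborhood of
#' `g` (over all tree-based labelings, by default) and returns the
#' highest-scoring orientation.  The input network's own refit is the
#' first candidate, so the returned likelihood never falls below it.
#'
#' @param g a valid `admix_graph`.
#' @param data an `f2_dataset`.
#' @param convention fitting convention, see [fit_params()].
#' @param outgroup population name fixing the root edge.
#' @param max_h refuse exhaustive search above this admixture count.
#' @param all_roots consider every root edge.
#' @param ... passed to [score_graph()].
#' @return list with `network`, `fit`, `scores` (per candidate), and
#'   `candidates`.
#' @export
mlno <- function(g, data, convention = "treemix", outgroup,
                 max_h = 6L, all_roots = FALSE, ...) {
  if (n_admixture(g) > max_h)
    stop("exhaustive MLNO refused for h > ", max_h,
         "; a constrained heuristic is required at this scale")
  cands <- c(list(g), enumerate_orientations(g, outgroup, all_roots))
  ## coarse ranking (best labeling per candidate), exact refits of leaders
  ## plus the input network itself
  coarse <- vapply(cands, function(n) {
    labs <- tryCatch(enumerate_labelings(n), error = function(e) list())
    if (convention == "admixturegraph")
      return(tryCatch(fit_quick(n, data, convention)$loglik,
                      error = function(e) -Inf))
    if (!length(labs)) return(-Inf)
    max(vapply(labs, function(l)
      tryCatch(fit_quick(n, data, convention, l)$loglik,
               error = function(e) -Inf), numeric(1)))
  }, numeric(1))
  top <- union(1L, order(-coarse)[seq_len(min(3L, length(cands)))])
  fits <- vector("list", length(cands))
  scores <- rep(-Inf, length(cands))
  for (i in top) {
    fits[[i]] <- tryCatch(score_graph(cands[[i]], data, convention, ...),
                          error = function(e) NULL)
    scores[i] <- if (is.null(fits[[i]])) -Inf else fits[[i]]$loglik
  }
  best <- which.max(scores)
  list(network = cands[[best]], fit = fits[[best]], scores = scores,
       candidates = cands)
}
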