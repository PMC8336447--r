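## Tree-based labelings: 0/1 edge labelings separating base-tree edges from
## gene-flow edges.  Because every non-admixture vertex has a single incoming
## edge (forced to 0), a labeling is determined by choosing, at each
## admixture node, which of its two incoming edges belongs to the base tree.

#' Check that a 0/1 edge labeling is tree-based
#'
#' A labeling is tree-based when every non-root vertex has exactly one
#' incoming edge labeled 0, every vertex with children has at least one
#' outgoing edge labeled 0, and both root edges are labeled 0 (the last
#' condition is specific to base trees that span the root).
#'
#' @param g an `admix_graph`.
#' @param psi integer vector of 0/1 labels aligned with the rows of
#'   `g$edges`.
#' @return logical.
#' @export
is_tree_based_labeling <- function(g, psi) {
  if (length(psi) != nrow(g$edges) || !all(psi %in% c(0L, 1L))) return(FALSE)
  e <- g$edges
  nv <- ag_nv(g)
  in0 <- tabulate(e[psi == 0L, 2L], nv)
  present <- ag_indeg(g) > 0L | ag_outdeg(g) > 0L
  present[g$root] <- TRUE
  nonroot <- which(present); nonroot <- nonroot[nonroot != g$root]
  if (any(in0[nonroot] != 1L)) return(FALSE)
  out0 <- tabulate(e[psi == 0L, 1L], nv)
  haskids <- which(ag_outdeg(g) > 0L)
  if (any(out0[haskids] < 1L)) return(FALSE)
  if (any(psi[e[, 1L] == g$root] != 0L)) return(FALSE)
  TRUE
}

## All 2^h designation choices as labelings (unchecked); admixture nodes in
## id order, and per node the 0-designated parent in id order, so the
## enumeration is lexicographic and deterministic.
labeling_candidates <- function(g) {
  am <- admixture_nodes(g)
  h <- length(am)
  base <- rep(0L, nrow(g$edges))
  if (h == 0L) return(list(base))
  choices <- lapply(am, function(m) {
    rows <- which(g$edges[, 2L] == m)
    rows[order(g$edges[rows, 1L])]
  })
  out <- list()
  for (mask in 0:(2^h - 1L)) {
    psi <- base
    for (k in seq_len(h)) {
      pick <- if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0L) 2L else 1L
      psi[choices[[k]][-pick]] <- 1L   # non-designated incoming edge -> 1
    }
    out[[length(out) + 1L]] <- psi
  }
  out
}

#' Enumerate all tree-based labelings of a network
#'
#' Evaluates all `2^h` incoming-edge designation choices and keeps the ones
#' satisfying the tree-based conditions, in lexicographic order of the
#' designation choices (admixture nodes by id).
#'
#' @param g a valid `admix_graph`.
#' @param max_h guard on the number of admixture nodes (default 12).
#' @return list of 0/1 integer vectors aligned with `g$edges` rows.
#' @export
enumerate_labelings <- function(g, max_h = 12L) {
  if (n_admixture(g) > max_h)
    stop("refusing to enumerate labelings for h > ", max_h)
  Filter(function(psi) is_tree_based_labeling(g, psi), labeling_candidates(g))
}

#' Find one tree-based labeling, or NULL if none exists
#'
#' @param g a valid `admix_graph`.
#' @return 0/1 integer vector, or `NULL` when the network admits no
#'   tree-based labeling.
#' @export
find_tree_based_labeling <- function(g) {
  ls <- enumerate_labelings(g)
  if (length(ls)) ls[[1L]] else NULL
}

## ---- displayed trees ---------------------------------------------------

#' Trees displayed by a network
#'
#' One candidate tree per combination of keeping exactly one incoming edge
#' at each admixture node; resulting degree-2 vertices are suppressed and
#' dead internal branches pruned.  Duplicates (up to rooted isomorphism)
#' are removed.
#'
#' @param g a valid `admix_graph`.
#' @return list of `admix_graph` trees (h = 0).
#' @export
displayed_trees <- function(g) {
  out <- list(); seen <- character(0)
  for (psi in labeling_candidates(g)) {
    t <- ag_compact(ag_cleanup(ag_drop_edges(g, which(psi == 1L))))
    key <- ag_canonical(t)
    if (!(key %in% seen)) { seen <- c(seen, key); out[[length(out) + 1L]] <- t }
  }
  out
}

#' Base trees of a network
#'
#' The spanning trees given by the 0-labeled edges of each tree-based
#' labeling, deduplicated up to rooted isomorphism.
#'
#' @param g a valid `admix_graph`.
#' @return list of `admix_graph` trees.
#' @export
base_trees <- function(g) {
  out <- list(); seen <- character(0)
  for (psi in enumerate_labelings(g)) {
    t <- ag_compact(ag_cleanup(ag_drop_edges(g, which(psi == 1L))))
    key <- ag_canonical(t)
    if (!(key %in% seen)) { seen <- c(seen, key); out[[length(out) + 1L]] <- t }
  }
  out
}

#' Is a rooted tree a base tree of a network?
#' @param tree an `admix_graph` with h = 0.
#' @param g a valid `admix_graph`.
#' @return logical.
#' @export
is_base_tree <- function(tree, g) {
  key <- ag_canonical(ag_compact(tree))
  any(vapply(base_trees(g), ag_canonical, character(1)) == key)
}
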