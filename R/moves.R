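## Topology-modifying search moves: edge additions (which create one new
## admixture node), tail moves and head moves, together with neighborhood
## enumeration, legality testing via a reachability (ancestor) index, and
## BFS distances in move space.

#' Build the ancestor (reachability) index of a network
#'
#' Transitive closure of the DAG, computed in one reverse-topological
#' sweep: `R[u, v]` is `TRUE` iff a directed path `u -> ... -> v` exists
#' (vertices reach themselves).
#'
#' @param g a valid `admix_graph`.
#' @return logical matrix indexed by vertex id.
#' @export
build_reachability <- function(g) {
  nv <- ag_nv(g)
  R <- diag(nv) > 0
  for (v in rev(ag_topo_order(g))) {
    ch <- ag_children(g, v)
    for (c in ch) R[v, ] <- R[v, ] | R[c, ]
  }
  R
}

edge_row <- function(g, e) {
  i <- which(g$edges[, 1L] == e[1L] & g$edges[, 2L] == e[2L])
  if (length(i) != 1L) stop("no such edge ", e[1L], "->", e[2L])
  i
}

#' Apply an edge addition
#'
#' Subdivides `e` with a new vertex `s` and `f` with a new vertex `t`, then
#' adds the linking arc `s -> t`; `t` becomes an admixture node.  The edge
#' count grows by 3 and the admixture count by 1.
#'
#' @param g a valid `admix_graph`.
#' @param e,f length-2 integer vectors `(from, to)`; `e != f`.
#' @return the resulting `admix_graph` (not validity-checked; see
#'   [enumerate_edge_additions()] for legality).
#' @export
apply_edge_addition <- function(g, e, f) {
  if (all(e == f)) stop("edge addition requires two distinct edges")
  s1 <- ag_subdivide(g, e[1L], e[2L]); g <- s1$graph; s <- s1$new
  s2 <- ag_subdivide(g, f[1L], f[2L]); g <- s2$graph; t <- s2$new
  g$edges <- rbind(g$edges, c(s, t))
  g
}

#' Enumerate the (gene-flow) edge addition neighborhood
#'
#' All ordered pairs of edges `(e, f)` whose addition yields a valid
#' network.  Legality is the reachability test (the head of `f` must not
#' reach the tail of `e`, which would create a cycle) combined with
#' validation of the result.  With `gene_flow_only` both `e` and `f` must
#' be base-tree edges of the supplied labeling, and each returned labeling
#' is the input labeling extended with the linking arc labeled 1.
#'
#' @param g a valid `admix_graph`.
#' @param labeling tree-based labeling (required when `gene_flow_only`).
#' @param gene_flow_only restrict to base-tree edge pairs.
#' @return list of records `list(e, f, graph, labeling)`, in lexicographic
#'   edge-row order.
#' @export
enumerate_edge_additions <- function(g, labeling = NULL,
                                     gene_flow_only = FALSE) {
  if (gene_flow_only && is.null(labeling))
    stop("gene_flow_only requires a labeling")
  R <- build_reachability(g)
  ne <- nrow(g$edges)
  out <- list()
  for (i in seq_len(ne)) {
    for (j in seq_len(ne)) {
      if (i == j) next
      if (gene_flow_only && (labeling[i] != 0L || labeling[j] != 0L)) next
      e <- g$edges[i, ]; f <- g$edges[j, ]
      if (R[f[2L], e[1L]]) next               # would create a cycle
      g2 <- apply_edge_addition(g, e, f)
      if (!ag_is_valid(g2)) next
      lab2 <- NULL
      if (!is.null(labeling)) {
        ## rows: i -> (e1,s); j -> (f1,t); appended (s,e2), (t,f2), (s,t)
        lab2 <- c(labeling, labeling[i], labeling[j], 1L)
      }
      out[[length(out) + 1L]] <- list(e = e, f = f, graph = g2,
                                      labeling = lab2)
    }
  }
  out
}

#' Apply a tail move
#'
#' Detaches the tail of edge `e`, suppressing the old attachment vertex,
#' and reattaches it so that it subdivides edge `f`.  Vertex and edge
#' counts are unchanged.  The tail of `e` must be a tree vertex other than
#' the root.
#'
#' @param g a valid `admix_graph`.
#' @param e,f length-2 integer vectors `(from, to)`.
#' @return the resulting `admix_graph` (compacted; not validity-checked).
#' @export
apply_tail_move <- function(g, e, f) {
  u <- e[1L]; v <- e[2L]
  if (u == g$root) stop("cannot move the tail of a root edge")
  if (ag_outdeg(g)[u] != 2L || ag_indeg(g)[u] != 1L)
    stop("tail of e must be a tree vertex")
  p <- ag_parents(g, u)
  sib <- setdiff(ag_children(g, u), v)
  if (length(sib) != 1L) stop("tail of e must have two children")
  ## remove e and suppress u: p -> sib
  g$edges <- g$edges[!(g$edges[, 1L] == u | g$edges[, 2L] == u), , drop = FALSE]
  g$edges <- rbind(g$edges, c(p, sib))
  ## f may have been affected by the suppression
  if (all(f == c(p, u)) || all(f == c(u, sib))) f <- c(p, sib)
  if (all(f == e)) stop("cannot reattach onto the moved edge itself")
  s1 <- ag_subdivide(g, f[1L], f[2L]); g <- s1$graph; w <- s1$new
  g$edges <- rbind(g$edges, c(w, v))
  ag_compact(g)
}

#' Enumerate the tail-move neighborhood
#'
#' All legal tail moves, i.e. those whose application yields a valid
#' network.
#'
#' @param g a valid `admix_graph`.
#' @return list of records `list(e, f, graph)`, lexicographic order.
#' @export
enumerate_tail_moves <- function(g) {
  indeg <- ag_indeg(g); outdeg <- ag_outdeg(g)
  out <- list()
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    if (e[1L] == g$root || outdeg[e[1L]] != 2L || indeg[e[1L]] != 1L) next
    for (j in seq_len(nrow(g$edges))) {
      if (i == j) next
      f <- g$edges[j, ]
      g2 <- tryCatch(apply_tail_move(g, e, f), error = function(err) NULL)
      if (is.null(g2) || !ag_is_valid(g2)) next
      out[[length(out) + 1L]] <- list(e = e, f = f, graph = g2)
    }
  }
  out
}

#' Apply a head move
#'
#' Relocates the head of an admixture edge `a` so that it subdivides edge
#' `f`; the old admixture node is suppressed and the subdivision vertex of
#' `f` becomes the new admixture node, leaving `h` unchanged.
#'
#' @param g a valid `admix_graph`.
#' @param a length-2 integer vector, an admixture edge (head has in-degree 2).
#' @param f length-2 integer vector.
#' @return the resulting `admix_graph` (compacted; not validity-checked).
#' @export
apply_head_move <- function(g, a, f) {
  u <- a[1L]; m <- a[2L]
  if (ag_indeg(g)[m] != 2L) stop("a must be an admixture edge")
  q <- setdiff(ag_parents(g, m), u)
  if (length(q) != 1L) stop("a must be an admixture edge")
  child <- ag_children(g, m)
  ## remove a and suppress m: q -> child
  g$edges <- g$edges[!(g$edges[, 1L] == u & g$edges[, 2L] == m), , drop = FALSE]
  g$edges <- g$edges[!(g$edges[, 1L] == m | g$edges[, 2L] == m), , drop = FALSE]
  g$edges <- rbind(g$edges, c(q, child))
  if (all(f == c(q, m)) || all(f == c(m, child))) f <- c(q, child)
  if (all(f == a)) stop("cannot reattach onto the moved edge itself")
  s1 <- ag_subdivide(g, f[1L], f[2L]); g <- s1$graph; t <- s1$new
  g$edges <- rbind(g$edges, c(u, t))
  ag_compact(g)
}

#' Enumerate the head-move neighborhood
#' @param g a valid `admix_graph`.
#' @return list of records `list(e, f, graph)`, lexicographic order.
#' @export
enumerate_head_moves <- function(g) {
  am <- admixture_nodes(g)
  out <- list()
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, ]
    if (!(a[2L] %in% am)) next
    for (j in seq_len(nrow(g$edges))) {
      if (i == j) next
      f <- g$edges[j, ]
      g2 <- tryCatch(apply_head_move(g, a, f), error = function(err) NULL)
      if (is.null(g2) || !ag_is_valid(g2)) next
      out[[length(out) + 1L]] <- list(e = a, f = f, graph = g2)
    }
  }
  out
}

## All rootings of a network: orientations of its undirected version with
## the same admixture vertex set, over every root edge.  Used so that BFS
## in move space is taken modulo the root position.
all_rootings <- function(g) {
  u <- to_undirected(g)
  out <- list()
  rows <- which(!duplicated(paste(u$edges[, 1L], u$edges[, 2L])))
  for (i in rows) {
    n2 <- tryCatch(orient(u, orientation_spec(u$edges[i, ], u$admix)),
                   error = function(e) NULL)
    if (!is.null(n2)) out[[length(out) + 1L]] <- n2
  }
  ## dedup by directed isomorphism
  keys <- vapply(out, ag_canonical, character(1))
  out[!duplicated(keys)]
}

## Isomorphism-deduplicated layer store for BFS (keyed by refinement
## invariant; exact isomorphism check inside each bucket).  Each entry
## caches the marked undirected form, its adjacency and refined colors so
## repeated comparisons cost only a backtracking match.
new_net_set <- function() new.env(parent = emptyenv())

net_entry <- function(g) {
  u <- to_undirected(g)
  col <- ug_refine(u, u$admix)
  list(graph = g, adj = ug_adj(u), col = col,
       key = paste(sort(col), collapse = ","))
}

net_entry_iso <- function(a, b)
  iso_backtrack(a$adj, b$adj, a$col, b$col)

net_set_add <- function(set, g, entry = NULL) {
  if (is.null(entry)) entry <- net_entry(g)
  bucket <- set[[entry$key]]
  if (!is.null(bucket)) {
    for (other in bucket) if (net_entry_iso(entry, other)) return(FALSE)
    set[[entry$key]] <- c(bucket, list(entry))
  } else set[[entry$key]] <- list(entry)
  TRUE
}

net_set_has <- function(set, g, entry = NULL) {
  if (is.null(entry)) entry <- net_entry(g)
  bucket <- set[[entry$key]]
  if (is.null(bucket)) return(FALSE)
  for (other in bucket) if (net_entry_iso(entry, other)) return(TRUE)
  FALSE
}

## Neighbors of g under a move type, over all rootings of g.  `dseen` is an
## optional environment keyed by directed canonical form: identical directed
## networks reached through different moves are filtered before the more
## expensive unrooted-class handling.
move_neighbors <- function(g, kind = "tail", dseen = NULL) {
  enum <- switch(kind,
                 tail = enumerate_tail_moves,
                 head = enumerate_head_moves,
                 stop("unknown move kind ", kind))
  nets <- list()
  for (r in all_rootings(g)) {
    for (rec in enum(r)) {
      if (!is.null(dseen)) {
        key <- ag_canonical(rec$graph)
        if (!is.null(dseen[[key]])) next
        dseen[[key]] <- TRUE
      }
      nets[[length(nets) + 1L]] <- rec$graph
    }
  }
  nets
}

#' BFS distance between two networks in move space
#'
#' Breadth-first search over isomorphism-deduplicated layers, comparing
#' networks modulo the root position (each visited network is expanded from
#' all of its rootings).
#'
#' @param a,b valid `admix_graph`s on the same populations with the same
#'   number of admixture nodes.
#' @param kind move type, `"tail"` or `"head"`.
#' @param cap maximum depth (default 4).
#' @return integer distance, or `NA` (meaning `>= cap + 1`) when `b` is not
#'   reached within `cap` moves.
#' @export
move_distance <- function(a, b, kind = "tail", cap = 4L) {
  if (!identical(populations(a), populations(b)))
    stop("networks must share the population set")
  target <- net_entry(b)
  ea <- net_entry(a)
  if (ea$key == target$key && net_entry_iso(ea, target)) return(0L)
  seen <- new_net_set()
  net_set_add(seen, a, ea)
  dseen <- new.env(parent = emptyenv())
  frontier <- list(a)
  for (depth in seq_len(cap)) {
    nxt <- list()
    for (g in frontier) {
      for (g2 in move_neighbors(g, kind, dseen)) {
        e2 <- net_entry(g2)
        if (e2$key == target$key && net_entry_iso(e2, target)) return(depth)
        if (net_set_add(seen, g2, e2)) nxt <- c(nxt, list(g2))
      }
    }
    if (!length(nxt)) break
    frontier <- nxt
  }
  NA_integer_
}

#' BFS layers of move space around a network
#'
#' Returns the isomorphism-deduplicated networks at each move distance
#' `1..depth` from `a` (modulo root position).
#'
#' @param a a valid `admix_graph`.
#' @param depth number of layers.
#' @param kind move type.
#' @return list of lists of `admix_graph`s, one per layer.
#' @export
move_layers <- function(a, depth = 2L, kind = "tail") {
  seen <- new_net_set()
  net_set_add(seen, a)
  dseen <- new.env(parent = emptyenv())
  frontier <- list(a)
  layers <- vector("list", depth)
  for (d in seq_len(depth)) {
    nxt <- list()
    for (g in frontier) {
      for (g2 in move_neighbors(g, kind, dseen)) {
        if (net_set_add(seen, g2)) nxt <- c(nxt, list(g2))
      }
    }
    layers[[d]] <- nxt
    frontier <- nxt
  }
  layers
}
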