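## Core data structures for binary directed/undirected phylogenetic networks.
##
## A directed network ("admix_graph") is a rooted binary leaf-labeled DAG in
## which internal vertices of in-degree 2 are admixture nodes.  Vertices are
## plain integer ids; edges live in a two-column integer matrix in creation
## order, which makes every enumeration in the package deterministic.

#' Construct a directed phylogenetic network
#'
#' @param edges two-column integer matrix (or data.frame) of arcs
#'   `(from, to)`, i.e. `(parent, child)`.
#' @param labels character vector indexed by vertex id; `labels[v]` is the
#'   population name of leaf `v`, `NA` for internal vertices.
#' @param root integer id of the root vertex.
#' @return An object of class `admix_graph`.
#' @export
admix_graph <- function(edges, labels, root) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("from", "to")
  labels <- as.character(labels)
  structure(list(edges = edges, labels = labels, root = as.integer(root)),
            class = "admix_graph")
}

#' Build a directed network from a parent/child name table
#'
#' Vertex names that never appear as a parent become leaves and keep their
#' name as population label; all other names are internal and receive fresh
#' integer ids.  The single name that never appears as a child is the root.
#'
#' @param parent,child character vectors of equal length naming the arcs.
#' @return An `admix_graph`.
#' @export
graph_from_names <- function(parent, child) {
  nm <- unique(c(parent, child))
  id <- seq_along(nm)
  names(id) <- nm
  edges <- cbind(from = id[parent], to = id[child])
  is_leaf <- !(nm %in% parent)
  labels <- ifelse(is_leaf, nm, NA_character_)
  root_nm <- setdiff(nm, child)
  if (length(root_nm) != 1L)
    stop("expected exactly one root (name never appearing as child), got: ",
         paste(root_nm, collapse = ", "))
  admix_graph(edges, labels, id[[root_nm]])
}

## ---- basic accessors --------------------------------------------------

ag_nv <- function(g) max(g$edges, g$root)

ag_vertices <- function(g) sort(unique(c(as.integer(g$edges), g$root)))

ag_indeg <- function(g) tabulate(g$edges[, 2L], nbins = ag_nv(g))

ag_outdeg <- function(g) tabulate(g$edges[, 1L], nbins = ag_nv(g))

#' Leaves of a network
#' @param g an `admix_graph`.
#' @return integer vertex ids of the leaves, ordered by population label.
#' @export
leaves <- function(g) {
  lv <- which(!is.na(g$labels))
  lv[order(g$labels[lv])]
}

#' Population label set of a network
#' @param g an `admix_graph` or `admix_ugraph`.
#' @return sorted character vector of population names.
#' @export
populations <- function(g) sort(g$labels[!is.na(g$labels)])

#' Admixture nodes (in-degree 2 vertices)
#' @param g an `admix_graph`.
#' @return sorted integer vertex ids.
#' @export
admixture_nodes <- function(g) sort(which(ag_indeg(g) == 2L))

#' Number of admixture nodes
#' @param g an `admix_graph`.
#' @export
n_admixture <- function(g) length(admixture_nodes(g))

ag_children <- function(g, v) g$edges[g$edges[, 1L] == v, 2L]
ag_parents  <- function(g, v) g$edges[g$edges[, 2L] == v, 1L]

#' @export
print.admix_graph <- function(x, ...) {
  cat(sprintf("Directed phylogenetic network: %d populations, %d vertices, %d edges, h = %d\n",
              length(populations(x)), length(ag_vertices(x)), nrow(x$edges),
              n_admixture(x)))
  cat("  populations:", paste(populations(x), collapse = " "), "\n")
  invisible(x)
}

## ---- topological order / reachability ---------------------------------

## Kahn's algorithm; returns NULL when the graph has a directed cycle.
ag_topo_order <- function(g) {
  nv <- ag_nv(g)
  indeg <- ag_indeg(g)
  present <- ag_outdeg(g) > 0L | indeg > 0L
  present[g$root] <- TRUE
  queue <- which(present & indeg == 0L)
  ord <- integer(0)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    ch <- ag_children(g, v)
    for (c in ch) {
      indeg2[c] <- indeg2[c] - 1L
      if (indeg2[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(ord) != sum(present)) NULL else ord
}

## ---- validation --------------------------------------------------------

#' Validate a directed network
#'
#' Checks the defining invariants of a binary directed phylogenetic network:
#' simple DAG, all vertices reachable from the root, root with in-degree 0 and
#' out-degree 2, leaves with in-degree 1 and out-degree 0, internal vertices
#' with degree sum 3, and leaf labels forming a bijection onto the population
#' set.
#'
#' @param g an `admix_graph`.
#' @return list with `ok` (logical) and `violations` (character vector naming
#'   each failed rule and the offending vertex or edge).
#' @export
validate_directed <- function(g) {
  v <- character(0)
  e <- g$edges
  if (nrow(e) == 0L) return(list(ok = FALSE, violations = "empty edge set"))
  if (any(e[, 1L] == e[, 2L]))
    v <- c(v, paste0("self-loop at vertex ", e[e[, 1L] == e[, 2L], 1L][1L]))
  if (anyDuplicated(paste(e[, 1L], e[, 2L])))
    v <- c(v, "parallel/cycle: duplicated arc")
  nv <- ag_nv(g)
  indeg <- ag_indeg(g); outdeg <- ag_outdeg(g)
  present <- indeg > 0L | outdeg > 0L
  present[g$root] <- TRUE
  if (indeg[g$root] != 0L || outdeg[g$root] != 2L)
    v <- c(v, sprintf("non-binary: root %d has in-degree %d, out-degree %d",
                      g$root, indeg[g$root], outdeg[g$root]))
  for (u in which(present)) {
    if (u == g$root) next
    if (outdeg[u] == 0L) {
      if (indeg[u] != 1L)
        v <- c(v, sprintf("non-binary: leaf %d has in-degree %d", u, indeg[u]))
      if (is.na(g$labels[u]))
        v <- c(v, sprintf("unlabeled leaf %d", u))
    } else {
      if (indeg[u] + outdeg[u] != 3L || indeg[u] < 1L)
        v <- c(v, sprintf("non-binary: internal vertex %d has degrees %d+%d",
                          u, indeg[u], outdeg[u]))
      if (!is.na(g$labels[u]))
        v <- c(v, sprintf("labeled internal vertex %d", u))
    }
  }
  labs <- g$labels[which(present)]
  labs <- labs[!is.na(labs)]
  if (anyDuplicated(labs))
    v <- c(v, paste0("duplicate population label ", labs[duplicated(labs)][1L]))
  if (is.null(ag_topo_order(g)))
    v <- c(v, "parallel/cycle: directed cycle present")
  ## reachability from root
  reach <- rep(FALSE, nv)
  reach[g$root] <- TRUE
  frontier <- g$root
  while (length(frontier)) {
    nxt <- unique(e[e[, 1L] %in% frontier, 2L])
    nxt <- nxt[!reach[nxt]]
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  if (any(present & !reach))
    v <- c(v, sprintf("vertex %d unreachable from root",
                      which(present & !reach)[1L]))
  list(ok = length(v) == 0L, violations = v)
}

## Fast boolean version used in move enumeration hot loops.
ag_is_valid <- function(g) {
  e <- g$edges
  if (any(e[, 1L] == e[, 2L])) return(FALSE)
  if (anyDuplicated(e[, 1L] * (max(e) + 1L) + e[, 2L])) return(FALSE)
  nv <- ag_nv(g)
  indeg <- tabulate(e[, 2L], nv); outdeg <- tabulate(e[, 1L], nv)
  present <- indeg > 0L | outdeg > 0L
  present[g$root] <- TRUE
  if (indeg[g$root] != 0L || outdeg[g$root] != 2L) return(FALSE)
  others <- which(present); others <- others[others != g$root]
  io <- indeg[others]; oo <- outdeg[others]
  leaf <- oo == 0L
  if (any(io[leaf] != 1L)) return(FALSE)
  if (any(is.na(g$labels[others[leaf]]))) return(FALSE)
  if (any(!is.na(g$labels[others[!leaf]]))) return(FALSE)
  if (any(io[!leaf] + oo[!leaf] != 3L) || any(io[!leaf] < 1L)) return(FALSE)
  if (is.null(ag_topo_order(g))) return(FALSE)
  TRUE
}

## ---- structural editing helpers ---------------------------------------

## Subdivide arc (from,to) with a fresh vertex; returns list(graph, new_id).
ag_subdivide <- function(g, from, to) {
  i <- which(g$edges[, 1L] == from & g$edges[, 2L] == to)
  if (length(i) != 1L) stop("no such edge ", from, "->", to)
  s <- ag_nv(g) + 1L
  g$edges[i, ] <- c(from, s)
  g$edges <- rbind(g$edges, c(s, to))
  g$labels <- c(g$labels, rep(NA_character_, s - length(g$labels)))
  list(graph = g, new = s)
}

## Remove arcs by row index.
ag_drop_edges <- function(g, rows) {
  if (length(rows)) g$edges <- g$edges[-rows, , drop = FALSE]
  g
}

## Suppress all degree-2 (in 1 / out 1) vertices and prune dead internal
## branches (unlabeled vertices with out-degree 0).  Used after moves and
## after restricting a network to a displayed tree.
ag_cleanup <- function(g) {
  repeat {
    nv <- ag_nv(g)
    indeg <- ag_indeg(g); outdeg <- ag_outdeg(g)
    present <- indeg > 0L | outdeg > 0L
    present[g$root] <- TRUE
    dead <- which(present & outdeg == 0L & is.na(g$labels[seq_len(nv)]))
    dead <- dead[dead != g$root]
    if (length(dead)) {
      g$edges <- g$edges[!(g$edges[, 2L] %in% dead), , drop = FALSE]
      next
    }
    ## root with a single child: new root is the child
    if (outdeg[g$root] == 1L && indeg[g$root] == 0L) {
      child <- ag_children(g, g$root)
      g$edges <- g$edges[g$edges[, 1L] != g$root, , drop = FALSE]
      g$root <- child
      next
    }
    unary <- which(present & indeg == 1L & outdeg == 1L)
    unary <- unary[unary != g$root]
    if (!length(unary)) break
    u <- unary[1L]
    p <- ag_parents(g, u); c <- ag_children(g, u)
    g$edges <- g$edges[!(g$edges[, 1L] == u | g$edges[, 2L] == u), , drop = FALSE]
    g$edges <- rbind(g$edges, c(p, c))
  }
  g
}

## Relabel vertex ids to 1..nv (creation order preserved).
ag_compact <- function(g) {
  vs <- ag_vertices(g)
  map <- integer(max(vs)); map[vs] <- seq_along(vs)
  admix_graph(cbind(map[g$edges[, 1L]], map[g$edges[, 2L]]),
              g$labels[vs], map[g$root])
}

## ---- undirected networks ----------------------------------------------

#' Undirect a network
#'
#' Drops edge directions and suppresses the root (merging its two incident
#' edges into one), yielding an unrooted leaf-labeled graph in which leaves
#' have degree 1 and all other vertices degree 3.
#'
#' @param g a valid `admix_graph` (validity is assumed, not rechecked).
#' @return An object of class `admix_ugraph` with fields `edges` (two-column
#'   matrix of unordered pairs, smaller id first), `labels`, and `admix`
#'   (the former admixture nodes, retained for orientation book-keeping).
#' @export
to_undirected <- function(g) {
  am <- admixture_nodes(g)
  ch <- ag_children(g, g$root)
  e <- g$edges[g$edges[, 1L] != g$root, , drop = FALSE]
  e <- rbind(e, sort(ch))             # merge the two root edges
  e <- t(apply(e, 1L, sort))
  keep <- sort(unique(as.integer(e)))
  map <- integer(max(keep)); map[keep] <- seq_along(keep)
  structure(list(edges = cbind(map[e[, 1L]], map[e[, 2L]]),
                 labels = g$labels[keep],
                 admix = sort(map[am])),
            class = "admix_ugraph")
}

#' @export
print.admix_ugraph <- function(x, ...) {
  cat(sprintf("Undirected phylogenetic network: %d populations, %d vertices, %d edges\n",
              sum(!is.na(x$labels)), length(unique(as.integer(x$edges))),
              nrow(x$edges)))
  invisible(x)
}

ug_degree <- function(u) tabulate(as.integer(u$edges), nbins = max(u$edges))

ug_adj <- function(u) {
  nv <- max(u$edges)
  adj <- vector("list", nv)
  for (i in seq_len(nrow(u$edges))) {
    a <- u$edges[i, 1L]; b <- u$edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## ---- isomorphism -------------------------------------------------------

## Iterated neighborhood color refinement anchored at leaf labels.  `marks`
## optionally distinguishes internal vertices (e.g. admixture nodes).
## Returns integer colors; isomorphic graphs receive identical color
## multisets, so paste(sort(colors)) is a cheap dedup key.
ug_refine <- function(u, marks = NULL) {
  adj <- ug_adj(u)
  nv <- length(adj)
  labs <- u$labels[seq_len(nv)]
  all_labs <- sort(labs[!is.na(labs)])
  col <- ifelse(is.na(labs), 1L, 2L + match(labs, all_labs))
  if (!is.null(marks)) col[marks] <- 2L
  ## refinement only ever splits classes, so the partition is stable as
  ## soon as the class count stops growing
  repeat {
    sig <- vapply(seq_len(nv), function(v)
      paste(col[v], paste(sort(col[adj[[v]]]), collapse = ","), sep = "|"),
      character(1))
    newcol <- match(sig, sort(unique(sig)))
    stable <- length(unique(newcol)) == length(unique(col))
    col <- newcol
    if (stable) break
  }
  col
}

ug_key <- function(u, marks = NULL)
  paste(sort(ug_refine(u, marks)), collapse = ",")

## Backtracking leaf-label-preserving isomorphism on refined color classes.
iso_backtrack <- function(adj1, adj2, col1, col2) {
  n <- length(adj1)
  if (length(adj2) != n) return(FALSE)
  if (!identical(sort(col1), sort(col2))) return(FALSE)
  ord <- order(col1)
  map <- integer(n)          # 0 = unmapped
  used <- logical(n)
  rec <- function(k) {
    if (k > n) return(TRUE)
    v <- ord[k]
    for (w in which(col2 == col1[v] & !used)) {
      ok <- TRUE
      for (x in adj1[[v]]) {
        if (map[x] != 0L && !(map[x] %in% adj2[[w]])) { ok <- FALSE; break }
      }
      if (ok) {
        ## mapped non-neighbors must stay non-neighbors (degree equality
        ## plus injectivity makes the neighbor check sufficient both ways)
        if (length(adj1[[v]]) != length(adj2[[w]])) ok <- FALSE
      }
      if (ok) {
        map[v] <<- w; used[w] <<- TRUE
        if (rec(k + 1L)) return(TRUE)
        map[v] <<- 0L; used[w] <<- FALSE
      }
    }
    FALSE
  }
  rec(1L)
}

#' Test leaf-label-preserving isomorphism of undirected networks
#'
#' Decided by iterated neighborhood color refinement anchored at the leaf
#' labels, with a backtracking matching fallback within refined classes.
#'
#' @param a,b `admix_ugraph` objects.
#' @param marks_a,marks_b optional vertex sets (e.g. admixture nodes) that
#'   must map onto each other; used when comparing directed networks modulo
#'   the root position.
#' @return logical.
#' @export
is_isomorphic <- function(a, b, marks_a = NULL, marks_b = NULL) {
  if (!identical(populations(a), populations(b))) return(FALSE)
  if (nrow(a$edges) != nrow(b$edges)) return(FALSE)
  ca <- ug_refine(a, marks_a); cb <- ug_refine(b, marks_b)
  if (!identical(sort(ca), sort(cb))) return(FALSE)
  iso_backtrack(ug_adj(a), ug_adj(b), ca, cb)
}

## Directed isomorphism via canonical recursive form: sufficient for the
## rooted DAGs here because leaf labels anchor the recursion and admixture
## sharing is reflected by in-degrees.
ag_canonical <- function(g) {
  memo <- new.env(parent = emptyenv())
  indeg <- ag_indeg(g)
  rec <- function(v) {
    k <- as.character(v)
    if (!is.null(memo[[k]])) return(memo[[k]])
    ch <- sort(ag_children(g, v))
    s <- if (!length(ch)) g$labels[v] else
      paste0("(", paste(sort(vapply(ch, rec, character(1))), collapse = ","),
             ")", if (indeg[v] == 2L) "#" else "")
    memo[[k]] <- s
    s
  }
  rec(g$root)
}

#' Test isomorphism of two directed networks (same root position)
#' @param a,b `admix_graph` objects.
#' @return logical.
#' @export
is_isomorphic_directed <- function(a, b)
  identical(ag_canonical(a), ag_canonical(b))

#' Test isomorphism of two directed networks modulo the root position
#'
#' Two directed networks are equivalent modulo rerooting when their
#' undirected versions are isomorphic by a map carrying admixture nodes to
#' admixture nodes; by orientation uniqueness this captures exactly the
#' networks obtainable from one another by relocating the root.
#'
#' @param a,b `admix_graph` objects.
#' @return logical.
#' @export
is_isomorphic_unrooted <- function(a, b) {
  ua <- to_undirected(a); ub <- to_undirected(b)
  is_isomorphic(ua, ub, ua$admix, ub$admix)
}

## Unrooted-equivalence dedup key.
ag_unrooted_key <- function(g) {
  u <- to_undirected(g)
  ug_key(u, u$admix)
}
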