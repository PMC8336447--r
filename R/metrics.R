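## Topological accuracy: rooted-triplet profiles and the triplet distance
## between networks.  A network's profile maps every 3-subset of the
## populations to the set of rooted triplet topologies displayed by the
## network (union over its displayed trees).

## Rooted triplet topology of three leaves in a tree: the pair with the
## strictly deepest most recent common ancestor forms the cherry.
tree_triplets <- function(t) {
  lv <- leaves(t)
  labs <- t$labels[lv]
  ## ancestor chains and depths
  parent <- integer(ag_nv(t))
  for (i in seq_len(nrow(t$edges))) parent[t$edges[i, 2L]] <- t$edges[i, 1L]
  depth <- integer(ag_nv(t))
  for (v in ag_topo_order(t)) if (v != t$root) depth[v] <- depth[parent[v]] + 1L
  chain <- lapply(lv, function(v) {
    anc <- v
    while (v != t$root) { v <- parent[v]; anc <- c(anc, v) }
    anc
  })
  names(chain) <- labs
  mrca_depth <- function(a, b) max(depth[intersect(chain[[a]], chain[[b]])])
  out <- character(0)
  trips <- utils::combn(sort(labs), 3L)
  for (k in seq_len(ncol(trips))) {
    a <- trips[1L, k]; b <- trips[2L, k]; c <- trips[3L, k]
    dab <- mrca_depth(a, b); dac <- mrca_depth(a, c); dbc <- mrca_depth(b, c)
    top <- if (dab > dac && dab > dbc) paste0(a, b, "|", c)
      else if (dac > dab && dac > dbc) paste0(a, c, "|", b)
      else paste0(b, c, "|", a)
    out[paste(a, b, c, sep = "|")] <- top
  }
  out
}

#' Rooted-triplet profile of a network
#'
#' @param g a valid `admix_graph`.
#' @return named list: for each 3-subset key `"a|b|c"`, the sorted set of
#'   rooted triplet topologies displayed by the network.
#' @export
triplet_profile <- function(g) {
  prof <- list()
  for (t in displayed_trees(g)) {
    tt <- tree_triplets(t)
    for (key in names(tt))
      prof[[key]] <- union(prof[[key]], tt[[key]])
  }
  lapply(prof, sort)
}

#' Triplet distance between two networks
#'
#' With the default `"subsets"` convention, the number of 3-subsets of the
#' populations on which the two networks display different rooted-triplet
#' sets (bounded by `choose(n, 3)`).  The `"symdiff"` convention instead
#' sums the sizes of the per-subset symmetric differences.
#'
#' @param a,b valid `admix_graph`s on the same population set.
#' @param convention `"subsets"` (default) or `"symdiff"`.
#' @return integer distance; 0 iff the profiles are identical.
#' @export
triplet_distance <- function(a, b, convention = c("subsets", "symdiff")) {
  convention <- match.arg(convention)
  if (!identical(populations(a), populations(b)))
    stop("networks must share the population set")
  pa <- triplet_profile(a); pb <- triplet_profile(b)
  keys <- names(pa)
  if (convention == "subsets") {
    sum(vapply(keys, function(k) !identical(pa[[k]], pb[[k]]), logical(1)))
  } else {
    sum(vapply(keys, function(k)
      length(setdiff(pa[[k]], pb[[k]])) + length(setdiff(pb[[k]], pa[[k]])),
      integer(1)))
  }
}
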