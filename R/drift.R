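## Expected f2-statistics under the drift model, and the composite Gaussian
## log-likelihood used to score admixture graphs.
##
## In an admixture graph, allele frequencies evolve by genetic drift along
## edges (variance c_e per edge) and mix at admixture nodes with proportion
## gamma.  For a pair of populations i, j the expected f2-statistic is
##   Y(i,j) = sum_e (p_i(e) - p_j(e))^2 * c_e,
## where p_i(e) is the probability that the inheritance path from the root
## to leaf i traverses edge e (admixture-weighted).  On trees this reduces
## to the path-length sum between the two leaves.

#' Construct drift parameters for a network
#'
#' @param g an `admix_graph`.
#' @param lengths numeric vector of drift branch lengths, one per row of
#'   `g$edges` (recycled if length 1); all `>= 0`.
#' @param gamma named numeric vector of admixture proportions in `[0, 1]`,
#'   one per admixture node.  Names are vertex ids as character.  Each
#'   proportion attaches to the node's designated incoming edge (see
#'   `gamma_parent`); the other incoming edge receives `1 - gamma`.
#' @param gamma_parent named integer vector (same names) giving the parent
#'   id of the designated incoming edge; defaults to the smaller parent id.
#' @return An object of class `drift_params`.
#' @export
drift_params <- function(g, lengths, gamma = numeric(0), gamma_parent = NULL) {
  lengths <- rep_len(as.numeric(lengths), nrow(g$edges))
  if (any(lengths < 0)) stop("negative drift length")
  am <- admixture_nodes(g)
  if (length(am)) {
    if (is.null(names(gamma))) names(gamma) <- as.character(am)
    if (!setequal(names(gamma), as.character(am)))
      stop("gamma must name every admixture node")
    if (any(gamma < 0 | gamma > 1)) stop("gamma outside [0, 1]")
    if (is.null(gamma_parent)) {
      gamma_parent <- vapply(am, function(m) min(ag_parents(g, m)), integer(1))
      names(gamma_parent) <- as.character(am)
    }
  } else {
    gamma <- numeric(0); gamma_parent <- integer(0)
  }
  structure(list(lengths = lengths, gamma = gamma,
                 gamma_parent = gamma_parent),
            class = "drift_params")
}

## Per-edge traversal weight of the arc into each vertex, as seen from one
## of its parents: gamma / (1 - gamma) at admixture nodes, 1 elsewhere.
edge_inherit_weight <- function(g, params) {
  w <- rep(1, nrow(g$edges))
  for (m in admixture_nodes(g)) {
    rows <- which(g$edges[, 2L] == m)
    gm <- params$gamma[[as.character(m)]]
    des <- params$gamma_parent[[as.character(m)]]
    w[rows] <- ifelse(g$edges[rows, 1L] == des, gm, 1 - gm)
  }
  w
}

#' Admixture-weighted path probabilities
#'
#' For each leaf `i` and edge `e`, the probability `p_i(e)` that the
#' root-to-`i` inheritance path traverses `e`, computed in one pass over
#' reverse topological order: the leaf's pendant edge has probability 1;
#' at an admixture node the lineage follows each incoming edge with
#' probability `gamma` / `1 - gamma`.
#'
#' @param g a valid `admix_graph`.
#' @param params a `drift_params` for `g`.
#' @return numeric matrix, rows = populations (sorted by label),
#'   columns = rows of `g$edges`.
#' @export
path_weights <- function(g, params) {
  ord <- ag_topo_order(g)
  if (is.null(ord)) stop("network contains a cycle")
  w <- edge_inherit_weight(g, params)
  lv <- leaves(g)
  nv <- ag_nv(g)
  P <- matrix(0, nrow = length(lv), ncol = nrow(g$edges),
              dimnames = list(g$labels[lv], NULL))
  for (k in seq_along(lv)) {
    cvert <- numeric(nv)          # prob. lineage of leaf passes vertex
    cvert[lv[k]] <- 1
    for (v in rev(ord)) {
      if (v == lv[k]) next
      rows <- which(g$edges[, 1L] == v)
      pe <- cvert[g$edges[rows, 2L]] * w[rows]
      P[k, rows] <- pe
      cvert[v] <- sum(pe)
    }
  }
  P
}

pair_keys <- function(pops) {
  cmb <- utils::combn(sort(pops), 2L)
  paste(cmb[1L, ], cmb[2L, ], sep = "|")
}

#' Expected f2-statistics implied by an admixture graph
#'
#' @param g a valid `admix_graph`.
#' @param params a `drift_params` for `g`.
#' @return named numeric vector over all unordered population pairs
#'   (names `"A|B"` with `A < B` lexicographically).
#' @export
expected_f2 <- function(g, params) {
  P <- path_weights(g, params)
  pops <- rownames(P)
  keys <- pair_keys(pops)
  y <- numeric(length(keys)); names(y) <- keys
  cmb <- utils::combn(pops, 2L)
  for (k in seq_len(ncol(cmb))) {
    d <- P[cmb[1L, k], ] - P[cmb[2L, k], ]
    y[k] <- sum(d * d * params$lengths)
  }
  y
}

## ---- f2 datasets -------------------------------------------------------

#' Construct an f2 dataset
#'
#' @param pop1,pop2 character vectors naming the populations of each pair.
#' @param f2 observed f2 values.
#' @param se per-pair standard errors (scales in the likelihood), `> 0`;
#'   recycled if length 1.
#' @return data.frame of class `f2_dataset` with columns `pop1`, `pop2`
#'   (pair normalized so `pop1 < pop2`, rows sorted), `f2`, `se`.
#' @export
f2_dataset <- function(pop1, pop2, f2, se) {
  se <- rep_len(as.numeric(se), length(f2))
  if (any(se <= 0)) stop("standard errors must be positive")
  a <- pmin(pop1, pop2); b <- pmax(pop1, pop2)
  d <- data.frame(pop1 = a, pop2 = b, f2 = as.numeric(f2), se = se,
                  stringsAsFactors = FALSE)
  d <- d[order(d$pop1, d$pop2), , drop = FALSE]
  key <- paste(d$pop1, d$pop2, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate population pair: ", key[duplicated(key)][1L])
  pops <- sort(unique(c(d$pop1, d$pop2)))
  want <- pair_keys(pops)
  if (!identical(key, want))
    stop("missing population pair: ", setdiff(want, key)[1L])
  rownames(d) <- NULL
  class(d) <- c("f2_dataset", "data.frame")
  d
}

f2_keys <- function(data) paste(data$pop1, data$pop2, sep = "|")

## Exact dataset implied by a model (graph + params) at constant SE.
f2_from_model <- function(g, params, se = 1e-4) {
  y <- expected_f2(g, params)
  pp <- do.call(rbind, strsplit(names(y), "|", fixed = TRUE))
  f2_dataset(pp[, 1L], pp[, 2L], unname(y), se)
}

#' Composite Gaussian log-likelihood of expected f2-statistics
#'
#' Each observed statistic is modeled as normal with mean equal to the
#' model expectation and scale `se`:
#' `loglik = -(1/2) * sum((X - Y)^2 / Z^2 + 2 log Z + log 2 pi)`.
#' At a perfect fit with constant `Z` over `n` pairs this equals
#' `-(n/2) (2 log Z + log 2 pi)`.
#'
#' @param data an `f2_dataset`.
#' @param y named expected f2 vector over the same pairs.
#' @return scalar log-likelihood (natural log).
#' @export
log_likelihood <- function(data, y) {
  y <- y[f2_keys(data)]
  if (anyNA(y)) stop("expected f2 vector does not cover the data pairs")
  -0.5 * sum((data$f2 - y)^2 / data$se^2 + 2 * log(data$se) + log(2 * pi))
}

#' Perfect-fit log-likelihood bound
#'
#' The global maximum of the likelihood over expected values, attained at
#' `Y = X`.
#'
#' @param data an `f2_dataset`.
#' @return scalar.
#' @export
perfect_fit_loglik <- function(data)
  -0.5 * sum(2 * log(data$se) + log(2 * pi))

#' Residuals of a model fit
#'
#' @param data an `f2_dataset`.
#' @param y named expected f2 vector.
#' @return data.frame with the pair columns, `raw = X - Y` and
#'   `scaled = (X - Y) / Z`, ordered as `data`.
#' @export
f2_residuals <- function(data, y) {
  y <- y[f2_keys(data)]
  data.frame(pop1 = data$pop1, pop2 = data$pop2,
             raw = data$f2 - unname(y),
             scaled = (data$f2 - unname(y)) / data$se)
}
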