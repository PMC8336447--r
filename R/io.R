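## Plain-text interchange: f2 tables (pair and matrix dialects), graph
## edge-list TSV, and an extended-Newick writer for display.  TSV, UTF-8,
## '.' decimal everywhere.

#' Read an f2 dataset
#'
#' The `pairs` dialect is a TSV with header `popA popB f2 se`.  The
#' `matrix` dialect is a square table of f2 values with population names as
#' header row and first column (a common standard error must then be
#' supplied); the matrix must be symmetric to 1e-12.
#'
#' @param path file path.
#' @param dialect `"pairs"` or `"matrix"`.
#' @param se standard error applied to every pair (matrix dialect only).
#' @return an `f2_dataset`.
#' @export
read_f2 <- function(path, dialect = c("pairs", "matrix"), se = 1e-4) {
  dialect <- match.arg(dialect)
  if (dialect == "pairs") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    need <- c("popA", "popB", "f2", "se")
    if (!all(need %in% names(d)))
      stop("pairs file must have columns: ", paste(need, collapse = ", "))
    f2_dataset(d$popA, d$popB, d$f2, d$se)
  } else {
    M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     row.names = 1L, check.names = FALSE))
    if (nrow(M) != ncol(M) || !identical(rownames(M), colnames(M)))
      stop("matrix dialect requires a square table with matching names")
    if (max(abs(M - t(M))) > 1e-12) stop("asymmetric f2 matrix")
    cmb <- utils::combn(sort(rownames(M)), 2L)
    f2_dataset(cmb[1L, ], cmb[2L, ], M[cbind(cmb[1L, ], cmb[2L, ])], se)
  }
}

#' Write an f2 dataset
#' @param data an `f2_dataset`.
#' @param path file path.
#' @param dialect `"pairs"` or `"matrix"`.
#' @export
write_f2 <- function(data, path, dialect = c("pairs", "matrix")) {
  dialect <- match.arg(dialect)
  if (dialect == "pairs") {
    d <- data.frame(popA = data$pop1, popB = data$pop2, f2 = data$f2,
                    se = data$se)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    M <- f2_matrix(data)
    utils::write.table(cbind(data.frame(pop = rownames(M)), as.data.frame(M)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

vertex_names <- function(g) {
  vs <- seq_len(ag_nv(g))
  ifelse(is.na(g$labels[vs]), paste0("v", vs), g$labels[vs])
}

#' Write a network (and optional parameters) as an edge-list TSV
#'
#' One row per edge with columns `child`, `parent`, `edge_type`
#' (`tree`/`admixture`), `length`, `weight`.  Admixture nodes appear in
#' exactly two rows of type `admixture`, whose weights are the admixture
#' proportions `gamma` and `1 - gamma`.
#'
#' @param g a valid `admix_graph`.
#' @param path file path.
#' @param params optional `drift_params` (lengths/weights default to 0/1).
#' @export
write_graph <- function(g, path, params = NULL) {
  g <- ag_compact(g)
  if (is.null(params)) params <- drift_params(g, 0, rep(0.5, n_admixture(g)))
  nm <- vertex_names(g)
  am <- admixture_nodes(g)
  d <- data.frame(child = nm[g$edges[, 2L]], parent = nm[g$edges[, 1L]],
                  edge_type = ifelse(g$edges[, 2L] %in% am, "admixture", "tree"),
                  length = params$lengths,
                  weight = edge_inherit_weight(g, params))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network (and parameters) from an edge-list TSV
#'
#' @param path file path as written by [write_graph()].
#' @return list with `graph` (an `admix_graph`) and `params`
#'   (a `drift_params`).
#' @export
read_graph <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("child", "parent", "edge_type", "length", "weight")
  if (!all(need %in% names(d)))
    stop("graph file must have columns: ", paste(need, collapse = ", "))
  g <- graph_from_names(d$parent, d$child)
  chk <- validate_directed(g)
  if (!chk$ok) stop("invalid network in ", path, ": ", chk$violations[1L])
  am <- admixture_nodes(g)
  n_adm_rows <- sum(d$edge_type == "admixture")
  if (n_adm_rows != 2L * length(am))
    stop("admixture nodes must appear in exactly two admixture rows each")
  gamma <- numeric(0); gamma_parent <- integer(0)
  ## vertex ids follow the name-appearance order used by graph_from_names
  nm <- unique(c(d$parent, d$child))
  ids <- stats::setNames(seq_along(nm), nm)
  for (m in am) {
    rows <- which(ids[d$child] == m)
    first <- rows[1L]
    gamma <- c(gamma, d$weight[first])
    gamma_parent <- c(gamma_parent, unname(ids[d$parent[first]]))
  }
  names(gamma) <- as.character(am)
  names(gamma_parent) <- as.character(am)
  params <- drift_params(g, d$length, gamma, gamma_parent)
  list(graph = g, params = params)
}

#' Write a network in extended Newick format
#'
#' The base tree of a tree-based labeling is written as Newick, with each
#' admixture node appearing once in full (tagged `#H<k>`) at its base-tree
#' position and once as a bare `#H<k>` leaf at the gene-flow attachment.
#'
#' @param g a valid `admix_graph`.
#' @param path file path; `NULL` returns the string invisibly.
#' @param labeling tree-based labeling (found automatically by default).
#' @return the extended-Newick string, invisibly when written to a file.
#' @export
write_enewick <- function(g, path = NULL, labeling = NULL) {
  if (is.null(labeling)) labeling <- find_tree_based_labeling(g)
  if (is.null(labeling)) stop("network admits no tree-based labeling")
  am <- admixture_nodes(g)
  htag <- stats::setNames(paste0("#H", seq_along(am)), as.character(am))
  render <- function(v) {
    rows <- which(g$edges[, 1L] == v)
    if (!length(rows)) return(g$labels[v])
    parts <- vapply(rows, function(i) {
      c0 <- g$edges[i, 2L]
      if (c0 %in% am && labeling[i] == 1L) htag[[as.character(c0)]]
      else render(c0)
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")",
           if (v %in% am) htag[[as.character(v)]] else "")
  }
  s <- paste0(render(g$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
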