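## Fitting drift parameters for a fixed topology by maximizing the
## composite Gaussian likelihood.  For fixed admixture proportions the
## expected f2 vector is linear in the branch lengths, so the profile
## problem is a weighted nonnegative least-squares solve (exact, via
## Lawson-Hanson NNLS); the proportions are then optimized by grid-seeded
## coordinate descent with bounded 1-D refinement per admixture node.
##
## The three branch lengths incident to an admixture node are not jointly
## identifiable, so fitting conventions pin some of them to zero:
##   * "admixturegraph": both incoming edges of every admixture node are
##     fixed to 0, the outgoing edge is estimated;
##   * "treemix": the estimated edges are exactly the base-tree edges
##     (psi = 0) whose tail is not an admixture node; all other edges
##     (gene-flow edges, and edges emanating from admixture nodes) are
##     fixed to 0.  Requires a tree-based labeling.

fixed_zero_edges <- function(g, labeling, convention) {
  am <- admixture_nodes(g)
  if (convention == "admixturegraph") {
    which(g$edges[, 2L] %in% am)
  } else {
    if (is.null(labeling)) stop("treemix convention requires a tree-based labeling")
    which(labeling == 1L | g$edges[, 1L] %in% am)
  }
}

## Weighted NNLS profile fit for fixed gamma.  Returns loglik and lengths.
nnls_profile <- function(g, params_gamma, free, data) {
  P <- path_weights(g, params_gamma)
  keys <- f2_keys(data)
  pops_row <- match(data$pop1, rownames(P))
  pops_row2 <- match(data$pop2, rownames(P))
  D <- P[pops_row, , drop = FALSE] - P[pops_row2, , drop = FALSE]
  A <- (D * D)[, free, drop = FALSE]
  w <- 1 / data$se
  cfit <- rep(0, nrow(g$edges))
  if (length(free)) {
    ## A tiny ridge keeps the active-set solve well posed when columns are
    ## collinear (e.g. the two root edges, whose lengths only enter through
    ## their sum).  It is escalated on the rare exact-singularity failure;
    ## even the largest ridge biases the solution far below the data scale.
    Aw <- A * w
    bw <- data$f2 * w
    scale <- max(abs(Aw), 1e-12)
    sol <- NULL
    for (r in c(1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2) * scale) {
      sol <- tryCatch(
        pracma::lsqnonneg(rbind(Aw, diag(r, ncol(Aw))),
                          c(bw, rep(0, ncol(Aw)))),
        error = function(e) NULL)
      if (!is.null(sol)) break
    }
    if (is.null(sol)) stop("nonnegative least-squares solve failed")
    cfit[free] <- sol$x
  }
  y <- as.numeric((D * D) %*% cfit)
  names(y) <- keys
  ll <- -0.5 * sum((data$f2 - y)^2 / data$se^2 + 2 * log(data$se) + log(2 * pi))
  list(loglik = ll, lengths = cfit, y = y)
}

#' Fit drift parameters for a fixed topology
#'
#' Maximizes the composite Gaussian likelihood over the free branch lengths
#' (nonnegative) and admixture proportions (in `[0, 1]`).  For fixed
#' proportions the branch lengths are solved exactly by weighted
#' nonnegative least squares; proportions are optimized by coordinate
#' descent seeded from a grid, with bounded one-dimensional refinement per
#' admixture node, alternating with the NNLS solve until the objective
#' improves by less than `tol`.
#'
#' @param g a valid `admix_graph`.
#' @param data an `f2_dataset` covering all leaf pairs of `g`.
#' @param convention `"treemix"` or `"admixturegraph"` (which edge lengths
#'   are pinned to zero around admixture nodes).
#' @param labeling tree-based labeling (required for `"treemix"`); see
#'   [find_tree_based_labeling()].
#' @param grid admixture-proportion start grid.
#' @param n_refine number of best grid starts refined by coordinate descent.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_rounds cap on coordinate-descent rounds.
#' @return list of class `fit_result`: `params` (a `drift_params`), `loglik`,
#'   `converged`, `residuals`, `convention`, `labeling`.
#' @export
fit_params <- function(g, data, convention = c("treemix", "admixturegraph"),
                       labeling = NULL,
                       grid = seq(0.05, 0.95, by = 0.05), n_refine = 2L,
                       tol = 1e-10, max_rounds = 200L) {
  convention <- match.arg(convention)
  if (!identical(sort(populations(g)), sort(unique(c(data$pop1, data$pop2)))))
    stop("data populations do not match network leaves")
  if (convention == "treemix" && is.null(labeling)) {
    labeling <- find_tree_based_labeling(g)
    if (is.null(labeling)) stop("network admits no tree-based labeling")
  }
  am <- admixture_nodes(g)
  h <- length(am)
  free <- setdiff(seq_len(nrow(g$edges)),
                  fixed_zero_edges(g, labeling, convention))

  make_params <- function(gam) {
    gm <- rep_len(gam, h)
    names(gm) <- as.character(am)
    drift_params(g, rep(0, nrow(g$edges)), gm)
  }
  objective <- function(gam) nnls_profile(g, make_params(gam), free, data)

  if (h == 0L) {
    best <- objective(numeric(0)); best_g <- numeric(0); conv <- TRUE
  } else {
    ## grid seeding: all proportions set to each grid value
    scores <- vapply(grid, function(v) objective(rep(v, h))$loglik, numeric(1))
    starts <- grid[order(-scores)][seq_len(min(n_refine, length(grid)))]
    best <- NULL; best_g <- NULL; conv <- FALSE
    for (s in starts) {
      gam <- rep(s, h)
      cur <- objective(gam)
      ok <- FALSE
      for (round in seq_len(max_rounds)) {
        prev <- cur$loglik
        for (k in seq_len(h)) {
          opt <- stats::optimize(function(v) {
            gk <- gam; gk[k] <- v; objective(gk)$loglik
          }, interval = c(0, 1), maximum = TRUE, tol = 1e-9)
          if (opt$objective > cur$loglik) {
            gam[k] <- opt$maximum
            cur <- objective(gam)
          }
        }
        if (cur$loglik - prev < tol) { ok <- TRUE; break }
      }
      if (is.null(best) || cur$loglik > best$loglik + 1e-12) {
        best <- cur; best_g <- gam; conv <- ok
      }
    }
  }
  params <- make_params(best_g)
  params$lengths <- best$lengths
  res <- structure(list(params = params, loglik = best$loglik,
                        converged = conv,
                        residuals = f2_residuals(data, best$y),
                        fitted = best$y,
                        convention = convention, labeling = labeling),
                   class = "fit_result")
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Admixture graph fit (%s convention): loglik = %.3f%s\n",
              x$convention, x$loglik,
              if (x$converged) "" else " (not converged)"))
  if (length(x$params$gamma))
    cat("  admixture proportions:",
        paste(sprintf("%s: %.4f", names(x$params$gamma), x$params$gamma),
              collapse = ", "), "\n")
  invisible(x)
}

## Cheap profile fit used to rank candidates during neighborhood scans;
## the few best candidates are always refit exactly before a decision.
fit_quick <- function(g, data, convention, labeling = NULL) {
  fit_params(g, data, convention, labeling = labeling,
             grid = c(0.1, 0.3, 0.5, 0.7, 0.9), n_refine = 1L,
             max_rounds = 10L, tol = 1e-8)
}

#' Score a network over all of its tree-based labelings
#'
#' Under the treemix convention the likelihood can depend on which incoming
#' admixture edges are designated base-tree edges; this evaluates
#' [fit_params()] for every tree-based labeling and returns the best fit
#' (ties broken by enumeration order).  Under the admixturegraph convention
#' there is a single fit.
#'
#' @inheritParams fit_params
#' @param labelings optional list of labelings to evaluate (defaults to all
#'   tree-based labelings).
#' @return the best `fit_result`, with an extra field `scores` giving the
#'   per-labeling log-likelihood table.
#' @export
score_graph <- function(g, data, convention = c("treemix", "admixturegraph"),
                        labelings = NULL, ...) {
  convention <- match.arg(convention)
  if (convention == "admixturegraph") {
    fit <- fit_params(g, data, convention, ...)
    fit$scores <- fit$loglik
    return(fit)
  }
  if (is.null(labelings)) labelings <- enumerate_labelings(g)
  if (!length(labelings)) stop("network admits no tree-based labeling")
  best <- NULL; scores <- numeric(length(labelings))
  for (i in seq_along(labelings)) {
    fit <- fit_params(g, data, convention, labeling = labelings[[i]], ...)
    scores[i] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik + 1e-12) best <- fit
  }
  best$scores <- scores
  best
}
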