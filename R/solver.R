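#' Solver configuration
#'
#' Collects the penalty pair and the numerical knobs of the AMA solver.
#'
#' @param gamma1 fusion penalty (>= 0): larger values fuse more sample
#'   centers, giving fewer clusters.
#' @param gamma2 sparsity penalty (>= 0): larger values zero out more
#'   feature columns of the center matrix.
#' @param nu dual step size; `NULL` (default) resolves at fit time to
#'   `1/rho(L)`, the reciprocal of the largest eigenvalue of the edge
#'   graph's (unweighted) Laplacian, the sharpest step for which
#'   projected dual ascent is guaranteed monotone. `1/n` is a valid
#'   conservative alternative (`rho(L) <= n` for any graph) but is many
#'   times slower on sparse kNN graphs.
#' @param max_iter iteration cap (default 10000).
#' @param tol convergence tolerance: maximum dual change relative to the
#'   dual scale (default 1e-6).
#' @param eps_fuse fusion-detection tolerance for the cluster readout;
#'   an edge is fused when `||v_l||_2 <= eps_fuse * sqrt(p)`. Default 1e-3:
#'   at the solver's stopping accuracy fused differences sit many orders
#'   of magnitude below unfused ones (which are O(1) on standardized
#'   data), so the readout is insensitive to this value over a wide range.
#' @param seed integer seed retained for any randomized tie-breaking;
#'   the solver itself is deterministic.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(gamma1 = 0, gamma2 = 0, nu = NULL,
                          max_iter = 10000L, tol = 1e-6,
                          eps_fuse = 1e-3, seed = 1L) {
  stopifnot(gamma1 >= 0, gamma2 >= 0, is.null(nu) || nu > 0,
            max_iter >= 1L, tol > 0, eps_fuse > 0)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, nu = nu,
                 max_iter = as.integer(max_iter), tol = tol,
                 eps_fuse = eps_fuse, seed = as.integer(seed)),
            class = "solver_config")
}

#' Group soft-thresholding operator
#'
#' The proximal operator of `tau * ||.||_2`:
#' `max(0, 1 - tau / ||v||_2) * v`, with an exact zero vector whenever
#' `||v||_2 <= tau`. Applied per feature column it performs the hard
#' feature selection of the group-lasso term.
#'
#' @param v numeric vector.
#' @param tau threshold, `tau >= 0`.
#' @return The shrunken vector.
#' @export
group_soft_threshold <- function(v, tau) {
  stopifnot(tau >= 0)
  if (tau == 0) return(v)
  nv <- sqrt(sum(v^2))
  if (nv <= tau) return(rep(0, length(v)))
  (1 - tau / nv) * v
}

#' Fit sparse convex clustering by AMA dual ascent
#'
#' Minimizes
#' \deqn{\frac12 \sum_j \|x_j - u_j\|_2^2
#'       + \gamma_1 \sum_{l \in E} w_l \|U_{i_1\cdot} - U_{i_2\cdot}\|_2
#'       + \gamma_2 \sum_j z_j \|u_j\|_2}
#' over the center matrix `U`, where the fused-lasso term runs over the
#' kNN edge set `E` with Gaussian weights `w_l` and the group-lasso term
#' carries the prior feature weights `z_j` (0.5 for literature-supported
#' features, 1 otherwise). Clusters are the connected components of fused
#' centers; selected features are the columns of `U` with positive norm
#' (the prox yields exact zeros).
#'
#' The solver alternates an exact center update (group soft thresholding
#' of `X` plus the aggregated duals) with a projected gradient step on the
#' edge-wise dual variables; the dual objective is non-decreasing.
#'
#' @param X `concat_data` or numeric matrix (n x p), columns centered.
#' @param E an [build_edge_set()] `edge_set` (may have zero edges only if
#'   `gamma1 = 0`).
#' @param z a [feature_weights()] object, or numeric vector of length p;
#'   `NULL` means all ones (plain sparse convex clustering).
#' @param cfg a [solver_config()].
#' @param Lambda0 optional m x p matrix of warm-start duals (e.g. from the
#'   previous point of a tuning grid).
#' @param record_trace record per-iteration primal/dual objective values
#'   (default `TRUE`; tuning sweeps disable it for speed).
#' @return Object of class `iscc_fit`: `U` (n x p), `V` (m x p edge
#'   differences), `Lambda` (m x p duals), `labels`, `selected` (logical),
#'   `n_clusters`, `n_selected`, `primal_trace`, `dual_trace`,
#'   `converged`, `iterations`, plus the inputs' bookkeeping.
#' @export
ama_fit <- function(X, E, z = NULL, cfg = solver_config(), Lambda0 = NULL,
                    record_trace = TRUE) {
  cd <- NULL
  if (inherits(X, "concat_data")) { cd <- X; X <- X$X }
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (inherits(z, "feature_weights")) z <- z$z
  if (is.null(z)) z <- rep(1, p)
  stopifnot(length(z) == p, inherits(cfg, "solver_config"))
  m <- nrow(E$edges)
  if (m == 0L && cfg$gamma1 > 0) {
    stop("empty edge set with gamma1 > 0: no fusion is possible")
  }
  nu <- if (is.null(cfg$nu)) 1 / .laplacian_rho(E$edges, n) else cfg$nu
  L0 <- if (is.null(Lambda0)) matrix(0, 0, 0) else t(as.matrix(Lambda0))
  res <- ama_fit_cpp(t(X), E$edges - 1L, E$w, z,
                     cfg$gamma1, cfg$gamma2, nu,
                     cfg$max_iter, cfg$tol, L0, record_trace)
  U <- t(res$Ut)
  V <- if (m > 0L) U[E$edges[, 1L], , drop = FALSE] -
                   U[E$edges[, 2L], , drop = FALSE]
       else matrix(0, 0L, p)
  fit <- structure(
    list(U = U, V = V, Lambda = t(res$Lambda),
         labels = NULL, selected = NULL,
         n_clusters = NA_integer_, n_selected = NA_integer_,
         gamma1 = cfg$gamma1, gamma2 = cfg$gamma2,
         primal_trace = res$primal_trace, dual_trace = res$dual_trace,
         converged = res$converged, iterations = res$iterations,
         eps_fuse = cfg$eps_fuse,
         sample_ids = if (!is.null(cd)) cd$sample_ids else rownames(X),
         feature_names = if (!is.null(cd)) cd$feature_names else colnames(X)),
    class = "iscc_fit"
  )
  fit$labels <- extract_clusters(fit, E, cfg$eps_fuse)
  fit$selected <- selected_features(fit)
  fit$n_clusters <- length(unique(fit$labels))
  fit$n_selected <- sum(fit$selected)
  fit
}

#' @export
print.iscc_fit <- function(x, ...) {
  cat(sprintf(paste0("iscc_fit: gamma1 = %.4g, gamma2 = %.4g | %d clusters, ",
                     "%d/%d features selected | %s in %d iterations\n"),
              x$gamma1, x$gamma2, x$n_clusters, x$n_selected, ncol(x$U),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

# largest eigenvalue of the unweighted graph Laplacian (dense eigen for
# moderate n, 2 * max-degree upper bound beyond that)
.laplacian_rho <- function(edges, n) {
  if (nrow(edges) == 0L) return(n)
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), n)
  if (n <= 2000L) {
    L <- diag(deg)
    L[edges] <- L[edges] - 1
    L[edges[, 2:1, drop = FALSE]] <- L[edges[, 2:1, drop = FALSE]] - 1
    max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  } else {
    2 * max(deg)
  }
}

#' Read cluster labels off a fitted center matrix
#'
#' Builds a graph on the samples with an edge for every pair `l` of the
#' fitted edge set whose center difference satisfies
#' `||v_l||_2 <= eps_fuse * sqrt(p)`; cluster labels are the connected
#' components. Samples touching no fused edge are singletons.
#'
#' @param fit an [ama_fit()] result (produced on the same `E`).
#' @param E the `edge_set` used for the fit.
#' @param eps_fuse fusion tolerance per feature dimension (scaled by
#'   `sqrt(p)`); defaults to the value stored in the fit.
#' @return Integer vector of cluster labels (1-based, ordered by first
#'   occurrence).
#' @export
extract_clusters <- function(fit, E, eps_fuse = fit$eps_fuse) {
  n <- nrow(fit$U); p <- ncol(fit$U)
  m <- nrow(E$edges)
  if (m == 0L) return(seq_len(n))
  fused <- sqrt(rowSums(fit$V^2)) <= eps_fuse * sqrt(p)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (any(fused)) {
    g <- igraph::add_edges(g, t(E$edges[fused, , drop = FALSE]))
  }
  comp <- igraph::components(g)$membership
  # relabel by first occurrence so labels are deterministic in sample order
  as.integer(match(comp, unique(comp)))
}

#' Indices of selected features
#'
#' A feature is selected when its center column has positive Euclidean
#' norm; the group soft-threshold prox produces exact zeros, so no
#' tolerance is involved.
#'
#' @param fit an [ama_fit()] result.
#' @return Logical vector of length p (`TRUE` = selected).
#' @export
selected_features <- function(fit) {
  colSums(fit$U^2) > 0
}
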