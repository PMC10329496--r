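#' Read a feature co-occurrence table
#'
#' Two-column delimited text with a header: feature name, then a
#' non-negative integer count of publications mentioning the feature
#' together with the disease of interest (the output of a literature
#' text-mining query, performed outside this package).
#'
#' @param path file path.
#' @return A named integer vector of counts (class `cooccurrence_table`).
#' @export
read_cooccurrence <- function(path) {
  if (!file.exists(path)) stop("cannot read co-occurrence file: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("co-occurrence file needs two columns: feature, count")
  cooccurrence_table(counts = dt[[2L]], features = as.character(dt[[1L]]))
}

#' Construct a co-occurrence table
#'
#' @param counts non-negative numeric counts.
#' @param features feature names, same length as `counts`.
#' @return Named numeric vector of class `cooccurrence_table`.
#' @export
cooccurrence_table <- function(counts, features) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == length(features))
  if (length(counts) == 0L) stop("no counts")
  if (anyNA(counts) || any(counts < 0)) {
    stop("co-occurrence counts must be non-negative and non-missing")
  }
  names(counts) <- as.character(features)
  if (anyDuplicated(names(counts))) stop("duplicated feature names in counts")
  class(counts) <- "cooccurrence_table"
  counts
}

#' Co-occurrence count threshold
#'
#' The q-quantile of all counts, used as the cut above which a feature is
#' treated as literature-supported ("informative"). The default q = 0.9
#' reflects that co-occurrence distributions are typically highly skewed,
#' so only the top decile of features is trusted as informative. Quantiles
#' use linear interpolation between order statistics (`type = 7`); since
#' the downstream rule is a strict inequality, features tied exactly at the
#' threshold are non-informative under any interpolation convention.
#'
#' @param table a [cooccurrence_table()] (or bare numeric vector of counts).
#' @param q quantile level in `[0, 1]`; default `0.9`.
#' @return The count threshold (scalar).
#' @export
cooccurrence_threshold <- function(table, q = 0.9) {
  counts <- unclass(table)
  if (length(counts) == 0L) stop("no counts")
  stopifnot(q >= 0, q <= 1)
  unname(stats::quantile(as.numeric(counts), probs = q, type = 7, names = FALSE))
}

#' Binary prior feature weights from co-occurrence counts
#'
#' Features whose count strictly exceeds the threshold get group-lasso
#' weight 0.5 (half the penalty: easier to keep), all others get weight 1.
#' The swapped variant `z_prime` (0.5 <-> 1) is also returned; it is used
#' to emphasize informative features when re-weighting sample distances.
#'
#' @param table a [cooccurrence_table()].
#' @param fT count threshold, e.g. from [cooccurrence_threshold()].
#' @param feature_order character vector giving the feature order of the
#'   concatenated analysis matrix. Features absent from `table` are treated
#'   as count 0 (weight 1) with a warning.
#' @return An object of class `feature_weights` with fields `z`, `z_prime`
#'   (numeric, length `length(feature_order)`), `fT`, `feature_names`.
#' @export
counts_to_feature_weights <- function(table, fT, feature_order) {
  stopifnot(fT >= 0 || is.finite(fT))
  counts <- unclass(table)
  feature_order <- as.character(feature_order)
  missing <- setdiff(feature_order, names(counts))
  if (length(missing) > 0L) {
    warning(length(missing), " feature(s) absent from the co-occurrence table; ",
            "treated as count 0 (weight 1): ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "")
  }
  fj <- ifelse(feature_order %in% names(counts),
               as.numeric(counts[feature_order]), 0)
  feature_weights(ifelse(fj > fT, 0.5, 1), fT = fT,
                  feature_names = feature_order)
}

#' Construct a feature-weight object directly
#'
#' @param z numeric vector with entries in `{0.5, 1}`: 0.5 for informative
#'   (literature-supported) features, 1 otherwise.
#' @param fT the count threshold that produced `z` (NA if constructed
#'   directly).
#' @param feature_names optional names.
#' @return Object of class `feature_weights`.
#' @export
feature_weights <- function(z, fT = NA_real_, feature_names = NULL) {
  z <- as.numeric(z)
  if (!all(z %in% c(0.5, 1))) stop("feature weights must be exactly 0.5 or 1")
  structure(
    list(z = z, z_prime = ifelse(z == 0.5, 1, 0.5), fT = fT,
         feature_names = feature_names),
    class = "feature_weights"
  )
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("feature_weights: %d features, %d informative (z = 0.5), fT = %s\n",
              length(x$z), sum(x$z == 0.5), format(x$fT)))
  invisible(x)
}

#' Build the k-nearest-neighbour edge set with Gaussian sample weights
#'
#' A pair of samples (i1, i2) is an edge when i2 is among i1's `d` nearest
#' neighbours or vice versa (the symmetric kNN union graph). Each edge
#' carries the Gaussian kernel weight
#' `w_l = exp(-phi * || scale * (X[i1, ] - X[i2, ]) ||_2^2 / p)`,
#' so near pairs are fused more strongly than distant ones and non-edges
#' not at all. The squared distance is normalized by the feature count p
#' (i.e. the kernel acts on the mean squared per-feature difference):
#' without this, standardized high-dimensional data drive every weight to
#' numerical zero and the rate `phi` would have to be re-tuned with every
#' p. With p = 1 the rule is the plain Gaussian kernel. `scale` allows the
#' informative-feature-emphasizing variant: passing the swapped weight
#' vector `z_prime` doubles the influence of informative features on the
#' sample distances.
#'
#' Neighbour ranks and weights use the same (optionally scaled) Euclidean
#' metric; rank ties are broken toward the smaller sample index.
#'
#' @param X a `concat_data` object or bare numeric matrix (samples x
#'   features).
#' @param d number of nearest neighbours (default 5). `d >= n` keeps all
#'   pairs with a warning.
#' @param phi Gaussian kernel rate, default 0.5.
#' @param scale optional length-p vector multiplying row differences
#'   elementwise before the squared norm (e.g. `z_prime`).
#' @return Object of class `edge_set`: integer matrix `edges` (m x 2,
#'   `i1 < i2`, 1-based), numeric `w`, plus `d` and `phi`.
#' @export
build_edge_set <- function(X, d = 5L, phi = 0.5, scale = NULL) {
  if (inherits(X, "concat_data")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(d >= 1L, phi >= 0, n >= 2L)
  if (!is.null(scale)) {
    stopifnot(length(scale) == p)
    X <- sweep(X, 2L, as.numeric(scale), "*")
  }
  D2 <- as.matrix(stats::dist(X))^2 / p
  if (d >= n) {
    warning("d >= n: retaining all sample pairs")
    d <- n - 1L
  }
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    # order() is stable, so distance ties resolve to the smaller index
    nb <- order(D2[i, -i])         # ranks among the other n-1 samples
    others <- seq_len(n)[-i]
    nb <- others[nb[seq_len(d)]]
    keep[i, nb] <- TRUE
  }
  keep <- keep | t(keep)
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  w <- exp(-phi * D2[idx])
  structure(
    list(edges = cbind(i1 = as.integer(idx[, 1L]), i2 = as.integer(idx[, 2L])),
         w = as.numeric(w), d = as.integer(d), phi = phi),
    class = "edge_set"
  )
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("edge_set: %d edges (d = %d, phi = %g), weights in [%.3g, %.3g]\n",
              nrow(x$edges), x$d, x$phi,
              if (length(x$w)) min(x$w) else NA, if (length(x$w)) max(x$w) else NA))
  invisible(x)
}
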