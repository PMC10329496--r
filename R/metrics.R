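#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie).
#' From the contingency table `n_ij` with row sums `a_i`, column sums
#' `b_j`:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - e}
#'   {\tfrac12\left(\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right) - e},
#'   \quad e = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}.}
#' Ranges over `[-1, 1]`; 1 for identical partitions, about 0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI value.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  n <- length(a)
  stopifnot(n >= 2L)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(ifelse(sum_ij - expected == 0, 1, 0))
  (sum_ij - expected) / denom
}

#' Feature-selection accuracy metrics
#'
#' Confusion of a selected feature set against the true informative set
#' over `p` features, reported as the false negative rate
#' `FNR = FN / (TP + FN)`, false positive rate `FPR = FP / (FP + TN)`,
#' and Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' with `MCC = 0` (logged) when any factor of the denominator vanishes.
#'
#' @param selected selected features: logical vector of length `p` or
#'   integer index vector.
#' @param truth true informative features, same conventions; must be
#'   non-empty.
#' @param p total number of features (required when indices are given).
#' @return List with `tp`, `fp`, `tn`, `fn`, `fnr`, `fpr`, `mcc`.
#' @export
selection_metrics <- function(selected, truth, p = NULL) {
  as_mask <- function(x, p) {
    if (is.logical(x)) return(x)
    if (is.null(p)) stop("p is required when features are given as indices")
    stopifnot(all(x >= 1), all(x <= p))
    mask <- rep(FALSE, p); mask[x] <- TRUE; mask
  }
  if (is.logical(selected) && is.null(p)) p <- length(selected)
  if (is.logical(truth) && is.null(p)) p <- length(truth)
  sel <- as_mask(selected, p)
  tru <- as_mask(truth, p)
  stopifnot(length(sel) == length(tru))
  if (!any(tru)) stop("empty truth set")
  tp <- sum(sel & tru); fp <- sum(sel & !tru)
  tn <- sum(!sel & !tru); fn <- sum(!sel & tru)
  fnr <- fn / (tp + fn)
  fpr <- if (fp + tn == 0) 0 else fp / (fp + tn)
  denom2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (denom2 == 0) {
    message("MCC denominator has a zero factor; reporting 0")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(denom2)
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn, fnr = fnr, fpr = fpr, mcc = mcc)
}
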