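#' Construct an omics block
#'
#' An omics block is one assay's sample-by-feature matrix together with its
#' bookkeeping: feature names, sample identifiers, and a label naming the
#' platform (for example `"mRNA"` or `"methylation"`). Blocks are the unit
#' of standardization; after standardization they are concatenated
#' column-wise into the single analysis matrix.
#'
#' @param matrix numeric matrix, samples in rows, features in columns.
#' @param block_label single string naming the block.
#' @param feature_names optional character vector of length `ncol(matrix)`;
#'   defaults to existing column names or `"<label>_f<j>"`.
#' @param sample_ids optional character vector of length `nrow(matrix)`;
#'   defaults to existing row names or `"s<i>"`.
#' @return An object of class `omics_block`.
#' @export
omics_block <- function(matrix, block_label, feature_names = NULL,
                        sample_ids = NULL) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("block '", block_label, "': matrix must be numeric")
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("block '", block_label, "': missing or non-finite values are not allowed; ",
         "remove or impute offending rows/columns before loading")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(matrix)
    if (is.null(feature_names)) {
      feature_names <- paste0(block_label, "_f", seq_len(ncol(matrix)))
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(matrix)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(matrix)))
  }
  stopifnot(length(feature_names) == ncol(matrix),
            length(sample_ids) == nrow(matrix))
  dimnames(matrix) <- NULL
  structure(
    list(matrix = matrix, feature_names = as.character(feature_names),
         block_label = as.character(block_label)[1L],
         sample_ids = as.character(sample_ids)),
    class = "omics_block"
  )
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("omics_block '%s': %d samples x %d features\n",
              x$block_label, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Standardize one omics block
#'
#' Each feature (column) is centered to mean zero; the whole centered block
#' is then divided by a single scalar, the standard deviation of all its
#' entries ("data-wise scaling"). This puts blocks from different platforms
#' on a common scale without distorting the relative variances of features
#' within a block. The scalar SD uses the population convention
#' (denominator `n * p_b`).
#'
#' A per-feature alternative (`scale = "feature"`) divides every centered
#' column by its own population SD instead.
#'
#' Constant features are centered to exactly zero (with a warning);
#' an all-constant block is degenerate and raises an error.
#'
#' @param block an [omics_block()].
#' @param scale `"data"` (default) for one scalar per block, `"feature"`
#'   for per-column scaling.
#' @return The standardized `omics_block`.
#' @export
standardize_block <- function(block, scale = c("data", "feature")) {
  stopifnot(inherits(block, "omics_block"))
  scale <- match.arg(scale)
  M <- block$matrix
  ctr <- sweep(M, 2L, colMeans(M), "-")
  col_ss <- colSums(ctr^2)
  const <- col_ss == 0
  if (all(const)) stop("degenerate block '", block$block_label,
                       "': every feature is constant")
  if (any(const)) {
    warning("block '", block$block_label, "': ", sum(const),
            " constant feature(s) centered to zero")
  }
  if (scale == "data") {
    s <- sqrt(mean(ctr^2))
    ctr <- ctr / s
  } else {
    s <- sqrt(col_ss / nrow(ctr))
    s[const] <- 1
    ctr <- sweep(ctr, 2L, s, "/")
  }
  block$matrix <- ctr
  block
}

#' Concatenate standardized omics blocks
#'
#' Column-binds the blocks into the analysis matrix `X` (n x p), recording
#' half-open column spans `[start, end)` per block so that downstream
#' reports can map features back to their platform. All blocks must carry
#' identical sample identifiers in identical order.
#'
#' @param blocks a list of [omics_block()] objects (a single block is
#'   accepted and wrapped).
#' @return An object of class `concat_data` with fields `X`, `block_spans`
#'   (data.frame of `label`, `start`, `end`, 0-based half-open),
#'   `feature_names`, `sample_ids`.
#' @export
concatenate_blocks <- function(blocks) {
  if (inherits(blocks, "omics_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, logical(1), "omics_block")))
  ids <- blocks[[1L]]$sample_ids
  for (b in blocks[-1L]) {
    if (!identical(b$sample_ids, ids)) {
      bad <- union(setdiff(b$sample_ids, ids), setdiff(ids, b$sample_ids))
      if (length(bad) == 0L) bad <- "(same IDs, different order)"
      stop("sample IDs of block '", b$block_label,
           "' do not match block '", blocks[[1L]]$block_label, "': ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  widths <- vapply(blocks, function(b) ncol(b$matrix), integer(1))
  ends <- cumsum(widths)
  spans <- data.frame(
    label = vapply(blocks, function(b) b$block_label, character(1)),
    start = c(0L, ends[-length(ends)]),
    end = ends,
    stringsAsFactors = FALSE
  )
  structure(
    list(X = do.call(cbind, lapply(blocks, function(b) b$matrix)),
         block_spans = spans,
         feature_names = unlist(lapply(blocks, function(b) b$feature_names),
                                use.names = FALSE),
         sample_ids = ids),
    class = "concat_data"
  )
}

#' @export
print.concat_data <- function(x, ...) {
  cat(sprintf("concat_data: %d samples x %d features in %d block(s)\n",
              nrow(x$X), ncol(x$X), nrow(x$block_spans)))
  for (k in seq_len(nrow(x$block_spans))) {
    cat(sprintf("  %s: columns [%d, %d)\n", x$block_spans$label[k],
                x$block_spans$start[k], x$block_spans$end[k]))
  }
  invisible(x)
}

#' Read a sample-by-feature matrix from delimited text
#'
#' Expects samples in rows, a header row of feature names, and the sample
#' identifier in the first column. The delimiter is taken from the file
#' extension (`.csv` comma, `.tsv`/`.txt` tab) and otherwise auto-detected.
#'
#' @param path file path.
#' @param block_label label for the resulting block; defaults to the file
#'   name without extension.
#' @return An [omics_block()].
#' @export
read_omics_matrix <- function(path, block_label = NULL) {
  if (!file.exists(path)) stop("cannot read matrix file: ", path)
  if (is.null(block_label)) {
    block_label <- sub("\\.[^.]*$", "", basename(path))
  }
  sep <- switch(tolower(sub(".*\\.", "", path)),
                csv = ",", tsv = "\t", txt = "\t", "auto")
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("matrix file '", path,
                          "' needs a sample-ID column plus >=1 feature")
  ids <- as.character(dt[[1L]])
  M <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  omics_block(M, block_label = block_label,
              feature_names = colnames(dt)[-1L], sample_ids = ids)
}

#' Write a sample-by-feature matrix as delimited text
#'
#' Emits the same dialect [read_omics_matrix()] reads: header of feature
#' names, first column `sample_id`, delimiter chosen by extension.
#'
#' @param block an [omics_block()], or a `concat_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(block, path) {
  if (inherits(block, "concat_data")) {
    M <- block$X; fn <- block$feature_names; ids <- block$sample_ids
  } else {
    stopifnot(inherits(block, "omics_block"))
    M <- block$matrix; fn <- block$feature_names; ids <- block$sample_ids
  }
  sep <- switch(tolower(sub(".*\\.", "", path)), csv = ",", "\t")
  df <- data.frame(sample_id = ids, M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", fn)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}
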