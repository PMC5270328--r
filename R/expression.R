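#' Construct an expression matrix
#'
#' Wraps a numeric genes-by-conditions matrix in a light container that
#' records whether the values are raw counts or CPM. Row names are gene
#' identifiers, column names are condition labels.
#'
#' @param values Numeric matrix, genes in rows, conditions in columns.
#'   Must have unique, non-empty row names and non-negative entries.
#' @param normalized Logical; `TRUE` when `values` are already counts per
#'   million, `FALSE` (default) for raw counts.
#' @return An object of class `ExpressionMatrix` (a numeric matrix with a
#'   `normalized` attribute).
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || anyNA(rownames(values)) ||
      any(rownames(values) == "")) {
    stop("expression matrix requires non-empty gene identifiers as row names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("cond", seq_len(ncol(values)))
  }
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (anyNA(values)) stop("expression values must not contain NA")
  structure(values, normalized = isTRUE(normalized),
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d conditions (%s)\n",
              nrow(x), ncol(x),
              if (is_normalized(x)) "CPM" else "raw counts"))
  invisible(x)
}

#' Test whether an expression matrix is CPM-normalized
#' @param x An `ExpressionMatrix`.
#' @return Logical scalar.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Read a counts table from TSV
#'
#' Expects a header row of condition labels and gene identifiers in the
#' first column.
#'
#' @param file Path to a tab-separated counts file.
#' @return An `ExpressionMatrix` of raw counts.
#' @export
read_counts <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m, normalized = FALSE)
}

#' Normalize raw counts to counts per million
#'
#' Each count is divided by its library size (column total) and scaled by
#' 1e6. No effective-library-size adjustment (such as TMM) is applied; the
#' scaling is the plain counts/total definition.
#'
#' @param matrix An `ExpressionMatrix` of raw counts.
#' @return A CPM `ExpressionMatrix` with the same genes and conditions.
#' @export
cpm_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (is_normalized(matrix)) {
    stop("matrix is already CPM-normalized; refusing to rescale")
  }
  totals <- colSums(matrix)
  zero <- totals == 0
  if (any(zero)) {
    stop("zero library size in condition(s): ",
         paste(colnames(matrix)[zero], collapse = ", "))
  }
  out <- sweep(unclass(matrix), 2, totals, "/") * 1e6
  expression_matrix(out, normalized = TRUE)
}

#' Remove non-expressed genes
#'
#' Keeps genes whose CPM exceeds `threshold` in at least one condition;
#' the comparison is strict (> threshold).
#'
#' @param matrix A CPM-normalized `ExpressionMatrix`.
#' @param threshold CPM cutoff; default 1.
#' @return The filtered `ExpressionMatrix`, with attribute `n_removed`
#'   giving the number of genes dropped.
#' @export
filter_expressed <- function(matrix, threshold = 1.0) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!is_normalized(matrix)) {
    stop("filter_expressed requires a CPM-normalized matrix")
  }
  keep <- apply(unclass(matrix) > threshold, 1, any)
  out <- expression_matrix(unclass(matrix)[keep, , drop = FALSE],
                           normalized = TRUE)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Resolve gene identifiers through a mapping table
#'
#' Applies a possibly many-to-many (source, target) identifier mapping.
#' Genes whose source id maps to more than one target, and targets claimed
#' by more than one retained source, are treated as ambiguous and dropped;
#' genes absent from the mapping are dropped as unmapped.
#'
#' @param matrix An `ExpressionMatrix` keyed by source identifiers.
#' @param mapping Data frame with columns `source_id` and `target_id`
#'   (first two columns are used regardless of names).
#' @return An `ExpressionMatrix` keyed by target identifiers, with
#'   attributes `n_unmapped` and `n_ambiguous` reporting drop counts.
#' @export
resolve_ids <- function(matrix, mapping) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  mapping <- as.data.frame(mapping)
  if (nrow(mapping) == 0) stop("empty identifier mapping")
  src <- as.character(mapping[[1]])
  tgt <- as.character(mapping[[2]])
  pairs <- unique(data.frame(src = src, tgt = tgt, stringsAsFactors = FALSE))

  genes <- rownames(matrix)
  unmapped <- setdiff(genes, pairs$src)
  pairs <- pairs[pairs$src %in% genes, , drop = FALSE]
  # a source with >1 target, or a target shared by >1 source, is ambiguous
  multi_src <- unique(pairs$src[duplicated(pairs$src)])
  multi_tgt <- unique(pairs$tgt[duplicated(pairs$tgt)])
  ambiguous <- pairs$src %in% multi_src | pairs$tgt %in% multi_tgt
  n_ambiguous <- length(unique(pairs$src[ambiguous]))
  pairs <- pairs[!ambiguous, , drop = FALSE]

  out <- unclass(matrix)[pairs$src, , drop = FALSE]
  rownames(out) <- pairs$tgt
  out <- expression_matrix(out, normalized = is_normalized(matrix))
  attr(out, "n_unmapped") <- length(unmapped)
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Log-transform CPM values for Gaussian modelling
#'
#' Computes log2(CPM + 1), the transform applied before clustering and
#' network scoring so that count-scale data behave approximately
#' Gaussian.
#'
#' @param matrix A CPM-normalized `ExpressionMatrix`.
#' @return A plain numeric matrix (genes x conditions) of log2(CPM + 1).
#' @export
log_cpm <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!is_normalized(matrix)) stop("log_cpm requires CPM input")
  log2(unclass(matrix) + 1)
}
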