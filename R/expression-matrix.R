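#' Expression matrix container
#'
#' A light container for a gene-by-observation count matrix (observations are
#' cells, bulk samples, or spatial spots) with an optional normalized layer of
#' identical shape. Counts are stored sparse (`Matrix::dgCMatrix`); gene and
#' observation identifiers live in the dimnames and must be unique.
#'
#' @param counts non-negative numeric matrix or sparse Matrix, genes in rows,
#'   observations in columns; both dimnames required.
#' @param normalized optional matrix of the same dimensions and dimnames.
#' @return an object of class `expr_matrix` with elements `counts` and
#'   `normalized` (possibly `NULL`).
#' @export
expression_matrix <- function(counts, normalized = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and observation colnames")
  }
  rownames(counts) <- toupper(rownames(counts)) # symbols are case-normalized
  gn <- rownames(counts)
  ob <- colnames(counts)
  if (anyDuplicated(gn)) stop("duplicate gene identifiers in counts")
  if (anyDuplicated(ob)) stop("duplicate observation identifiers in counts")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (!is.null(normalized)) {
    if (!identical(dim(normalized), dim(counts))) {
      stop("normalized layer must match counts dimensions")
    }
    rownames(normalized) <- toupper(rownames(normalized))
    if (!identical(rownames(normalized), gn) || !identical(colnames(normalized), ob)) {
      stop("normalized layer must match counts dimnames")
    }
  }
  structure(list(counts = counts, normalized = normalized), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$counts)

#' Gene identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of gene symbols.
#' @export
genes <- function(x) rownames(x$counts)

#' Observation (cell/sample/spot) identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of observation identifiers.
#' @export
observations <- function(x) colnames(x$counts)

#' @export
print.expr_matrix <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "expr_matrix: %d genes x %d observations (%d stored counts)%s\n",
    d[1], d[2], length(x$counts@x),
    if (is.null(x$normalized)) "" else ", with normalized layer"
  ))
  invisible(x)
}

#' Subset an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param i gene index (names, logical or integer); missing keeps all.
#' @param j observation index; missing keeps all.
#' @param ... unused.
#' @return the subsetted `expr_matrix`.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  expression_matrix(
    x$counts[i, j, drop = FALSE],
    if (is.null(x$normalized)) NULL else as.matrix(x$normalized[i, j, drop = FALSE])
  )
}

#' Library-size normalization of UMI counts
#'
#' Divides each gene's count by the observation's total count, multiplies by
#' `scale`, and applies `log(1 + .)`. Zero-total observations are left all-zero
#' with a warning; zero counts stay exactly zero so sparsity is preserved.
#'
#' @param m an `expr_matrix`.
#' @param scale scale factor applied to the count fraction (default `1e4`).
#' @return `m` with its `normalized` layer filled in.
#' @export
normalize_counts <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "expr_matrix"))
  totals <- Matrix::colSums(m$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " observation(s) have zero total counts; left all-zero")
    totals[zero] <- 1
  }
  norm <- m$counts %*% Matrix::Diagonal(x = scale / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m$counts)
  m$normalized <- methods::as(methods::as(norm, "generalMatrix"), "CsparseMatrix")
  m
}

# normalized layer or informative failure
.norm_layer <- function(m) {
  if (is.null(m$normalized)) {
    stop("expression matrix has no normalized layer; run normalize_counts() first")
  }
  m$normalized
}

#' Per-cell annotation table
#'
#' Validates a data.frame of per-cell labels against an expression matrix:
#' columns `cell_id`, `sample_id`, `tissue` (tumor/normal), `major_type`,
#' `subtype`; each cell exactly once; every subtype nested in a single major
#' type; every cell present among the matrix observations.
#'
#' @param df data.frame with the five required columns.
#' @param m optional `expr_matrix` whose observations the cells must match.
#' @return the validated data.frame (character columns, class `cell_annotation`).
#' @export
cell_annotation <- function(df, m = NULL) {
  need <- c("cell_id", "sample_id", "tissue", "major_type", "subtype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(lapply(df[need], as.character), stringsAsFactors = FALSE)
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in annotation")
  if (!all(df$tissue %in% c("tumor", "normal"))) {
    stop("tissue must be 'tumor' or 'normal'")
  }
  parent <- unique(df[, c("subtype", "major_type")])
  if (anyDuplicated(parent$subtype)) {
    stop("each subtype must belong to exactly one major_type")
  }
  if (!is.null(m)) {
    absent <- setdiff(df$cell_id, observations(m))
    if (length(absent)) {
      stop(length(absent), " annotated cell(s) absent from expression matrix, e.g. ",
        absent[1])
    }
  }
  class(df) <- c("cell_annotation", "data.frame")
  df
}
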