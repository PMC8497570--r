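#' Feature-by-cell expression matrix with a layer tag
#'
#' Light container used throughout the package. The matrix is stored in the
#' mathematical orientation (features in rows, cells in columns); sparse
#' [Matrix::dgCMatrix-class] input is kept sparse. The `layer` records which
#' transform the values carry so downstream steps can check they are fed the
#' right kind of data (`counts`, `lognorm`, `scaled` or `tfidf`).
#'
#' @param values Numeric matrix (dense or sparse), features x cells, with
#'   unique row and column names.
#' @param layer One of `"counts"`, `"lognorm"`, `"scaled"`, `"tfidf"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `layer`.
#' @export
expression_matrix <- function(values, layer = c("counts", "lognorm", "scaled", "tfidf")) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature (row) and cell (column) names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicated cell ids")
  if (layer == "counts") {
    mn <- if (inherits(values, "sparseMatrix")) min(values@x, 0) else min(values)
    if (mn < 0) stop("counts layer must be nonnegative")
  }
  structure(list(values = values, layer = layer), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d features x %d cells, layer '%s'%s\n",
              nrow(x$values), ncol(x$values), x$layer,
              if (inherits(x$values, "sparseMatrix")) " (sparse)" else ""))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Coerce to ExpressionMatrix
#'
#' Bare matrices are wrapped with the given default layer; existing
#' `ExpressionMatrix` objects are checked against `expect` when provided.
#'
#' @param x Matrix or `ExpressionMatrix`.
#' @param layer Layer to assume for bare matrices.
#' @param expect Optional layer(s) the caller requires.
#' @return An `ExpressionMatrix`.
#' @export
as_expression_matrix <- function(x, layer = "counts", expect = NULL) {
  if (!inherits(x, "ExpressionMatrix")) x <- expression_matrix(x, layer)
  if (!is.null(expect) && !(x$layer %in% expect)) {
    stop("expected expression layer ", paste(expect, collapse = "/"),
         " but got '", x$layer, "'")
  }
  x
}

feature_ids <- function(x) rownames(x$values)
cell_ids <- function(x) colnames(x$values)
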