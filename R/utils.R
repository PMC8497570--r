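`%||%` <- function(a, b) if (is.null(a)) b else a

#' L2-normalize the columns of a matrix
#'
#' Columns with zero norm are returned unchanged (all zeros) and reported via
#' the `"zero_columns"` attribute so callers can flag degenerate cells.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape with unit-norm columns.
#' @keywords internal
l2_normalize_cols <- function(x) {
  x <- as.matrix(x)
  nrm <- sqrt(colSums(x^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  out <- sweep(x, 2, nrm, "/")
  attr(out, "zero_columns") <- which(zero)
  out
}

#' Stack one-hot design blocks for one or more covariates
#'
#' @param meta Data frame of per-cell covariates, or a single factor/vector.
#' @param cols Column names to encode (ignored when `meta` is a vector).
#' @return A `c x m` 0/1 matrix, one row per covariate level, with row names
#'   `"<covariate>:<level>"`, plus a `"blocks"` attribute giving the row
#'   indices of each covariate block.
#' @keywords internal
build_design <- function(meta, cols = NULL) {
  if (is.null(meta)) {
    return(structure(matrix(0, 0, 0), blocks = list()))
  }
  if (!is.data.frame(meta)) meta <- data.frame(batch = meta)
  cols <- cols %||% names(meta)
  missing_cols <- setdiff(cols, names(meta))
  if (length(missing_cols) > 0) {
    stop("covariate column(s) not in metadata: ", paste(missing_cols, collapse = ", "))
  }
  blocks <- list()
  rows <- list()
  for (cn in cols) {
    f <- factor(meta[[cn]])
    if (anyNA(f)) stop("covariate '", cn, "' contains missing values")
    oh <- matrix(0, nlevels(f), length(f))
    oh[cbind(as.integer(f), seq_along(f))] <- 1
    rownames(oh) <- paste0(cn, ":", levels(f))
    blocks[[cn]] <- seq_len(nrow(oh)) + sum(lengths(blocks))
    rows[[cn]] <- oh
  }
  X <- do.call(rbind, rows)
  attr(X, "blocks") <- blocks
  X
}

#' k nearest neighbours between two embeddings
#'
#' Thin wrapper around [RANN::nn2()] with the package's cells-in-columns
#' orientation.
#'
#' @param ref d x n reference coordinates.
#' @param query d x m query coordinates (defaults to `ref`).
#' @param k Number of neighbours.
#' @param exclude_self When TRUE (and querying an embedding against itself),
#'   the first neighbour (the point itself) is dropped.
#' @return List with `idx` (m x k integer) and `dist` (m x k numeric).
#' @keywords internal
find_knn <- function(ref, query = ref, k, exclude_self = FALSE) {
  n <- ncol(ref)
  k_search <- if (exclude_self) k + 1L else k
  if (k_search > n) stop("k = ", k, " exceeds the ", n, " available reference cells")
  nn <- RANN::nn2(t(ref), t(query), k = k_search)
  if (exclude_self) {
    nn$nn.idx <- nn$nn.idx[, -1L, drop = FALSE]
    nn$nn.dists <- nn$nn.dists[, -1L, drop = FALSE]
  }
  list(idx = nn$nn.idx, dist = nn$nn.dists)
}

softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

#' Row means and (sample) variances, sparse-aware
#' @keywords internal
row_mean_var <- function(x) {
  n <- ncol(x)
  if (inherits(x, "sparseMatrix")) {
    mu <- Matrix::rowMeans(x)
    ex2 <- Matrix::rowSums(x^2) / n
  } else {
    mu <- rowMeans(x)
    ex2 <- rowSums(x^2) / n
  }
  v <- (ex2 - mu^2) * n / (n - 1)
  list(mean = as.numeric(mu), var = pmax(as.numeric(v), 0))
}
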