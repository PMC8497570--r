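#' Library-size normalization: log(CP10K + 1)
#'
#' Divides each cell's counts by its total, multiplies by `scale_factor`
#' (10,000 by default, i.e. counts per 10K) and applies `log(x + 1)`. Zeros
#' stay zero, so sparsity is preserved. Natural log is the default; base 2 is
#' available for protocols that use `log2(CP10K + 1)`.
#'
#' @param counts `ExpressionMatrix` (layer counts) or bare nonnegative matrix.
#' @param scale_factor Pseudo library size, default `1e4`.
#' @param log_base `"e"` (default) or `"2"`.
#' @return `ExpressionMatrix` with layer `lognorm` and a `log_base` field
#'   recorded for dialect checking.
#' @export
normalize_log_cp10k <- function(counts, scale_factor = 1e4, log_base = c("e", "2")) {
  log_base <- match.arg(as.character(log_base), c("e", "2"))
  counts <- as_expression_matrix(counts, "counts", expect = "counts")
  x <- counts$values
  totals <- if (inherits(x, "sparseMatrix")) Matrix::colSums(x) else colSums(x)
  if (any(totals == 0)) {
    bad <- colnames(x)[totals == 0]
    stop("cell(s) with zero total counts cannot be normalized: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (inherits(x, "sparseMatrix")) {
    x <- methods::as(x, "CsparseMatrix")
    x@x <- x@x / rep.int(totals, diff(x@p)) * scale_factor
    x@x <- log1p(x@x)
  } else {
    x <- log1p(sweep(x, 2, totals, "/") * scale_factor)
  }
  if (log_base == "2") {
    if (inherits(x, "sparseMatrix")) x@x <- x@x / log(2) else x <- x / log(2)
  }
  out <- expression_matrix(x, "lognorm")
  out$log_base <- log_base
  out
}

# Standardized per-gene variance after variance stabilization, for one batch.
# Mirrors the published VST recipe: loess of log10(variance) on log10(mean)
# (span 0.3, degree 2), standardize by observed mean / expected sd, clip at
# sqrt(n), then take the variance of the standardized values (zeros handled
# analytically so sparse input is never densified).
vst_standardized_variance <- function(x, span = 0.3) {
  n <- ncol(x)
  if (n < 2) stop("a batch must contain at least 2 cells for variable-gene selection")
  mv <- row_mean_var(x)
  mu <- mv$mean
  v <- mv$var
  std_var <- numeric(nrow(x))
  fit_on <- v > 0 & mu > 0
  if (sum(fit_on) < 2) {
    return(v) # degenerate fixture: fall back to raw variance ranking
  }
  lv <- log10(v[fit_on])
  lm_ <- log10(mu[fit_on])
  # loess needs a reasonable number of points; small fixtures get a linear trend
  fitted_lv <- if (sum(fit_on) >= 10) {
    suppressWarnings(stats::fitted(stats::loess(lv ~ lm_, span = span, degree = 2)))
  } else {
    stats::fitted(stats::lm(lv ~ lm_))
  }
  esd <- sqrt(10^fitted_lv)
  clipmax <- sqrt(n)
  idx_fit <- which(fit_on)
  if (inherits(x, "sparseMatrix")) {
    # genes as columns for cheap per-gene access; zeros handled analytically
    xt <- methods::as(Matrix::t(x), "CsparseMatrix")
    for (j in seq_along(idx_fit)) {
      g <- idx_fit[j]
      vals <- xt@x[seq.int(xt@p[g] + 1L, length.out = xt@p[g + 1L] - xt@p[g])]
      z <- pmin((vals - mu[g]) / esd[j], clipmax)
      z0 <- pmin(-mu[g] / esd[j], clipmax)
      std_var[g] <- (sum(z^2) + (n - length(vals)) * z0^2) / (n - 1)
    }
  } else {
    z <- (x[idx_fit, , drop = FALSE] - mu[idx_fit]) / esd
    z <- pmin(z, clipmax)
    std_var[idx_fit] <- rowSums(z^2) / (n - 1)
  }
  std_var
}

#' Variable-gene selection by variance-stabilizing transform (VST)
#'
#' Per batch, fits a local polynomial regression (loess, span 0.3) of
#' log10(variance) on log10(mean), standardizes each gene by its observed
#' mean and the trend-expected standard deviation, clips standardized values
#' at `sqrt(n_cells)`, ranks genes by the variance of the standardized
#' values, and takes the top `n_top`. Ranked lists are then pooled across
#' batches: the union is formed batch by batch in rank order, de-duplicated,
#' so the result is order-stable.
#'
#' @param lognorm `ExpressionMatrix` (layer lognorm) or matrix.
#' @param batch Per-cell batch labels (factor-like) or `NULL` for one batch.
#' @param n_top Number of genes to keep per batch.
#' @return Character vector of selected gene ids.
#' @export
select_variable_genes_vst <- function(lognorm, batch = NULL, n_top) {
  lognorm <- as_expression_matrix(lognorm, "lognorm")
  x <- lognorm$values
  if (n_top < 1) stop("n_top must be >= 1")
  batch <- if (is.null(batch)) factor(rep("all", ncol(x))) else factor(batch)
  if (length(batch) != ncol(x)) stop("batch labels must match the number of cells")
  small <- table(batch) < 2
  if (any(small)) {
    stop("batch(es) with fewer than 2 cells: ",
         paste(names(small)[small], collapse = ", "))
  }
  if (n_top > nrow(x)) {
    warning("n_top exceeds the number of genes; returning all expressed genes")
  }
  selected <- character(0)
  for (b in levels(batch)) {
    xb <- x[, batch == b, drop = FALSE]
    sv <- vst_standardized_variance(xb)
    sv[is.na(sv)] <- 0
    ranked <- rownames(x)[order(-sv)]
    ranked <- ranked[sv[order(-sv)] > 0]
    take <- utils::head(ranked, n_top)
    selected <- c(selected, setdiff(take, selected))
  }
  selected
}

#' Scale genes to zero mean and unit variance, with a reusable model
#'
#' Reference mode (`model = NULL`): computes per-gene means and sample
#' standard deviations over the selected genes and standardizes. Query mode
#' (`model` given): the output rows follow `model$genes` exactly; query genes
#' absent from the model are dropped, model genes absent from the query get
#' all-zero rows, and the *model's* means/sds are applied, so the result is a
#' pure function of the query matrix and the model.
#'
#' Zero-variance genes are kept (row of zeros) and flagged in
#' `model$zero_variance` so gene indices stay aligned with the reference.
#'
#' @param lognorm `ExpressionMatrix` (lognorm or tfidf layer) or matrix.
#' @param genes Genes to scale (reference mode). Defaults to all rows.
#' @param model A scaling model from a previous reference-mode call.
#' @return List with `scaled` (`ExpressionMatrix`, dense, layer scaled) and
#'   `model` (list: `genes`, `mu`, `sigma`, `zero_variance`).
#' @export
scale_genes <- function(lognorm, genes = NULL, model = NULL) {
  lognorm <- as_expression_matrix(lognorm, "lognorm")
  x <- lognorm$values
  if (is.null(model)) {
    genes <- genes %||% rownames(x)
    if (anyDuplicated(genes)) stop("duplicated genes in selection")
    missing <- setdiff(genes, rownames(x))
    if (length(missing) > 0) stop("genes absent from the matrix: ",
                                  paste(utils::head(missing, 5), collapse = ", "))
    xs <- as_dense(x[genes, , drop = FALSE])
    mv <- row_mean_var(xs)
    sigma <- sqrt(mv$var)
    zerovar <- sigma == 0
    sig_use <- ifelse(zerovar, 1, sigma)
    scaled <- (xs - mv$mean) / sig_use
    scaled[zerovar, ] <- 0
    model <- list(genes = genes, mu = stats::setNames(mv$mean, genes),
                  sigma = stats::setNames(sigma, genes), zero_variance = zerovar)
  } else {
    if (anyDuplicated(model$genes)) stop("scaling model contains duplicated genes")
    m <- ncol(x)
    scaled <- matrix(0, length(model$genes), m,
                     dimnames = list(model$genes, colnames(x)))
    present <- intersect(model$genes, rownames(x))
    if (length(present) > 0) {
      sig <- model$sigma[present]
      zv <- sig == 0
      sig[zv] <- 1
      sub <- as_dense(x[present, , drop = FALSE])
      sub <- (sub - model$mu[present]) / sig
      sub[zv, ] <- 0
      scaled[present, ] <- sub
    }
  }
  list(scaled = expression_matrix(scaled, "scaled"), model = model)
}

#' Truncated SVD embedding (PCA on scaled expression)
#'
#' Factorizes the scaled matrix `X = U D V'` and returns the gene loadings
#' `U` (orthonormal columns) together with the cell embedding `Z = D V' =
#' U' X`. The loadings are what make the embedding reusable: new cells are
#' projected with the same linear map. Component signs are fixed
#' deterministically (largest-magnitude loading positive).
#'
#' @param scaled `ExpressionMatrix` (layer scaled) or matrix.
#' @param d Number of dimensions, at most `min(genes, cells)`.
#' @param seed Seed for the randomized solver used on large inputs.
#' @return List with `model` (list: `loadings`, `singular_values`, `d`) and
#'   `Z` (d x cells matrix).
#' @export
run_svd_embedding <- function(scaled, d, seed = 0) {
  scaled <- as_expression_matrix(scaled, "scaled")
  x <- scaled$values
  if (d > min(dim(x))) {
    stop("d = ", d, " exceeds min(genes, cells) = ", min(dim(x)))
  }
  use_irlba <- d <= min(dim(x)) / 3 && min(dim(x)) > 10
  if (use_irlba) {
    set.seed(seed)
    sv <- irlba::irlba(x, nv = d, tol = 1e-9, maxit = 1000)
    U <- sv$u; D <- sv$d; V <- sv$v
  } else {
    sv <- svd(as_dense(x), nu = d, nv = d)
    U <- sv$u; D <- sv$d[seq_len(d)]; V <- sv$v
  }
  tol <- max(dim(x)) * .Machine$double.eps * max(D, 1)
  achievable <- sum(D > max(D) * 1e-10)
  if (any(D <= tol)) {
    stop("requested d = ", d, " exceeds the matrix rank; achievable rank is ",
         achievable)
  }
  flip <- apply(U, 2, function(u) sign(u[which.max(abs(u))]))
  U <- sweep(U, 2, flip, "*")
  # Z = U'X; identical to D V' up to solver tolerance, and makes projection
  # through the saved loadings reproduce the training embedding exactly
  Z <- as.matrix(t(U) %*% x)
  dimnames(Z) <- list(paste0("dim", seq_len(d)), colnames(x))
  rownames(U) <- rownames(x)
  colnames(U) <- paste0("dim", seq_len(d))
  list(model = list(loadings = U, singular_values = D, d = d), Z = Z)
}

#' TF-IDF normalization for binarized accessibility peaks
#'
#' Term frequency is each peak's share of a cell's total open peaks; inverse
#' document frequency is computed on the *reference* cells only
#' (`n_ref / cells-with-peak`) and reused verbatim for queries so both land
#' in the same space. The output is `log(TF x IDF x 1e4 + 1)` — the scale
#' factor and pseudocount keep zeros at zero (the dialect string is recorded
#' in the model).
#'
#' @param binary_peaks `ExpressionMatrix` (counts layer, values in 0/1).
#' @param model Optional TF-IDF model from the reference pass.
#' @param scale_factor Scale inside the log, default `1e4`.
#' @return List with `tfidf` (`ExpressionMatrix`, layer tfidf) and `model`
#'   (list: `idf`, `n_ref`, `absent`, `dialect`). Peaks absent from all
#'   reference cells have undefined IDF: their rows are zeroed and flagged.
#' @export
tfidf_normalize <- function(binary_peaks, model = NULL, scale_factor = 1e4) {
  em <- as_expression_matrix(binary_peaks, "counts")
  x <- em$values
  vals <- if (inherits(x, "sparseMatrix")) x@x else as.numeric(x)
  if (!all(vals %in% c(0, 1))) stop("TF-IDF input must be binarized (0/1)")
  if (is.null(model)) {
    n_ref <- ncol(x)
    peak_cells <- as.numeric(if (inherits(x, "sparseMatrix")) Matrix::rowSums(x) else rowSums(x))
    absent <- peak_cells == 0
    idf <- rep(NA_real_, nrow(x))
    idf[!absent] <- n_ref / peak_cells[!absent]
    names(idf) <- rownames(x)
    model <- list(idf = idf, n_ref = n_ref, absent = stats::setNames(absent, rownames(x)),
                  dialect = paste0("log_tfidf_", format(scale_factor, scientific = FALSE)))
  } else {
    if (length(model$idf) != nrow(x)) {
      stop("TF-IDF model covers ", length(model$idf), " peaks but input has ", nrow(x))
    }
  }
  totals <- as.numeric(if (inherits(x, "sparseMatrix")) Matrix::colSums(x) else colSums(x))
  totals[totals == 0] <- 1
  tf <- as_dense(x)
  tf <- sweep(tf, 2, totals, "/")
  idf_use <- ifelse(model$absent, 0, model$idf)
  out <- log1p(tf * idf_use * scale_factor)
  out[model$absent, ] <- 0
  list(tfidf = expression_matrix(out, "tfidf"), model = model)
}

#' Build a column-stochastic ortholog map from symbol pairs
#'
#' @param pairs Data frame (or 2-column matrix) with mouse symbols in the
#'   first column and human symbols in the second; one-to-many rows allowed.
#' @return List with `matrix` (human x mouse sparse, columns sum to 1),
#'   `human_ids`, `mouse_ids`.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2) stop("ortholog pairs need two columns (mouse, human)")
  mouse <- factor(pairs[[1]])
  human <- factor(pairs[[2]])
  M <- Matrix::sparseMatrix(i = as.integer(human), j = as.integer(mouse), x = 1,
                            dims = c(nlevels(human), nlevels(mouse)),
                            dimnames = list(levels(human), levels(mouse)))
  colsum <- Matrix::colSums(M)
  M <- M %*% Matrix::Diagonal(x = ifelse(colsum > 0, 1 / colsum, 0))
  dimnames(M) <- list(levels(human), levels(mouse))
  list(matrix = M, human_ids = levels(human), mouse_ids = levels(mouse))
}

#' Map mouse counts into human gene space with a count-preserving map
#'
#' Multiplies the counts by a column-stochastic matrix `M` (human genes x
#' mouse genes), so each mouse gene's counts are split across its human
#' orthologs and per-cell totals over mapped genes are conserved exactly.
#' Human genes with no mouse ortholog present end up as zero rows.
#'
#' @param mouse_counts `ExpressionMatrix` (counts) or matrix, mouse genes x cells.
#' @param orthologs An [ortholog_map()] object.
#' @return `ExpressionMatrix` (counts layer; values may be fractional) in
#'   human gene space.
#' @export
map_orthologs <- function(mouse_counts, orthologs) {
  em <- as_expression_matrix(mouse_counts, "counts", expect = "counts")
  x <- em$values
  M <- orthologs$matrix
  colsum <- Matrix::colSums(M)
  if (any(abs(colsum) > 1e-8 & abs(colsum - 1) > 1e-8)) {
    stop("invalid ortholog map: columns must sum to 0 or 1")
  }
  keep <- intersect(rownames(x), orthologs$mouse_ids)
  dropped <- setdiff(rownames(x), keep)
  if (length(dropped) > 0) {
    warning(length(dropped), " mouse gene(s) missing from the ortholog map were dropped")
  }
  if (length(keep) == 0) stop("no mouse genes overlap the ortholog map")
  out <- M[, keep, drop = FALSE] %*% x[keep, , drop = FALSE]
  expression_matrix(out, "counts")
}
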