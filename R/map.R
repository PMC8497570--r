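#' Project query cells into the reference embedding
#'
#' Scales the query's normalized expression with the *reference* gene means
#' and standard deviations (genes missing from the query become zero rows;
#' query genes unknown to the reference are ignored) and applies the saved
#' gene loadings: `Z_q = U' G_qs`. No reference cell data is touched.
#'
#' @param expr_q Query `ExpressionMatrix` with layer lognorm (or tfidf),
#'   normalized with the same dialect as the reference.
#' @param ref `MinimalReference`.
#' @return d x m query embedding in the pre-harmonized reference space.
#' @export
project_query <- function(expr_q, ref) {
  expr_q <- as_expression_matrix(expr_q, "lognorm", expect = c("lognorm", "tfidf"))
  if (!is.null(expr_q$log_base) && !is.null(ref$dialect$log_base) &&
      !identical(expr_q$log_base, ref$dialect$log_base)) {
    stop("normalization dialect mismatch: query uses log base '", expr_q$log_base,
         "', reference uses '", ref$dialect$log_base, "'")
  }
  overlap <- length(intersect(rownames(expr_q$values), ref$genes)) / length(ref$genes)
  if (overlap < 0.01) {
    stop("query shares fewer than 1% of the reference variable genes (",
         sprintf("%.2f%%", 100 * overlap), ")")
  }
  if (overlap < 0.5) {
    warning(sprintf("only %.1f%% of reference variable genes found in the query",
                    100 * overlap))
  }
  scaled <- scale_genes(expr_q, model = list(genes = ref$genes, mu = ref$mu,
                                             sigma = ref$sigma))$scaled
  Z_q <- t(ref$loadings) %*% scaled$values
  dimnames(Z_q) <- list(paste0("dim", seq_len(ref$d)), colnames(expr_q$values))
  Z_q
}

#' Soft-assign query cells to the frozen reference clusters
#'
#' Memberships follow the entropy-regularized cosine rule
#' `R_q[k,i] propto exp(-(2/s)(1 - Y_cos[,k]' z_cos_i))` on the L2-normalized
#' query coordinates, computed with max-subtraction. Cells with all-zero
#' expression on the reference genes have no direction: they get uniform
#' `1/k` membership and are reported in the `"flagged_cells"` attribute.
#'
#' @param Z_q d x m query embedding.
#' @param Y_cos d x k L2-normalized reference centroids.
#' @param s Entropy weight (default 0.1).
#' @return k x m membership matrix (columns sum to 1).
#' @export
assign_query_clusters <- function(Z_q, Y_cos, s = 0.1) {
  if (s <= 0) stop("s must be positive")
  Zcos <- l2_normalize_cols(Z_q)
  zero <- attr(Zcos, "zero_columns")
  R_q <- soft_assign(Y_cos, Zcos, s)
  if (length(zero) > 0) {
    R_q[, zero] <- 1 / nrow(R_q)
    warning(length(zero), " query cell(s) with zero norm assigned uniform membership")
  }
  rownames(R_q) <- paste0("cluster", seq_len(ncol(Y_cos)))
  attr(R_q, "flagged_cells") <- zero
  R_q
}

#' Solve the query mixture model from the compression terms
#'
#' For each cluster assembles the (1+c) x (1+c) ridge system using only the
#' compression terms `N_r` and `C` plus query-side sums — no reference cell
#' ever enters — and solves for the intercept (the cluster centroid) and the
#' per-batch coefficients. This equals the full ridge solve on the explicit
#' reference+query concatenation in which reference cells carry zero query
#' design and their harmonized coordinates.
#'
#' @param R_q k x m query memberships.
#' @param Z_q d x m query embedding (same space the reference was compressed
#'   in).
#' @param X_q c x m one-hot query batch design (`NULL` or 0-row for c = 0,
#'   in which case only intercepts are fit).
#' @param ref `MinimalReference`, or any list with `N_r` and `C`.
#' @param lambda Ridge penalty for batch coefficients (default 1; the
#'   intercept is never penalized).
#' @return k x (1+c) x d array of coefficients.
#' @export
solve_query_betas <- function(R_q, Z_q, X_q = NULL, ref, lambda = 1) {
  k <- nrow(R_q)
  d <- nrow(Z_q)
  if (is.null(X_q)) X_q <- matrix(0, 0, ncol(Z_q))
  X_q <- as.matrix(X_q)
  cc <- nrow(X_q)
  N_r <- ref$N_r
  C <- as.matrix(ref$C)
  if (length(N_r) != k || nrow(C) != k) stop("compression terms disagree with k")
  if (length(lambda) == 1) lambda <- rep(lambda, cc)
  batch_names <- rownames(X_q) %||% if (cc > 0) paste0("batch", seq_len(cc)) else character(0)
  B_q <- array(0, dim = c(k, 1 + cc, d),
               dimnames = list(paste0("cluster", seq_len(k)),
                               c("intercept", batch_names), rownames(Z_q)))
  ZqT <- t(Z_q)
  for (kk in seq_len(k)) {
    rq <- R_q[kk, ]
    s_a <- as.numeric(X_q %*% rq)                    # per-batch query weight
    A <- matrix(0, 1 + cc, 1 + cc)
    A[1, 1] <- N_r[kk] + sum(rq)
    if (cc > 0) {
      A[1, -1] <- s_a
      A[-1, 1] <- s_a
      diag(A)[-1] <- s_a + lambda
    }
    b <- matrix(0, 1 + cc, d)
    b[1, ] <- C[kk, ] + as.numeric(crossprod(ZqT, rq))
    if (cc > 0) {
      b[-1, ] <- sweep(X_q, 2, rq, "*") %*% ZqT
    }
    B_q[kk, , ] <- solve(A, b)
  }
  B_q
}

#' Remove query batch effects
#'
#' Subtracts each cell's membership-weighted batch terms:
#' `Z_hat_q[,i] = Z_q[,i] - sum_k R_q[k,i] B_qk[1:c,]' X_q[,i]`. The
#' reference embedding is not an input, so reference cells cannot move.
#'
#' @param Z_q d x m query embedding.
#' @param R_q k x m memberships.
#' @param B_q k x (1+c) x d coefficients from [solve_query_betas()].
#' @param X_q c x m one-hot design (`NULL` for c = 0, returning `Z_q`).
#' @return d x m corrected query embedding.
#' @export
correct_query <- function(Z_q, R_q, B_q, X_q = NULL) {
  if (is.null(X_q) || nrow(as.matrix(X_q)) == 0) return(Z_q)
  X_q <- as.matrix(X_q)
  k <- nrow(R_q)
  delta <- matrix(0, nrow(Z_q), ncol(Z_q))
  for (kk in seq_len(k)) {
    Bk <- matrix(B_q[kk, -1, ], nrow = dim(B_q)[2] - 1)  # c x d
    term <- t(Bk) %*% X_q                                # d x m
    delta <- delta + sweep(term, 2, R_q[kk, ], "*")
  }
  Z_q - delta
}

#' Map query cells onto a frozen reference
#'
#' The full mapping pipeline: normalize (if counts are given), project with
#' the saved scaling and loadings, soft-assign to the frozen centroids,
#' solve the per-cluster ridge mixture model from the compression terms, and
#' subtract the estimated query batch terms. Mapping is deterministic, a
#' pure function of `(expr_q, meta_q, ref)`, and its cost is independent of
#' the number of reference cells.
#'
#' @param expr_q Query `ExpressionMatrix` (counts are normalized with the
#'   reference dialect; lognorm used as-is).
#' @param meta_q Per-cell query metadata (data frame) or `NULL`.
#' @param ref `MinimalReference`.
#' @param batch_cols Metadata columns forming the query batch design; each
#'   covariate contributes a one-hot block. `NULL` maps without correction.
#' @param s Entropy weight for assignment (default 0.1).
#' @param lambda Ridge penalty for batch coefficients (default 1).
#' @param normalize_embedding If TRUE, the query coordinates are L2-normalized
#'   once after projection and the normalized coordinates are used in the
#'   solve/correct steps as well (cluster assignment is always cosine).
#'   Default FALSE: the solve/correct run in the raw embedding scale, the
#'   same scale the reference compression terms were computed in.
#' @return Object of class `MappedQuery`: `Z_q` (raw projection), `R_q`,
#'   `B_q`, `Z_hat_q` (corrected embedding), `X_q`, `cell_ids`.
#' @export
map_query <- function(expr_q, meta_q = NULL, ref, batch_cols = NULL, s = 0.1,
                      lambda = 1, normalize_embedding = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop(name, ": ", conditionMessage(e), call. = FALSE))
  }
  em <- as_expression_matrix(expr_q, "counts")
  if (em$layer == "counts") {
    em <- stage("normalize", normalize_log_cp10k(em, log_base = ref$dialect$log_base %||% "e"))
  }
  Z_q <- stage("project", project_query(em, ref))
  Z_use <- if (normalize_embedding) l2_normalize_cols(Z_q) else Z_q
  R_q <- stage("assign", assign_query_clusters(Z_use, ref$Y_cos, s = s))
  X_q <- if (!is.null(batch_cols)) {
    if (is.null(meta_q)) stop("map: batch_cols given but meta_q is NULL")
    stage("design", build_design(meta_q, batch_cols))
  } else NULL
  B_q <- stage("solve", solve_query_betas(R_q, Z_use, X_q, ref, lambda = lambda))
  Z_hat_q <- stage("correct", correct_query(Z_use, R_q, B_q, X_q))
  res <- list(Z_q = Z_q, R_q = R_q, B_q = B_q, Z_hat_q = Z_hat_q, X_q = X_q,
              cell_ids = colnames(Z_q),
              normalize_embedding = normalize_embedding)
  class(res) <- "MappedQuery"
  res
}

#' @export
print.MappedQuery <- function(x, ...) {
  cat(sprintf("<MappedQuery> %d cells, d = %d, k = %d, %d query batch column(s)\n",
              ncol(x$Z_hat_q), nrow(x$Z_hat_q), nrow(x$R_q),
              if (is.null(x$X_q)) 0L else nrow(x$X_q)))
  invisible(x)
}
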