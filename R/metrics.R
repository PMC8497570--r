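#' Mahalanobis distance of point(s) to a distribution
#'
#' `D = sqrt((x - mu)' Sigma^{-1} (x - mu))`, the multivariate analogue of a
#' Z-score. A ridge of `1e-6` is added to the covariance diagonal before the
#' solve; if the regularized matrix is still not positive definite an error
#' is raised.
#'
#' @param x d-vector, or d x m matrix of column points.
#' @param mean d-vector.
#' @param cov d x d symmetric covariance.
#' @param ridge Diagonal regularization (default 1e-6).
#' @return Distance (scalar or length-m vector).
#' @export
mahalanobis_dist <- function(x, mean, cov, ridge = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) != length(mean)) x <- t(x)
  cov <- (cov + t(cov)) / 2 + diag(ridge, length(mean))
  ch <- tryCatch(chol(cov), error = function(e) {
    stop("covariance is not positive semidefinite after ridge regularization")
  })
  centered <- x - as.numeric(mean)
  w <- backsolve(ch, centered, transpose = TRUE)
  sqrt(colSums(w^2))
}

#' Per-cell mapping confidence
#'
#' For each query cell, the Mahalanobis distance to every reference
#' soft-cluster distribution (weighted mean/covariance in pre-harmonized PC
#' space) averaged with the cell's cluster memberships:
#' `score_i = sum_k R_q[k,i] D(Z_q[,i]; mean_k, cov_k)`. Cell states well
#' captured by the reference tend to score below about 10; large scores flag
#' potentially novel states.
#'
#' @param mapped `MappedQuery` (its raw pre-harmonized projection `Z_q` is
#'   used, matching the space of the statistics).
#' @param stats `ClusterStats`; omit to use the one stored in `ref`.
#' @param ref Optional `MinimalReference` carrying `extras$cluster_stats`.
#' @return Nonnegative per-cell score vector.
#' @export
per_cell_mapping_metric <- function(mapped, stats = NULL, ref = NULL) {
  stats <- stats %||% ref$extras$cluster_stats
  if (is.null(stats)) stop("ClusterStats absent")
  Z_q <- mapped$Z_q
  R_q <- mapped$R_q
  k <- nrow(R_q)
  D <- matrix(0, k, ncol(Z_q))
  for (kk in seq_len(k)) {
    D[kk, ] <- mahalanobis_dist(Z_q, stats$mean[kk, ], stats$cov[[kk]])
  }
  score <- colSums(R_q * D)
  names(score) <- colnames(Z_q)
  score
}

#' Per-cluster mapping confidence
#'
#' Takes user-defined query cluster labels (e.g. de novo clusters), computes
#' each cluster's mean and covariance in the reference pre-harmonized PC
#' space, finds the nearest reference centroid (Euclidean distance to the
#' cluster mean) and scores the cluster by the Mahalanobis distance of that
#' centroid under the *query cluster's* covariance. Clusters smaller than
#' `2d` give numerically unstable covariances and are returned as `NA`. All
#' cells of a cluster share its score.
#'
#' @param Z_q d x m query embedding (pre-harmonized space).
#' @param query_clusters Length-m cluster labels.
#' @param ref_centroids k x d reference centroid matrix in the same space
#'   (e.g. `ClusterStats$mean`), or a `ClusterStats` object.
#' @return List with `per_cluster` (named score or NA per cluster) and
#'   `per_cell` (scores broadcast to cells).
#' @export
per_cluster_mapping_metric <- function(Z_q, query_clusters, ref_centroids) {
  if (inherits(ref_centroids, "ClusterStats")) ref_centroids <- ref_centroids$mean
  ref_centroids <- as.matrix(ref_centroids)
  if (length(query_clusters) != ncol(Z_q)) stop("unknown labels: length mismatch with cells")
  if (anyNA(query_clusters)) stop("unknown labels: NA cluster labels")
  d <- nrow(Z_q)
  labs <- factor(query_clusters)
  per_cluster <- stats::setNames(rep(NA_real_, nlevels(labs)), levels(labs))
  for (lv in levels(labs)) {
    idx <- which(labs == lv)
    if (length(idx) < 2 * d) next
    sub <- Z_q[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    cv <- stats::cov(t(sub))
    nearest <- which.min(colSums((t(ref_centroids) - mu)^2))
    per_cluster[lv] <- mahalanobis_dist(ref_centroids[nearest, ], mu, cv)
  }
  list(per_cluster = per_cluster,
       per_cell = stats::setNames(per_cluster[as.character(labs)], colnames(Z_q)))
}

#' Neighborhood distance correlation between two embeddings (k-NN-corr)
#'
#' For each query cell: fix its k nearest *reference* neighbors in the gold
#' embedding, compute the distances to those same reference cells in both
#' embeddings, and return the Spearman correlation of the two distance
#' lists. Asymmetric in (gold, alt) by construction; 1 means the alternative
#' embedding preserves the local distance ordering perfectly.
#'
#' @param gold,alt d x N embeddings containing all listed cells (columns
#'   named, or indexable by the id vectors).
#' @param query_ids,ref_ids Column names (or indices) of query and reference
#'   cells.
#' @param k Neighbors (default 500), at most the number of reference cells.
#' @return Named per-query-cell Spearman correlation vector.
#' @export
knn_corr <- function(gold, alt, query_ids, ref_ids, k = 500) {
  if (k > length(ref_ids)) stop("k = ", k, " exceeds the ", length(ref_ids),
                                " reference cells")
  g_ref <- gold[, ref_ids, drop = FALSE]
  g_query <- gold[, query_ids, drop = FALSE]
  a_ref <- alt[, ref_ids, drop = FALSE]
  a_query <- alt[, query_ids, drop = FALSE]
  nn <- find_knn(g_ref, g_query, k)
  out <- numeric(length(query_ids))
  for (i in seq_along(query_ids)) {
    idx <- nn$idx[i, ]
    dg <- nn$dist[i, ]
    da <- sqrt(colSums((a_ref[, idx, drop = FALSE] - a_query[, i])^2))
    out[i] <- stats::cor(dg, da, method = "spearman")
  }
  stats::setNames(out, if (is.character(query_ids)) query_ids else colnames(g_query))
}

#' Within-query neighborhood preservation (wiq-kNN-corr)
#'
#' Runs a standard per-batch PCA pipeline (log-normalization assumed done;
#' VST variable genes, scaling, truncated SVD) on each query batch alone,
#' fixes each cell's k nearest *within-batch* neighbors in that PCA, and
#' returns the Spearman correlation between the pre-mapping (per-batch PCA)
#' and post-mapping distances to those fixed neighbors. Rigid isometries of
#' the per-batch PCA give 1.
#'
#' @param expr_q Query `ExpressionMatrix` (layer lognorm).
#' @param batch Per-cell batch labels.
#' @param Z_hat_q d x m mapped query embedding (columns align with cells).
#' @param k Neighbors (default 500); truncated with a warning for batches
#'   smaller than k + 1.
#' @param d_pca PCA dimensions per batch (default 20).
#' @param n_vargenes Variable genes per batch (default 2000).
#' @return Named per-cell correlation vector.
#' @export
wiq_knn_corr <- function(expr_q, batch, Z_hat_q, k = 500, d_pca = 20,
                         n_vargenes = 2000) {
  expr_q <- as_expression_matrix(expr_q, "lognorm")
  batch <- factor(batch)
  m <- ncol(expr_q$values)
  if (length(batch) != m) stop("batch labels must cover all query cells")
  out <- stats::setNames(rep(NA_real_, m), colnames(expr_q$values))
  for (b in levels(batch)) {
    idx <- which(batch == b)
    k_b <- min(k, length(idx) - 1)
    if (k_b < k) warning("batch '", b, "' smaller than k + 1; using k = ", k_b)
    sub <- expression_matrix(expr_q$values[, idx, drop = FALSE], "lognorm")
    genes <- select_variable_genes_vst(sub, n_top = min(n_vargenes, nrow(sub$values)))
    scaled <- scale_genes(sub, genes = genes)$scaled
    P <- run_svd_embedding(scaled, d = min(d_pca, length(genes), length(idx)))$Z
    nn <- find_knn(P, P, k_b, exclude_self = TRUE)
    Zb <- Z_hat_q[, idx, drop = FALSE]
    for (j in seq_along(idx)) {
      nb <- nn$idx[j, ]
      d_pre <- nn$dist[j, ]
      d_post <- sqrt(colSums((Zb[, nb, drop = FALSE] - Zb[, j])^2))
      out[idx[j]] <- stats::cor(d_pre, d_post, method = "spearman")
    }
  }
  out
}

#' Local inverse Simpson index (LISI)
#'
#' The effective number of categories in each cell's local neighborhood.
#' Neighbor weights use a Gaussian kernel on squared distances over the
#' 3 x perplexity nearest neighbors, with the bandwidth tuned per cell by
#' bisection so the weight entropy matches log(perplexity) (to 1e-5); the
#' score is the inverse Simpson index of the category-summed weights.
#' 1 means a pure neighborhood; the maximum is the number of categories.
#'
#' @param embedding d x n embedding.
#' @param categories Length-n labels (e.g. dataset of origin).
#' @param perplexity Effective neighbor count (default 30).
#' @return Per-cell score vector in `[1, n_categories]`.
#' @export
lisi <- function(embedding, categories, perplexity = 30) {
  n <- ncol(embedding)
  if (n < 2) stop("need at least 2 cells")
  categories <- factor(categories)
  n_neighbors <- min(3 * perplexity, n - 1)
  if (perplexity >= n_neighbors + 1) {
    stop("perplexity must be smaller than the neighborhood size")
  }
  nn <- find_knn(embedding, embedding, n_neighbors, exclude_self = TRUE)
  target <- log(perplexity)
  scores <- numeric(n)
  cat_idx <- as.integer(categories)
  for (i in seq_len(n)) {
    d2 <- nn$dist[i, ]^2
    d2 <- d2 - min(d2)
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in seq_len(100)) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      H <- log(sw) + beta * sum(d2 * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p <- w / sum(w)
    pc <- vapply(split(p, cat_idx[nn$idx[i, ]]), sum, numeric(1))
    scores[i] <- 1 / sum(pc^2)
  }
  stats::setNames(scores, colnames(embedding))
}

#' Per-type F1, accuracy and confusion matrix for label transfer
#'
#' Per-type precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic
#' mean. Unassigned predictions (rejection option) are excluded from the F1
#' and accuracy computation and reported separately. Types never predicted
#' get F1 = 0.
#'
#' @param truth Ground-truth labels.
#' @param predicted Predicted labels (same length).
#' @param assigned Optional logical; `FALSE` entries are excluded.
#' @return List with `f1`, `precision`, `recall` (named per type),
#'   `accuracy`, `median_f1`, `confusion` (truth x predicted table) and
#'   `unassigned_frac`.
#' @export
cell_type_f1 <- function(truth, predicted, assigned = NULL) {
  if (length(truth) == 0) stop("empty inputs")
  if (length(truth) != length(predicted)) stop("truth and predicted lengths differ")
  assigned <- assigned %||% rep(TRUE, length(truth))
  unassigned_frac <- mean(!assigned)
  truth_all <- as.character(truth)
  truth <- truth_all[assigned]
  predicted <- as.character(predicted)[assigned]
  types <- sort(unique(truth_all))
  lev <- sort(unique(c(types, predicted)))
  confusion <- table(truth = factor(truth, lev), predicted = factor(predicted, lev))
  f1 <- precision <- recall <- stats::setNames(numeric(length(types)), types)
  for (ty in types) {
    tp <- confusion[ty, ty]
    fp <- sum(confusion[, ty]) - tp
    fn <- sum(confusion[ty, ]) - tp
    precision[ty] <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall[ty] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[ty] <- if (precision[ty] + recall[ty] > 0) {
      2 * precision[ty] * recall[ty] / (precision[ty] + recall[ty])
    } else 0
  }
  list(f1 = f1, precision = precision, recall = recall,
       accuracy = mean(truth == predicted), median_f1 = stats::median(f1),
       confusion = confusion, unassigned_frac = unassigned_frac)
}
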