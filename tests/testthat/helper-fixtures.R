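# Shared fixtures and independent oracles. Everything here is deliberately
# written in the most direct (loop-based) style so it stays independent of
# the package's vectorized implementations.

named_matrix <- function(x, prefix_row = "g", prefix_col = "c") {
  dimnames(x) <- list(sprintf("%s%03d", prefix_row, seq_len(nrow(x))),
                      sprintf("%s%03d", prefix_col, seq_len(ncol(x))))
  x
}

# Gaussian blobs around given centroids (d x K), sd per coordinate
make_blobs <- function(centroids, n_per, sd = 1, seed = 1) {
  set.seed(seed)
  d <- nrow(centroids)
  K <- ncol(centroids)
  Z <- NULL
  labels <- integer(0)
  for (k in seq_len(K)) {
    Z <- cbind(Z, centroids[, k] + matrix(rnorm(d * n_per, sd = sd), d))
    labels <- c(labels, rep(k, n_per))
  }
  colnames(Z) <- sprintf("cell%04d", seq_len(ncol(Z)))
  list(Z = Z, labels = labels)
}

# Brute-force weighted ridge solve of the joint model on the explicit
# reference + query concatenation (reference design rows all zero).
eq_concat_oracle <- function(R_r, Z_hat_r, R_q, Z_q, X_q, lambda) {
  k <- nrow(R_r)
  cc <- nrow(X_q)
  d <- nrow(Z_q)
  N <- ncol(Z_hat_r) + ncol(Z_q)
  X_star <- rbind(rep(1, N), cbind(matrix(0, cc, ncol(Z_hat_r)), X_q))
  Z <- cbind(Z_hat_r, Z_q)
  lam <- diag(c(0, rep(lambda, cc)), 1 + cc)
  B <- array(0, dim = c(k, 1 + cc, d))
  for (kk in seq_len(k)) {
    W <- diag(c(R_r[kk, ], R_q[kk, ]), N)
    A <- X_star %*% W %*% t(X_star) + lam
    B[kk, , ] <- solve(A, X_star %*% W %*% t(Z))
  }
  B
}

# Penalized weighted normal equations, naive version
ridge_wls_oracle <- function(X_star, w, Z, lambda_vec) {
  A <- X_star %*% diag(w, length(w)) %*% t(X_star) + diag(lambda_vec, nrow(X_star))
  solve(A, X_star %*% diag(w, length(w)) %*% t(Z))
}

# Independent re-implementation of the VST ranking (plain loops, no clipping
# shortcuts) used to check select_variable_genes_vst on dense fixtures.
vst_rank_oracle <- function(x) {
  n <- ncol(x)
  mu <- apply(x, 1, mean)
  v <- apply(x, 1, var)
  ok <- which(v > 0 & mu > 0)
  fit <- suppressWarnings(stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.3, degree = 2))
  esd <- sqrt(10^fitted(fit))
  sv <- rep(0, nrow(x))
  for (j in seq_along(ok)) {
    g <- ok[j]
    z <- pmin((x[g, ] - mu[g]) / esd[j], sqrt(n))
    sv[g] <- sum(z^2) / (n - 1)
  }
  rownames(x)[order(-sv)]
}

# Trivial rank AUC of scores for the positive class
rank_auc <- function(score, positive) {
  r <- rank(score)
  np <- sum(positive)
  nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# Small reference built from the generator, reused across map/transfer tests
build_test_reference <- function(n_ref_per_batch = 600, n_query = 200, seed = 42,
                                 d = 10, k = 5, held_out = integer(0),
                                 n_genes = 300, n_signals = 0) {
  spec <- simulation_spec(
    cells_per_batch = c(refA = n_ref_per_batch, refB = n_ref_per_batch, query = n_query),
    query_batches = "query", n_genes = n_genes, held_out_clusters = held_out,
    n_signals = n_signals, seed = seed)
  sim <- simulate_counts(spec)
  is_q <- sim$meta$is_query
  # non-convergence within the default iteration cap returns the last
  # iterate with a warning; the fixtures below assert on outcomes, so the
  # warning itself is not under test here
  ref <- suppressWarnings(
    build_reference(expression_matrix(sim$counts$values[, !is_q, drop = FALSE], "counts"),
                    meta = sim$meta[!is_q, ], batch_cols = "batch",
                    d = d, k = k, n_vargenes = n_genes, seed = 1,
                    labels = sim$meta$cluster[!is_q]))
  list(spec = spec, sim = sim, ref = ref, is_q = is_q,
       query_counts = expression_matrix(sim$counts$values[, is_q, drop = FALSE], "counts"),
       query_meta = sim$meta[is_q, ])
}
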