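#' Default number of soft clusters for a reference of n cells
#'
#' Uses `min(100, n/30)`, floored at 1.
#'
#' @param n Number of reference cells.
#' @return Integer cluster count.
#' @export
default_num_clusters <- function(n) {
  if (n < 1) stop("n must be >= 1")
  max(1L, min(100L, as.integer(floor(n / 30))))
}

# Multi-restart kmeans++ initialization: each candidate seeding is refined by
# a few plain E/M rounds and scored by the clustering objective; the best
# candidate is returned. Protects against local optima that merge clusters.
kmeanspp_init_best <- function(Zcos, k, s, seed = 0, n_init = 5, refine = 5) {
  best <- NULL
  best_obj <- Inf
  for (j in seq_len(n_init)) {
    Ycos <- kmeanspp_init(Zcos, k, seed + (j - 1) * 1000L)
    for (it in seq_len(refine)) {
      R <- soft_assign(Ycos, Zcos, s)
      Ycos <- l2_normalize_cols(Zcos %*% t(R))
    }
    obj <- sum(2 * R * (1 - crossprod(Ycos, Zcos))) + s * sum(R * log(R))
    if (obj < best_obj) {
      best_obj <- obj
      best <- Ycos
    }
  }
  best
}

# kmeans++-style initialization on L2-normalized columns; deterministic given
# the seed, ties broken by lowest index (sample() over equal weights).
kmeanspp_init <- function(Zcos, k, seed = 0) {
  n <- ncol(Zcos)
  set.seed(seed)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- 2 * (1 - as.numeric(crossprod(Zcos[, centers[1]], Zcos)))
    for (j in 2:k) {
      w <- pmax(d2, 0)
      centers[j] <- if (sum(w) == 0) which.min(seq_len(n) %in% centers) else
        sample.int(n, 1, prob = w)
      d2 <- pmin(d2, 2 * (1 - as.numeric(crossprod(Zcos[, centers[j]], Zcos))))
    }
  }
  Zcos[, centers, drop = FALSE]
}

# E-step of cosine soft k-means: column-stochastic memberships with
# max-subtraction for numerical stability.
soft_assign <- function(Ycos, Zcos, s) {
  logits <- (2 / s) * (crossprod(Ycos, Zcos) - 1) # k x n
  logits <- sweep(logits, 2, apply(logits, 2, max), "-")
  R <- exp(logits)
  sweep(R, 2, colSums(R), "/")
}

#' Soft k-means clustering with cosine distance and entropy regularization
#'
#' Minimizes `sum_ik 2 R[k,i] (1 - y_k' z_i) + s R log R` over unit-norm
#' columns, alternating exact E-steps (softmax memberships) and exact M-steps
#' (centroids proportional to the membership-weighted sum of the
#' L2-normalized cells), so the objective is non-increasing. Initialization
#' is kmeans++ on the normalized columns with a fixed seed.
#'
#' @param Z d x n embedding (columns are cells).
#' @param k Number of clusters (`k <= n`).
#' @param s Entropy weight, default 0.1.
#' @param max_iter,tol Stop when `max |R - R_prev| < tol` or after `max_iter`.
#' @param seed Initialization seed.
#' @return List with `R` (k x n memberships), `Y` (d x k centroids in the raw
#'   embedding scale, `Z R'`), `objective` (per-iteration trace) and
#'   `converged`.
#' @export
soft_kmeans_cosine <- function(Z, k, s = 0.1, max_iter = 50, tol = 1e-5, seed = 0) {
  n <- ncol(Z)
  if (k > n) stop("k = ", k, " exceeds the number of cells (", n, ")")
  Zcos <- l2_normalize_cols(Z)
  Ycos <- kmeanspp_init_best(Zcos, k, s, seed)
  R_prev <- NULL
  objective <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    R <- soft_assign(Ycos, Zcos, s)
    objective <- c(objective,
                   sum(2 * R * (1 - crossprod(Ycos, Zcos))) + s * sum(R * log(R)))
    Ycos <- l2_normalize_cols(Zcos %*% t(R))
    if (!is.null(R_prev) && max(abs(R - R_prev)) < tol) {
      converged <- TRUE
      break
    }
    R_prev <- R
  }
  rownames(R) <- paste0("cluster", seq_len(k))
  Y <- Z %*% t(R)
  list(R = R, Y = Y, objective = objective, converged = converged)
}

#' Solve one cluster's ridge-penalized linear mixture model
#'
#' Weighted ridge regression of the embedding on the design:
#' `B_k = (X* diag(R_k) X*' + diag(lambda))^{-1} X* diag(R_k) Z'`.
#' The first design row is the all-ones intercept and is never penalized
#' (`lambda[1] = 0`); unidentified batch coefficients (zero total weight) are
#' pulled to exactly 0 by the ridge.
#'
#' @param X_star (1+b) x N design, row 1 all ones.
#' @param R_k Per-cell nonnegative weights (length N).
#' @param Z d x N embedding.
#' @param lambda Ridge penalties: scalar applied to all non-intercept rows,
#'   or a vector of length `nrow(X_star)` with `lambda[1] == 0`.
#' @return (1+b) x d coefficient matrix (row 1 = intercept).
#' @export
solve_mixture_betas <- function(X_star, R_k, Z, lambda = 1) {
  X_star <- as.matrix(X_star)
  p <- nrow(X_star)
  if (any(X_star[1, ] != 1)) stop("first design row must be the all-ones intercept")
  if (any(R_k < 0)) stop("weights must be nonnegative")
  if (length(lambda) == 1) lambda <- c(0, rep(lambda, p - 1))
  if (length(lambda) != p) stop("lambda must be scalar or length nrow(X_star)")
  if (lambda[1] != 0) stop("the intercept must not be penalized (lambda[1] == 0)")
  Xw <- sweep(X_star, 2, R_k, "*")
  A <- Xw %*% t(X_star) + diag(lambda, p)
  rhs <- Xw %*% t(Z)
  B <- tryCatch(solve(A, rhs), error = function(e) {
    stop("singular mixture system (cluster has zero total weight)")
  })
  rownames(B) <- rownames(X_star)
  B
}

# Diversity-weighted soft assignment: base cosine memberships multiplied, per
# covariate, by (expected / observed batch mass in cluster)^theta. The
# observed masses depend on the assignment itself, so the update is iterated
# to a damped fixed point; a single full-batch update can oscillate when
# clusters merge or a batch is small.
diversity_assign <- function(Ycos, Zcos, s, X, blocks, theta, R_prev) {
  base <- soft_assign(Ycos, Zcos, s)
  if (theta == 0 || nrow(X) == 0) return(base)
  R <- R_prev
  for (it in seq_len(10)) {
    Nk <- rowSums(R)
    R_new <- base
    for (bl in blocks) {
      Xb <- X[bl, , drop = FALSE]
      freq <- rowSums(Xb) / ncol(Xb)
      O <- R %*% t(Xb)                      # k x levels observed mass
      E <- outer(Nk, freq)                  # expected under independence
      ratio <- (pmax(E, 1e-12) / pmax(O, 1e-12))^theta
      R_new <- R_new * exp(log(ratio) %*% Xb)  # factor for each cell's level
    }
    R_new <- sweep(R_new, 2, colSums(R_new), "/")
    if (max(abs(R_new - R)) < 1e-4) return(R_new)
    R <- 0.5 * R + 0.5 * R_new
  }
  R
}

#' Integrate a multi-batch reference embedding
#'
#' Alternates diversity-weighted soft k-means clustering with per-cluster
#' linear mixture-model correction: each cluster fits an intercept (the
#' centroid) plus one coefficient per batch level by ridge regression
#' ([solve_mixture_betas()]), and each cell's batch terms, weighted by its
#' cluster memberships, are subtracted from its coordinates. Iterations stop
#' when the largest per-cell displacement falls below `tol` times the
#' embedding scale. The diversity penalty is implemented in its simplest
#' multiplicative form (expected over observed batch frequency per cluster,
#' raised to `theta`); `tau` cluster-size discounting is exposed but inert.
#'
#' With fewer than two batch levels no integration is performed: clusters are
#' defined by [soft_kmeans_cosine()] and the embedding is returned unchanged.
#' Externally integrated embeddings can be passed through via `external`,
#' in which case only the Eq-3 centroids are recomputed.
#'
#' @param Z_r d x n reference embedding.
#' @param batch Per-cell batch labels: a factor/vector, a data frame of
#'   covariate columns, or a prebuilt one-hot design matrix (b x n).
#' @param k Number of clusters; default `default_num_clusters(n)`.
#' @param s Entropy weight (default 0.1).
#' @param theta Diversity strength (default 2).
#' @param tau Cluster-size discounting; accepted for interface compatibility
#'   but not operational (a warning is emitted when nonzero).
#' @param lambda Ridge penalty for batch coefficients (default 1).
#' @param max_iter,tol Outer-loop control (defaults 20 and 1e-4 of scale).
#' @param seed Clustering initialization seed.
#' @param external Optional list with `Z_hat_r` and `R_r` from an external
#'   integrator; returned as-is with centroids recomputed.
#' @return List of class `IntegrationResult`: `Z_r`, `Z_hat_r`, `R_r`, `Y`
#'   (= `Z_hat_r R_r'`), `B_r` (k x (1+b) x d array or NULL), `converged`.
#' @export
harmonize_reference <- function(Z_r, batch = NULL, k = NULL, s = 0.1, theta = 2,
                                tau = 0, lambda = 1, max_iter = 20, tol = 1e-4,
                                seed = 0, external = NULL) {
  n <- ncol(Z_r)
  k <- k %||% default_num_clusters(n)
  if (!is.null(external)) {
    R_r <- external$R_r
    Z_hat <- external$Z_hat_r
    res <- list(Z_r = Z_r, Z_hat_r = Z_hat, R_r = R_r,
                Y = Z_hat %*% t(R_r), B_r = NULL, converged = TRUE)
    class(res) <- "IntegrationResult"
    return(res)
  }
  if (tau != 0) warning("tau cluster-size discounting is not operational; ignored")
  X <- if (is.matrix(batch) || inherits(batch, "Matrix")) {
    structure(as.matrix(batch), blocks = attr(batch, "blocks") %||% list(all = seq_len(nrow(batch))))
  } else {
    build_design(batch)
  }
  b <- nrow(X)
  if (b > 0 && any(rowSums(X) == 0)) stop("every batch level must be nonempty")
  if (b < 2) {
    sk <- soft_kmeans_cosine(Z_r, k, s = s, seed = seed)
    res <- list(Z_r = Z_r, Z_hat_r = Z_r, R_r = sk$R, Y = Z_r %*% t(sk$R),
                B_r = NULL, converged = sk$converged)
    class(res) <- "IntegrationResult"
    return(res)
  }
  blocks <- attr(X, "blocks")
  X_star <- rbind(intercept = 1, X)
  lambda_vec <- c(0, rep(lambda, b))
  scale <- max(abs(Z_r))
  Z_hat <- Z_r
  Zcos <- l2_normalize_cols(Z_hat)
  Ycos <- kmeanspp_init_best(Zcos, k, s, seed)
  R <- soft_assign(Ycos, Zcos, s)
  converged <- FALSE
  B_r <- NULL
  for (it in seq_len(max_iter)) {
    # clustering rounds on the current corrected embedding
    Zcos <- l2_normalize_cols(Z_hat)
    for (cl_it in seq_len(10)) {
      R_new <- diversity_assign(Ycos, Zcos, s, X, blocks, theta, R)
      Ycos <- l2_normalize_cols(Zcos %*% t(R_new))
      done <- max(abs(R_new - R)) < tol * 0.1
      R <- R_new
      if (done) break
    }
    # correction: fit per-cluster mixture model, subtract batch terms
    B_r <- array(0, dim = c(k, 1 + b, nrow(Z_r)),
                 dimnames = list(paste0("cluster", seq_len(k)),
                                 c("intercept", rownames(X)), rownames(Z_r)))
    delta <- matrix(0, nrow(Z_r), n)
    for (kk in seq_len(k)) {
      if (sum(R[kk, ]) < 1e-8) next  # collapsed cluster: nothing to correct
      Bk <- solve_mixture_betas(X_star, R[kk, ], Z_hat, lambda_vec)
      B_r[kk, , ] <- Bk
      term <- t(Bk[-1, , drop = FALSE]) %*% X   # d x n batch term per cell
      delta <- delta + sweep(term, 2, R[kk, ], "*")
    }
    Z_new <- Z_hat - delta
    disp <- max(abs(Z_new - Z_hat))
    Z_hat <- Z_new
    if (disp < tol * scale) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("harmonization did not converge in ", max_iter, " iterations")
  rownames(R) <- paste0("cluster", seq_len(k))
  res <- list(Z_r = Z_r, Z_hat_r = Z_hat, R_r = R, Y = Z_hat %*% t(R),
              B_r = B_r, converged = converged)
  class(res) <- "IntegrationResult"
  res
}
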