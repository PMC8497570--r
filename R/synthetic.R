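#' Specification for the synthetic mixture generator
#'
#' Describes a Gaussian-mixture latent structure with per-batch offsets and a
#' simple linear-Poisson count model on top, so every stage of the pipeline
#' is testable against known ground truth. Defaults describe a balanced
#' five-state mixture with unit within-cluster spread, centroids separated by
#' 8 within-cluster SDs (pairwise), batch offsets of norm 3 SD units, and a
#' mean library size of 2000 counts over 500 genes.
#'
#' @param n_clusters Number of latent cell states (default 5).
#' @param d_latent Latent dimension (default 10; must be >= n_clusters so
#'   centroid directions can be made orthogonal).
#' @param n_genes Genes in the count model (default 500).
#' @param cells_per_batch Named integer vector, cells per batch.
#' @param query_batches Names of batches that are query rather than
#'   reference (default none).
#' @param cluster_proportions Mixture weights (default balanced; must sum
#'   to 1).
#' @param centroid_separation Pairwise centroid distance in units of the
#'   within-cluster SD (default 8).
#' @param batch_offset_scale Norm of each per-batch per-cluster offset
#'   vector, in SD units (default 2, i.e. a quarter of the default state
#'   separation: large enough that uncorrected embeddings cluster by batch,
#'   small enough that batch shift does not exceed the biological separation
#'   — the regime reference mapping assumes). Set 0 for batch-free data, or
#'   supply `batch_offsets` explicitly (list of d x n_clusters matrices per
#'   batch).
#' @param batch_offset_shared_frac Fraction of the squared offset norm that
#'   is shared across clusters within a batch (default 0.7): technical batch
#'   effects displace all cell states in a mostly common direction, with a
#'   smaller state-specific modulation.
#' @param batch_offsets Optional explicit offsets overriding the scale.
#' @param library_size_mean Expected counts per cell (default 2000).
#' @param noise_sd Within-cluster latent SD (default 1; the separation is
#'   expressed in these units).
#' @param dropout_rate Probability of zeroing each count (default 0).
#' @param held_out_clusters Cluster indices (1-based) excluded from
#'   *reference* batches but present in query batches, for novel-state
#'   experiments (default none).
#' @param loading_scale Scale of the gene loading matrix in the count model
#'   (default 1). At this scale the softplus rate function stays in its
#'   near-linear regime, so the latent geometry (and the specified centroid
#'   separation) carries through the PCA pipeline essentially undistorted;
#'   larger values saturate many genes and warp between-state angles.
#' @param n_signals Number of continuous annotation signals (linear maps of
#'   the batch-free latent position; default 0).
#' @param signal_noise_sd SD of the noise added to the signals (default 0.1).
#' @param seed Mandatory integer seed.
#' @return Validated list of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_clusters = 5, d_latent = 10, n_genes = 500,
                            cells_per_batch = c(batchA = 1500, batchB = 1500),
                            query_batches = character(0),
                            cluster_proportions = NULL,
                            centroid_separation = 8, batch_offset_scale = 2,
                            batch_offset_shared_frac = 0.7,
                            batch_offsets = NULL, library_size_mean = 2000,
                            noise_sd = 1, dropout_rate = 0,
                            held_out_clusters = integer(0), loading_scale = 1,
                            n_signals = 0, signal_noise_sd = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cluster_proportions <- cluster_proportions %||% rep(1 / n_clusters, n_clusters)
  if (abs(sum(cluster_proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (centroid_separation <= 0) stop("separation must be positive")
  if (d_latent < n_clusters) stop("d_latent must be >= n_clusters")
  if (is.null(names(cells_per_batch))) {
    names(cells_per_batch) <- paste0("batch", seq_along(cells_per_batch))
  }
  if (!all(query_batches %in% names(cells_per_batch))) {
    stop("query_batches must name entries of cells_per_batch")
  }
  if (length(held_out_clusters) > 0 &&
      (any(held_out_clusters < 1) || any(held_out_clusters > n_clusters))) {
    stop("held_out_clusters must index clusters in [1, n_clusters]")
  }
  spec <- list(n_clusters = n_clusters, d_latent = d_latent, n_genes = n_genes,
               cells_per_batch = cells_per_batch, query_batches = query_batches,
               cluster_proportions = cluster_proportions,
               centroid_separation = centroid_separation,
               batch_offset_scale = batch_offset_scale,
               batch_offset_shared_frac = batch_offset_shared_frac,
               batch_offsets = batch_offsets,
               library_size_mean = library_size_mean, noise_sd = noise_sd,
               dropout_rate = dropout_rate, held_out_clusters = held_out_clusters,
               loading_scale = loading_scale, n_signals = n_signals,
               signal_noise_sd = signal_noise_sd, seed = as.integer(seed))
  class(spec) <- "SimulationSpec"
  spec
}

#' Draw the latent Gaussian-mixture embedding
#'
#' Centroids sit along random orthogonal directions scaled so every pairwise
#' centroid distance equals `centroid_separation` (in within-cluster SD
#' units). Cells get isotropic Gaussian within-cluster noise plus their
#' batch's per-cluster offset. Reference batches never contain held-out
#' clusters; query batches draw from all clusters. Deterministic per seed.
#'
#' @param spec `SimulationSpec`.
#' @return List with `Z_true` (batch-free d x N latent), `Z_obs` (with batch
#'   offsets), `meta` (data frame: cell_id, batch, cluster, is_query,
#'   held_out), `centroids` (d x n_clusters) and `batch_offsets`.
#' @export
simulate_latent <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  d <- spec$d_latent
  K <- spec$n_clusters
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))[, seq_len(K), drop = FALSE]
  centroids <- Q * spec$centroid_separation * spec$noise_sd / sqrt(2)
  batches <- names(spec$cells_per_batch)
  offsets <- spec$batch_offsets
  if (is.null(offsets)) {
    sf <- spec$batch_offset_shared_frac
    offsets <- lapply(batches, function(b) {
      u <- stats::rnorm(d)
      u <- u / sqrt(sum(u^2))                      # batch-wide direction
      O <- matrix(stats::rnorm(d * K), d)
      O <- sweep(O, 2, sqrt(colSums(O^2)), "/")    # per-state modulation
      off <- sqrt(sf) * u + sqrt(1 - sf) * O
      sweep(off, 2, sqrt(colSums(off^2)), "/") * spec$batch_offset_scale * spec$noise_sd
    })
    names(offsets) <- batches
  }
  cl_list <- list(); batch_list <- list()
  for (b in batches) {
    nb <- spec$cells_per_batch[[b]]
    props <- spec$cluster_proportions
    if (!(b %in% spec$query_batches) && length(spec$held_out_clusters) > 0) {
      props[spec$held_out_clusters] <- 0
      props <- props / sum(props)
    }
    cl_list[[b]] <- sample.int(K, nb, replace = TRUE, prob = props)
    batch_list[[b]] <- rep(b, nb)
  }
  cl <- unlist(cl_list, use.names = FALSE)
  batch <- unlist(batch_list, use.names = FALSE)
  N <- length(cl)
  noise <- matrix(stats::rnorm(d * N, sd = spec$noise_sd), d)
  Z_true <- centroids[, cl, drop = FALSE] + noise
  off <- vapply(seq_len(N), function(i) offsets[[batch[i]]][, cl[i]], numeric(d))
  Z_obs <- Z_true + off
  ids <- sprintf("cell%05d", seq_len(N))
  dimnames(Z_true) <- dimnames(Z_obs) <- list(paste0("lat", seq_len(d)), ids)
  meta <- data.frame(cell_id = ids, batch = batch,
                     cluster = paste0("state", cl),
                     is_query = batch %in% spec$query_batches,
                     held_out = cl %in% spec$held_out_clusters,
                     stringsAsFactors = FALSE)
  list(Z_true = Z_true, Z_obs = Z_obs, meta = meta, centroids = centroids,
       batch_offsets = offsets)
}

#' Generate a synthetic count matrix with recoverable latent structure
#'
#' Gene expression rates are `softplus(L z + a)` for a fixed random loading
#' matrix `L` and gene intercepts `a`, rescaled per cell to the target
#' library size, then Poisson-sampled with optional dropout. Because the
#' rates are a monotone near-linear function of the latent position, the
#' cluster and batch structure is linearly recoverable by the PCA pipeline.
#'
#' @param spec `SimulationSpec`.
#' @return List with `counts` (`ExpressionMatrix`, sparse), `meta`, `latent`
#'   (the [simulate_latent()] result) and, when `n_signals > 0`, `signals`
#'   (N x n_signals: noisy linear functions of the batch-free latent) and
#'   `signals_true` (noise-free).
#' @export
simulate_counts <- function(spec) {
  lat <- simulate_latent(spec)
  # continue the seeded stream from simulate_latent
  d <- spec$d_latent
  g <- spec$n_genes
  L <- matrix(stats::rnorm(g * d, sd = spec$loading_scale / sqrt(d)), g)
  a <- stats::rnorm(g, mean = 0.5, sd = 1)
  rate <- softplus(L %*% lat$Z_obs + a)
  totals <- colSums(rate)
  rate <- sweep(rate, 2, spec$library_size_mean / totals, "*")
  N <- ncol(rate)
  counts <- matrix(stats::rpois(g * N, lambda = as.numeric(rate)), g)
  if (spec$dropout_rate > 0) {
    keep <- matrix(stats::runif(g * N) >= spec$dropout_rate, g)
    counts <- counts * keep
  }
  dimnames(counts) <- list(sprintf("gene%04d", seq_len(g)), colnames(lat$Z_obs))
  out <- list(counts = expression_matrix(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                     "CsparseMatrix"), "counts"),
              meta = lat$meta, latent = lat)
  if (spec$n_signals > 0) {
    W <- matrix(stats::rnorm(spec$n_signals * d, sd = 1 / sqrt(d)), spec$n_signals)
    truth <- t(W %*% lat$Z_true)
    noisy <- truth + matrix(stats::rnorm(length(truth), sd = spec$signal_noise_sd),
                            nrow(truth))
    colnames(truth) <- colnames(noisy) <- paste0("signal", seq_len(spec$n_signals))
    rownames(truth) <- rownames(noisy) <- lat$meta$cell_id
    out$signals <- noisy
    out$signals_true <- truth
  }
  out
}
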