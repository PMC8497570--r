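#' Cluster centroids from an integrated embedding
#'
#' `Y = Z_hat_r R_r'`: column k is the membership-weighted sum of cell
#' coordinates. L2-normalize the columns (see [l2_normalize_cols()]) to get
#' the centroid directions used for cosine assignment of query cells.
#'
#' @param Z_hat_r d x n harmonized embedding.
#' @param R_r k x n soft memberships (columns sum to 1).
#' @return d x k centroid matrix.
#' @export
compute_centroids <- function(Z_hat_r, R_r) {
  if (ncol(Z_hat_r) != ncol(R_r)) stop("embedding and memberships disagree on cell count")
  if (any(rowSums(R_r) == 0)) {
    stop("cluster(s) with zero total membership: ",
         paste(which(rowSums(R_r) == 0), collapse = ", "))
  }
  Z_hat_r %*% t(R_r)
}

#' Reference compression terms
#'
#' The two summaries of the reference side of the mixture model that query
#' mapping needs: per-cluster sizes `N_r[k] = sum_i R_r[k,i]` and
#' `C = R_r Z_hat_r'`. Together with the centroids they let the query-side
#' ridge systems be assembled without touching any reference cell.
#'
#' @param R_r k x n soft memberships (columns sum to 1).
#' @param Z_hat_r d x n harmonized embedding.
#' @return List with `N_r` (length k) and `C` (k x d).
#' @export
compute_compression_terms <- function(R_r, Z_hat_r) {
  if (ncol(Z_hat_r) != ncol(R_r)) stop("embedding and memberships disagree on cell count")
  list(N_r = rowSums(R_r), C = R_r %*% t(Z_hat_r))
}

#' Per-cluster weighted means and covariances in pre-harmonized space
#'
#' For each soft cluster, the membership-weighted mean and covariance of the
#' reference cells in the *pre-harmonized* embedding (the space query cells
#' are projected into), normalized by the cluster's total weight (population
#' normalization). These feed the Mahalanobis mapping-confidence metrics.
#' Clusters whose effective size falls below the embedding dimension are
#' kept but flagged unstable.
#'
#' @param Z_r d x n pre-harmonized embedding.
#' @param R_r k x n soft memberships.
#' @return List of class `ClusterStats`: `mean` (k x d), `cov` (list of d x d
#'   symmetric matrices), `n_eff` (per-cluster weight), `unstable` (logical),
#'   `space = "pre_harmonized"`.
#' @export
compute_cluster_stats <- function(Z_r, R_r) {
  k <- nrow(R_r)
  d <- nrow(Z_r)
  N <- rowSums(R_r)
  if (any(N == 0)) stop("cluster(s) with zero total weight")
  means <- matrix(0, k, d, dimnames = list(rownames(R_r), rownames(Z_r)))
  covs <- vector("list", k)
  for (kk in seq_len(k)) {
    w <- R_r[kk, ]
    mu <- as.numeric(Z_r %*% w) / N[kk]
    centered <- Z_r - mu
    cv <- (sweep(centered, 2, w, "*") %*% t(centered)) / N[kk]
    cv <- (cv + t(cv)) / 2
    means[kk, ] <- mu
    covs[[kk]] <- cv
  }
  res <- list(mean = means, cov = covs, n_eff = N, unstable = N < d,
              space = "pre_harmonized")
  class(res) <- "ClusterStats"
  res
}

#' Build a compressed, mappable reference from counts
#'
#' Runs the full reference pipeline — normalization, per-batch variable-gene
#' selection, scaling, truncated SVD, batch integration — then compresses the
#' result into the minimal elements needed for query mapping: gene means and
#' standard deviations (`mu`, `sigma`), gene loadings (`loadings`),
#' L2-normalized centroids (`Y_cos`), and the compression terms (`N_r`, `C`).
#' None of these scales with the number of reference cells. The per-cell
#' harmonized embedding (for k-NN annotation transfer) and per-cluster
#' statistics (for mapping-confidence metrics) are stored as optional extras.
#'
#' @param counts `ExpressionMatrix` with layer counts (normalized here) or
#'   lognorm (used as-is).
#' @param meta Data frame of per-cell covariates (rows follow cells).
#' @param batch_cols Names of covariate columns to integrate over; `NULL`
#'   for a single-batch reference (soft k-means only).
#' @param d Embedding dimension (default 20).
#' @param k Number of clusters; default `min(100, n/30)`.
#' @param n_vargenes Variable genes per batch (default 2000).
#' @param s,theta,lambda,max_iter,tol,seed Integration parameters, see
#'   [harmonize_reference()].
#' @param log_base Normalization dialect, `"e"` or `"2"`.
#' @param save_cells Keep the harmonized per-cell embedding as an extra.
#' @param save_stats Keep per-cluster means/covariances as an extra.
#' @param labels Optional per-cell annotation vector stored for transfer.
#' @param prune_empty Drop clusters that end up with no reference mass
#'   (default TRUE); their centroid directions are numerical noise. Set
#'   FALSE to keep the requested `k` exactly (e.g. to compare containers of
#'   fixed shape across reference sizes).
#' @param external Optional externally integrated `list(Z_hat_r, R_r)`.
#' @return Object of class `MinimalReference`.
#' @export
build_reference <- function(counts, meta = NULL, batch_cols = NULL, d = 20,
                            k = NULL, n_vargenes = 2000, s = 0.1, theta = 2,
                            lambda = 1, max_iter = 20, tol = 1e-4, seed = 0,
                            log_base = "e", save_cells = TRUE, save_stats = TRUE,
                            labels = NULL, prune_empty = TRUE, external = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop(name, ": ", conditionMessage(e), call. = FALSE))
  }
  em <- as_expression_matrix(counts, "counts")
  lognorm <- if (em$layer == "counts") {
    stage("normalize", normalize_log_cp10k(em, log_base = log_base))
  } else {
    stage("normalize", as_expression_matrix(em, expect = "lognorm"))
  }
  n <- ncol(lognorm$values)
  k <- k %||% default_num_clusters(n)
  batch_fac <- if (!is.null(batch_cols)) {
    interaction(meta[, batch_cols, drop = FALSE], drop = TRUE)
  } else NULL
  genes <- stage("vargenes",
                 select_variable_genes_vst(lognorm, batch = batch_fac, n_top = n_vargenes))
  sc <- stage("scale", scale_genes(lognorm, genes = genes))
  emb <- stage("svd", run_svd_embedding(sc$scaled, d = d, seed = seed))
  X_r <- if (!is.null(batch_cols)) build_design(meta, batch_cols) else NULL
  integ <- stage("integrate",
                 harmonize_reference(emb$Z, batch = X_r, k = k, s = s, theta = theta,
                                     lambda = lambda, max_iter = max_iter, tol = tol,
                                     seed = seed, external = external))
  # drop clusters that hold no reference mass: their centroid direction is
  # numerical noise and would still attract query cells under cosine assignment
  keep_k <- if (prune_empty) rowSums(integ$R_r) > 1e-6 else rep(TRUE, nrow(integ$R_r))
  if (!all(keep_k)) {
    integ$R_r <- sweep(integ$R_r[keep_k, , drop = FALSE], 2,
                       colSums(integ$R_r[keep_k, , drop = FALSE]), "/")
    k <- sum(keep_k)
  }
  Y <- stage("centroids", compute_centroids(integ$Z_hat_r, integ$R_r))
  comp <- stage("compress", compute_compression_terms(integ$R_r, integ$Z_hat_r))
  extras <- list(cell_ids = colnames(lognorm$values))
  if (save_cells) extras$Z_hat_r <- integ$Z_hat_r
  if (save_stats) extras$cluster_stats <- stage("cluster_stats",
                                                compute_cluster_stats(integ$Z_r, integ$R_r))
  if (!is.null(labels)) extras$labels <- as.character(labels)
  ref <- list(
    mu = sc$model$mu,
    sigma = sc$model$sigma,
    loadings = emb$model$loadings,
    Y_cos = l2_normalize_cols(Y),
    N_r = comp$N_r,
    C = comp$C,
    genes = genes,
    d = d,
    k = k,
    dialect = list(normalization = "log_cp10k", log_base = log_base),
    version = REFERENCE_FORMAT_VERSION,
    extras = extras
  )
  class(ref) <- "MinimalReference"
  ref
}

REFERENCE_FORMAT_VERSION <- "1.0"

#' @export
print.MinimalReference <- function(x, ...) {
  cat(sprintf("<MinimalReference> %d genes, d = %d, k = %d (format %s)\n",
              length(x$genes), x$d, x$k, x$version))
  cat("  extras:", paste(names(x$extras), collapse = ", "), "\n")
  invisible(x)
}

required_elements <- c("mu", "sigma", "loadings", "Y_cos", "N_r", "C")

#' Serialize a reference to a single HDF5 container
#'
#' Writes the six required elements as named datasets under `/elements`, a
#' JSON metadata block (format version, dimensions, gene list, normalization
#' dialect) under `/meta`, and — unless `include_extras = FALSE` — the
#' optional extras under `/extras`. A reference saved without extras is still
#' fully mappable; only neighbor-based transfer and the confidence metrics
#' need them.
#'
#' @param ref `MinimalReference`.
#' @param path Output file path (overwritten).
#' @param include_extras Write the optional per-cell / per-cluster extras.
#' @return `path`, invisibly.
#' @export
serialize_reference <- function(ref, path, include_extras = TRUE) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "elements")
  for (el in required_elements) {
    # stored uncompressed: container size is then a function of (g, d, k) only
    rhdf5::h5write(unname(as.matrix(ref[[el]])) * 1.0, path,
                   paste0("elements/", el), level = 0)
  }
  meta <- jsonlite::toJSON(list(version = ref$version, d = ref$d, k = ref$k,
                                genes = ref$genes, dialect = ref$dialect),
                           auto_unbox = TRUE, digits = NA)
  rhdf5::h5write(as.character(meta), path, "meta", level = 0)
  if (include_extras && length(ref$extras) > 0) {
    rhdf5::h5createGroup(path, "extras")
    ex <- ref$extras
    if (!is.null(ex$Z_hat_r)) rhdf5::h5write(unname(ex$Z_hat_r), path, "extras/Z_hat_r")
    if (!is.null(ex$cell_ids)) rhdf5::h5write(ex$cell_ids, path, "extras/cell_ids")
    if (!is.null(ex$labels)) rhdf5::h5write(ex$labels, path, "extras/labels")
    if (!is.null(ex$cluster_stats)) {
      cs <- ex$cluster_stats
      rhdf5::h5createGroup(path, "extras/cluster_stats")
      rhdf5::h5write(unname(cs$mean), path, "extras/cluster_stats/mean")
      rhdf5::h5write(simplify2array(cs$cov), path, "extras/cluster_stats/cov")
      rhdf5::h5write(unname(cs$n_eff), path, "extras/cluster_stats/n_eff")
      rhdf5::h5write(as.integer(cs$unstable), path, "extras/cluster_stats/unstable")
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load a serialized reference
#'
#' @param path HDF5 container written by [serialize_reference()].
#' @return `MinimalReference`; mapping on the loaded object reproduces
#'   mapping on the in-memory original bit for bit.
#' @export
deserialize_reference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)
  present <- contents$name[contents$group == "/elements"]
  missing <- setdiff(required_elements, present)
  if (length(missing) > 0) {
    stop("missing required element ", paste(missing, collapse = ", "))
  }
  meta <- jsonlite::fromJSON(rhdf5::h5read(path, "meta"))
  if (!identical(as.character(meta$version), REFERENCE_FORMAT_VERSION)) {
    stop("reference format version mismatch: file has ", meta$version,
         ", this package reads ", REFERENCE_FORMAT_VERSION)
  }
  el <- lapply(stats::setNames(required_elements, required_elements),
               function(nm) rhdf5::h5read(path, paste0("elements/", nm)))
  genes <- as.character(meta$genes)
  ref <- list(
    mu = stats::setNames(as.numeric(el$mu), genes),
    sigma = stats::setNames(as.numeric(el$sigma), genes),
    loadings = structure(el$loadings,
                         dimnames = list(genes, paste0("dim", seq_len(meta$d)))),
    Y_cos = el$Y_cos,
    N_r = as.numeric(el$N_r),
    C = el$C,
    genes = genes,
    d = as.integer(meta$d),
    k = as.integer(meta$k),
    dialect = as.list(meta$dialect),
    version = as.character(meta$version),
    extras = list()
  )
  groups <- unique(contents$group)
  if (any(groups == "/extras")) {
    exnames <- contents$name[contents$group == "/extras"]
    if ("Z_hat_r" %in% exnames) {
      ref$extras$Z_hat_r <- rhdf5::h5read(path, "extras/Z_hat_r")
      rownames(ref$extras$Z_hat_r) <- paste0("dim", seq_len(meta$d))
    }
    if ("cell_ids" %in% exnames) {
      ref$extras$cell_ids <- as.character(rhdf5::h5read(path, "extras/cell_ids"))
      if (!is.null(ref$extras$Z_hat_r)) colnames(ref$extras$Z_hat_r) <- ref$extras$cell_ids
    }
    if ("labels" %in% exnames) ref$extras$labels <- as.character(rhdf5::h5read(path, "extras/labels"))
    if ("cluster_stats" %in% contents$name[contents$group == "/extras"]) {
      covarr <- rhdf5::h5read(path, "extras/cluster_stats/cov")
      cs <- list(
        mean = rhdf5::h5read(path, "extras/cluster_stats/mean"),
        cov = lapply(seq_len(dim(covarr)[3]), function(i) covarr[, , i]),
        n_eff = as.numeric(rhdf5::h5read(path, "extras/cluster_stats/n_eff")),
        unstable = as.logical(rhdf5::h5read(path, "extras/cluster_stats/unstable")),
        space = "pre_harmonized"
      )
      class(cs) <- "ClusterStats"
      ref$extras$cluster_stats <- cs
    }
  }
  rhdf5::h5closeAll()
  class(ref) <- "MinimalReference"
  ref
}
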