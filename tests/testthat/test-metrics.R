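test_that("Mahalanobis distance reduces to the familiar special cases", {
  x <- c(3, 4)
  expect_equal(mahalanobis_dist(x, c(0, 0), diag(2), ridge = 0), 5)
  expect_equal(mahalanobis_dist(x, x, diag(2)), 0)
  # 1-D: distance in standard deviations
  expect_equal(mahalanobis_dist(2, 0, matrix(4, 1, 1), ridge = 0), 1)
  # vectorized over columns, against stats::mahalanobis
  set.seed(101)
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  X <- matrix(rnorm(3 * 15), 3)
  mu <- rnorm(3)
  expect_equal(unname(mahalanobis_dist(X, mu, S, ridge = 0)),
               sqrt(stats::mahalanobis(t(X), mu, S)), tolerance = 1e-10)
  expect_error(mahalanobis_dist(x, c(0, 0), matrix(c(1, 2, 2, -5), 2), ridge = 0),
               "positive semidefinite")
})

test_that("per-cell mapping scores weight cluster distances by membership", {
  set.seed(102)
  d <- 3
  stats_obj <- structure(list(
    mean = rbind(c(0, 0, 0), c(10, 0, 0)),
    cov = list(diag(d), 4 * diag(d)),
    n_eff = c(50, 50), unstable = c(FALSE, FALSE), space = "pre_harmonized"),
    class = "ClusterStats")
  # a cell at a cluster's mean with hard membership scores 0
  mapped <- list(Z_q = matrix(c(0, 0, 0), 3, 1), R_q = matrix(c(1, 0), 2, 1))
  expect_equal(unname(per_cell_mapping_metric(mapped, stats_obj)), 0)
  # mixed membership: weighted average of the two distances
  z <- c(1, 1, 1)
  mapped2 <- list(Z_q = matrix(z, 3, 1), R_q = matrix(c(0.3, 0.7), 2, 1))
  d1 <- mahalanobis_dist(z, stats_obj$mean[1, ], stats_obj$cov[[1]])
  d2 <- mahalanobis_dist(z, stats_obj$mean[2, ], stats_obj$cov[[2]])
  expect_equal(unname(per_cell_mapping_metric(mapped2, stats_obj)),
               0.3 * d1 + 0.7 * d2, tolerance = 1e-10)
  expect_error(per_cell_mapping_metric(mapped, NULL), "ClusterStats absent")
  # far-away cells score far above in-distribution cells
  Zin <- matrix(rnorm(3 * 200), 3)
  Zout <- Zin + 10
  min_in <- list(Z_q = Zin, R_q = rbind(rep(1, 200), rep(0, 200)))
  min_out <- list(Z_q = Zout, R_q = rbind(rep(1, 200), rep(0, 200)))
  s_in <- per_cell_mapping_metric(min_in, stats_obj)
  s_out <- per_cell_mapping_metric(min_out, stats_obj)
  expect_gt(median(s_out), 5 * median(s_in))
})

test_that("per-cluster scores use the query covariance and the 2d size rule", {
  set.seed(103)
  d <- 3
  centroids <- rbind(c(0, 0, 0), c(20, 0, 0))
  # a query cluster centred on a reference centroid scores ~0
  Zq <- cbind(matrix(rnorm(d * 100, sd = 1), d),            # on centroid 1
              matrix(rnorm(d * 100, sd = 1) + 20 * c(1, 0, 0) * 0 + c(50, 0, 0), d))
  labels <- rep(c("near", "far"), each = 100)
  res <- per_cluster_mapping_metric(Zq, labels, centroids)
  expect_lt(res$per_cluster[["near"]], 0.5)
  expect_gt(res$per_cluster[["far"]], 5)
  # all cells of a cluster share the score
  expect_equal(unname(res$per_cell[1:100]), rep(res$per_cluster[["near"]], 100),
               ignore_attr = TRUE)
  # clusters smaller than 2d give NA, at exactly 2d they do not
  Zs <- matrix(rnorm(d * (2 * d - 1)), d)
  res_small <- per_cluster_mapping_metric(Zs, rep("tiny", 2 * d - 1), centroids)
  expect_true(is.na(res_small$per_cluster[["tiny"]]))
  Zs2 <- matrix(rnorm(d * (2 * d)), d)
  res_ok <- per_cluster_mapping_metric(Zs2, rep("ok", 2 * d), centroids)
  expect_false(is.na(res_ok$per_cluster[["ok"]]))
  # matches a direct computation
  idx <- labels == "near"
  mu <- rowMeans(Zq[, idx]); cv <- stats::cov(t(Zq[, idx]))
  expect_equal(unname(res$per_cluster[["near"]]),
               unname(mahalanobis_dist(centroids[1, ], mu, cv)), tolerance = 1e-8)
  expect_error(per_cluster_mapping_metric(Zq, labels[1:10], centroids), "length mismatch")
})

test_that("neighborhood distance correlation identities and the rank oracle", {
  set.seed(104)
  d <- 5
  Z <- matrix(rnorm(d * 120), d, dimnames = list(NULL, sprintf("c%03d", 1:120)))
  q_ids <- colnames(Z)[1:20]; r_ids <- colnames(Z)[21:120]
  expect_true(all(knn_corr(Z, Z, q_ids, r_ids, k = 30) == 1))
  expect_true(all(knn_corr(Z, Z * 2, q_ids, r_ids, k = 30) == 1))  # scale-free
  expect_error(knn_corr(Z, Z, q_ids, r_ids, k = 500), "exceeds")
  # hand case: a 3-cycle of ranks among 5 neighbors gives 1 - 6*6/(5*24) = 0.7
  gold <- matrix(0, 2, 6)
  gold[, 1] <- c(0, 0)
  gold[, 2:6] <- rbind(c(1, 2, 3, 4, 5), 0)        # distances 1..5
  colnames(gold) <- c("q", paste0("r", 1:5))
  alt <- gold
  # permute which reference is at which distance: ranks (2,3,1,4,5)
  alt[1, 2:6] <- c(2, 3, 1, 4, 5)
  kc <- knn_corr(gold, alt, "q", paste0("r", 1:5), k = 5)
  expect_equal(unname(kc), 0.7)
  expect_equal(unname(kc), 1 - 6 * sum(c(1, 1, 2, 0, 0)^2) / (5 * (25 - 1)))
})

test_that("within-query neighborhood preservation is 1 under isometry, ~0 under shuffling", {
  spec <- simulation_spec(cells_per_batch = c(qa = 300, qb = 300),
                          query_batches = c("qa", "qb"), n_clusters = 3,
                          n_genes = 150, seed = 105)
  sim <- simulate_counts(spec)
  lognorm <- normalize_log_cp10k(sim$counts)
  batch <- sim$meta$batch
  # mapping = the per-batch PCA itself, batch blocks rotated rigidly
  d_pca <- 6
  Zmap <- matrix(0, d_pca, ncol(lognorm$values))
  set.seed(105)
  for (b in unique(batch)) {
    idx <- batch == b
    sub <- expression_matrix(lognorm$values[, idx], "lognorm")
    genes <- select_variable_genes_vst(sub, n_top = 150)
    P <- run_svd_embedding(scale_genes(sub, genes = genes)$scaled, d = d_pca)$Z
    Q <- qr.Q(qr(matrix(rnorm(d_pca^2), d_pca)))
    Zmap[, idx] <- Q %*% P + 5
  }
  w <- wiq_knn_corr(lognorm, batch, Zmap, k = 50, d_pca = d_pca, n_vargenes = 150)
  expect_equal(unname(w), rep(1, length(w)), tolerance = 1e-10)
  # random coordinates: no preserved ordering, mean correlation near zero
  set.seed(106)
  Zrand <- matrix(rnorm(d_pca * ncol(lognorm$values)), d_pca)
  wr <- wiq_knn_corr(lognorm, batch, Zrand, k = 50, d_pca = d_pca, n_vargenes = 150)
  expect_lt(abs(mean(wr)), 0.05)
})

test_that("LISI hits its algebraic limits and matches a direct implementation", {
  set.seed(107)
  # one category: exactly 1 everywhere
  Z <- matrix(rnorm(2 * 100), 2)
  expect_equal(unname(lisi(Z, rep("a", 100), perplexity = 10)), rep(1, 100))
  # two categories perfectly interleaved on a line: effective number -> 2
  n <- 400
  line <- matrix(c(seq_len(n), rep(0, n)), 2, byrow = TRUE)
  cats <- rep(c("a", "b"), n / 2)
  li <- lisi(line, cats, perplexity = 30)
  expect_gt(median(li), 1.9)
  expect_true(all(li <= 2 + 1e-8))
  # 60-cell fixture vs an independent direct implementation
  Z60 <- matrix(rnorm(3 * 60), 3)
  cats60 <- sample(c("x", "y", "z"), 60, replace = TRUE)
  perplexity <- 10
  ours <- lisi(Z60, cats60, perplexity = perplexity)
  # direct: full distance matrix, per-cell beta by fine grid + bisection
  D2 <- as.matrix(dist(t(Z60)))^2
  direct <- numeric(60)
  for (i in 1:60) {
    ord <- order(D2[i, -i])
    nb <- (seq_len(60)[-i])[ord][seq_len(3 * perplexity)]
    d2 <- D2[i, nb] - min(D2[i, nb])
    f <- function(beta) {
      w <- exp(-beta * d2); sw <- sum(w)
      log(sw) + beta * sum(d2 * w) / sw - log(perplexity)
    }
    lo <- 1e-8; hi <- 1e4
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    w <- exp(-((lo + hi) / 2) * d2); p <- w / sum(w)
    pc <- tapply(p, cats60[nb], sum)
    direct[i] <- 1 / sum(pc^2)
  }
  expect_equal(unname(ours), direct, tolerance = 1e-4)
})

test_that("per-type F1 follows the precision/recall formulas", {
  truth <- c(rep("A", 10), rep("B", 10))
  pred <- truth
  perfect <- cell_type_f1(truth, pred)
  expect_true(all(perfect$f1 == 1))
  expect_equal(perfect$accuracy, 1)
  # TP=8, FP=2, FN=2 for type A
  pred2 <- c(rep("A", 8), "B", "B", rep("B", 8), "A", "A")
  sc <- cell_type_f1(truth, pred2)
  expect_equal(unname(sc$precision["A"]), 0.8)
  expect_equal(unname(sc$recall["A"]), 0.8)
  expect_equal(unname(sc$f1["A"]), 0.8)
  # a type never predicted gets F1 = 0
  sc3 <- cell_type_f1(c("A", "A", "B"), c("A", "A", "A"))
  expect_equal(unname(sc3$f1["B"]), 0)
  # unassigned predictions are excluded but reported
  sc4 <- cell_type_f1(truth, pred2, assigned = c(rep(TRUE, 15), rep(FALSE, 5)))
  expect_equal(sc4$unassigned_frac, 0.25)
  expect_error(cell_type_f1(character(0), character(0)), "empty")
})
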