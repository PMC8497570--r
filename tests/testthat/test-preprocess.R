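test_that("log CP10K normalization matches the closed form and preserves zeros", {
  counts <- named_matrix(matrix(c(1, 0, 3,
                                  0, 0, 0,
                                  2, 5, 1), 3, byrow = TRUE))
  ln <- normalize_log_cp10k(expression_matrix(counts, "counts"))
  # first cell: totals 3; entry (1,1) = log(1/3*1e4 + 1)
  expect_equal(ln$values[1, 1], log(1 / 3 * 1e4 + 1))
  # single-cell worked example: totals 4 -> log(2501), 0, log(7501)
  one <- named_matrix(matrix(c(1, 0, 3), 3, 1))
  ln1 <- normalize_log_cp10k(expression_matrix(one, "counts"))
  expect_equal(unname(ln1$values[, 1]), c(log(2501), 0, log(7501)))
  # all-zero gene row stays zero
  expect_true(all(ln$values[2, ] == 0))
  # base-2 dialect is the same values over log(2)
  ln2 <- normalize_log_cp10k(expression_matrix(one, "counts"), log_base = "2")
  expect_equal(ln2$values, ln1$values / log(2))
  expect_identical(ln2$log_base, "2")
})

test_that("normalization rejects zero-total cells by name and keeps sparsity", {
  counts <- Matrix::Matrix(c(1, 0, 0, 0, 2, 0), 3, 2, sparse = TRUE,
                           dimnames = list(paste0("g", 1:3), c("good", "empty")))
  counts[, 2] <- 0
  expect_error(normalize_log_cp10k(expression_matrix(counts, "counts")), "empty")
  counts[1, 2] <- 1
  ln <- normalize_log_cp10k(expression_matrix(counts, "counts"))
  expect_s4_class(ln$values, "sparseMatrix")
  expect_equal(as.matrix(ln$values == 0), as.matrix(counts == 0))
})

test_that("VST variable-gene selection ranks by standardized variance", {
  set.seed(11)
  n <- 200
  x <- matrix(abs(rnorm(50 * n, mean = 3, sd = 0.5)), 50, n)
  # one gene with ~10x inflated variance at the same mean
  x[7, ] <- abs(rnorm(n, mean = 3, sd = sqrt(10) * 0.5))
  x <- named_matrix(x)
  sel <- select_variable_genes_vst(expression_matrix(x, "lognorm"), n_top = 10)
  expect_identical(sel[1], "g007")
  # matches an independent re-implementation of the VST ranking
  expect_identical(sel, vst_rank_oracle(x)[1:10])
})

test_that("VST handles degenerate and exhaustive selections", {
  set.seed(2)
  x <- named_matrix(rbind(matrix(rnorm(5 * 40, mean = 3), 5, 40),
                          matrix(1, 2, 40)))  # two constant genes
  em <- expression_matrix(x, "lognorm")
  sel <- select_variable_genes_vst(em, n_top = 3)
  expect_false(any(c("g006", "g007") %in% sel))
  expect_warning(all_sel <- select_variable_genes_vst(em, n_top = 100), "all expressed")
  expect_setequal(all_sel, paste0("g", sprintf("%03d", 1:5)))
  expect_error(select_variable_genes_vst(em, batch = c("a", rep("b", 39)), n_top = 2),
               "fewer than 2")
})

test_that("gene scaling standardizes in reference mode and replays in query mode", {
  x <- named_matrix(matrix(c(1, 2, 3,
                             5, 5, 5), 2, byrow = TRUE))
  res <- scale_genes(expression_matrix(x, "lognorm"))
  # sample-SD convention: sd(1,2,3) = 1, so the scaled row is (-1, 0, 1)
  expect_equal(unname(res$scaled$values[1, ]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(mean(res$scaled$values[1, ]), 0)
  expect_equal(stats::sd(res$scaled$values[1, ]), 1)
  # zero-variance gene: flagged, scaled to zero, index retained
  expect_true(res$model$zero_variance[2])
  expect_true(all(res$scaled$values[2, ] == 0))
  # query mode is a pure replay: same data -> identical matrix
  q <- scale_genes(expression_matrix(x, "lognorm"), model = res$model)
  expect_equal(q$scaled$values, res$scaled$values)
  # model gene missing from the query -> zero row in the model's order
  x2 <- x[2, , drop = FALSE]
  q2 <- scale_genes(expression_matrix(x2, "lognorm"), model = res$model)
  expect_identical(rownames(q2$scaled$values), res$model$genes)
  expect_true(all(q2$scaled$values["g001", ] == 0))
  # duplicated model genes rejected
  bad <- res$model; bad$genes <- c("g001", "g001")
  expect_error(scale_genes(expression_matrix(x, "lognorm"), model = bad), "duplicated")
})

test_that("SVD embedding factorizes exactly and saves reusable loadings", {
  # rank-1: loadings x Z reconstructs the matrix
  u <- c(1, 2, 3); v <- c(2, 0.5, 1, 4)
  x <- named_matrix(outer(u, v))
  res <- run_svd_embedding(expression_matrix(x, "scaled"), d = 1)
  expect_lt(max(abs(res$model$loadings %*% res$Z - x)), 1e-8)
  expect_error(run_svd_embedding(expression_matrix(x, "scaled"), d = 2),
               "achievable rank")
  # random matrix: Z equals U' X entrywise; loadings orthonormal
  set.seed(3)
  x <- named_matrix(matrix(rnorm(30 * 100), 30, 100))
  res <- run_svd_embedding(expression_matrix(x, "scaled"), d = 6)
  expect_lt(max(abs(res$Z - t(res$model$loadings) %*% x)), 1e-8)
  expect_equal(crossprod(res$model$loadings), diag(6), tolerance = 1e-6,
               ignore_attr = TRUE)
  # agrees with the dense SVD oracle up to sign
  sv <- svd(x)
  expect_equal(abs(unname(res$Z)), abs(sv$d[1:6] * t(sv$v[, 1:6])), tolerance = 1e-6)
  # variance ordering on a two-blob fixture
  blobs <- make_blobs(cbind(c(10, 0), c(-10, 0)), 50, sd = 0.5, seed = 4)
  xb <- named_matrix(blobs$Z - rowMeans(blobs$Z))
  rb <- run_svd_embedding(expression_matrix(xb, "scaled"), d = 2)
  expect_gt(var(rb$Z[1, ]), var(rb$Z[2, ]))
})

test_that("TF-IDF uses reference-only IDF and matches a hand-computed table", {
  x <- named_matrix(matrix(c(1, 1, 1, 1, 1,
                             1, 0, 1, 0, 0,
                             0, 0, 0, 1, 1,
                             0, 0, 0, 0, 0), 4, byrow = TRUE), "peak", "cell")
  res <- tfidf_normalize(expression_matrix(x, "counts"))
  # hand-computed oracle with explicit loops
  n_ref <- 5
  expected <- matrix(0, 4, 5)
  idf <- c(5 / 5, 5 / 2, 5 / 2, NA)
  for (j in 1:5) {
    tot <- sum(x[, j])
    for (i in 1:3) expected[i, j] <- log(x[i, j] / tot * idf[i] * 1e4 + 1)
  }
  expect_equal(unname(res$tfidf$values), expected, tolerance = 1e-12)
  # peak open in all reference cells: IDF = 1
  expect_equal(res$model$idf[["peak001"]], 1)
  # absent peak flagged and zeroed
  expect_true(res$model$absent[["peak004"]])
  expect_true(all(res$tfidf$values[4, ] == 0))
  # reusing the model is deterministic
  q1 <- tfidf_normalize(expression_matrix(x, "counts"), model = res$model)
  q2 <- tfidf_normalize(expression_matrix(x, "counts"), model = res$model)
  expect_identical(q1$tfidf$values, q2$tfidf$values)
  expect_error(tfidf_normalize(expression_matrix(x * 2, "counts")), "binarized")
})

test_that("ortholog mapping splits counts stochastically and conserves totals", {
  om <- ortholog_map(data.frame(mouse = c("Ma", "Ma", "Mb"),
                                human = c("HA1", "HA2", "HB")))
  counts <- named_matrix(matrix(c(4, 8,
                                  3, 0), 2, byrow = TRUE), "m", "cell")
  rownames(counts) <- c("Ma", "Mb")
  out <- map_orthologs(expression_matrix(counts, "counts"), om)
  expect_equal(unname(as.matrix(out$values["HA1", ])), unname(as.matrix(out$values["HA2", ])))
  expect_equal(as.numeric(out$values["HA1", "cell001"]), 2)
  expect_equal(as.numeric(out$values["HB", "cell001"]), 3)
  # identity one-to-one map relabels only
  omi <- ortholog_map(data.frame(mouse = c("Ma", "Mb"), human = c("A", "B")))
  outi <- map_orthologs(expression_matrix(counts, "counts"), omi)
  expect_equal(unname(as.matrix(outi$values)), unname(counts))
  # conservation property on random sparse maps
  set.seed(8)
  for (rep in 1:5) {
    pairs <- data.frame(mouse = sample(paste0("m", 1:20), 40, replace = TRUE),
                        human = sample(paste0("h", 1:30), 40, replace = TRUE))
    omr <- ortholog_map(unique(pairs))
    cm <- matrix(rpois(20 * 6, 3), 20, 6,
                 dimnames = list(paste0("m", 1:20), paste0("c", 1:6)))
    outr <- suppressWarnings(map_orthologs(expression_matrix(cm, "counts"), omr))
    mapped_rows <- intersect(rownames(cm), omr$mouse_ids)
    expect_lt(max(abs(Matrix::colSums(outr$values) -
                        colSums(cm[mapped_rows, , drop = FALSE]))), 1e-9)
  }
  # invalid (non-stochastic) map rejected
  om_bad <- om; om_bad$matrix[1, 1] <- 0.9
  expect_error(map_orthologs(expression_matrix(counts, "counts"), om_bad), "invalid")
})
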