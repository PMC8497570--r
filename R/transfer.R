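#' Transfer discrete labels by k-nearest-neighbor majority vote
#'
#' Finds each query cell's k nearest reference cells by Euclidean distance in
#' the harmonized embedding and takes the majority label, ties broken
#' randomly (seeded). Confidence is the fraction of the k neighbors voting
#' for the winner; a cell is left unassigned when its confidence does not
#' exceed `min_confidence` (strictly — 0.6 with k = 5 requires at least 4
#' agreeing neighbors).
#'
#' @param Z_hat_r d x n reference harmonized embedding.
#' @param ref_labels Length-n label vector; cells with missing labels are
#'   excluded from voting with a warning.
#' @param Z_hat_q d x m query harmonized embedding.
#' @param k Neighbors (default 5); must not exceed the reference size.
#' @param min_confidence Assignment threshold in \[0, 1) (default 0: always
#'   assign).
#' @param seed Seed for random tie-breaking.
#' @param metric `"euclidean"` (default) or `"cosine"` (k-NN on L2-normalized
#'   coordinates).
#' @return Data frame with `cell_id`, `label`, `confidence`, `assigned`.
#' @export
knn_predict_labels <- function(Z_hat_r, ref_labels, Z_hat_q, k = 5,
                               min_confidence = 0, seed = 0,
                               metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (k < 1) stop("k must be >= 1")
  ref_labels <- as.character(ref_labels)
  if (length(ref_labels) != ncol(Z_hat_r)) {
    stop("labels must match the number of reference cells")
  }
  keep <- !is.na(ref_labels)
  if (!all(keep)) {
    warning(sum(!keep), " reference cell(s) without labels excluded from voting")
    Z_hat_r <- Z_hat_r[, keep, drop = FALSE]
    ref_labels <- ref_labels[keep]
  }
  if (k > ncol(Z_hat_r)) stop("k = ", k, " exceeds the ", ncol(Z_hat_r),
                              " labelled reference cells")
  if (metric == "cosine") {
    Z_hat_r <- l2_normalize_cols(Z_hat_r)
    Z_hat_q <- l2_normalize_cols(Z_hat_q)
  }
  nn <- find_knn(Z_hat_r, Z_hat_q, k)
  m <- ncol(Z_hat_q)
  set.seed(seed)
  label <- character(m)
  confidence <- numeric(m)
  for (i in seq_len(m)) {
    votes <- table(ref_labels[nn$idx[i, ]])
    winners <- names(votes)[votes == max(votes)]
    label[i] <- if (length(winners) == 1) winners else sample(winners, 1)
    confidence[i] <- max(votes) / k
  }
  data.frame(cell_id = colnames(Z_hat_q) %||% paste0("cell", seq_len(m)),
             label = label, confidence = confidence,
             assigned = confidence > min_confidence,
             stringsAsFactors = FALSE)
}

#' Transfer continuous annotations by k-nearest-neighbor averaging
#'
#' Each query cell receives the unweighted mean of its k nearest reference
#' cells' values (trajectory coordinates, surface-protein levels, ...).
#' Applied reference-to-reference this is the k-NN smoothing operator used
#' to build denoised ground truths. Non-finite reference values are excluded
#' per dimension, with the mean over the remaining neighbors.
#'
#' @param Z_hat_r d x n reference harmonized embedding.
#' @param ref_values n x p matrix (or vector) of values, rows aligned to
#'   reference cells.
#' @param Z_hat_q d x m query harmonized embedding.
#' @param k Neighbors.
#' @return m x p matrix of transferred values.
#' @export
knn_transfer_continuous <- function(Z_hat_r, ref_values, Z_hat_q, k) {
  ref_values <- as.matrix(ref_values)
  if (nrow(ref_values) != ncol(Z_hat_r)) {
    stop("ref_values rows must align with reference cells")
  }
  nn <- find_knn(Z_hat_r, Z_hat_q, k)
  m <- ncol(Z_hat_q)
  p <- ncol(ref_values)
  out <- matrix(NA_real_, m, p,
                dimnames = list(colnames(Z_hat_q), colnames(ref_values)))
  any_nonfinite <- !all(is.finite(ref_values))
  if (any_nonfinite) warning("non-finite reference values excluded from the k-NN mean")
  for (j in seq_len(p)) {
    vals <- matrix(ref_values[nn$idx, j], m, k)
    if (any_nonfinite) {
      vals[!is.finite(vals)] <- NA
      out[, j] <- rowMeans(vals, na.rm = TRUE)
    } else {
      out[, j] <- rowMeans(vals)
    }
  }
  out
}
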