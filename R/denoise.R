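#' Configuration for k-NN consensus label cleaning
#'
#' @param k neighbour count (default 50).
#' @param th consensus threshold in percent, in `(0, 100]` (default 40).
#' @param mode `"consensus_keep"` keeps a sample iff at least `th`% of its
#'   k nearest neighbours share its current label (labels never change);
#'   `"relabel_majority"` keeps a sample iff the neighbourhood's plurality
#'   class reaches `th`% of k, and replaces the label by that class.
#' @param metric distance metric; Euclidean only.
#' @param normalize L2-normalize embeddings before computing distances.
#' @return object of class `denoise_config`.
#' @export
denoise_config <- function(k = 50, th = 40,
                           mode = c("consensus_keep", "relabel_majority"),
                           metric = "euclidean", normalize = FALSE) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, th > 0, th <= 100, identical(metric, "euclidean"))
  structure(list(k = as.integer(k), th = th, mode = mode, metric = metric,
                 normalize = normalize),
            class = "denoise_config")
}

# Exact k-nearest-neighbour indices by squared Euclidean distance,
# self excluded, distance ties broken by lower original index.
knn_indices <- function(emb, k) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(emb)
  diag(d2) <- Inf
  t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}

#' Thresholded k-NN consensus label filter
#'
#' For each sample, its `k` nearest other samples by Euclidean distance are
#' found (self excluded, distance ties broken by lower index). The
#' consensus fraction is the share of neighbours whose current label equals
#' the sample's own; the sample is kept iff that fraction reaches
#' `th / 100`. In `relabel_majority` mode the neighbourhood plurality class
#' is used instead and assigned to kept samples.
#'
#' @param embeddings `n x d` numeric matrix, one embedding per row.
#' @param labels integer class ids, length n.
#' @param cfg a [denoise_config()]; requires `k < n`.
#' @return object of class `denoise_result`: list with `kept_mask`
#'   (logical n), `labels_out` (class ids of the kept samples),
#'   `consensus_fraction` (numeric n) and `kept_idx`.
#' @export
knn_consensus_filter <- function(embeddings, labels, cfg = denoise_config()) {
  n <- nrow(embeddings)
  stopifnot(n == length(labels))
  if (cfg$k >= n) stop("`k` must be smaller than the number of samples")
  labels <- as.integer(labels)
  emb <- if (cfg$normalize) embeddings / sqrt(rowSums(embeddings^2)) else
    embeddings
  nbr <- knn_indices(emb, cfg$k)
  nbr_labels <- matrix(labels[nbr], n, cfg$k)
  if (cfg$mode == "consensus_keep") {
    frac <- rowMeans(nbr_labels == labels)
    kept <- frac >= cfg$th / 100
    labels_out <- labels[kept]
  } else {
    classes <- sort(unique(labels))
    counts <- vapply(classes, function(cl) rowSums(nbr_labels == cl),
                     numeric(n))
    if (n == 1) counts <- matrix(counts, 1)
    best <- max.col(counts, ties.method = "first")
    frac <- counts[cbind(seq_len(n), best)] / cfg$k
    kept <- frac >= cfg$th / 100
    labels_out <- classes[best[kept]]
  }
  structure(list(kept_mask = kept, labels_out = labels_out,
                 consensus_fraction = frac, kept_idx = which(kept)),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat("<denoise_result> kept ", sum(x$kept_mask), "/", length(x$kept_mask),
      " samples (", round(100 * mean(x$kept_mask), 1), "%)\n", sep = "")
  invisible(x)
}

#' Consensus-threshold selection sweep
#'
#' For each combination of threshold and noise rate: inject symmetric
#' exclusive noise into the true labels, run the consensus filter, and
#' report the percentage of preserved samples and the percentage of kept
#' samples whose (current) label disagrees with the true label
#' (residual noise).
#'
#' @param embeddings `n x d` matrix.
#' @param true_labels clean integer class ids.
#' @param th_list thresholds in percent (default `c(40, 50, 60, 70)`).
#' @param noise_rates noise fractions (default `c(0, 0.2, 0.5)`).
#' @param k neighbour count.
#' @param noise_seed seed for the noise injection.
#' @return data.frame with columns `th`, `noise_rate`, `preserved_pct`,
#'   `residual_noise_pct`, `n_kept`.
#' @export
threshold_sweep <- function(embeddings, true_labels,
                            th_list = c(40, 50, 60, 70),
                            noise_rates = c(0, 0.2, 0.5),
                            k = 50, noise_seed = 1) {
  stopifnot(length(th_list) > 0, all(noise_rates >= 0 & noise_rates <= 1))
  n <- length(true_labels)
  rows <- list()
  for (rate in noise_rates) {
    noisy <- inject_label_noise(true_labels, rate,
                                seed = derive_seed(noise_seed, rate * 1000))
    for (th in th_list) {
      res <- knn_consensus_filter(embeddings, noisy,
                                  denoise_config(k = k, th = th))
      kept <- res$kept_mask
      residual <- if (any(kept)) {
        100 * mean(noisy[kept] != true_labels[kept])
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        th = th, noise_rate = rate,
        preserved_pct = 100 * mean(kept),
        residual_noise_pct = residual,
        n_kept = sum(kept))
    }
  }
  do.call(rbind, rows)
}
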