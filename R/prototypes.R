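#' Compute per-class prototype embeddings
#'
#' The prototype of class `c` is the arithmetic mean of the embeddings
#' currently labelled `c`. Prototypes are the compact, privacy-compliant
#' class representation shared across the federation: transmitting them
#' reveals `n_classes x embedding_dim` numbers and no per-sample data.
#'
#' @param embeddings `n x d` matrix of clean embeddings.
#' @param labels integer class ids, length n.
#' @return object of class `prototypes`: list with `classes` (sorted ids
#'   present in the input) and `vectors` (`n_classes x d` matrix, one row
#'   per class).
#' @export
compute_prototypes <- function(embeddings, labels) {
  if (length(labels) == 0 || nrow(embeddings) == 0) {
    stop("cannot compute prototypes from an empty set")
  }
  stopifnot(nrow(embeddings) == length(labels))
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  vectors <- matrix(0, length(classes), ncol(embeddings))
  for (i in seq_along(classes)) {
    vectors[i, ] <- colMeans(embeddings[labels == classes[i], , drop = FALSE])
  }
  rownames(vectors) <- as.character(classes)
  structure(list(classes = classes, vectors = vectors), class = "prototypes")
}

#' @export
print.prototypes <- function(x, ...) {
  cat("<prototypes> ", length(x$classes), " classes, dim ",
      ncol(x$vectors), "\n", sep = "")
  invisible(x)
}

#' Nearest-prototype assignment
#'
#' @param z embedding vector.
#' @param protos a [compute_prototypes()] result.
#' @return list with `class` (id of the closest prototype by Euclidean
#'   distance; ties broken by lowest class id) and `distance`.
#' @export
nearest_prototype <- function(z, protos) {
  if (length(protos$classes) == 0) stop("empty prototype list")
  d <- unname(sqrt(colSums((t(protos$vectors) - z)^2)))
  i <- which.min(d)    # first minimum = lowest class id (classes sorted)
  list(class = protos$classes[i], distance = d[i])
}

# Distances from each row of emb to each prototype: n x n_classes.
prototype_distances <- function(emb, protos) {
  p2 <- rowSums(protos$vectors^2)
  d2 <- outer(rowSums(emb^2), p2, "+") - 2 * emb %*% t(protos$vectors)
  sqrt(pmax(d2, 0))
}

#' Configuration of the augmented-view voting ensemble
#'
#' @param n_views ensemble size T (>= 1); view 1 is always the identity.
#' @param aug [augmentation_spec()] used for views 2..T.
#' @param seed integer seed.
#' @param normalize L2-normalize view embeddings before the nearest-
#'   prototype assignment (cosine-style matching; the prototypes must then
#'   be computed from L2-normalized embeddings too, see
#'   [l2_normalize_rows()]). Default `FALSE`: raw Euclidean matching.
#' @return object of class `view_ensemble_config`.
#' @export
view_ensemble_config <- function(n_views = 8, aug = augmentation_spec(),
                                 seed = 1, normalize = FALSE) {
  stopifnot(n_views >= 1)
  structure(list(n_views = as.integer(n_views), aug = aug, seed = seed,
                 normalize = normalize),
            class = "view_ensemble_config")
}

#' L2-normalize the rows of an embedding matrix
#'
#' Projecting embeddings onto the unit sphere makes nearest-prototype
#' matching equivalent to cosine similarity, which removes the global
#' intensity-scaling component of cross-site acquisition shift.
#'
#' @param emb `n x d` matrix with non-zero rows.
#' @return matrix of the same shape with unit-norm rows.
#' @export
l2_normalize_rows <- function(emb) {
  nrm <- sqrt(rowSums(emb^2))
  if (any(nrm == 0)) stop("cannot normalize a zero embedding")
  emb / nrm
}

# Majority vote over per-view class assignments. Ties are broken by the
# smallest summed view-to-prototype distance among the tied classes, then
# by lowest class id.
vote_from_assignments <- function(assigned, dists, classes) {
  counts <- vapply(classes, function(cl) sum(assigned == cl), integer(1))
  top <- which(counts == max(counts))
  if (length(top) > 1) {
    sums <- vapply(top, function(i) sum(dists[, i]), numeric(1))
    top <- top[sums == min(sums)]
  }
  winner <- top[1]                      # classes sorted: lowest id first
  list(label = classes[winner], counts = counts, winner_idx = winner)
}

#' Label one image by augmented-view majority voting
#'
#' Builds the view ensemble `A(x)` (identity first), embeds each view,
#' assigns each its nearest prototype's class, and returns the majority
#' class.
#'
#' @param img intensity matrix.
#' @param encoder an `encoder` object.
#' @param protos a [compute_prototypes()] result.
#' @param cfg a [view_ensemble_config()].
#' @return a vote record: list with `label`, `votes` (named count per
#'   class, summing to T), `per_view` (class per view) and
#'   `mean_distance` (mean distance of the views to the winning class's
#'   prototype).
#' @export
label_by_view_ensemble <- function(img, encoder, protos,
                                   cfg = view_ensemble_config()) {
  views <- withr::with_seed(derive_seed(cfg$seed, "views"),
                            augmented_views(img, cfg$aug, cfg$n_views))
  emb <- embed_images(encoder, views)
  if (isTRUE(cfg$normalize)) emb <- l2_normalize_rows(emb)
  dists <- prototype_distances(emb, protos)
  assigned <- protos$classes[max.col(-dists, ties.method = "first")]
  v <- vote_from_assignments(assigned, dists, protos$classes)
  list(label = v$label,
       votes = stats::setNames(v$counts, protos$classes),
       per_view = assigned,
       mean_distance = mean(dists[, v$winner_idx]))
}

#' Pseudo-label a client dataset by view-ensemble voting
#'
#' Every sample receives a label (voting is unthresholded, so nothing is
#' discarded); any labels the client may carry are never read.
#'
#' @param images list of intensity matrices or a `plane_dataset` (only its
#'   images are used).
#' @param encoder an `encoder`.
#' @param protos a [compute_prototypes()] result.
#' @param cfg a [view_ensemble_config()].
#' @return list with `labels` (integer pseudo-labels) and `records`
#'   (list of vote records).
#' @export
label_client <- function(images, encoder, protos,
                         cfg = view_ensemble_config()) {
  if (inherits(images, "plane_dataset")) images <- images$images
  n <- length(images)
  if (n == 0) return(list(labels = integer(0), records = list()))
  all_views <- withr::with_seed(derive_seed(cfg$seed, "views"),
    lapply(images, augmented_views, aug = cfg$aug, n_views = cfg$n_views))
  emb <- embed_images(encoder, do.call(c, all_views))
  if (isTRUE(cfg$normalize)) emb <- l2_normalize_rows(emb)
  dists <- prototype_distances(emb, protos)
  assigned <- protos$classes[max.col(-dists, ties.method = "first")]
  records <- lapply(seq_len(n), function(i) {
    rows <- (i - 1L) * cfg$n_views + seq_len(cfg$n_views)
    v <- vote_from_assignments(assigned[rows], dists[rows, , drop = FALSE],
                               protos$classes)
    list(label = v$label,
         votes = stats::setNames(v$counts, protos$classes),
         per_view = assigned[rows],
         mean_distance = mean(dists[rows, v$winner_idx]))
  })
  list(labels = vapply(records, `[[`, integer(1), "label"), records = records)
}

#' The exact payload shared with a non-representative client
#'
#' Asserts the privacy contract of prototype sharing: the payload consists
#' of the encoder parameters and one `n_classes x embedding_dim` prototype
#' matrix — no per-sample data.
#'
#' @param encoder an `encoder`.
#' @param protos a [compute_prototypes()] result.
#' @return list with `encoder_params`, `prototype_matrix`, `classes` and
#'   `n_values_shared` (count of prototype numbers transmitted).
#' @export
shared_payload <- function(encoder, protos) {
  list(encoder_params = encoder$params,
       prototype_matrix = protos$vectors,
       classes = protos$classes,
       n_values_shared = length(protos$vectors))
}
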