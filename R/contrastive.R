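#' Cosine similarity between two embeddings
#'
#' @param a,b non-zero numeric vectors of equal length.
#' @return `dot(a, b) / (||a|| ||b||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

check_pairing <- function(pair, n) {
  if (length(pair) != n || any(pair < 1 | pair > n) ||
      any(pair[pair] != seq_len(n)) || any(pair == seq_len(n))) {
    stop("`pair` must be a perfect matching of the rows")
  }
}

default_pairing <- function(n2) {
  n <- n2 / 2
  c(n + seq_len(n), seq_len(n))
}

# Normalized rows + temperature-scaled cosine-similarity matrix.
nt_xent_sim <- function(proj, tau) {
  norms <- sqrt(rowSums(proj^2))
  if (any(norms == 0)) stop("zero-norm projection vector")
  u <- proj / norms
  list(u = u, norms = norms, s = tcrossprod(u) / tau)
}

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' For a batch of `2N` projection vectors with a perfect matching of
#' positive pairs, computes the mean over all `2N` anchors of
#' `-log[ exp(sim(z_i, z_pair(i)) / tau) / sum_{r != i} exp(sim(z_i, z_r) / tau) ]`
#' where `sim` is cosine similarity. Evaluated with log-sum-exp
#' stabilization; always >= 0, and exactly 0 for a single pair (no
#' negatives).
#'
#' @param proj `2N x d` matrix of projection vectors (rows).
#' @param tau temperature (> 0).
#' @param pair integer vector with `pair[i]` the row index of anchor `i`'s
#'   positive; defaults to the two-block layout `(N+1..2N, 1..N)`.
#' @return scalar loss.
#' @export
nt_xent_loss <- function(proj, tau = 0.5, pair = NULL) {
  n2 <- nrow(proj)
  if (is.null(n2) || n2 < 2 || n2 %% 2 != 0) {
    stop("`proj` must have an even number (>= 2) of rows")
  }
  if (tau <= 0) stop("`tau` must be positive")
  pair <- pair %||% default_pairing(n2)
  check_pairing(pair, n2)
  s <- nt_xent_sim(proj, tau)$s
  li <- vapply(seq_len(n2), function(i) {
    -s[i, pair[i]] + logsumexp(s[i, -i])
  }, numeric(1))
  mean(li)
}

# Loss plus analytic gradient wrt the (unnormalized) projections; used by
# pretrain_encoder and verified against finite differences in the tests.
nt_xent_grad <- function(proj, tau = 0.5, pair = NULL) {
  n2 <- nrow(proj)
  pair <- pair %||% default_pairing(n2)
  check_pairing(pair, n2)
  sm <- nt_xent_sim(proj, tau)
  s <- sm$s
  diag(s) <- -Inf                       # self term excluded
  p <- t(apply(s, 1, function(r) exp(r - logsumexp(r[is.finite(r)]))))
  p[!is.finite(p)] <- 0
  g <- p / n2
  g[cbind(seq_len(n2), pair)] <- g[cbind(seq_len(n2), pair)] - 1 / n2
  du <- (g + t(g)) %*% sm$u / tau
  dproj <- (du - rowSums(du * sm$u) * sm$u) / sm$norms
  loss <- mean(-s[cbind(seq_len(n2), pair)] +
                 apply(s, 1, function(r) logsumexp(r[is.finite(r)])))
  list(loss = loss, grad = dproj)
}

#' Configuration for contrastive pretraining
#'
#' @param tau NT-Xent temperature (default 0.5).
#' @param batch_pairs number N of images per batch (each contributes two
#'   views, so batches hold 2N projections).
#' @param embedding_dim backbone embedding length.
#' @param projection_dim projection-head output size.
#' @param epochs pretraining epochs.
#' @param lr pretraining learning rate.
#' @param optimizer `"adam"` (default; the adaptive choice keeps the
#'   unnormalized desk-scale backbone stable, playing the role LARS plays
#'   in large-scale contrastive training) or `"sgd"` with momentum.
#' @param momentum SGD momentum (ignored by adam).
#' @param augmentation [augmentation_spec()] for view generation.
#' @param channels conv widths of the tinycnn backbone.
#' @param seed integer seed.
#' @return object of class `contrastive_config`.
#' @export
contrastive_config <- function(tau = 0.5, batch_pairs = 32,
                               embedding_dim = 64, projection_dim = 32,
                               epochs = 10, lr = 1e-3,
                               optimizer = c("adam", "sgd"), momentum = 0.9,
                               augmentation = augmentation_spec(),
                               channels = c(8, 16), seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(tau > 0, batch_pairs >= 2, embedding_dim >= 2, epochs >= 0)
  structure(list(tau = tau, batch_pairs = batch_pairs,
                 embedding_dim = embedding_dim,
                 projection_dim = projection_dim, epochs = epochs,
                 lr = lr, optimizer = optimizer, momentum = momentum,
                 augmentation = augmentation,
                 channels = channels, seed = seed),
            class = "contrastive_config")
}

new_encoder <- function(arch, embedding_dim, params) {
  structure(list(arch = arch, embedding_dim = embedding_dim, params = params),
            class = "encoder")
}

#' @export
print.encoder <- function(x, ...) {
  cat("<encoder> arch:", x$arch, " embedding_dim:", x$embedding_dim, "\n")
  cat("  parameters:", paste(names(x$params), collapse = ", "), "\n")
  invisible(x)
}

#' Contrastive (SimCLR-style) pretraining of the encoder
#'
#' Self-supervised: labels are never read. Each step draws a batch of N
#' images, builds two augmented views of each, embeds all 2N views through
#' the backbone and projection head, and takes an SGD-with-momentum step on
#' the NT-Xent loss.
#'
#' @param images list of intensity matrices, or a `plane_dataset` (only its
#'   images are used).
#' @param cfg a [contrastive_config()].
#' @param arch backbone architecture id; only `"tinycnn"` is provided in
#'   this desk-scale implementation.
#' @return an object of class `encoder` with attributes `loss_history`
#'   (mean NT-Xent per epoch) and the training config.
#' @export
pretrain_encoder <- function(images, cfg = contrastive_config(),
                             arch = "tinycnn") {
  if (inherits(images, "plane_dataset")) images <- images$images
  if (!identical(arch, "tinycnn")) {
    stop("architecture '", arch, "' is not provided at desk scale; ",
         "use 'tinycnn'")
  }
  n <- length(images)
  if (n < cfg$batch_pairs) stop("dataset smaller than one batch")
  params <- init_tinycnn(embedding_dim = cfg$embedding_dim,
                         channels = cfg$channels,
                         projection_dim = cfg$projection_dim,
                         seed = derive_seed(cfg$seed, "init"))
  opt_state <- list()
  history <- numeric(0)
  train_names <- grep("^(conv|proj)", names(params), value = TRUE)
  if (cfg$epochs > 0) {
    withr::with_seed(derive_seed(cfg$seed, "pretrain"), {
      for (epoch in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        losses <- numeric(0)
        for (start in seq(1, n - cfg$batch_pairs + 1, by = cfg$batch_pairs)) {
          idx <- ord[start:(start + cfg$batch_pairs - 1)]
          views <- lapply(images[idx], make_simclr_views, aug = cfg$augmentation)
          batch <- c(lapply(views, `[[`, "xi"), lapply(views, `[[`, "xj"))
          fwd <- backbone_forward(params, batch, want_cache = TRUE)
          pre <- params$proj1.w %*% fwd$emb + params$proj1.b
          h1 <- relu(pre)
          p <- params$proj2.w %*% h1 + params$proj2.b
          gl <- nt_xent_grad(t(p), tau = cfg$tau)
          losses <- c(losses, gl$loss)
          dp <- t(gl$grad)
          dh1 <- crossprod(params$proj2.w, dp) * (pre > 0)
          grads <- list(proj1.w = tcrossprod(dh1, fwd$emb),
                        proj1.b = rowSums(dh1),
                        proj2.w = tcrossprod(dp, h1),
                        proj2.b = rowSums(dp))
          demb <- crossprod(params$proj1.w, dh1)
          grads <- c(grads, backbone_backward(params, fwd$cache, demb))
          step <- if (cfg$optimizer == "adam") {
            adam_step(params, grads[train_names], opt_state, cfg$lr)
          } else {
            sgd_step(params, grads[train_names], opt_state, cfg$lr,
                     cfg$momentum)
          }
          params <- step$params
          opt_state <- step$state %||% step$velocity
        }
        history <- c(history, mean(losses))
      }
    })
  }
  enc <- new_encoder("tinycnn", cfg$embedding_dim, params)
  attr(enc, "loss_history") <- history
  attr(enc, "config") <- cfg
  enc
}

#' Extract backbone embeddings for a set of images
#'
#' Embeddings are the global-average-pooled backbone activations (not the
#' projection-head outputs), evaluated deterministically in inference mode.
#'
#' @param encoder an `encoder` object.
#' @param images list of intensity matrices or a `plane_dataset`.
#' @param batch_size forward-pass batch size (does not affect the result).
#' @return `n x embedding_dim` matrix, rows in input order.
#' @export
embed_images <- function(encoder, images, batch_size = 256) {
  if (inherits(images, "plane_dataset")) images <- images$images
  n <- length(images)
  if (n == 0) return(matrix(numeric(0), 0, encoder$embedding_dim))
  out <- matrix(0, n, encoder$embedding_dim)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out[idx, ] <- t(backbone_forward(encoder$params, images[idx])$emb)
  }
  out
}
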