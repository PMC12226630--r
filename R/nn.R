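# Small convolutional network used as the desk-scale encoder backbone:
# three 3x3 stride-2 same-padded conv + ReLU blocks followed by global
# average pooling. The pooled activation is the embedding z = f(x); a
# linear classifier head and a single-hidden-layer (ReLU) projection head
# attach to it. Parameters live in a flat named list of numeric arrays
# (the unit of FedAvg aggregation); convolution kernels run in C++.

he_init <- function(nrow, ncol) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)
}

#' Initialize tinycnn model parameters
#'
#' @param embedding_dim length of the embedding (channels of the last conv
#'   block, pooled).
#' @param channels channel widths of the first two conv blocks.
#' @param n_classes classifier-head output size.
#' @param projection_dim projection-head output size (contrastive loss only).
#' @param in_channels input image channels (grayscale images use 1).
#' @param seed integer seed for the random initialization.
#' @return named list of parameter arrays.
#' @export
init_tinycnn <- function(embedding_dim = 64, channels = c(8, 16),
                         n_classes = 4, projection_dim = 32,
                         in_channels = 1, seed = 1) {
  stopifnot(embedding_dim >= 2, length(channels) == 2)
  withr::with_seed(seed, {
    p <- list(
      conv1.w = he_init(channels[1], 9 * in_channels),
      conv1.b = numeric(channels[1]),
      conv2.w = he_init(channels[2], 9 * channels[1]),
      conv2.b = numeric(channels[2]),
      conv3.w = he_init(embedding_dim, 9 * channels[2]),
      conv3.b = numeric(embedding_dim),
      head.w = he_init(n_classes, embedding_dim),
      head.b = numeric(n_classes),
      proj1.w = he_init(projection_dim, embedding_dim),
      proj1.b = numeric(projection_dim),
      proj2.w = he_init(projection_dim, projection_dim),
      proj2.b = numeric(projection_dim)
    )
  })
  p
}

# Stack a list of HxW matrices into a (1, H, W, N) activation array.
stack_images <- function(images) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  array(unlist(images, use.names = FALSE), dim = c(1, h, w, length(images))) *
    1  # force double storage
}

gap_forward <- function(a) {
  d <- dim(a)                       # (C, Ho, Wo, N)
  hw <- d[2] * d[3]
  arr <- array(a, c(d[1], hw, d[4]))
  emb <- colMeans(aperm(arr, c(2, 1, 3)))   # (C, N)
  if (is.null(dim(emb))) emb <- matrix(emb, d[1], d[4])
  emb
}

gap_backward <- function(demb, d) {
  hw <- d[2] * d[3]
  array(demb[, rep(seq_len(d[4]), each = hw), drop = FALSE] / hw, dim = d)
}

#' Backbone forward pass
#'
#' @param params tinycnn parameter list.
#' @param x activation array `(1, H, W, N)` or list of image matrices.
#' @param want_cache keep intermediate activations for backprop.
#' @return list with `emb` (embedding_dim x N matrix) and, if requested,
#'   `cache`.
#' @keywords internal
backbone_forward <- function(params, x, want_cache = FALSE) {
  if (is.list(x)) x <- stack_images(x)
  d0 <- dim(x)
  c1 <- .conv2d_forward(x, d0, params$conv1.w, params$conv1.b, 2L, 1L)
  a1 <- relu(c1$out)
  d1 <- dim(a1)
  c2 <- .conv2d_forward(a1, d1, params$conv2.w, params$conv2.b, 2L, 1L)
  a2 <- relu(c2$out)
  d2 <- dim(a2)
  c3 <- .conv2d_forward(a2, d2, params$conv3.w, params$conv3.b, 2L, 1L)
  a3 <- relu(c3$out)
  emb <- gap_forward(a3)
  cache <- if (want_cache) {
    list(d0 = d0, d1 = d1, d2 = d2, d3 = dim(a3),
         cols1 = c1$cols, cols2 = c2$cols, cols3 = c3$cols,
         a1 = a1, a2 = a2, a3 = a3)
  }
  list(emb = emb, cache = cache)
}

#' Backbone backward pass
#'
#' @param params tinycnn parameter list.
#' @param cache cache from [backbone_forward()].
#' @param demb gradient of the loss wrt the embedding matrix.
#' @return named list of gradients for the conv parameters.
#' @keywords internal
backbone_backward <- function(params, cache, demb) {
  da3 <- gap_backward(demb, cache$d3)
  da3 <- da3 * (cache$a3 > 0)
  g3 <- .conv2d_backward(da3, cache$d2, params$conv3.w, cache$cols3, 2L, 1L)
  da2 <- g3$dx * (cache$a2 > 0)
  g2 <- .conv2d_backward(da2, cache$d1, params$conv2.w, cache$cols2, 2L, 1L)
  da1 <- g2$dx * (cache$a1 > 0)
  g1 <- .conv2d_backward(da1, cache$d0, params$conv1.w, cache$cols1, 2L, 1L)
  list(conv1.w = g1$dw, conv1.b = as.numeric(g1$db),
       conv2.w = g2$dw, conv2.b = as.numeric(g2$db),
       conv3.w = g3$dw, conv3.b = as.numeric(g3$db))
}

# One Adam step over the named subset of parameters; state carries the
# first/second moment estimates and the step counter.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- (state$t %||% 0) + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * (state$m[[nm]] %||% 0) + (1 - beta1) * g
    state$v[[nm]] <- beta2 * (state$v[[nm]] %||% 0) + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# One SGD-with-momentum step over the named subset of parameters.
sgd_step <- function(params, grads, velocity, lr, momentum) {
  for (nm in names(grads)) {
    v <- momentum * (velocity[[nm]] %||% 0) - lr * grads[[nm]]
    velocity[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, velocity = velocity)
}

# Softmax cross-entropy with (possibly soft) targets; returns loss and
# gradient wrt logits.
softmax_xent <- function(logits, targets) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  loss <- -sum(targets * log(pmax(p, 1e-12))) / n
  list(loss = loss, dlogits = (p - targets) / n)
}
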