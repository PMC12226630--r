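#' @useDynLib fedproto, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbeta predict
#' @importFrom utils read.csv write.csv head
NULL

CLASS_NAMES <- c("abdomen", "brain", "femur", "thorax")

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a reproducible child seed from a base seed and a stream label
#'
#' All stochastic stages of the pipeline draw their seeds through this
#' function so that a single top-level seed determines every random choice
#' while distinct stages (pretraining, noise injection, each client's local
#' training in each round, ...) use decorrelated streams.
#'
#' @param seed base integer seed.
#' @param ... integers or strings identifying the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), vapply(list(...), function(p) {
    if (is.character(p)) {
      v <- utf8ToInt(p)
      sum(v * seq_along(v))
    } else as.numeric(p)
  }, numeric(1)))
  h <- 0
  for (p in parts) h <- (h * 48271 + abs(p) + 1) %% 2147483647
  as.integer(h)
}

one_hot <- function(labels, n_classes) {
  m <- matrix(0, n_classes, length(labels))
  m[cbind(labels + 1L, seq_along(labels))] <- 1
  m
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
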