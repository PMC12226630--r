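# Shared fixtures: all built in code, sized for speed.

# A small balanced image set (n per class, 64x64) with clean labels.
tiny_dataset <- function(n_per_class = 4, seed = 101, shift = client_shift()) {
  gen_client_dataset(n_per_class, shift, client = "t", seed = seed)
}

# A randomly initialized encoder (no training) for contract tests.
tiny_encoder <- function(embedding_dim = 16, seed = 7) {
  params <- init_tinycnn(embedding_dim = embedding_dim, channels = c(4, 8),
                         projection_dim = 8, seed = seed)
  structure(list(arch = "tinycnn", embedding_dim = embedding_dim,
                 params = params), class = "encoder")
}

# Random parameter list shaped like a small model, for fedavg tests.
random_params <- function(seed) {
  withr::with_seed(seed, list(
    a = matrix(rnorm(6), 2, 3),
    b = rnorm(4),
    c = array(rnorm(8), c(2, 2, 2))
  ))
}

# Brute-force NT-Xent: plain double loops over all similarity terms.
brute_nt_xent <- function(proj, tau, pair) {
  n <- nrow(proj)
  u <- proj / sqrt(rowSums(proj^2))
  total <- 0
  for (i in seq_len(n)) {
    num <- exp(sum(u[i, ] * u[pair[i], ]) / tau)
    den <- 0
    for (r in seq_len(n)) {
      if (r != i) den <- den + exp(sum(u[i, ] * u[r, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / n
}

# Brute-force k-NN consensus filter from the full pairwise distance matrix.
brute_knn_filter <- function(emb, labels, k, th) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  kept <- logical(n)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])
    nbr <- (seq_len(n)[-i])[ord][seq_len(k)]
    frac[i] <- mean(labels[nbr] == labels[i])
    kept[i] <- frac[i] >= th / 100
  }
  list(kept = kept, frac = frac)
}

# Second-moment elongation of an image: ratio of principal axis variances.
elongation <- function(img) {
  img <- pmax(img - 0.2, 0)            # suppress the uniform background
  w <- img / sum(img)
  xs <- row(img); ys <- col(img)
  mx <- sum(w * xs); my <- sum(w * ys)
  cxx <- sum(w * (xs - mx)^2); cyy <- sum(w * (ys - my)^2)
  cxy <- sum(w * (xs - mx) * (ys - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
  ev[1] / max(ev[2], 1e-12)
}
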