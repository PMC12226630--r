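test_that("compute_prototypes equals the elementwise-mean oracle", {
  # degenerate cases
  u <- c(1, 2, 3)
  p <- compute_prototypes(matrix(u, 1), 2L)
  expect_equal(p$vectors[1, ], u)
  p2 <- compute_prototypes(rbind(u, -u), c(1L, 1L))
  expect_equal(p2$vectors[1, ], c(0, 0, 0))

  withr::with_seed(31, {
    emb <- matrix(rnorm(400 * 8), 400, 8)
    labels <- rep(0:3, each = 100)
    p <- compute_prototypes(emb, labels)
    for (c in 0:3) {
      oracle <- vapply(seq_len(8), function(j) {
        s <- 0; cnt <- 0
        for (i in seq_len(400)) if (labels[i] == c) { s <- s + emb[i, j]
          cnt <- cnt + 1 }
        s / cnt
      }, numeric(1))
      expect_equal(p$vectors[as.character(c), ], oracle, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
  # absent classes are omitted; empty input rejected
  p3 <- compute_prototypes(matrix(rnorm(6), 3), c(0, 0, 2))
  expect_identical(p3$classes, c(0L, 2L))
  expect_error(compute_prototypes(matrix(numeric(0), 0, 3), integer(0)),
               "empty")
})

test_that("nearest_prototype matches exhaustive search and breaks ties low", {
  protos <- compute_prototypes(diag(4) * 2, 0:3)
  r <- nearest_prototype(c(2, 0, 0, 0), protos)
  expect_identical(r$class, 0L)
  expect_equal(r$distance, 0)
  # equidistant from prototypes 0 and 1 -> class 0 by tie-break
  r2 <- nearest_prototype(c(1, 1, 0, 0), protos)
  expect_identical(r2$class, 0L)
  withr::with_seed(32, {
    for (i in 1:20) {
      z <- rnorm(4)
      d <- apply(protos$vectors, 1, function(v) sqrt(sum((v - z)^2)))
      expect_identical(nearest_prototype(z, protos)$class,
                       protos$classes[which.min(d)])
    }
  })
  expect_error(nearest_prototype(1:3, list(classes = integer(0))), "empty")
})

test_that("sigma -> 0 clusters: prototypes recover every training label", {
  g <- gen_embedding_clusters(4, dim = 8, n_per_class = 10, separation = 5,
                              sigma = 1e-10, seed = 33)
  protos <- compute_prototypes(g$embeddings, g$labels)
  got <- apply(g$embeddings, 1, function(z) nearest_prototype(z, protos)$class)
  expect_identical(as.integer(got), g$labels)
})

test_that("majority voting equals a brute-force tally and breaks ties fairly", {
  classes <- 0:3
  withr::with_seed(34, {
    for (rep in 1:40) {
      n_views <- sample(1:16, 1)
      assigned <- sample(classes, n_views, replace = TRUE)
      dists <- matrix(runif(n_views * 4), n_views, 4)
      v <- fedproto:::vote_from_assignments(assigned, dists, classes)
      counts <- sapply(classes, function(cl) sum(assigned == cl))
      expect_equal(unname(v$counts), counts)
      expect_equal(sum(v$counts), n_views)
      top <- classes[counts == max(counts)]
      expect_true(v$label %in% top)
      if (length(top) > 1) {
        sums <- sapply(top, function(cl) sum(dists[, cl + 1]))
        expect_identical(v$label, top[which.min(sums)])
      }
    }
  })
})

test_that("vote ties resolve by summed distance on a fixed fixture", {
  # 6 views: three votes for class 0, three for class 1
  assigned <- c(0L, 0L, 0L, 1L, 1L, 1L)
  dists <- cbind(c(1, 1, 1, 5, 5, 5) / 10,    # class 0 closer overall
                 c(5, 5, 5, 3, 3, 3) / 10,
                 rep(9, 6), rep(9, 6))
  v <- fedproto:::vote_from_assignments(assigned, dists, 0:3)
  expect_identical(v$label, 0L)               # 1.8 < 2.4 by hand
  # reversing the distance advantage flips the winner
  v2 <- fedproto:::vote_from_assignments(assigned, dists[, c(2, 1, 3, 4)], 0:3)
  expect_identical(v2$label, 1L)
})

test_that("label_by_view_ensemble with T = 1 equals nearest_prototype", {
  enc <- tiny_encoder()
  ds <- tiny_dataset(2, seed = 35)
  emb <- embed_images(enc, ds$images)
  protos <- compute_prototypes(emb, ds$labels)
  cfg <- view_ensemble_config(n_views = 1, seed = 9)
  for (i in c(1, 3, 6)) {
    rec <- label_by_view_ensemble(ds$images[[i]], enc, protos, cfg)
    expect_identical(rec$label, nearest_prototype(emb[i, ], protos)$class)
    expect_equal(sum(rec$votes), 1)
  }
})

test_that("identity augmentation makes any ensemble unanimous", {
  enc <- tiny_encoder()
  ds <- tiny_dataset(2, seed = 36)
  emb <- embed_images(enc, ds$images)
  protos <- compute_prototypes(emb, ds$labels)
  cfg1 <- view_ensemble_config(1, identity_augmentation(), seed = 2)
  cfg6 <- view_ensemble_config(6, identity_augmentation(), seed = 2)
  l1 <- label_client(ds$images, enc, protos, cfg1)
  l6 <- label_client(ds$images, enc, protos, cfg6)
  expect_identical(l1$labels, l6$labels)
  expect_true(all(vapply(l6$records, function(r) max(r$votes) == 6, logical(1))))
})

test_that("label_client ignores input labels and labels every sample", {
  enc <- tiny_encoder()
  ds <- tiny_dataset(3, seed = 37)
  emb <- embed_images(enc, ds$images)
  protos <- compute_prototypes(emb, ds$labels)
  cfg <- view_ensemble_config(4, seed = 5)
  out1 <- label_client(ds, enc, protos, cfg)
  sentinel <- ds
  sentinel$labels <- rep(3L, length(ds))     # sentinel labels
  out2 <- label_client(sentinel, enc, protos, cfg)
  expect_identical(out1$labels, out2$labels)
  expect_length(out1$labels, length(ds))
  empty <- label_client(list(), enc, protos, cfg)
  expect_identical(empty$labels, integer(0))
})

test_that("pseudo-labelling separated clusters is near-perfect via images", {
  # encoder contract on Gaussian clusters: use true means as prototypes
  g <- gen_embedding_clusters(4, dim = 32, n_per_class = 250, separation = 6,
                              sigma = 1, seed = 38)
  protos <- structure(list(classes = 0:3, vectors = g$means),
                      class = "prototypes")
  got <- apply(g$embeddings, 1, function(z) nearest_prototype(z, protos)$class)
  expect_gte(mean(got == g$labels), 0.99)
})

test_that("the shared payload is prototypes plus encoder parameters only", {
  enc <- tiny_encoder()
  protos <- compute_prototypes(matrix(rnorm(40), 10, 4), rep(0:1, 5))
  pay <- shared_payload(enc, protos)
  expect_named(pay, c("encoder_params", "prototype_matrix", "classes",
                      "n_values_shared"))
  expect_equal(pay$n_values_shared,
               length(protos$classes) * ncol(protos$vectors))
  expect_identical(dim(pay$prototype_matrix),
                   c(length(protos$classes), 4L))
})
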