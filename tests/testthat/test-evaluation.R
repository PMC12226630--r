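test_that("f1_scores matches hand-computed confusion matrices", {
  expect_equal(f1_scores(0:3, 0:3)$macro, 1)
  expect_equal(unname(f1_scores(0:3, 0:3)$per_class), rep(1, 4))

  # all predictions one class, truth uniform over 4 classes (n = 40):
  # predicted class P = 0.25, R = 1 -> F1 = 0.4; others 0; macro 0.1
  truth <- rep(0:3, each = 10)
  f1 <- f1_scores(rep(0L, 40), truth)
  expect_equal(unname(f1$per_class), c(0.4, 0, 0, 0))
  expect_equal(f1$macro, 0.1)

  # binary fixture TP=2 FP=1 FN=1 -> F1 = 2*2 / (2*2 + 1 + 1) = 2/3
  pred <- c(1, 1, 1, 0, 0)
  tru <- c(1, 1, 0, 1, 0)
  expect_equal(f1_scores(pred, tru, n_classes = 2)$per_class[["1"]], 2 / 3)
  expect_error(f1_scores(0:2, 0:3), "length")
})

test_that("f1_scores agrees with an independent confusion-matrix oracle", {
  oracle_f1 <- function(pred, truth, n_classes) {
    cm <- table(factor(pred, levels = 0:(n_classes - 1)),
                factor(truth, levels = 0:(n_classes - 1)))
    f1 <- numeric(n_classes)
    for (c in seq_len(n_classes)) {
      tp <- cm[c, c]; fp <- sum(cm[c, -c]); fn <- sum(cm[-c, c])
      f1[c] <- if (2 * tp + fp + fn == 0) NA_real_ else
        2 * tp / (2 * tp + fp + fn)
    }
    f1
  }
  withr::with_seed(61, {
    for (rep in 1:200) {
      n <- sample(5:50, 1)
      pred <- sample(0:3, n, replace = TRUE)
      truth <- sample(0:3, n, replace = TRUE)
      got <- f1_scores(pred, truth)
      oracle <- oracle_f1(pred, truth, 4)
      expect_equal(unname(got$per_class), oracle)
      expect_equal(got$macro, mean(oracle, na.rm = TRUE))
    }
  })
})

test_that("macro F1 is invariant under consistent class relabelling", {
  withr::with_seed(62, {
    pred <- sample(0:3, 80, replace = TRUE)
    truth <- sample(0:3, 80, replace = TRUE)
    base <- f1_scores(pred, truth)$macro
    perm <- c(2L, 0L, 3L, 1L)
    expect_equal(f1_scores(perm[pred + 1], perm[truth + 1])$macro, base)
  })
})

test_that("report combines tables and computes deltas against a baseline", {
  mk <- function(mode, macro) {
    structure(data.frame(mode = mode, noise_repr = 0, noise_norepr = 0,
                         country = c("alpha", "Mean"),
                         f1_abdomen = 1, f1_brain = 1, f1_femur = 1,
                         f1_thorax = 1, macro_f1 = c(macro, macro)),
              class = c("metrics_table", "data.frame"))
  }
  r <- report(list(mk("baseline", 0.9), mk("proposed", 0.95)), "baseline")
  expect_equal(r$summary$delta_vs_baseline, c(0, 0.95 - 0.9))
  r_self <- report(list(mk("baseline", 0.9)), "baseline")
  expect_equal(r_self$summary$delta_vs_baseline, 0)
  bad <- mk("x", 1); bad$country <- c("other", "Mean")
  expect_error(report(list(mk("baseline", 0.9), bad), "baseline"), "country")
  # round-trip CSV fidelity
  tf <- tempfile(fileext = ".csv")
  tab <- mk("proposed", 0.876543219)
  utils::write.csv(as.data.frame(tab), tf, row.names = FALSE)
  back <- utils::read.csv(tf)
  expect_equal(back$macro_f1, tab$macro_f1)
  unlink(tf)
})

test_that("run_experiment smoke contract: tiny local_train end to end", {
  repr <- assign_splits(gen_client_dataset(6, client = "repr", seed = 71),
                        fractions = c(train = 0.5, val = 0.2, test = 0.3),
                        seed = 72)
  norepr <- assign_splits(gen_client_dataset(5, client = "norepr", seed = 73),
                          fractions = c(train = 0.5, val = 0.2, test = 0.3),
                          seed = 74)
  cfgs <- experiment_configs(seed = 1, embedding_dim = 8,
                             pretrain_epochs = 0, rounds = 1,
                             local_epochs = 1, n_views = 2, k = 3)
  cfgs$contrastive$channels <- c(4, 4)
  cfgs$federation$batch_size <- 4
  tab <- run_experiment("local_train", repr, norepr, 0, 0, cfgs)
  expect_s3_class(tab, "metrics_table")
  expect_setequal(tab$country, c("repr", "norepr", "Mean"))
  expect_true(all(tab$macro_f1 >= 0 & tab$macro_f1 <= 1))
  expect_error(run_experiment("nope", repr, norepr, 0, 0, cfgs), "unknown")
})

test_that("proposed mode runs end to end and ignores small-client labels", {
  repr <- assign_splits(gen_client_dataset(10, client = "repr", seed = 75),
                        seed = 76)
  norepr <- assign_splits(gen_client_dataset(4, client = "norepr", seed = 77),
                          seed = 78)
  cfgs <- experiment_configs(seed = 2, embedding_dim = 8,
                             pretrain_epochs = 1, rounds = 1,
                             local_epochs = 1, n_views = 2, k = 5)
  cfgs$contrastive$channels <- c(4, 4)
  cfgs$contrastive$batch_pairs <- 8
  cfgs$federation$batch_size <- 4
  tab <- run_experiment("proposed", repr, norepr, 0.2, 0.5, cfgs)
  expect_s3_class(tab, "metrics_table")
  # the norepr training labels are discarded: flipping them cannot change
  # anything (noise is injected into labels that are never read)
  tab2 <- run_experiment("proposed", repr, norepr, 0.2, 0.9, cfgs)
  keep <- setdiff(names(tab), "noise_norepr")   # metadata column differs
  expect_equal(as.data.frame(tab)[keep], as.data.frame(tab2)[keep])
})
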