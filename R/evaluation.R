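#' Per-class and macro F1 scores
#'
#' One-vs-rest F1 per class (`2PR / (P + R)`, zero when `P + R = 0`);
#' classes absent from both predictions and truth are excluded from the
#' unweighted macro mean.
#'
#' @param predictions predicted class ids.
#' @param truth true class ids, same length.
#' @param n_classes number of classes (ids `0:(n_classes - 1)`).
#' @return list with `per_class` (named numeric, NA for absent classes)
#'   and `macro`.
#' @export
f1_scores <- function(predictions, truth, n_classes = 4) {
  if (length(predictions) != length(truth) || length(truth) == 0) {
    stop("`predictions` and `truth` must be non-empty and of equal length")
  }
  per_class <- rep(NA_real_, n_classes)
  names(per_class) <- if (n_classes == 4) CLASS_NAMES else
    as.character(seq_len(n_classes) - 1)
  for (c in seq_len(n_classes) - 1L) {
    tp <- sum(predictions == c & truth == c)
    fp <- sum(predictions == c & truth != c)
    fn <- sum(predictions != c & truth == c)
    if (tp + fp + fn == 0) next        # class absent everywhere
    per_class[c + 1] <- if (2 * tp + fp + fn == 0) 0 else
      2 * tp / (2 * tp + fp + fn)
  }
  list(per_class = per_class, macro = mean(per_class, na.rm = TRUE))
}

#' Default configuration bundle for desk-scale experiments
#'
#' @param seed integer seed.
#' @param embedding_dim backbone embedding length.
#' @param pretrain_epochs contrastive pretraining epochs.
#' @param rounds,local_epochs federated schedule.
#' @param n_views view-ensemble size.
#' @param k,th consensus-filter settings.
#' @param aug_views augmentation family for view-ensemble voting:
#'   photometric only (flips plus brightness/contrast jitter), so the vote
#'   marginalizes acquisition-style shift without adding the border
#'   artifacts geometric transforms cause on 64 x 64 images.
#' @param aug_contrastive augmentation family for contrastive view pairs;
#'   rotation-heavy by default because plane orientation is arbitrary, so
#'   the encoder must learn rotation-invariant shape features.
#' @return named list of stage configs.
#' @export
experiment_configs <- function(seed = 1, embedding_dim = 64,
                               pretrain_epochs = 12, rounds = 3,
                               local_epochs = 5, n_views = 8,
                               k = 50, th = 40,
                               aug_views =
                                 augmentation_spec(max_rotation_deg = 0,
                                                   max_shift_px = 0,
                                                   brightness_range = c(0.85, 1.15),
                                                   contrast_range = c(0.85, 1.15)),
                               aug_contrastive =
                                 augmentation_spec(max_rotation_deg = 180,
                                                   max_shift_px = 8,
                                                   zoom_range = c(0.75, 1.3))) {
  list(
    contrastive = contrastive_config(embedding_dim = embedding_dim,
                                     epochs = pretrain_epochs,
                                     batch_pairs = 64,
                                     augmentation = aug_contrastive,
                                     seed = derive_seed(seed, "contrastive")),
    denoise = denoise_config(k = k, th = th),
    views = view_ensemble_config(n_views = n_views, aug = aug_views,
                                 seed = derive_seed(seed, "views"),
                                 normalize = TRUE),
    federation = federation_config(rounds = rounds,
                                   local_epochs = local_epochs,
                                   seed = derive_seed(seed, "federation")),
    seed = seed
  )
}

subset_split <- function(ds, splits) ds[ds$split %in% splits]

# Train a model and evaluate it per country on the test splits of the
# given datasets; returns the per-country metric rows.
eval_per_country <- function(params, datasets, mode_label, noise_repr,
                             noise_norepr, override = NULL) {
  rows <- list()
  for (ds in datasets) {
    test <- subset_split(ds, "test")
    for (ctry in unique(test$country)) {
      sel <- test[test$country == ctry]
      preds <- if (!is.null(override) && ctry %in% names(override)) {
        override[[ctry]]
      } else {
        evaluate_model(params, sel$images, sel$labels)$predictions
      }
      f1 <- f1_scores(preds, sel$labels)
      rows[[length(rows) + 1]] <- data.frame(
        mode = mode_label, noise_repr = noise_repr,
        noise_norepr = noise_norepr, country = ctry,
        f1_abdomen = f1$per_class[["abdomen"]],
        f1_brain = f1$per_class[["brain"]],
        f1_femur = f1$per_class[["femur"]],
        f1_thorax = f1$per_class[["thorax"]],
        macro_f1 = f1$macro)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

add_mean_row <- function(tab) {
  mean_row <- tab[1, ]
  mean_row$country <- "Mean"
  for (col in c("f1_abdomen", "f1_brain", "f1_femur", "f1_thorax",
                "macro_f1")) {
    mean_row[[col]] <- mean(tab[[col]], na.rm = TRUE)
  }
  rbind(tab, mean_row)
}

noisy_train_labels <- function(ds, rate, seed) {
  idx <- which(ds$split %in% c("train", "val"))
  noisy <- ds$labels
  if (rate > 0) {
    noisy[idx] <- inject_label_noise(ds$labels[idx], rate, seed = seed,
                                     classes = 0:3)
  }
  noisy
}

#' Run one ablation experiment mode end to end
#'
#' Orchestrates the pipeline for one experiment mode of the ablation grid:
#' \describe{
#'   \item{local_train}{each client trains alone on its noisy labels.}
#'   \item{simple_fl}{FedAvg over both clients with raw noisy labels and a
#'     randomly initialized backbone.}
#'   \item{baseline}{consensus-denoise the representative client, FedAvg;
#'     the small client keeps its (possibly noisy) labels.}
#'   \item{proto_baseline}{baseline, but the small client's labels are
#'     replaced by single-view nearest-prototype assignments.}
#'   \item{proto_views}{no federation: train on the denoised
#'     representative client only; the small client's test samples are
#'     classified directly by view-ensemble prototype voting.}
#'   \item{proposed}{denoise the representative client, view-ensemble
#'     pseudo-label the small client, FedAvg over both.}
#'   \item{pretrained_weights}{train on the denoised representative client
#'     only and evaluate the resulting model on all clients.}
#' }
#' Modes that consume embeddings (all but local_train/simple_fl) require a
#' contrastively pretrained encoder; training noise is injected into the
#' train/val splits only and test labels stay clean for scoring.
#'
#' @param mode experiment mode string.
#' @param repr_data,norepr_data `plane_dataset`s with assigned splits for
#'   the representative (large) and non-representative (small) clients.
#' @param noise_repr,noise_norepr symmetric label-noise rates injected into
#'   the two clients' training labels.
#' @param cfgs config bundle from [experiment_configs()].
#' @param encoder optional pretrained `encoder`; if `NULL` and the mode
#'   needs one, it is pretrained on the representative client's train
#'   split.
#' @return object of class `metrics_table`: a data.frame of per-country
#'   per-class and macro F1 plus a federation `"Mean"` row, with the
#'   fitted artefacts in attributes.
#' @export
run_experiment <- function(mode, repr_data, norepr_data,
                           noise_repr = 0.2, noise_norepr = 0.2,
                           cfgs = experiment_configs(), encoder = NULL) {
  modes <- c("local_train", "simple_fl", "baseline", "proto_baseline",
             "proto_views", "proposed", "pretrained_weights")
  if (!mode %in% modes) {
    stop("unknown mode '", mode, "'; expected one of: ",
         paste(modes, collapse = ", "))
  }
  seed <- cfgs$seed
  repr_noisy <- noisy_train_labels(repr_data, noise_repr,
                                   derive_seed(seed, "noise_repr"))
  norepr_noisy <- noisy_train_labels(norepr_data, noise_norepr,
                                     derive_seed(seed, "noise_norepr"))
  repr_tr_idx <- which(repr_data$split %in% c("train", "val"))
  norepr_tr_idx <- which(norepr_data$split %in% c("train", "val"))

  needs_encoder <- !mode %in% c("local_train", "simple_fl")
  if (needs_encoder && is.null(encoder)) {
    encoder <- pretrain_encoder(repr_data$images[repr_tr_idx],
                                cfgs$contrastive)
  }
  denoise_res <- protos <- NULL
  if (needs_encoder) {
    emb <- embed_images(encoder, repr_data$images[repr_tr_idx])
    denoise_res <- knn_consensus_filter(emb, repr_noisy[repr_tr_idx],
                                        cfgs$denoise)
    kept <- repr_tr_idx[denoise_res$kept_mask]
    repr_clean <- repr_noisy
    repr_clean[kept] <- denoise_res$labels_out
    kept_emb <- emb[denoise_res$kept_mask, , drop = FALSE]
    if (isTRUE(cfgs$views$normalize)) kept_emb <- l2_normalize_rows(kept_emb)
    protos <- compute_prototypes(kept_emb, denoise_res$labels_out)
  }

  init_params <- function() {
    p <- init_tinycnn(embedding_dim = cfgs$contrastive$embedding_dim,
                      channels = cfgs$contrastive$channels,
                      projection_dim = cfgs$contrastive$projection_dim,
                      seed = derive_seed(seed, "model_init"))
    if (needs_encoder) p[names(encoder$params)] <- encoder$params
    p
  }
  repr_client <- function(idx, labels) {
    client_state("repr", repr_data$images[idx], labels[idx],
                 repr_data$country[idx])
  }
  norepr_client <- function(labels) {
    client_state("norepr", norepr_data$images[norepr_tr_idx],
                 labels, norepr_data$country[norepr_tr_idx])
  }

  override <- NULL
  if (mode == "local_train") {
    fit_r <- run_federation(list(repr_client(repr_tr_idx, repr_noisy)),
                            init_params(), cfgs$federation)
    fit_n <- run_federation(list(norepr_client(norepr_noisy[norepr_tr_idx])),
                            init_params(), cfgs$federation)
    tab <- rbind(
      eval_per_country(fit_r$params, list(repr_data), mode,
                       noise_repr, noise_norepr),
      eval_per_country(fit_n$params, list(norepr_data), mode,
                       noise_repr, noise_norepr))
    fit <- list(repr = fit_r, norepr = fit_n)
  } else {
    clients <- switch(mode,
      simple_fl = list(repr_client(repr_tr_idx, repr_noisy),
                       norepr_client(norepr_noisy[norepr_tr_idx])),
      baseline = list(repr_client(kept, repr_clean),
                      norepr_client(norepr_noisy[norepr_tr_idx])),
      proto_baseline = {
        pl <- label_client(norepr_data$images[norepr_tr_idx], encoder, protos,
                           view_ensemble_config(n_views = 1,
                                                aug = cfgs$views$aug,
                                                seed = cfgs$views$seed,
                                                normalize =
                                                  cfgs$views$normalize))
        list(repr_client(kept, repr_clean), norepr_client(pl$labels))
      },
      proto_views = list(repr_client(kept, repr_clean)),
      proposed = {
        pl <- label_client(norepr_data$images[norepr_tr_idx], encoder, protos,
                           cfgs$views)
        list(repr_client(kept, repr_clean), norepr_client(pl$labels))
      },
      pretrained_weights = list(repr_client(kept, repr_clean)))
    fit <- run_federation(clients, init_params(), cfgs$federation)
    if (mode == "proto_views") {
      test_n <- subset_split(norepr_data, "test")
      pl <- label_client(test_n$images, encoder, protos, cfgs$views)
      override <- split(pl$labels, test_n$country)
      override <- lapply(override, as.integer)
    }
    tab <- eval_per_country(fit$params, list(repr_data, norepr_data), mode,
                            noise_repr, noise_norepr, override = override)
  }
  tab <- add_mean_row(tab)
  structure(tab, class = c("metrics_table", "data.frame"),
            fit = fit, denoise = denoise_res, prototypes = protos)
}

#' Combine metrics tables and compare against a baseline mode
#'
#' Reproduces the ablation-table layout: one row per (mode, country) with
#' per-class and macro F1, plus each mode's federation mean and its delta
#' versus the named baseline mode's mean.
#'
#' @param tables list of `metrics_table` objects.
#' @param baseline_mode mode name whose mean is the reference.
#' @return list with `table` (all rows combined), `summary` (data.frame:
#'   mode, mean_macro_f1, delta_vs_baseline).
#' @export
report <- function(tables, baseline_mode = "baseline") {
  tabs <- lapply(tables, as.data.frame)
  keys <- lapply(tabs, function(t) sort(unique(t$country)))
  if (length(unique(keys)) != 1) stop("tables do not share country keys")
  all_tab <- do.call(rbind, tabs)
  means <- vapply(tabs, function(t) t$macro_f1[t$country == "Mean"][1],
                  numeric(1))
  modes <- vapply(tabs, function(t) t$mode[1], character(1))
  if (!baseline_mode %in% modes) {
    stop("baseline mode '", baseline_mode, "' not among the tables")
  }
  base <- means[match(baseline_mode, modes)]
  summary <- data.frame(mode = modes, mean_macro_f1 = means,
                        delta_vs_baseline = means - base)
  list(table = all_tab, summary = summary)
}
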