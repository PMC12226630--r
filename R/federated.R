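#' Federated-averaging aggregation
#'
#' Computes the sample-count-weighted elementwise mean of client parameter
#' sets: each parameter becomes `sum_k (n_k / sum(n)) * w_k`.
#'
#' @param updates list of named parameter lists, one per client; all must
#'   share identical names and shapes.
#' @param n_k client sample counts (positive, one per client).
#' @return aggregated named parameter list.
#' @export
fedavg <- function(updates, n_k) {
  stopifnot(length(updates) >= 1, length(updates) == length(n_k),
            all(n_k > 0))
  total <- sum(n_k)
  nms <- names(updates[[1]])
  for (u in updates) {
    if (!identical(names(u), nms)) stop("clients disagree on parameter names")
  }
  out <- updates[[1]]
  for (nm in nms) {
    dims <- lapply(updates, function(u) dim(u[[nm]]) %||% length(u[[nm]]))
    if (length(unique(dims)) != 1) {
      stop("shape mismatch for parameter '", nm, "'")
    }
    acc <- updates[[1]][[nm]] * (n_k[1] / total)
    if (length(updates) > 1) {
      for (k in 2:length(updates)) {
        acc <- acc + updates[[k]][[nm]] * (n_k[k] / total)
      }
    }
    out[[nm]] <- acc
  }
  out
}

#' Cosine-annealing learning rate with warm restarts
#'
#' `lr(e) = lr_min + (lr_init - lr_min) * (1 + cos(pi * (e mod L) / L)) / 2`
#' with cycle length `L` equal to the number of local epochs per round, so
#' the schedule restarts at `lr_init` at every round boundary.
#'
#' @param global_epoch zero-based epoch index across rounds.
#' @param cycle_len epochs per cycle (>= 1).
#' @param lr_init,lr_min schedule endpoints.
#' @return learning rate.
#' @export
cosine_warm_restart_lr <- function(global_epoch, cycle_len = 20,
                                   lr_init = 0.05, lr_min = 1e-5) {
  stopifnot(cycle_len >= 1)
  e <- global_epoch %% cycle_len
  lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * e / cycle_len))
}

#' Federated-training configuration
#'
#' Defaults follow the study recipe: 5 communication rounds of 20 local
#' epochs, SGD (momentum 0.9) with a cosine-annealing warm-restart schedule
#' from 0.05 down to 1e-5 over each round, batch size 16, cross-entropy
#' loss with linear mix-up at `alpha = 0.5`.
#'
#' @param rounds communication rounds (>= 1).
#' @param local_epochs local epochs per round (>= 1); also the scheduler
#'   cycle length.
#' @param batch_size minibatch size.
#' @param lr_init,lr_min learning-rate schedule endpoints.
#' @param momentum SGD momentum.
#' @param mixup_alpha Beta(alpha, alpha) mix-up parameter; 0 disables.
#' @param val_fraction fraction of each client's samples held out for
#'   validation-based round selection.
#' @param seed integer seed.
#' @return object of class `federation_config`.
#' @export
federation_config <- function(rounds = 5, local_epochs = 20, batch_size = 16,
                              lr_init = 0.05, lr_min = 1e-5, momentum = 0.9,
                              mixup_alpha = 0.5, val_fraction = 0.2,
                              seed = 1) {
  stopifnot(rounds >= 1, local_epochs >= 0, batch_size >= 1,
            lr_init > lr_min, lr_min > 0, mixup_alpha >= 0)
  structure(list(rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_min = lr_min, momentum = momentum,
                 mixup_alpha = mixup_alpha, val_fraction = val_fraction,
                 seed = seed),
            class = "federation_config")
}

#' A federation client
#'
#' @param id client id string.
#' @param images list of intensity matrices.
#' @param labels training labels (clean, noisy or pseudo, depending on the
#'   experiment mode).
#' @param country optional per-sample country tags.
#' @return object of class `client_state` with sample count `n_k`.
#' @export
client_state <- function(id, images, labels, country = NULL) {
  stopifnot(length(images) >= 1, length(images) == length(labels))
  structure(list(id = as.character(id), images = images,
                 labels = as.integer(labels),
                 country = rep_len(country %||% id, length(images)),
                 n_k = length(images)),
            class = "client_state")
}

# Forward pass to class logits: backbone embedding + linear head.
classifier_logits <- function(params, images, want_cache = FALSE) {
  fwd <- backbone_forward(params, images, want_cache = want_cache)
  list(logits = params$head.w %*% fwd$emb + params$head.b, fwd = fwd)
}

#' Evaluate a model on labelled images
#'
#' @param params model parameter list.
#' @param images list of intensity matrices.
#' @param labels true class ids.
#' @param n_classes number of classes.
#' @param batch_size forward batch size.
#' @return list with `loss` (mean cross-entropy), `macro_f1`, `per_class_f1`
#'   and `predictions`.
#' @export
evaluate_model <- function(params, images, labels, n_classes = 4,
                           batch_size = 256) {
  n <- length(images)
  preds <- integer(n)
  loss <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    logits <- classifier_logits(params, images[idx])$logits
    preds[idx] <- max.col(t(logits), ties.method = "first") - 1L
    loss <- loss + softmax_xent(logits, one_hot(labels[idx],
                                                n_classes))$loss * length(idx)
  }
  f1 <- f1_scores(preds, labels, n_classes)
  list(loss = loss / n, macro_f1 = f1$macro, per_class_f1 = f1$per_class,
       predictions = preds)
}

#' Local supervised training of one client
#'
#' Initializes from the broadcast global parameters and runs
#' `local_epochs` epochs of SGD with momentum on softmax cross-entropy,
#' with linear mix-up inside each minibatch (one Beta(alpha, alpha)
#' coefficient per batch, labels mixed as one-hot convex combinations) and
#' the cosine warm-restart schedule indexed by the global epoch. The
#' optimizer state is local to the call, as in standard FedAvg.
#'
#' @param client a [client_state()].
#' @param global_params broadcast parameter list.
#' @param cfg a [federation_config()].
#' @param round_idx zero-based communication-round index (controls both the
#'   scheduler offset and the per-round RNG stream).
#' @param n_classes number of classes.
#' @return updated parameter list.
#' @export
local_train <- function(client, global_params, cfg, round_idx = 0,
                        n_classes = 4) {
  if (client$n_k < 1) stop("client has no training data")
  params <- global_params
  if (cfg$local_epochs == 0) return(params)
  velocity <- list()
  train_names <- grep("^(conv|head)", names(params), value = TRUE)
  n <- client$n_k
  bs <- min(cfg$batch_size, n)
  withr::with_seed(derive_seed(cfg$seed, client$id, round_idx), {
    for (epoch in seq_len(cfg$local_epochs) - 1L) {
      lr <- cosine_warm_restart_lr(round_idx * cfg$local_epochs + epoch,
                                   cfg$local_epochs, cfg$lr_init, cfg$lr_min)
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        x <- client$images[idx]
        targets <- one_hot(client$labels[idx], n_classes)
        if (cfg$mixup_alpha > 0 && length(idx) > 1) {
          lam <- rbeta(1, cfg$mixup_alpha, cfg$mixup_alpha)
          perm <- sample.int(length(idx))
          xs <- stack_images(x)
          x <- xs * lam + xs[, , , perm, drop = FALSE] * (1 - lam)
          targets <- targets * lam + targets[, perm, drop = FALSE] * (1 - lam)
        }
        out <- classifier_logits(params, x, want_cache = TRUE)
        ce <- softmax_xent(out$logits, targets)
        grads <- list(head.w = tcrossprod(ce$dlogits, out$fwd$emb),
                      head.b = rowSums(ce$dlogits))
        demb <- crossprod(params$head.w, ce$dlogits)
        grads <- c(grads, backbone_backward(params, out$fwd$cache, demb))
        step <- sgd_step(params, grads[train_names], velocity, lr,
                         cfg$momentum)
        params <- step$params
        velocity <- step$velocity
      }
    }
  })
  params
}

# Deterministic stratified train/validation split of a client; returns
# index list. Exported for use by the centralized-training oracle.
#' Stratified train/validation index split for a client
#' @param labels integer labels.
#' @param val_fraction validation fraction.
#' @param seed integer seed.
#' @return list with `train` and `val` index vectors.
#' @export
stratified_val_split <- function(labels, val_fraction, seed) {
  val <- integer(0)
  withr::with_seed(seed, {
    for (g in split(seq_along(labels), labels)) {
      g <- g[sample.int(length(g))]
      n_val <- floor(val_fraction * length(g))
      if (n_val > 0) val <- c(val, g[seq_len(n_val)])
    }
  })
  val <- sort(val)
  list(train = setdiff(seq_along(labels), val), val = val)
}

#' Run a FedAvg federation
#'
#' Each client's samples are first split (stratified, seed-fixed) into a
#' local training part and a validation part. Every round broadcasts the
#' global parameters, trains each client locally, aggregates with
#' [fedavg()] weighted by post-split training counts, and records each
#' client's validation loss and macro F1 under the aggregated model. The
#' returned parameters are those of the round with minimum mean validation
#' loss.
#'
#' @param clients list of [client_state()] objects.
#' @param model_init initial parameter list (e.g. a pretrained backbone
#'   with a fresh head, or [init_tinycnn()]).
#' @param cfg a [federation_config()].
#' @param n_classes number of classes.
#' @return object of class `federation_fit`: list with `params` (selected
#'   round), `final_params`, `best_round`, `history` (data.frame: round,
#'   client, val_loss, val_macro_f1).
#' @export
run_federation <- function(clients, model_init, cfg = federation_config(),
                           n_classes = 4) {
  stopifnot(length(clients) >= 1)
  splits <- lapply(seq_along(clients), function(k) {
    stratified_val_split(clients[[k]]$labels, cfg$val_fraction,
                         derive_seed(cfg$seed, "valsplit", clients[[k]]$id))
  })
  train_clients <- lapply(seq_along(clients), function(k) {
    idx <- splits[[k]]$train
    client_state(clients[[k]]$id, clients[[k]]$images[idx],
                 clients[[k]]$labels[idx], clients[[k]]$country[idx])
  })
  n_k <- vapply(train_clients, `[[`, numeric(1), "n_k")
  global <- model_init
  history <- list()
  round_losses <- numeric(cfg$rounds)
  best <- NULL
  for (r in seq_len(cfg$rounds) - 1L) {
    updates <- lapply(train_clients, local_train, global_params = global,
                      cfg = cfg, round_idx = r, n_classes = n_classes)
    global <- fedavg(updates, n_k)
    vals <- lapply(seq_along(clients), function(k) {
      idx <- splits[[k]]$val
      if (length(idx) == 0) return(list(loss = NA_real_, macro_f1 = NA_real_))
      evaluate_model(global, clients[[k]]$images[idx],
                     clients[[k]]$labels[idx], n_classes)
    })
    history[[r + 1]] <- data.frame(
      round = r + 1L,
      client = vapply(clients, `[[`, character(1), "id"),
      val_loss = vapply(vals, `[[`, numeric(1), "loss"),
      val_macro_f1 = vapply(vals, `[[`, numeric(1), "macro_f1"))
    round_losses[r + 1] <- mean(history[[r + 1]]$val_loss)
    if (is.null(best) || (is.finite(round_losses[r + 1]) &&
                          (!is.finite(best$loss) ||
                           round_losses[r + 1] < best$loss))) {
      best <- list(loss = round_losses[r + 1], round = r + 1L,
                   params = global)
    }
  }
  structure(list(params = best$params, final_params = global,
                 best_round = best$round,
                 history = do.call(rbind, history)),
            class = "federation_fit")
}

#' @export
print.federation_fit <- function(x, ...) {
  cat("<federation_fit> ", max(x$history$round), " rounds, best round ",
      x$best_round, "\n", sep = "")
  print(x$history)
  invisible(x)
}

#' Centralized training of a single client
#'
#' Runs the same round/epoch loop as a single-client federation but
#' without aggregation; with matching seeds it reproduces the
#' single-client [run_federation()] trajectory exactly.
#'
#' @inheritParams run_federation
#' @param client a [client_state()].
#' @return a `federation_fit` object.
#' @export
centralized_train <- function(client, model_init, cfg = federation_config(),
                              n_classes = 4) {
  run_federation(list(client), model_init, cfg, n_classes)
}
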