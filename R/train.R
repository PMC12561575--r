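# Training: AdamW (or Adam/SGD) on softmax cross-entropy with per-epoch
# validation accuracy, early stopping with best-weight restoration, and
# on-the-fly augmentation of training batches.

#' Training configuration
#'
#' Defaults follow the published recipe: learning rate 0.01, batch size 16,
#' at most 130 epochs, early-stopping patience 20 on validation accuracy,
#' AdamW with decoupled weight decay, cross-entropy loss.
#'
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   accuracy improvement); must not exceed `max_epochs`.
#' @param optimizer One of `"adamw"`, `"adam"`, `"sgd"`.
#' @param weight_decay Decoupled weight decay (AdamW only; applied to conv
#'   and linear weights, not biases or normalization).
#' @param betas Momentum coefficients of the adaptive optimizers.
#' @param augment An [augment_config()], or `NULL` to disable training-time
#'   augmentation.
#' @param lr_schedule Optional schedule hook: a function taking the epoch
#'   number and returning the learning rate used for that epoch. When
#'   `NULL` (the default) the constant rate `lr` is used throughout, which
#'   matches the published recipe.
#' @param seed Seed controlling initialization order, shuffling, dropout and
#'   augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.01, batch_size = 16L, max_epochs = 130L,
                         patience = 20L, optimizer = c("adamw", "adam", "sgd"),
                         weight_decay = 0.01, betas = c(0.9, 0.999),
                         augment = augment_config(), lr_schedule = NULL,
                         seed = 0L) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, patience <= max_epochs, batch_size >= 1,
            is.null(lr_schedule) || is.function(lr_schedule))
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), optimizer = optimizer,
                 weight_decay = weight_decay, betas = betas,
                 augment = augment, lr_schedule = lr_schedule,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Early-stopping decision rule
#'
#' Given a sequence of per-epoch validation accuracies, returns the epoch
#' whose weights are kept (first maximum) and the epoch after which training
#' stops: the first epoch at which `patience` epochs have passed without
#' improvement, or the end of the sequence.
#'
#' @param val_acc Numeric vector of validation accuracies by epoch.
#' @param patience Number of epochs without improvement tolerated.
#' @return List with `best_epoch` and `stop_epoch`.
#' @export
early_stop_schedule <- function(val_acc, patience) {
  best <- 1L
  for (e in seq_along(val_acc)) {
    if (val_acc[e] > val_acc[best]) best <- e
    if (e - best >= patience) return(list(best_epoch = best, stop_epoch = e))
  }
  list(best_epoch = best, stop_epoch = length(val_acc))
}

# Gather the stacked rows of a set of images from a load_images() matrix.
image_rows <- function(ids, hw) {
  as.vector(vapply(ids, function(i) ((i - 1L) * hw + 1L):(i * hw),
                   integer(hw)))
}

# Map pixel values to the network input range.
normalize_input <- function(x) x / 127.5 - 1

snapshot_params <- function(model) {
  lapply(collect_params(model), function(p) p$value)
}

restore_params <- function(model, snap) {
  ps <- collect_params(model)
  for (i in seq_along(ps)) ps[[i]]$value <- snap[[i]]
  invisible(NULL)
}

bn_states <- function(model) {
  leaves <- flatten_leaf_modules(model$modules)
  Filter(Negate(is.null), lapply(leaves, `[[`, "state"))
}

snapshot_bn <- function(model) {
  lapply(bn_states(model), function(st)
    list(mean = st$running_mean, var = st$running_var))
}

restore_bn <- function(model, snap) {
  sts <- bn_states(model)
  for (i in seq_along(sts)) {
    sts[[i]]$running_mean <- snap[[i]]$mean
    sts[[i]]$running_var <- snap[[i]]$var
  }
  invisible(NULL)
}

#' Train a network
#'
#' Optimizes softmax cross-entropy with the configured optimizer, evaluating
#' validation accuracy after every epoch. Training stops when validation
#' accuracy has not improved for `patience` epochs or at `max_epochs`, and
#' the weights (and normalization statistics) of the best-validation epoch
#' are restored. Fully seeded: the same configuration seed reproduces the
#' same history.
#'
#' @param model A built `slenet_model`.
#' @param data Either a split `dataset_manifest` (images are loaded with
#'   [load_images()]) or a list with elements `train` and `val`, each a list
#'   as returned by [load_images()].
#' @param cfg A [train_config()].
#' @param verbose Print a one-line summary after each epoch.
#' @return List with the trained `model` and a `history` data frame (epoch,
#'   train_loss, val_acc).
#' @export
train_model <- function(model, data, cfg = train_config(), verbose = FALSE) {
  if (inherits(data, "dataset_manifest")) {
    size <- model$config$input_size
    data <- list(train = load_images(data[data$split == "train", ], size),
                 val = load_images(data[data$split == "val", ], size))
  }
  n_train <- length(data$train$y)
  if (n_train == 0) stop("empty training split")
  hw <- data$train$size^2
  S <- data$train$size
  params <- collect_params(model)
  opt <- adamw_state(params)
  y_idx <- as.integer(data$train$y)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_acc = numeric(0))
  best <- list(acc = -Inf, epoch = 0L, params = NULL, bn = NULL)
  step <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      lr_epoch <- if (is.null(cfg$lr_schedule)) cfg$lr
                  else cfg$lr_schedule(epoch)
      ord <- sample.int(n_train)
      losses <- numeric(0)
      for (start in seq(1L, n_train, by = cfg$batch_size)) {
        ids <- ord[start:min(start + cfg$batch_size - 1L, n_train)]
        B <- length(ids)
        xb <- data$train$x[image_rows(ids, hw), , drop = FALSE]
        if (!is.null(cfg$augment)) {
          for (b in seq_len(B)) {
            rows <- ((b - 1L) * hw + 1L):(b * hw)
            img <- rows_chw(xb[rows, , drop = FALSE], S, S)
            xb[rows, ] <- chw_rows(augment_image(img, cfg$augment))
          }
        }
        logits <- network_forward(model, normalize_input(xb), B,
                                  training = TRUE)
        ls <- softmax_xent(logits, y_idx[ids])
        losses <- c(losses, ls$loss)
        zero_grads(params)
        network_backward(model, ls$grad)
        step <- step + 1L
        if (cfg$optimizer == "sgd") {
          opt <- sgd_step(params, opt, lr_epoch)
        } else {
          opt <- adamw_step(params, opt, step, lr_epoch,
                            weight_decay = if (cfg$optimizer == "adamw")
                              cfg$weight_decay else 0,
                            beta1 = cfg$betas[1], beta2 = cfg$betas[2])
        }
      }
      acc <- evaluate_accuracy(model, data$val, cfg$batch_size)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_acc = acc))
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f, val accuracy %.4f",
                        epoch, mean(losses), acc))
      if (acc > best$acc) {
        best <- list(acc = acc, epoch = epoch,
                     params = snapshot_params(model), bn = snapshot_bn(model))
      }
      if (epoch - best$epoch >= cfg$patience) break
    }
  })
  if (!is.null(best$params)) {
    restore_params(model, best$params)
    restore_bn(model, best$bn)
  }
  list(model = model, history = history, best_epoch = best$epoch)
}

sgd_step <- function(params, st, lr, momentum = 0.9) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    st[[i]]$m <- momentum * st[[i]]$m + p$grad
    p$value <- p$value - lr * st[[i]]$m
  }
  st
}

#' Predicted class probabilities for a loaded image set
#'
#' @param model A `slenet_model`.
#' @param imgset List as returned by [load_images()].
#' @param batch_size Evaluation batch size.
#' @return `N x num_classes` matrix of softmax probabilities, with class
#'   columns in stage order (P, E, M, D).
#' @export
predict_model <- function(model, imgset, batch_size = 16L) {
  n <- length(imgset$y)
  hw <- imgset$size^2
  K <- model$config$num_classes
  probs <- matrix(0, n, K, dimnames = list(NULL, STAGES[seq_len(K)]))
  for (start in seq(1L, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1L, n)
    xb <- imgset$x[image_rows(ids, hw), , drop = FALSE]
    logits <- network_forward(model, normalize_input(xb), length(ids),
                              training = FALSE)
    m <- apply(logits, 1, max)
    e <- exp(logits - m)
    probs[ids, ] <- e / rowSums(e)
  }
  probs
}

evaluate_accuracy <- function(model, imgset, batch_size = 16L) {
  if (length(imgset$y) == 0) return(NA_real_)
  probs <- predict_model(model, imgset, batch_size)
  pred <- STAGES[max.col(probs, ties.method = "first")]
  mean(pred == as.character(imgset$y))
}

#' Recalibrate normalization running statistics
#'
#' Runs forward-only passes over an image set in training mode so the
#' batch-normalization running means and variances are re-estimated for the
#' current weights; no parameters change. In short small-batch runs the
#' exponential running averages lag the parameter trajectory, so a trained
#' model can evaluate markedly below its training-mode behavior until its
#' statistics are refreshed.
#'
#' @param model A `slenet_model` (modified in place).
#' @param imgset List as returned by [load_images()], typically the
#'   training split.
#' @param batch_size Forward-pass batch size.
#' @param passes Number of passes over the set (one suffices when the set
#'   has many more batches than `1 / momentum = 10`).
#' @return The model, invisibly.
#' @export
recalibrate_bn <- function(model, imgset, batch_size = 16L, passes = 1L) {
  hw <- imgset$size^2
  n <- length(imgset$y)
  for (p in seq_len(passes)) {
    for (start in seq(1L, n, by = batch_size)) {
      ids <- start:min(start + batch_size - 1L, n)
      xb <- imgset$x[image_rows(ids, hw), , drop = FALSE]
      invisible(network_forward(model, normalize_input(xb), length(ids),
                                training = TRUE))
    }
  }
  invisible(model)
}
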