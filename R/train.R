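# SGD training harness with plateau learning-rate decay, and evaluation.

#' Training configuration
#'
#' Defaults follow the standard recipe for this network family: mini-batch
#' SGD with momentum 0.9 and weight decay 1e-4, initial learning rate 0.01,
#' batch size 16, cross-entropy loss, and a plateau schedule that multiplies
#' the learning rate by 0.3 after 3 epochs without a validation-accuracy
#' improvement.
#'
#' @param batch_size Mini-batch size (default 16).
#' @param init_lr Initial learning rate (default 0.01).
#' @param epochs Number of training epochs (default 100).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 weight decay coefficient (default 1e-4).
#' @param lr_decay_factor Multiplicative plateau decay factor in (0, 1)
#'   (default 0.3).
#' @param patience_epochs Epochs without improvement before a decay
#'   (default 3).
#' @param seed Integer seed controlling data order and any augmentation
#'   draws (default 1).
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, init_lr = 0.01, epochs = 100L,
                         momentum = 0.9, weight_decay = 1e-4,
                         lr_decay_factor = 0.3, patience_epochs = 3L,
                         seed = 1L) {
  stopifnot(batch_size >= 1L, init_lr > 0, epochs >= 0L, momentum >= 0,
            weight_decay >= 0, patience_epochs >= 1L)
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1) {
    stop("lr_decay_factor must lie in (0, 1)")
  }
  structure(list(batch_size = as.integer(batch_size), init_lr = init_lr,
                 epochs = as.integer(epochs), momentum = momentum,
                 weight_decay = weight_decay,
                 lr_decay_factor = lr_decay_factor,
                 patience_epochs = as.integer(patience_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Plateau learning-rate scheduler state
#'
#' @param init_lr Initial learning rate.
#' @return A list with fields `current_lr`, `best_val_accuracy` and
#'   `epochs_since_improvement`.
#' @export
lr_scheduler_state <- function(init_lr) {
  list(current_lr = init_lr, best_val_accuracy = -Inf,
       epochs_since_improvement = 0L)
}

#' One plateau-scheduler update
#'
#' A strictly greater validation accuracy than the best seen so far resets
#' the stale-epoch counter and records the new best; otherwise the counter
#' increments, and when it reaches `patience_epochs` the learning rate is
#' multiplied by `lr_decay_factor` (floored at 1e-8) and the counter resets.
#'
#' @param state A [lr_scheduler_state()] list.
#' @param val_accuracy Validation accuracy in `[0, 1]`.
#' @param config A [train_config()].
#' @return The updated state.
#' @examples
#' s <- lr_scheduler_state(0.01)
#' s <- plateau_step(s, 0.5, train_config())
#' for (i in 1:3) s <- plateau_step(s, 0.5, train_config())
#' s$current_lr  # 0.003
#' @export
plateau_step <- function(state, val_accuracy, config) {
  stopifnot(is.numeric(val_accuracy), length(val_accuracy) == 1L,
            val_accuracy >= 0, val_accuracy <= 1)
  if (val_accuracy > state$best_val_accuracy) {
    state$best_val_accuracy <- val_accuracy
    state$epochs_since_improvement <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
    if (state$epochs_since_improvement >= config$patience_epochs) {
      state$current_lr <- max(1e-8,
                              config$lr_decay_factor * state$current_lr)
      state$epochs_since_improvement <- 0L
    }
  }
  state
}

sgd_step <- function(net, lr, momentum, weight_decay) {
  comps <- net_components(net)
  for (comp in comps) {
    for (mm in nn_modules(comp)) {
      for (k in names(mm$par)) {
        g <- mm$grad[[k]] + weight_decay * mm$par[[k]]
        v <- mm$opt[[k]]
        v <- if (is.null(v)) g else momentum * v + g
        mm$opt[[k]] <- v
        mm$par[[k]] <- mm$par[[k]] - lr * v
      }
    }
  }
  invisible(net)
}

# Stack a labeled image set into an (H,W,C,N) tensor + 0-based label vector.
set_to_tensor <- function(set) {
  n <- length(set$items)
  d <- dim(set$items[[1]]$image)
  x <- array(0, c(d[2], d[3], d[1], n))
  y <- integer(n)
  for (i in seq_len(n)) {
    x[, , , i] <- aperm(set$items[[i]]$image, c(2L, 3L, 1L))
    y[i] <- set$items[[i]]$label
  }
  list(x = x, y = y)
}

accuracy_on <- function(net, tens, batch_size = 32L) {
  n <- dim(tens$x)[4]
  preds <- integer(n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    logits <- net_forward(net, tens$x[, , , idx, drop = FALSE],
                          train = FALSE)
    preds[idx] <- max.col(t(logits), ties.method = "first") - 1L
    at <- at + batch_size
  }
  list(accuracy = mean(preds == tens$y), predictions = preds)
}

#' Train a network with SGD and plateau learning-rate decay
#'
#' Mini-batch SGD with momentum and weight decay on the cross-entropy loss.
#' After each epoch, validation accuracy is evaluated (in evaluation mode)
#' and fed to [plateau_step()]. The run is fully seeded: data order and any
#' augmentation draws derive from `config$seed`, so two runs with the same
#' seed produce identical histories. The parameters from the epoch with the
#' highest validation accuracy are restored at the end (set
#' `restore_best = FALSE` to keep the final-epoch weights).
#'
#' @param net An `ercp_network` (modified in place and returned).
#' @param train_set,val_set `labeled_image_set` objects whose images match
#'   the network input size and whose labels lie in `[0, num_classes)`.
#' @param config A [train_config()].
#' @param augment Optional [augment_config()] applied on the fly to each
#'   training image; `NULL` (default) disables augmentation.
#' @param restore_best Restore the best-validation-accuracy parameters at
#'   the end (default `TRUE`).
#' @param verbose Print a line per epoch.
#' @return A list with `net`, `history` (data frame with columns `epoch`,
#'   `train_loss`, `train_accuracy`, `val_accuracy`, `lr`) and `best`
#'   (epoch and accuracy of the restored checkpoint).
#' @export
train_network <- function(net, train_set, val_set, config = train_config(),
                          augment = NULL, restore_best = TRUE,
                          verbose = FALSE) {
  stopifnot(inherits(net, "ercp_network"), inherits(config, "train_config"))
  if (!length(train_set$items)) stop("training set is empty")
  K <- net$config$num_classes
  labs <- vapply(train_set$items, `[[`, numeric(1), "label")
  if (any(labs < 0 | labs >= K)) {
    stop("training labels outside [0, num_classes)")
  }
  tr <- set_to_tensor(train_set)
  va <- set_to_tensor(val_set)
  state <- lr_scheduler_state(config$init_lr)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_accuracy = numeric(),
                        val_accuracy = numeric(), lr = numeric())
  best <- list(epoch = 0L, val_accuracy = -Inf, state = NULL)
  n <- dim(tr$x)[4]
  run <- function() {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- numeric(0)
      at <- 1L
      while (at <= n) {
        idx <- perm[at:min(n, at + config$batch_size - 1L)]
        xb <- tr$x[, , , idx, drop = FALSE]
        if (!is.null(augment)) {
          for (j in seq_along(idx)) {
            img <- aperm(xb[, , , j], c(3L, 1L, 2L))
            img <- augment_image(img, augment,
                                 rng_state = sample.int(.Machine$integer.max,
                                                        1L))
            xb[, , , j] <- aperm(img, c(2L, 3L, 1L))
          }
        }
        yb <- tr$y[idx]
        logits <- net_forward(net, xb, train = TRUE)
        p <- softmax_cols(logits)
        picked <- p[cbind(yb + 1L, seq_along(idx))]
        loss <- -mean(log(pmax(picked, 1e-300)))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d (lr = %g)",
                       epoch, state$current_lr))
        }
        losses <- c(losses, loss)
        onehot <- matrix(0, K, length(idx))
        onehot[cbind(yb + 1L, seq_along(idx))] <- 1
        dlogits <- (p - onehot) / length(idx)
        for (comp in net_components(net)) nn_zero_grad(comp)
        net_backward(net, dlogits)
        sgd_step(net, state$current_lr, config$momentum,
                 config$weight_decay)
        at <- at + config$batch_size
      }
      tr_eval <- accuracy_on(net, tr)
      va_eval <- accuracy_on(net, va)
      lr_used <- state$current_lr
      state <<- plateau_step(state, va_eval$accuracy, config)
      history[nrow(history) + 1L, ] <<- list(epoch, mean(losses),
                                             tr_eval$accuracy,
                                             va_eval$accuracy, lr_used)
      if (va_eval$accuracy > best$val_accuracy) {
        best <<- list(epoch = epoch, val_accuracy = va_eval$accuracy,
                      state = lapply(net_components(net), nn_state))
      }
      if (verbose) {
        message(sprintf(
          "epoch %3d  loss %.4f  train acc %.3f  val acc %.3f  lr %.5g",
          epoch, mean(losses), tr_eval$accuracy, va_eval$accuracy, lr_used))
      }
    }
  }
  if (config$epochs > 0L) with_seed(config$seed, run())
  if (restore_best && !is.null(best$state)) {
    comps <- net_components(net)
    for (nm in names(comps)) nn_load_state(comps[[nm]], best$state[[nm]])
  }
  list(net = net, history = history,
       best = best[c("epoch", "val_accuracy")])
}

#' Evaluate a network on a labeled image set
#'
#' @param net An `ercp_network`.
#' @param set A `labeled_image_set`.
#' @return A list with `confusion` (a [compute_confusion()] matrix),
#'   `metrics` (a [compute_metrics()] report) and `predictions` (0-based).
#' @export
evaluate_network <- function(net, set) {
  tens <- set_to_tensor(set)
  res <- accuracy_on(net, tens)
  cm <- compute_confusion(res$predictions, tens$y, net$config$num_classes)
  list(confusion = cm, metrics = compute_metrics(cm),
       predictions = res$predictions)
}
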