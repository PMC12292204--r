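#' Training configuration
#'
#' Optimization regime for [eegcnn()]: mini-batch Adam on the mean
#' negative log-likelihood of the log-softmax outputs, with early stopping
#' on validation binary accuracy.  "Improvement" means strictly exceeding
#' the best accuracy so far; training halts once `patience` consecutive
#' epochs fail to improve (with `patience = 0`, at the first
#' non-improving epoch) or at `max_epochs`, and the weights from the best
#' epoch are restored.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of passes over the training set.
#' @param patience early-stopping patience in epochs (<= `max_epochs`).
#' @param beta1,beta2,adam_eps Adam moment decay rates and numerical
#'   floor.
#' @param restore_best return the weights of the best validation epoch
#'   (the protocol's early-stopping semantics).  `FALSE` keeps the final
#'   weights -- useful when the goal is a fully converged model and
#'   validation accuracy saturates immediately.
#' @param verbose print per-epoch progress.
#' @return List of class `train_control`.
#' @export
train_control <- function(learning_rate = 0.001, batch_size = 64L,
                          max_epochs = 200L, patience = 20L,
                          beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                          restore_best = TRUE, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 0, patience <= max_epochs)
  out <- list(learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
              restore_best = isTRUE(restore_best),
              verbose = isTRUE(verbose))
  class(out) <- "train_control"
  out
}

#' Fit the interpretable EEG CNN
#'
#' Trains the seven-layer separable network on trial-level epochs.  The
#' first factor level of `y` is the negative class, the second the
#' positive (risk) class; validation binary accuracy (argmax predictions,
#' evaluation-mode batch-norm) drives early stopping.
#'
#' All randomness (weight initialization, per-epoch shuffling) derives
#' from `seed`, so a fit is exactly reproducible.
#'
#' @param x training epochs: `channels x samples x trials` array.
#' @param y training labels: factor (or coercible) with `n_classes`
#'   levels; both classes must be present.
#' @param val_x,val_y held-out epochs and labels used for early stopping
#'   and reported metrics.
#' @param config an [model_config()]; inferred from `x` if `NULL`.
#' @param control a [train_control()].
#' @param seed master seed for this fit.
#' @return Object of class `eegcnn`: list with `params` (best-epoch
#'   weights), `config`, `control`, `history` (per-epoch data frame with
#'   `epoch`, `loss`, `val_accuracy`), `best_epoch`, `stop_epoch`,
#'   `levels`, `seed`.
#' @seealso [predict.eegcnn()], [compute_relevance()]
#' @export
eegcnn <- function(x, y, val_x, val_y, config = NULL,
                   control = train_control(), seed = 1L) {
  if (is.null(config)) {
    config <- model_config(n_channels = dim(x)[1], n_samples = dim(x)[2])
  }
  x <- as_epoch_array(x, config)
  val_x <- as_epoch_array(val_x, config)
  y <- as.factor(y)
  lev <- levels(y)
  if (length(lev) != config$n_classes) {
    stop(sprintf("`y` has %d levels but the model expects %d classes",
                 length(lev), config$n_classes), call. = FALSE)
  }
  yi <- as.integer(y)
  if (length(unique(yi)) < 2L) {
    stop("training split contains a single class", call. = FALSE)
  }
  vy <- as.integer(factor(as.character(val_y), levels = lev))
  if (anyNA(vy)) stop("validation labels outside training levels", call. = FALSE)
  n <- dim(x)[3]
  stopifnot(length(yi) == n, length(vy) == dim(val_x)[3], n > 0,
            length(vy) > 0)

  init_seed <- derive_seed(seed, 101L)
  shuffle_seed <- derive_seed(seed, 202L)
  config$init_seed <- init_seed
  params <- build_model(config)

  upd <- c("pointwise", "depthwise", "bn_gamma", "bn_beta", "dense",
           "dense_bias")
  if (!is.null(params$pointwise_bias)) upd <- c(upd, "pointwise_bias")
  if (!is.null(params$depthwise_bias)) upd <- c(upd, "depthwise_bias")
  mstate <- lapply(params[upd], function(p) p * 0)
  vstate <- mstate
  step <- 0L

  best_acc <- -Inf
  best_epoch <- 0L
  best_params <- params
  wait <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  stop_epoch <- control$max_epochs

  for (epoch in seq_len(control$max_epochs)) {
    perm <- with_seed(derive_seed(shuffle_seed, epoch), sample.int(n))
    losses <- numeric(0)
    for (start in seq(1L, n, by = control$batch_size)) {
      idx <- perm[start:min(start + control$batch_size - 1L, n)]
      fw <- nn_forward(params, x[, , idx, drop = FALSE], train_mode = TRUE,
                       keep = TRUE)
      loss <- nll_loss(fw$log_probs, yi[idx])
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d (diverged); lower the learning rate",
                     epoch), call. = FALSE)
      }
      losses <- c(losses, loss)
      params$bn_mean <- fw$bn_mean
      params$bn_var <- fw$bn_var
      grads <- nn_backward(params, fw, yi[idx])
      step <- step + 1L
      bc1 <- 1 - control$beta1^step
      bc2 <- 1 - control$beta2^step
      for (nm in upd) {
        g <- grads[[nm]]
        mstate[[nm]] <- control$beta1 * mstate[[nm]] + (1 - control$beta1) * g
        vstate[[nm]] <- control$beta2 * vstate[[nm]] + (1 - control$beta2) * g^2
        params[[nm]] <- params[[nm]] - control$learning_rate *
          (mstate[[nm]] / bc1) / (sqrt(vstate[[nm]] / bc2) + control$adam_eps)
      }
    }
    pred <- max.col(t(nn_forward(params, val_x)$log_probs), ties.method = "first")
    acc <- mean(pred == vy)
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         val_accuracy = acc))
    if (control$verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_acc %.3f", epoch,
                      mean(losses), acc))
    }
    if (acc > best_acc) {
      best_acc <- acc
      best_epoch <- epoch
      best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= max(1L, control$patience)) {
        stop_epoch <- epoch
        break
      }
    }
    stop_epoch <- epoch
  }

  out <- list(params = if (control$restore_best) best_params else params,
              config = config, control = control,
              history = history, best_epoch = best_epoch,
              stop_epoch = stop_epoch, levels = lev, seed = seed,
              n_train = n, call = match.call())
  class(out) <- "eegcnn"
  out
}

#' Predict from a fitted EEG CNN
#'
#' @param object a fitted [eegcnn()] model.
#' @param newdata epochs: `channels x samples x trials` array or a single
#'   channels x samples matrix.
#' @param type `"prob"` for class probabilities, `"class"` for argmax
#'   labels, `"logprob"` for log-probabilities.
#' @param ... unused.
#' @return A trials x classes matrix for `"prob"`/`"logprob"`, or a
#'   factor for `"class"`.
#' @export
predict.eegcnn <- function(object, newdata,
                           type = c("prob", "class", "logprob"), ...) {
  type <- match.arg(type)
  lp <- nn_forward(object$params, newdata)$log_probs
  if (type == "class") {
    cls <- max.col(t(lp), ties.method = "first")
    return(factor(object$levels[cls], levels = object$levels))
  }
  out <- t(if (type == "prob") exp(lp) else lp)
  colnames(out) <- object$levels
  out
}

#' @export
print.eegcnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<eegcnn> %d ch x %d samples -> %d classes (%s)\n",
              cfg$n_channels, cfg$n_samples, cfg$n_classes,
              paste(x$levels, collapse = " vs ")))
  cat(sprintf("  S = %d demixed sources, D = %d kernels of length %d (%d maps)\n",
              cfg$spatial_filters, cfg$depth_multiplier,
              cfg$temporal_kernel_len,
              cfg$spatial_filters * cfg$depth_multiplier))
  cat(sprintf("  trained %d epochs (best %d), best val accuracy %.3f\n",
              x$stop_epoch, x$best_epoch,
              max(x$history$val_accuracy)))
  invisible(x)
}

#' @export
summary.eegcnn <- function(object, ...) {
  shapes <- layer_shapes(object$config)
  cat("Layer output shapes (N = batch):\n")
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    s <- paste(ifelse(is.na(s), "N", s), collapse = ", ")
    cat(sprintf("  %-16s (%s)\n", nm, s))
  }
  cat(sprintf("\nTraining: %d trials, stopped at epoch %d (best %d)\n",
              object$n_train, object$stop_epoch, object$best_epoch))
  cat(sprintf("  final loss %.4f, best val accuracy %.3f\n",
              utils::tail(object$history$loss, 1),
              max(object$history$val_accuracy)))
  invisible(object)
}

#' @export
coef.eegcnn <- function(object, ...) {
  p <- object$params
  p[c("pointwise", "pointwise_bias", "depthwise", "depthwise_bias",
      "bn_gamma", "bn_beta", "bn_mean", "bn_var", "dense", "dense_bias")]
}

#' Plot training history
#'
#' Training loss and validation accuracy per epoch, with the best epoch
#' marked.
#'
#' @param x a fitted [eegcnn()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.eegcnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "NLL loss", ...)
  graphics::plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
                 ylab = "validation accuracy", main = "early stopping",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey40")
  invisible(x)
}

#' Write the per-epoch training log as CSV
#'
#' @param object a fitted [eegcnn()] model.
#' @param path output CSV path.
#' @export
write_training_log <- function(object, path) {
  stopifnot(inherits(object, "eegcnn"))
  utils::write.csv(object$history, path, row.names = FALSE)
  invisible(path)
}
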