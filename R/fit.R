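#' Train the paired weights on a labeled dataset
#'
#' Off-line supervised training: per-epoch shuffled mini-batches, full
#' (untruncated) backpropagation-through-time gradients, and the ADAM
#' update rule (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`). The frozen
#' prefix of the network (everything no trainable weight can influence) is
#' simulated once per dataset and cached; only the differentiable tail is
#' re-run during the epochs.
#'
#' @param pm A paired trainer from [pair_trainer()].
#' @param train,test Datasets from [gen_rate_classes()] / [split_dataset()]
#'   (lists with `x` `[n, T, C]`, `y` labels in `1..n_classes`,
#'   `n_classes`); `test` may be `NULL`.
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param lr ADAM learning rate.
#' @param seed Seed for the epoch shuffles.
#' @param chunk Batch size used when caching the frozen-prefix traces.
#' @param verbose Print one line per epoch.
#' @return An object of class `"snn_fit"`: trained `weights`, per-epoch
#'   `history` (data.frame: epoch, loss, train_acc, test_acc), the final
#'   test `confusion` matrix, and the paired trainer.
#' @export
train_snn <- function(pm, train, test = NULL, epochs = 30, batch_size = 16,
                      lr = 1e-3, seed = 1, chunk = 64, verbose = FALSE) {
  stopifnot(inherits(pm, "snn_trainable"))
  if (length(train$y) == 0) stop("empty training dataset", call. = FALSE)
  n_classes <- train$n_classes %||% max(train$y)
  n_out <- pm$sim$groups[[pm$out_id]]$n_out
  if (n_classes > n_out) {
    stop(sprintf(
      "dataset has %d classes but output port '%s' has %d components",
      n_classes, pm$out_id, n_out
    ), call. = FALSE)
  }
  T_run <- dim(train$x)[2]
  tr_bound <- cache_boundary(pm, train$x, chunk)
  te_bound <- if (!is.null(test)) cache_boundary(pm, test$x, chunk)

  weights <- pm$weights
  opt <- lapply(weights, function(w) {
    list(m = array(0, dim(w)), v = array(0, dim(w)), t = 0L)
  })
  n_tr <- length(train$y)
  history <- data.frame(
    epoch = integer(0), loss = double(0),
    train_acc = double(0), test_acc = double(0)
  )
  for (ep in seq_len(epochs)) {
    ord <- with_substream(seed, c("epoch", ep), sample.int(n_tr))
    losses <- double(0)
    correct <- 0L
    for (start in seq(1L, n_tr, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n_tr)]
      b <- length(idx)
      ctx <- tail_context(pm, b)
      res <- tail_loss_grad(
        pm, ctx, T_run, b,
        bound = index_bound(tr_bound, idx),
        x_ext = if (pm$input_in_tail) {
          train$x[idx, , , drop = FALSE]
        },
        labels = train$y[idx], weights = weights
      )
      losses <- c(losses, res$loss)
      correct <- correct + sum(res$pred == train$y[idx])
      for (id in pm$trainable) {
        st <- opt[[id]]
        st$t <- st$t + 1L
        g <- res$gw[[id]]
        st$m <- 0.9 * st$m + 0.1 * g
        st$v <- 0.999 * st$v + 0.001 * g * g
        mhat <- st$m / (1 - 0.9^st$t)
        vhat <- st$v / (1 - 0.999^st$t)
        weights[[id]] <- weights[[id]] - lr * mhat / (sqrt(vhat) + 1e-8)
        opt[[id]] <- st
      }
    }
    test_acc <- NA_real_
    if (!is.null(test)) {
      ev <- tail_evaluate(pm, te_bound, test, weights)
      test_acc <- ev$accuracy
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = mean(losses),
      train_acc = correct / n_tr, test_acc = test_acc
    ))
    if (verbose) {
      cat(sprintf(
        "epoch %3d  loss %.4f  train %.3f  test %s\n",
        ep, mean(losses), correct / n_tr,
        if (is.na(test_acc)) "-" else sprintf("%.3f", test_acc)
      ))
    }
  }
  final <- if (!is.null(test)) {
    tail_evaluate(pm, te_bound, test, weights)
  } else {
    tail_evaluate(pm, tr_bound, train, weights)
  }
  structure(
    list(
      pm = pm, weights = weights, history = history,
      accuracy = final$accuracy, confusion = final$confusion,
      n_classes = n_classes
    ),
    class = "snn_fit"
  )
}

#' @export
print.snn_fit <- function(x, ...) {
  cat(sprintf(
    "<snn_fit: %d epoch(s), final accuracy %.3f>\n",
    nrow(x$history), x$accuracy
  ))
  invisible(x)
}

# Simulate the frozen prefix once for every sample; returns a list mapping
# boundary group id -> [n_samples, T, n] output trace. When the trainable
# tail covers the whole network this is empty and the raw input is used.
cache_boundary <- function(pm, x, chunk = 64) {
  if (length(pm$boundary) == 0) {
    return(list())
  }
  n <- dim(x)[1]
  T_run <- dim(x)[2]
  out <- lapply(pm$boundary, function(id) {
    array(0, c(n, T_run, pm$sim$groups[[id]]$n_out))
  })
  names(out) <- pm$boundary
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    sub <- suppressWarnings(init_network(
      pm$net, pm$sim$dt,
      batch_size = length(idx), seed = pm$sim$seed
    ))
    for (id in pm$boundary) set_monitor(sub, id, "O")
    run_network(sub, x[idx, , , drop = FALSE])
    for (id in pm$boundary) {
      out[[id]][idx, , ] <- get_monitored_results(sub, id, "O")
    }
  }
  out
}

index_bound <- function(bound, idx) {
  lapply(bound, function(a) a[idx, , , drop = FALSE])
}

# accuracy + confusion over a dataset through the differentiable tail
tail_evaluate <- function(pm, bound, dataset, weights) {
  n <- length(dataset$y)
  T_run <- dim(dataset$x)[2]
  ctx <- tail_context(pm, n)
  res <- tail_loss_grad(
    pm, ctx, T_run, n,
    bound = bound,
    x_ext = if (pm$input_in_tail) dataset$x,
    labels = dataset$y, weights = weights, gradient = FALSE
  )
  n_classes <- dataset$n_classes %||% max(dataset$y)
  conf <- table(
    factor(dataset$y, levels = seq_len(n_classes)),
    factor(res$pred, levels = seq_len(n_classes))
  )
  list(
    accuracy = mean(res$pred == dataset$y),
    confusion = unclass(conf), loss = res$loss
  )
}

#' Evaluate a network on a labeled dataset with the plain engine
#'
#' Runs the full clock-driven simulation (no cached prefix, no surrogate
#' machinery) for every sample, reads out the max-membrane logits and
#' reports accuracy and the confusion matrix. `weights` overrides install
#' weight matrices (e.g. trained, quantized, or drifted ones) onto the
#' network before simulation, leaving the original network untouched.
#'
#' @param fit An `"snn_fit"` (its trained weights are installed
#'   automatically) or an `"snn_trainable"`.
#' @param dataset Dataset list (`x`, `y`, `n_classes`).
#' @param weights Named list: synaptic group id -> weight matrix override.
#' @param chunk Samples per simulation batch.
#' @return List with `accuracy`, `confusion`, and the logit matrix.
#' @export
evaluate_snn <- function(fit, dataset, weights = NULL, chunk = 64) {
  pm <- if (inherits(fit, "snn_fit")) fit$pm else fit
  stopifnot(inherits(pm, "snn_trainable"))
  w_all <- if (inherits(fit, "snn_fit")) fit$weights else pm$weights
  for (id in names(weights)) w_all[[id]] <- weights[[id]]
  net <- pm$net
  for (id in names(w_all)) {
    net <- set_weights(net, id, as.matrix(array(
      w_all[[id]], dim(w_all[[id]])
    )))
  }
  n <- length(dataset$y)
  T_run <- dim(dataset$x)[2]
  n_out <- pm$sim$groups[[pm$out_id]]$n_out
  logits <- matrix(0, n, n_out)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    sub <- suppressWarnings(init_network(
      net, pm$sim$dt,
      batch_size = length(idx), seed = pm$sim$seed
    ))
    y <- run_network(sub, dataset$x[idx, , , drop = FALSE])
    logits[idx, ] <- unclass(readout_logits(unclass(y)))
  }
  pred <- max.col(logits, ties.method = "first")
  n_classes <- dataset$n_classes %||% max(dataset$y)
  conf <- table(
    factor(dataset$y, levels = seq_len(n_classes)),
    factor(pred, levels = seq_len(n_classes))
  )
  list(
    accuracy = mean(pred == dataset$y), confusion = unclass(conf),
    logits = logits
  )
}
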