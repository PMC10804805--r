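#' Surrogate spike nonlinearity
#'
#' During backpropagation-through-time the spike Heaviside has no useful
#' derivative, so training substitutes a smooth pseudo-derivative while the
#' forward pass stays the exact threshold function (training-time inference
#' is therefore bitwise identical to plain simulation). The pseudo-
#' derivative is the normalized fast sigmoid
#' `g(u) = 1 / (1 + beta * |u - theta|)^2`, peaking at 1 on the threshold;
#' `beta` controls its steepness (default 10).
#'
#' @param u Membrane potential (array).
#' @param theta Spike threshold.
#' @param beta Surrogate steepness (> 0).
#' @return `surrogate_spike()`: the exact 0/1 spike (`u >= theta`);
#'   `surrogate_grad()`: the pseudo-derivative at `u`.
#' @export
#' @examples
#' surrogate_spike(c(0.9, 1.0, 1.1), theta = 1)
#' surrogate_grad(1 + c(-0.1, 0, 0.1), theta = 1, beta = 10)
surrogate_spike <- function(u, theta, beta = 10) {
  (u >= theta) * 1
}

#' @rdname surrogate_spike
#' @export
surrogate_grad <- function(u, theta, beta = 10) {
  stopifnot(beta > 0)
  1 / (1 + beta * abs(u - theta))^2
}

#' Max-membrane-potential readout
#'
#' Credit assignment uses the peak of each output neuron's membrane
#' potential over the simulation window: `logit[b, j] = max_t u[b, t, j]`.
#' The step index attaining the maximum is kept (attribute `"which"`) so
#' the training backward pass can route the loss gradient to that step.
#'
#' @param u_traces Membrane traces `[B, T, N_out]` of a non-spiking (LI)
#'   output group.
#' @return Logit matrix `[B, N_out]` with attribute `"which"`.
#' @export
readout_logits <- function(u_traces) {
  d <- dim(u_traces)
  stopifnot(length(d) == 3L)
  logits <- matrix(0, d[1], d[3])
  which_t <- matrix(1L, d[1], d[3])
  for (j in seq_len(d[3])) {
    m <- matrix(u_traces[, , j], d[1], d[2])
    idx <- max.col(m, ties.method = "first")
    which_t[, j] <- idx
    logits[, j] <- m[cbind(seq_len(d[1]), idx)]
  }
  structure(logits, which = which_t)
}

#' Log-likelihood classification loss
#'
#' Mean negative log-likelihood of the softmax over the readout logits.
#'
#' @param logits Matrix `[B, n_classes]`.
#' @param labels Integer class labels in `1..n_classes`.
#' @return The scalar loss.
#' @export
nll_loss <- function(logits, labels) {
  softmax_nll(logits, labels)$loss
}

softmax_nll <- function(logits, labels) {
  B <- nrow(logits)
  if (any(labels < 1) || any(labels > ncol(logits))) {
    stop("label out of range", call. = FALSE)
  }
  z <- logits - apply(logits, 1, max)
  p <- exp(z)
  p <- p / rowSums(p)
  picked <- p[cbind(seq_len(B), labels)]
  grad <- p
  grad[cbind(seq_len(B), labels)] <- picked - 1
  list(loss = -mean(log(pmax(picked, 1e-300))), grad = grad / B, prob = p)
}

trainer_supported <- c("input", "lif", "li", "ls1", "ls2")

#' Pair a trainer with a simulator
#'
#' Exposes the engine's forward pass as a differentiable computation over
#' the selected synaptic weight matrices; all other parameters are frozen.
#' The backward pass is an exact reverse-mode sweep over time and the stack
#' (backpropagation-through-time) using the analytic adjoints of each model
#' update; spike nonlinearities use [surrogate_grad()], and the spike-reset
#' is treated as constant in the backward pass (the standard detached-reset
#' convention).
#'
#' Groups whose outputs cannot be influenced by any trainable weight form a
#' frozen *prefix* of the network; their traces are computed once per
#' dataset by the plain engine and cached, so e.g. a liquid-state machine
#' whose readout alone is trained never re-simulates its reservoir during
#' the epochs.
#'
#' @param sim An initialized simulator ([init_network()]).
#' @param trainable Character vector of synaptic group ids to train.
#' @param surrogate_beta Steepness of the surrogate derivative.
#' @return An object of class `"snn_trainable"`.
#' @export
pair_trainer <- function(sim, trainable, surrogate_beta = 10) {
  stopifnot(inherits(sim, "snn_sim"))
  net <- sim$net
  for (id in trainable) {
    gr <- net$groups[[id]]
    if (is.null(gr) || gr$kind != "synapse") {
      stop(sprintf("trainable group '%s' is not a synaptic group", id),
        call. = FALSE
      )
    }
  }
  # downstream closure of the trainable groups
  affected <- trainable
  repeat {
    grew <- FALSE
    for (id in sim$ids) {
      if (id %in% affected) next
      srcs <- vapply(sim$plan$read_map[[id]], function(r) r$src, "")
      if (any(srcs %in% affected)) {
        affected <- c(affected, id)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  affected <- sim$stack$order[sim$stack$order %in% affected]
  out_id <- sim$output_id
  if (!out_id %in% affected) {
    stop("the output port is not downstream of any trainable group",
      call. = FALSE
    )
  }
  out_model <- sim$groups[[out_id]]$model$name
  if (sim$groups[[out_id]]$model$spiking) {
    stop(sprintf(
      paste0(
        "output port '%s' uses spiking model '%s'; the max-membrane ",
        "readout needs a non-spiking (li) output group"
      ),
      out_id, out_model
    ), call. = FALSE)
  }
  weights <- list()
  for (id in affected) {
    g <- sim$groups[[id]]
    if (!g$model$name %in% trainer_supported) {
      stop(sprintf(
        "group '%s' (model '%s') lies on the trainable path; supported: %s",
        id, g$model$name, paste(trainer_supported, collapse = ", ")
      ), call. = FALSE)
    }
    if (g$model$name == "lif" && !identical(g$params_raw$rho, 0)) {
      stop(sprintf(
        "refractory LIF group '%s' on the trainable path is not supported",
        id
      ), call. = FALSE)
    }
    for (nm in names(g$params_raw)) {
      if (param_has_batch(g$params_raw[[nm]], g$shape)) {
        stop(sprintf(
          "group '%s': batch-dependent parameter '%s' on the trainable path",
          id, nm
        ), call. = FALSE)
      }
    }
    if (id %in% trainable) {
      w <- g$params_raw$w
      weights[[id]] <- if (length(w) == 1L) {
        array(w, g$shape)
      } else {
        array(w, g$shape)
      }
    }
  }
  boundary <- unique(unlist(lapply(affected, function(id) {
    srcs <- vapply(sim$plan$read_map[[id]], function(r) r$src, "")
    setdiff(srcs, affected)
  })))
  structure(
    list(
      sim = sim, net = net, trainable = trainable, affected = affected,
      boundary = boundary, out_id = out_id,
      input_in_tail = sim$input_id %in% affected,
      beta = surrogate_beta, weights = weights
    ),
    class = "snn_trainable"
  )
}

#' @export
print.snn_trainable <- function(x, ...) {
  cat(sprintf(
    "<snn_trainable: %d trainable weight group(s) [%s], %d parameters>\n",
    length(x$trainable), paste(x$trainable, collapse = ", "),
    sum(vapply(x$weights, length, 1))
  ))
  cat(sprintf(
    "  differentiable tail: %s%s\n", paste(x$affected, collapse = " -> "),
    if (length(x$boundary) > 0) {
      sprintf("  (cached prefix: %s)", paste(x$boundary, collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}

# per-tail-batch parameter/cache tables for the affected groups
tail_context <- function(pm, b) {
  sim <- pm$sim
  ctx <- list()
  for (id in pm$affected) {
    g <- sim$groups[[id]]
    params <- lapply(g$params_raw, bcast_full, batch_size = b, shape = g$shape)
    cache <- g$model$time_dep(params, sim$dt, b, g$shape)
    reads <- lapply(sim$plan$read_map[[id]], function(r) {
      r$in_tail <- r$src %in% pm$affected
      r
    })
    ctx[[id]] <- list(
      id = id, model = g$model, shape = g$shape, n_out = g$n_out,
      params = params, cache = cache, reads = reads,
      trainable = id %in% pm$trainable
    )
  }
  ctx
}

expand_weight <- function(w, b) {
  array(rep(w, each = b), c(b, dim(w)))
}

# Forward pass over the differentiable tail. `bound` maps boundary group id
# to its cached output trace [b, T, n]; `x_ext` is the external input for
# the input port when it lies inside the tail. Records everything the
# backward sweep needs.
tail_forward <- function(pm, ctx, T_run, b, bound = list(), x_ext = NULL,
                         weights = pm$weights) {
  rec_out <- list()
  rec_in <- list()
  u_pre <- list()
  states <- list()
  W_full <- list()
  for (id in pm$affected) {
    c_ <- ctx[[id]]
    states[[id]] <- c_$model$init_state(c_$params, c_$cache, b, c_$shape)
    rec_out[[id]] <- array(0, c(b, T_run, c_$n_out))
    if (c_$model$kind == "synapse") {
      rec_in[[id]] <- array(0, c(b, T_run, c_$shape[1]))
      w <- if (c_$trainable) weights[[id]] else c_$params$w
      W_full[[id]] <- if (length(w) == 1L) {
        array(w, c(b, c_$shape))
      } else if (length(dim(w)) == 2L) {
        expand_weight(w, b)
      } else {
        w
      }
    }
    if (c_$model$name == "lif") {
      u_pre[[id]] <- array(0, c(b, T_run, c_$shape[1]))
    }
  }
  read_at <- function(src, t, in_tail) {
    if (t < 1L) {
      n <- if (in_tail) ctx[[src]]$n_out else dim(bound[[src]])[3]
      return(matrix(0, b, n))
    }
    if (in_tail) {
      matrix(rec_out[[src]][, t, ], b, ctx[[src]]$n_out)
    } else {
      matrix(bound[[src]][, t, ], b, dim(bound[[src]])[3])
    }
  }
  for (t in seq_len(T_run)) {
    for (id in pm$affected) {
      c_ <- ctx[[id]]
      S <- NULL
      for (rd in c_$reads) {
        v <- read_at(rd$src, t - rd$offset, rd$in_tail)
        S <- if (is.null(S)) v else S + v
      }
      if (pm$input_in_tail && id == pm$sim$input_id) {
        ext <- matrix(x_ext[, t, ], b, dim(x_ext)[3])
        S <- if (is.null(S)) ext else S + ext
      }
      if (is.null(S)) S <- matrix(0, b, c_$shape[1])
      if (c_$model$kind == "synapse") {
        rec_in[[id]][, t, ] <- S
        st <- states[[id]]
        integ <- identical(c_$params$integrate_output, 1)
        if (c_$model$name == "ls1") {
          O <- c_$params$phi *
            sum_sources(if (integ) st$I * c_$cache$a2 else st$I)
          D <- expand_targets(S, c_$shape[2])
          states[[id]]$I <- st$I * c_$cache$a1 + W_full[[id]] * D
        } else {
          O <- c_$params$phi * sum_sources(if (integ) {
            st$I_plus * c_$cache$a2p + st$I_minus * c_$cache$a2m
          } else {
            st$I_plus + st$I_minus
          })
          D <- W_full[[id]] * expand_targets(S, c_$shape[2])
          states[[id]]$I_plus <- st$I_plus * c_$cache$a1p + D
          states[[id]]$I_minus <- st$I_minus * c_$cache$a1m - D
        }
        out <- O
      } else if (c_$model$name == "lif") {
        up <- states[[id]]$u * c_$cache$decay + S
        u_pre[[id]][, t, ] <- up
        out <- (up >= c_$params$theta) * 1
        states[[id]]$u <- up * (1 - out) + c_$params$u_r * out
      } else if (c_$model$name == "li") {
        u2 <- states[[id]]$u * c_$cache$decay + S
        states[[id]]$u <- u2
        out <- u2
      } else { # relay
        out <- S
      }
      rec_out[[id]][, t, ] <- out
    }
  }
  list(
    rec_out = rec_out, rec_in = rec_in, u_pre = u_pre,
    W_full = W_full, T_run = T_run, b = b
  )
}

# Reverse-mode sweep over the tail: returns the loss gradient for each
# trainable weight matrix.
tail_backward <- function(pm, ctx, fwd, adj_seed) {
  T_run <- fwd$T_run
  b <- fwd$b
  adjO <- list()
  carry <- list()
  gw <- list()
  for (id in pm$affected) {
    c_ <- ctx[[id]]
    adjO[[id]] <- array(0, c(b, T_run, c_$n_out))
    if (c_$model$name == "ls1") {
      carry[[id]] <- array(0, c(b, c_$shape))
    } else if (c_$model$name == "ls2") {
      carry[[id]] <- list(
        p = array(0, c(b, c_$shape)), m = array(0, c(b, c_$shape))
      )
    } else if (c_$model$name %in% c("lif", "li")) {
      carry[[id]] <- matrix(0, b, c_$shape[1])
    }
    if (c_$trainable) gw[[id]] <- matrix(0, c_$shape[1], c_$shape[2])
  }
  adjO[[pm$out_id]] <- adj_seed

  route <- function(id, adj_in, t) {
    for (rd in ctx[[id]]$reads) {
      if (!rd$in_tail) next
      ts <- t - rd$offset
      if (ts >= 1L) {
        adjO[[rd$src]][, ts, ] <<- adjO[[rd$src]][, ts, ] +
          matrix(adj_in, b, ctx[[rd$src]]$n_out)
      }
    }
  }

  rev_order <- rev(pm$affected)
  for (t in seq(T_run, 1L)) {
    for (id in rev_order) {
      c_ <- ctx[[id]]
      a_out <- matrix(adjO[[id]][, t, ], b, c_$n_out)
      if (c_$model$name == "li") {
        adj_u <- a_out + carry[[id]]
        route(id, adj_u, t)
        carry[[id]] <- c_$cache$decay * adj_u
      } else if (c_$model$name == "lif") {
        spike <- matrix(fwd$rec_out[[id]][, t, ], b, c_$n_out)
        upre <- matrix(fwd$u_pre[[id]][, t, ], b, c_$n_out)
        adj_upre <- a_out * surrogate_grad(upre, c_$params$theta, pm$beta) +
          carry[[id]] * (1 - spike)
        route(id, adj_upre, t)
        carry[[id]] <- c_$cache$decay * adj_upre
      } else if (c_$model$name == "input") {
        route(id, a_out, t)
      } else if (c_$model$name == "ls1") {
        A <- carry[[id]]
        ns <- c_$shape[1]
        nt <- c_$shape[2]
        if (c_$trainable) {
          D <- expand_targets(matrix(fwd$rec_in[[id]][, t, ], b, ns), nt)
          gw[[id]] <- gw[[id]] +
            matrix(colSums(matrix(A * D, b, ns * nt)), ns, nt)
        }
        adj_in <- matrix(rowSums(matrix(A * fwd$W_full[[id]], b * ns, nt)),
          b, ns
        )
        route(id, adj_in, t)
        E <- aperm(array(a_out, c(b, nt, ns)), c(1L, 3L, 2L))
        k2 <- if (identical(c_$params$integrate_output, 1)) c_$cache$a2 else 1
        carry[[id]] <- c_$cache$a1 * A + c_$params$phi * k2 * E
      } else if (c_$model$name == "ls2") {
        Ap <- carry[[id]]$p
        Am <- carry[[id]]$m
        ns <- c_$shape[1]
        nt <- c_$shape[2]
        k2p <- if (identical(c_$params$integrate_output, 1)) c_$cache$a2p else 1
        k2m <- if (identical(c_$params$integrate_output, 1)) c_$cache$a2m else 1
        Adiff <- Ap - Am
        if (c_$trainable) {
          D <- expand_targets(matrix(fwd$rec_in[[id]][, t, ], b, ns), nt)
          gw[[id]] <- gw[[id]] +
            matrix(colSums(matrix(Adiff * D, b, ns * nt)), ns, nt)
        }
        adj_in <- matrix(
          rowSums(matrix(Adiff * fwd$W_full[[id]], b * ns, nt)), b, ns
        )
        route(id, adj_in, t)
        E <- aperm(array(a_out, c(b, nt, ns)), c(1L, 3L, 2L))
        carry[[id]]$p <- c_$cache$a1p * Ap + c_$params$phi * k2p * E
        carry[[id]]$m <- c_$cache$a1m * Am + c_$params$phi * k2m * E
      }
    }
  }
  gw
}

# Loss + gradients of one minibatch (used by train_snn and by the
# finite-difference tests).
tail_loss_grad <- function(pm, ctx, T_run, b, bound, x_ext, labels,
                           weights = pm$weights, gradient = TRUE) {
  fwd <- tail_forward(pm, ctx, T_run, b, bound, x_ext, weights)
  logits <- readout_logits(fwd$rec_out[[pm$out_id]])
  sm <- softmax_nll(unclass(logits), labels)
  out <- list(
    loss = sm$loss, logits = logits,
    pred = max.col(sm$prob, ties.method = "first")
  )
  if (gradient) {
    which_t <- attr(logits, "which")
    adj_seed <- array(0, c(b, T_run, ncol(logits)))
    for (j in seq_len(ncol(logits))) {
      adj_seed[cbind(seq_len(b), which_t[, j], j)] <- sm$grad[, j]
    }
    out$gw <- tail_backward(pm, ctx, fwd, adj_seed)
  }
  out
}
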