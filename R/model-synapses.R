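#' Built-in leaky synapse models
#'
#' @description
#' Synaptic groups connect a source group of `n_src` components to a target
#' group of `n_tgt` components and are always represented fully connected:
#' state and weights are dense `[n_src, n_tgt]` (pruning = zero weight).
#'
#' * **`"ls1"`** — first-order leaky synapse. Each (i, j) pair carries a
#'   current `I_ij` that decays with time constant `tau_alpha` and jumps by
#'   `w_ij` when source component i spikes:
#'   `I_ij(t+dt) = I_ij(t) * exp(-dt/tau_alpha) + w_ij * spike_i(t)`.
#'   The group output towards target j sums the group's contributions,
#'   integrated over the time-step:
#'   `O_j(t) = phi * sum_i I_ij(t) * tau_alpha * (1 - exp(-dt/tau_alpha))`,
#'   with `phi` a group-wise scalar scaling factor. Note the printed-equation
#'   ordering: the output is computed from the *pre-update* state, so a
#'   spike first affects the target one step after it reaches the synapse.
#'   Set `integrate_output = 0` to emit `phi * sum_i I_ij(t)` instead.
#' * **`"ls2"`** — second-order leaky synapse, solved by splitting the
#'   double-exponential kernel into independent branches: `I+` (time
#'   constant `tau_alpha_plus`, incremented by `+w`) and `I-`
#'   (`tau_alpha_minus`, incremented by `-w`); the output sums both
#'   integrated branches. With `tau+ > tau-` this yields the classic
#'   alpha-like rise-and-decay post-synaptic current.
#'
#' Parameters: `w` (required; scalar, `[n_src, n_tgt]`, or generator),
#' `tau_alpha` (`ls1`, required), `tau_alpha_plus` / `tau_alpha_minus`
#' (`ls2`, required), `phi` (1), `integrate_output` (1), `delay` (0 —
#' realized by the engine as a read offset on the group's output, see
#' [compute_stack()]).
#'
#' @return A model object.
#' @name synapse_models
NULL

# sum over the source axis of a [B, n_src, n_tgt] array -> [B, n_tgt]
sum_sources <- function(arr) {
  d <- dim(arr)
  out <- colSums(aperm(arr, c(2L, 1L, 3L)))
  matrix(out, d[1], d[3])
}

# broadcast a [B, n_src] slice along the target axis -> [B, n_src, n_tgt]
expand_targets <- function(x, n_tgt) {
  array(as.vector(x), c(dim(x), n_tgt))
}

# align a scalar / [n_src, n_tgt] / [B, n_src, n_tgt] parameter with the
# [B, n_src, n_tgt] state array
align3 <- function(x, d3) {
  if (identical(length(dim(x)), 3L)) {
    return(x)
  }
  if (length(x) == 1L) {
    return(as.vector(x))
  }
  array(rep(x, each = d3[1]), d3)
}

#' @rdname synapse_models
#' @export
model_ls1 <- function() {
  new_snn_model(
    name = "ls1", kind = "synapse", spiking = FALSE,
    required = c("tau_alpha", "w"),
    defaults = list(phi = 1, integrate_output = 1, delay = 0),
    time_dep = function(params, dt, B, shape) {
      a1 <- exp(-dt / params$tau_alpha)
      list(a1 = a1, a2 = params$tau_alpha * (1 - a1))
    },
    init_state = function(params, cache, B, shape) {
      list(I = array(0, c(B, shape)))
    },
    step = function(state, input, params, cache) {
      I <- state$I
      d3 <- dim(I)
      kernel <- if (identical(params$integrate_output, 1)) {
        align3(cache$a2, d3)
      } else {
        1
      }
      O <- params$phi * sum_sources(I * kernel)
      D <- expand_targets(input, d3[3])
      list(
        state = list(I = I * align3(cache$a1, d3) + align3(params$w, d3) * D),
        output = O
      )
    },
    monitorable = c("I", "O")
  )
}

#' @rdname synapse_models
#' @export
model_ls2 <- function() {
  new_snn_model(
    name = "ls2", kind = "synapse", spiking = FALSE,
    required = c("tau_alpha_plus", "tau_alpha_minus", "w"),
    defaults = list(phi = 1, integrate_output = 1, delay = 0),
    time_dep = function(params, dt, B, shape) {
      a1p <- exp(-dt / params$tau_alpha_plus)
      a1m <- exp(-dt / params$tau_alpha_minus)
      list(
        a1p = a1p, a2p = params$tau_alpha_plus * (1 - a1p),
        a1m = a1m, a2m = params$tau_alpha_minus * (1 - a1m)
      )
    },
    init_state = function(params, cache, B, shape) {
      list(I_plus = array(0, c(B, shape)), I_minus = array(0, c(B, shape)))
    },
    step = function(state, input, params, cache) {
      Ip <- state$I_plus
      Im <- state$I_minus
      d3 <- dim(Ip)
      O <- if (identical(params$integrate_output, 1)) {
        params$phi * sum_sources(
          Ip * align3(cache$a2p, d3) + Im * align3(cache$a2m, d3)
        )
      } else {
        params$phi * sum_sources(Ip + Im)
      }
      D <- align3(params$w, d3) * expand_targets(input, d3[3])
      list(
        state = list(
          I_plus = Ip * align3(cache$a1p, d3) + D,
          I_minus = Im * align3(cache$a1m, d3) - D
        ),
        output = O
      )
    },
    monitorable = c("I_plus", "I_minus", "O")
  )
}

#' Delay a model's output along the time axis
#'
#' Decorates a model so that its emitted output at engine step `t` is the
#' wrapped model's output of step `t - round(delay/dt)`; earlier steps emit
#' zeros. Sub-`dt` delays round to zero steps (with a warning). Within a
#' network, prefer the group-level `delay` parameter, which the engine
#' realizes without copying; this wrapper is the standalone equivalent for
#' composing models directly.
#'
#' @param model A model object.
#' @param delay Delay duration (same time units as `dt`), `>= 0`.
#' @param dt Engine time-step size used to discretize the delay.
#' @param n_out Number of output components of the wrapped model's group.
#' @return The decorated model (or `model` unchanged for a zero-step delay).
#' @export
delay_wrap <- function(model, delay, dt, n_out) {
  if (delay < 0) stop("delay must be >= 0", call. = FALSE)
  L <- as.integer(round(delay / dt))
  if (L == 0L) {
    if (delay > 0) {
      warning(sprintf(
        "delay %g is below the time-step %g and rounds to zero steps",
        delay, dt
      ), call. = FALSE)
    }
    return(model)
  }
  new_snn_model(
    name = paste0("delayed(", model$name, ")"),
    kind = model$kind, spiking = model$spiking,
    required = model$required, defaults = model$defaults,
    time_dep = function(params, dt, B, shape) {
      list(inner = model$time_dep(params, dt, B, shape))
    },
    init_state = function(params, cache, B, shape) {
      list(
        inner = model$init_state(params, cache$inner, B, shape),
        buf = array(0, c(B, L, n_out))
      )
    },
    step = function(state, input, params, cache) {
      res <- model$step(state$inner, input, params, cache$inner)
      buf <- state$buf
      B <- dim(buf)[1]
      out <- matrix(buf[, 1L, ], B, n_out)
      if (L > 1L) {
        buf[, seq_len(L - 1L), ] <- buf[, 2:L, ]
      }
      buf[, L, ] <- res$output
      list(state = list(inner = res$state, buf = buf), output = out)
    },
    monitorable = model$monitorable,
    inner = model
  )
}
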