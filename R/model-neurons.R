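#' Built-in neuron models
#'
#' @description
#' Three neuron models are provided, all advanced on the fixed engine grid:
#'
#' * **`"lif"`** — leaky integrate-and-fire with optional refractoriness.
#'   The membrane potential decays with time constant `tau_beta` and
#'   integrates the synaptic drive `S`:
#'   `u' = u * exp(-dt/tau_beta) + Pi * S`. The neuron emits a spike where
#'   `u' >= theta` (equality spikes), then resets to `u_r`. For a refractory
#'   duration `rho > 0` the integration gate `Pi` is held at 0 for a time
#'   `rho` after each spike (the membrane keeps leaking; only the input is
#'   gated).
#' * **`"li"`** — leaky integrator: identical membrane dynamics but no
#'   threshold, no reset; the output is the membrane value itself. Used as
#'   an analog readout layer for training.
#' * **`"izhikevich"`** — the two-variable nonlinear model integrated by
#'   forward Euler: `v <- v + h*(0.04 v^2 + 5 v + 140 - u + S)`,
#'   `u <- (1 - h a) u + h a b v`, iterated `k = ceiling(1/h)` sub-steps per
#'   engine step, then spike where `v >= theta` with reset `v <- c`,
#'   `u <- u + d`. `h` (0 < h <= 1) trades accuracy for speed; the update
#'   equations carry no `dt`, so one engine step corresponds to one unit of
#'   model time (1 ms for the canonical parameter set) — rescale `a`..`d`
#'   yourself if you run a different `dt`.
#'
#' Parameters (any of which may be scalars, per-component arrays, or
#' generator functions): `lif`/`li`: `tau_beta` (required), `theta` (1),
#' `u_r` (0), `rho` (0); `izhikevich`: `a` (0.02), `b` (0.2), `c` (-65),
#' `d` (8), `theta` (30), `h` (1).
#'
#' All quantities are unitless; the conventional reading is ms for time
#' constants and engine `dt`, mV for Izhikevich voltages.
#'
#' @return A model object for [register_model()] / [get_model()].
#' @name neuron_models
NULL

#' @rdname neuron_models
#' @export
model_lif <- function() {
  new_snn_model(
    name = "lif", kind = "neuron", spiking = TRUE,
    required = "tau_beta",
    defaults = list(theta = 1, u_r = 0, rho = 0),
    time_dep = function(params, dt, B, shape) {
      list(decay = exp(-dt / params$tau_beta), dt = dt)
    },
    init_state = function(params, cache, B, shape) {
      n <- shape[1]
      list(
        u = full_mat(params$u_r, B, n),
        Pi = matrix(1, B, n),
        t_since_spike = full_mat(params$rho, B, n)
      )
    },
    step = function(state, input, params, cache) {
      gated <- !identical(params$rho, 0)
      u2 <- state$u * cache$decay + (if (gated) state$Pi * input else input)
      spike <- (u2 >= params$theta) * 1
      ns <- 1 - spike
      u_new <- u2 * ns + full_mat(params$u_r, nrow(u2), ncol(u2)) * spike
      tss <- (state$t_since_spike + cache$dt) * ns
      Pi <- if (gated) {
        # rho = 0 components never close their gate
        (state$Pi | (tss >= params$rho)) * ns + (params$rho <= 0) * spike
      } else {
        state$Pi
      }
      list(
        state = list(u = u_new, Pi = Pi, t_since_spike = tss),
        output = spike
      )
    },
    monitorable = c("u", "O", "Pi", "t_since_spike")
  )
}

#' @rdname neuron_models
#' @export
model_li <- function() {
  new_snn_model(
    name = "li", kind = "neuron", spiking = FALSE,
    required = "tau_beta",
    defaults = list(),
    time_dep = function(params, dt, B, shape) {
      list(decay = exp(-dt / params$tau_beta))
    },
    init_state = function(params, cache, B, shape) {
      list(u = matrix(0, B, shape[1]))
    },
    step = function(state, input, params, cache) {
      u2 <- state$u * cache$decay + input
      list(state = list(u = u2), output = u2)
    },
    monitorable = c("u", "O")
  )
}

#' @rdname neuron_models
#' @export
model_izhikevich <- function() {
  new_snn_model(
    name = "izhikevich", kind = "neuron", spiking = TRUE,
    required = character(),
    defaults = list(a = 0.02, b = 0.2, c = -65, d = 8, theta = 30, h = 1),
    time_dep = function(params, dt, B, shape) {
      h <- params$h
      if (any(h <= 0) || any(h > 1)) {
        stop("izhikevich sub-step parameter h must satisfy 0 < h <= 1",
          call. = FALSE
        )
      }
      list(k = as.integer(ceiling(1 / min(h) - 1e-12)))
    },
    init_state = function(params, cache, B, shape) {
      n <- shape[1]
      v0 <- full_mat(params$c, B, n)
      list(v = v0, u = full_mat(params$b, B, n) * v0)
    },
    step = function(state, input, params, cache) {
      v <- state$v
      u <- state$u
      h <- params$h
      a <- params$a
      for (s in seq_len(cache$k)) {
        v1 <- v + h * (0.04 * v * v + 5 * v + 140 - u + input)
        u <- (1 - h * a) * u + h * a * params$b * v
        v <- v1
      }
      spike <- (v >= params$theta) * 1
      ns <- 1 - spike
      B <- nrow(v)
      n <- ncol(v)
      v <- v * ns + full_mat(params$c, B, n) * spike
      u <- u + full_mat(params$d, B, n) * spike
      list(state = list(v = v, u = u), output = spike)
    },
    monitorable = c("v", "u", "O")
  )
}

#' Relay (input port) model
#'
#' A stateless pass-through: its output each step is exactly its input
#' slice. Used for input layers that re-emit an externally supplied spike
#' raster or analog drive.
#'
#' @return A model object.
#' @export
model_input <- function() {
  new_snn_model(
    name = "input", kind = "relay", spiking = TRUE,
    required = character(), defaults = list(),
    time_dep = function(params, dt, B, shape) list(),
    init_state = function(params, cache, B, shape) list(),
    step = function(state, input, params, cache) {
      list(state = state, output = input)
    },
    monitorable = "O"
  )
}

#' Add refractoriness to a spiking model
#'
#' Decorates any spiking model with the input-gating mechanism of the LIF
#' neuron: after each spike the integration gate `Pi` is held at 0 for a
#' time `rho` (the gate multiplies the input only; the internal dynamics
#' keep evolving). Adds the parameter `rho` to the wrapped model;
#' `rho = 0` is a no-op at run time.
#'
#' @param model A spiking model object (e.g. `model_izhikevich()`).
#' @return The decorated model.
#' @export
refractory_wrap <- function(model) {
  if (!model$spiking) {
    stop(sprintf(
      "cannot add refractoriness to non-spiking model '%s'", model$name
    ), call. = FALSE)
  }
  new_snn_model(
    name = paste0("refractory(", model$name, ")"),
    kind = model$kind, spiking = TRUE,
    required = model$required,
    defaults = c(model$defaults[setdiff(names(model$defaults), "rho")],
      list(rho = 0)
    ),
    time_dep = function(params, dt, B, shape) {
      list(inner = model$time_dep(params, dt, B, shape), dt = dt)
    },
    init_state = function(params, cache, B, shape) {
      n <- shape[1]
      list(
        inner = model$init_state(params, cache$inner, B, shape),
        Pi = matrix(1, B, n),
        t_since_spike = full_mat(params$rho, B, n)
      )
    },
    step = function(state, input, params, cache) {
      res <- model$step(state$inner, state$Pi * input, params, cache$inner)
      spike <- res$output
      ns <- 1 - spike
      tss <- (state$t_since_spike + cache$dt) * ns
      Pi <- (state$Pi | (tss >= params$rho)) * ns
      list(
        state = list(inner = res$state, Pi = Pi, t_since_spike = tss),
        output = spike
      )
    },
    monitorable = c("Pi", "t_since_spike", "O"),
    inner = model
  )
}
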