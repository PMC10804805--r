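#' Compact component models
#'
#' A *model* describes one kind of circuit component (a neuron or a synapse)
#' in vectorized, time-discrete form. Every model honours the same
#' three-method lifecycle:
#'
#' * `time_dep(params, dt, batch_size, shape)` — precompute everything that
#'   depends on the time-step size (e.g. `exp(-dt/tau)` factors). Called at
#'   initialization and again whenever `dt` changes.
#' * `init_state(params, cache, batch_size, shape)` — build the zero /
#'   default state arrays. Must be called before the first step.
#' * `step(state, input, params, cache)` — advance one time-step: takes the
#'   input slice `[B, N_in]` and returns `list(state = <new state>,
#'   output = <[B, N_out] slice>)`, with no side effects beyond its own
#'   state.
#'
#' Models are looked up by name in a registry; `"lif"`, `"li"`,
#' `"izhikevich"`, `"ls1"`, `"ls2"` and `"input"` are built in, and
#' [register_model()] adds user models.
#'
#' @name snn_models
NULL

.models <- new.env(parent = emptyenv())

new_snn_model <- function(name, kind, spiking, required, defaults,
                          time_dep, init_state, step,
                          monitorable, inner = NULL) {
  structure(
    list(
      name = name, kind = kind, spiking = spiking,
      required = required, defaults = defaults,
      time_dep = time_dep, init_state = init_state, step = step,
      monitorable = monitorable, inner = inner
    ),
    class = "snn_model"
  )
}

#' @export
print.snn_model <- function(x, ...) {
  cat(sprintf(
    "<snn_model '%s' (%s%s)  params: %s>\n",
    x$name, x$kind, if (x$spiking) ", spiking" else "",
    paste(unique(c(x$required, names(x$defaults))), collapse = ", ")
  ))
  invisible(x)
}

#' Register or retrieve component models
#'
#' @param model An object created by the package's model constructors.
#' @param name Model name, e.g. `"lif"`.
#' @return `get_model()` returns the model object; `list_models()` the
#'   registered names.
#' @export
register_model <- function(model) {
  stopifnot(inherits(model, "snn_model"))
  assign(model$name, model, envir = .models)
  invisible(model)
}

populate_builtin_models <- function() {
  if (length(ls(.models)) > 0) {
    return(invisible())
  }
  register_model(model_input())
  register_model(model_lif())
  register_model(model_li())
  register_model(model_izhikevich())
  register_model(model_ls1())
  register_model(model_ls2())
  invisible()
}

#' @rdname register_model
#' @export
get_model <- function(name) {
  populate_builtin_models()
  if (!exists(name, envir = .models, inherits = FALSE)) {
    stop(sprintf(
      "unknown model '%s'; registered models: %s",
      name, paste(sort(ls(.models)), collapse = ", ")
    ), call. = FALSE)
  }
  get(name, envir = .models, inherits = FALSE)
}

#' @rdname register_model
#' @export
list_models <- function() {
  populate_builtin_models()
  sort(ls(.models))
}

# --- shared helpers ---------------------------------------------------------

# Full [B, n] matrix from a scalar / [n] / [B, n] parameter.
full_mat <- function(value, B, n) {
  if (length(value) == 1L) {
    return(matrix(as.double(value), B, n))
  }
  d <- dim(value)
  if (is.null(d) || length(d) == 1L) {
    return(matrix(rep(as.double(value), each = B), B, n))
  }
  matrix(as.double(value), B, n)
}

# Look up a state / output variable, descending through decorator states.
state_var <- function(state, output, var) {
  if (var %in% c("O", "output")) {
    return(output)
  }
  s <- state
  while (!is.null(s)) {
    if (var %in% names(s)) {
      return(s[[var]])
    }
    s <- s$inner
  }
  NULL
}

monitorable_vars <- function(model) {
  vars <- model$monitorable
  inner <- model$inner
  while (!is.null(inner)) {
    vars <- union(vars, inner$monitorable)
    inner <- inner$inner
  }
  vars
}
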