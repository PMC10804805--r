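#' Initialize a network for simulation
#'
#' Consolidates a network definition into a runnable simulator object:
#' resolves every group parameter (calling generator functions under their
#' seeded sub-streams), computes the execution stack and the temporary
#' storage plan, precomputes all `dt`-dependent model constants, and builds
#' the initial state. The returned object is a mutable simulator
#' (environment semantics): [run_network()] advances it, [reset_sim()]
#' restores the initial state, and it is reusable across runs.
#'
#' @param net Network object from [new_network()].
#' @param dt Time-step size (time units, conventionally ms).
#' @param batch_size Number of independent parallel simulations.
#' @param seed Master seed for parameter resolution sub-streams.
#' @param n_steps Optional fixed step count; when given, [run_network()]
#'   rejects inputs whose time axis differs.
#' @param heuristic Passed to [compute_stack()].
#' @return An object of class `"snn_sim"`.
#' @export
init_network <- function(net, dt = 1, batch_size = 1, seed = 0,
                         n_steps = NULL, heuristic = FALSE) {
  stopifnot(inherits(net, "snn_network"), dt > 0, batch_size >= 1)
  ids <- names(net$groups)
  if (length(ids) == 0) stop("network is empty", call. = FALSE)
  B <- as.integer(batch_size)

  groups <- stats::setNames(vector("list", length(ids)), ids)
  failures <- character(0)
  for (id in ids) {
    gr <- net$groups[[id]]
    model <- gr$model_obj
    shape <- group_shape(net, id)
    resolved <- list()
    specs <- gr$params
    for (nm in setdiff(names(model$defaults), names(specs))) {
      specs[[nm]] <- model$defaults[[nm]]
    }
    missing <- setdiff(model$required, names(specs))
    if (length(missing) > 0) {
      failures <- c(failures, sprintf(
        "group '%s': missing required parameter(s) %s",
        id, paste(sQuote(missing), collapse = ", ")
      ))
      next
    }
    ok <- TRUE
    for (nm in names(specs)) {
      val <- tryCatch(
        resolve_param(specs[[nm]], B, shape,
          rng = substream_seed(seed, id, nm), group = id, name = nm
        ),
        error = function(e) {
          failures <<- c(failures, conditionMessage(e))
          ok <<- FALSE
          NULL
        }
      )
      if (!ok) break
      if (startsWith(nm, "tau") && any(val <= 0)) {
        failures <- c(failures, sprintf(
          "group '%s': parameter '%s' must be > 0", id, nm
        ))
        ok <- FALSE
        break
      }
      resolved[[nm]] <- val
    }
    if (!ok) next
    groups[[id]] <- list(
      id = id, model = model, shape = shape,
      n_out = group_out_n(net, id), params_raw = resolved,
      params = lapply(resolved, bcast_full, batch_size = B, shape = shape)
    )
  }
  if (length(failures) > 0) {
    stop(
      "network initialization failed:\n  ",
      paste(failures, collapse = "\n  "),
      call. = FALSE
    )
  }

  stack <- compute_stack(net, dt, heuristic = heuristic)
  plan <- allocate_buffers(stack, net, dt)

  sim <- new.env(parent = emptyenv())
  class(sim) <- "snn_sim"
  sim$net <- net
  sim$dt <- dt
  sim$B <- B
  sim$seed <- seed
  sim$n_steps <- n_steps
  sim$ids <- ids
  sim$input_id <- net_input_id(net)
  sim$output_id <- net_output_id(net)
  sim$stack <- stack
  sim$plan <- plan
  sim$groups <- groups
  sim$monitors <- list()
  refresh_time_dep(sim)
  reset_sim(sim)
  sim
}

# (re)compute dt-dependent caches for every group.
refresh_time_dep <- function(sim) {
  for (id in sim$ids) {
    g <- sim$groups[[id]]
    sim$groups[[id]]$cache <- g$model$time_dep(g$params, sim$dt, sim$B, g$shape)
  }
  invisible(sim)
}

#' @rdname init_network
#' @param sim Simulator object.
#' @export
reset_sim <- function(sim) {
  stopifnot(inherits(sim, "snn_sim"))
  for (id in sim$ids) {
    g <- sim$groups[[id]]
    sim$groups[[id]]$state <- g$model$init_state(
      g$params, sim$groups[[id]]$cache, sim$B, g$shape
    )
  }
  sim$hist <- lapply(stats::setNames(seq_len(nrow(sim$plan$slots)),
    sim$plan$slots$id
  ), function(r) {
    array(0, c(sim$B, sim$plan$slots$len[r], sim$plan$slots$n_out[r]))
  })
  sim$t_global <- 0L
  sim$traces <- list()
  invisible(sim)
}

#' @export
print.snn_sim <- function(x, ...) {
  cat(sprintf(
    "<snn_sim: %d groups, dt=%g, batch=%d, %d step(s) run>\n",
    length(x$ids), x$dt, x$B, x$t_global
  ))
  cat(sprintf("  stack: %s\n", paste(x$stack$order, collapse = " -> ")))
  invisible(x)
}

# Read the value a group wrote at absolute step t (zeros before step 1).
hist_read <- function(sim, id, t) {
  h <- sim$hist[[id]]
  if (t < 1L) {
    return(matrix(0, dim(h)[1], dim(h)[3]))
  }
  len <- dim(h)[2]
  matrix(h[, ((t - 1L) %% len) + 1L, ], dim(h)[1], dim(h)[3])
}

hist_write <- function(sim, id, t, value) {
  len <- dim(sim$hist[[id]])[2]
  sim$hist[[id]][, ((t - 1L) %% len) + 1L, ] <- value
  invisible(sim)
}

#' Run the clock-driven simulation
#'
#' Advances the simulator over the time axis of `input`: an outer loop over
#' time-steps and an inner loop over the stack, where each group (a) reads
#' its input from its source groups' storage slots at the planned offsets,
#' (b) advances one step, and (c) writes its output slice back to its own
#' slot. External input is injected at the input port each step; the output
#' port's slices are collected into the returned `[B, T, N_out]` tensor.
#'
#' @param sim Simulator from [init_network()].
#' @param input External input array `[batch, time, components]` (a `[T, N]`
#'   matrix is promoted to batch 1); the batch axis must match the
#'   simulator's `batch_size`.
#' @param reset Start from the initial state (default). With
#'   `reset = FALSE` the run resumes from the carried state, so splitting a
#'   run into consecutive segments reproduces the single run exactly.
#' @return The output-port signal `[B, T, N_out]` (a [signal_tensor()]).
#' @export
run_network <- function(sim, input, reset = TRUE) {
  stopifnot(inherits(sim, "snn_sim"))
  input <- as_input_array(input)
  d <- dim(input)
  if (d[1] != sim$B) {
    stop(sprintf(
      "input batch axis (%d) does not match simulator batch_size (%d)",
      d[1], sim$B
    ), call. = FALSE)
  }
  n_in <- sim$groups[[sim$input_id]]$n_out
  if (d[3] != n_in) {
    stop(sprintf(
      "input has %d components but input port '%s' expects %d",
      d[3], sim$input_id, n_in
    ), call. = FALSE)
  }
  if (!is.null(sim$n_steps) && d[2] != sim$n_steps && reset) {
    stop(sprintf(
      "input has %d time-steps but the simulator clock expects %d",
      d[2], sim$n_steps
    ), call. = FALSE)
  }
  if (reset) reset_sim(sim)
  T_run <- d[2]
  B <- sim$B
  out_n <- sim$groups[[sim$output_id]]$n_out
  output <- array(0, c(B, T_run, out_n))

  run_traces <- prepare_traces(sim, T_run)
  order <- sim$stack$order
  read_map <- sim$plan$read_map
  spiking_out <- sim$groups[[sim$output_id]]$model$spiking

  for (t_local in seq_len(T_run)) {
    t <- sim$t_global + t_local
    for (id in order) {
      g <- sim$groups[[id]]
      S <- NULL
      for (rd in read_map[[id]]) {
        v <- hist_read(sim, rd$src, t - rd$offset)
        S <- if (is.null(S)) v else S + v
      }
      if (id == sim$input_id) {
        ext <- matrix(input[, t_local, ], B, n_in)
        S <- if (is.null(S)) ext else S + ext
      }
      if (is.null(S)) {
        S <- matrix(0, B, if (g$model$kind == "synapse") g$shape[1] else g$shape[1])
      }
      res <- g$model$step(g$state, S, g$params, g$cache)
      if (!all(is.finite(res$output))) {
        stop(sprintf(
          "non-finite output in group '%s' at step %d", id, t
        ), call. = FALSE)
      }
      sim$groups[[id]]$state <- res$state
      hist_write(sim, id, t, res$output)
      if (!is.null(run_traces[[id]])) {
        for (var in names(run_traces[[id]])) {
          val <- state_var(res$state, res$output, var)
          if (is.null(run_traces[[id]][[var]])) {
            run_traces[[id]][[var]] <-
              array(NA_real_, c(B, T_run, dim(val)[-1]))
          }
          if (length(dim(run_traces[[id]][[var]])) == 3L) {
            run_traces[[id]][[var]][, t_local, ] <- val
          } else {
            run_traces[[id]][[var]][, t_local, , ] <- val
          }
        }
      }
    }
    output[, t_local, ] <- hist_read(sim, sim$output_id, t)
  }
  sim$t_global <- sim$t_global + T_run
  append_traces(sim, run_traces)
  # relays forward whatever they receive, so check the values, not the model
  spike_like <- spiking_out && all(output == 0 | output == 1)
  signal_tensor(output, if (spike_like) "spike" else "analog")
}

prepare_traces <- function(sim, T_run) {
  out <- list()
  for (id in names(sim$monitors)) {
    out[[id]] <- stats::setNames(
      vector("list", length(sim$monitors[[id]])), sim$monitors[[id]]
    )
  }
  out
}

append_traces <- function(sim, run_traces) {
  for (id in names(run_traces)) {
    for (var in names(run_traces[[id]])) {
      new <- run_traces[[id]][[var]]
      old <- sim$traces[[id]][[var]]
      sim$traces[[id]][[var]] <- if (is.null(old)) {
        new
      } else {
        bind_time(old, new)
      }
    }
  }
  invisible(sim)
}

# concatenate two [B, T, ...] arrays along the time axis
bind_time <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(NA_real_, c(da[1], da[2] + db[2], da[-(1:2)]))
  ia <- slice.index(out, 2L) <= da[2]
  out[ia] <- a
  out[!ia] <- b
  out
}

#' Run with multiple time-step segments
#'
#' Splits a simulation into consecutive segments that may use different
#' time-step sizes; between segments every group's `dt`-dependent constants
#' are recomputed and the dynamic state carries over. Useful to resolve a
#' fast transient finely and then coarsen the grid.
#'
#' @param sim Simulator object.
#' @param segments List of `list(dt =, n_steps =)` entries; the `n_steps`
#'   must sum to the time axis of `input`.
#' @param input External input `[B, T, N_in]` spanning all segments.
#' @return The concatenated output `[B, T, N_out]`.
#' @export
run_multi <- function(sim, segments, input) {
  stopifnot(inherits(sim, "snn_sim"))
  input <- as_input_array(input)
  steps <- vapply(segments, function(s) as.integer(s$n_steps), 1L)
  if (any(steps < 1)) stop("zero-length segment", call. = FALSE)
  if (sum(steps) != dim(input)[2]) {
    stop(sprintf(
      "segments cover %d steps but input has %d", sum(steps), dim(input)[2]
    ), call. = FALSE)
  }
  reset_sim(sim)
  out <- vector("list", length(segments))
  offset <- 0L
  for (k in seq_along(segments)) {
    new_dt <- segments[[k]]$dt
    if (!isTRUE(all.equal(new_dt, sim$dt))) {
      sim$dt <- new_dt
      refresh_time_dep(sim)
      plan <- allocate_buffers(compute_stack(sim$net, new_dt), sim$net, new_dt)
      if (any(plan$slots$len > 1)) {
        warning(
          "changing dt re-discretizes delayed connections; ",
          "their buffered history is cleared",
          call. = FALSE
        )
        sim$plan <- plan
        keep_t <- sim$t_global
        for (id in sim$ids) {
          r <- match(id, plan$slots$id)
          sim$hist[[id]] <- array(
            0, c(sim$B, plan$slots$len[r], plan$slots$n_out[r])
          )
        }
        sim$t_global <- keep_t
      }
    }
    seg_in <- input[, offset + seq_len(steps[k]), , drop = FALSE]
    out[[k]] <- unclass(run_network(sim, seg_in, reset = FALSE))
    offset <- offset + steps[k]
  }
  y <- out[[1]]
  for (k in seq_along(out)[-1]) y <- bind_time(y, out[[k]])
  spiking_out <- sim$groups[[sim$output_id]]$model$spiking
  spike_like <- spiking_out && all(y == 0 | y == 1)
  signal_tensor(y, if (spike_like) "spike" else "analog")
}

#' Monitor group states and outputs
#'
#' `set_monitor()` requests that the named state/output variables of a group
#' be recorded at every time-step of subsequent runs; monitoring is purely
#' observational and never changes the simulated dynamics.
#' `get_monitored_results()` retrieves the recorded traces, shaped
#' `[batch, time, component dims...]`.
#'
#' @param sim Simulator object.
#' @param id Group id.
#' @param variables Character vector of variable names (`"O"` is the group
#'   output; state names are model-specific, e.g. `"u"` for lif/li, `"I"`
#'   for ls1).
#' @param var Single variable to retrieve, or `NULL` for a named list of
#'   all monitored variables of the group.
#' @return `get_monitored_results()`: an array, or a named list of arrays.
#' @export
set_monitor <- function(sim, id, variables) {
  stopifnot(inherits(sim, "snn_sim"))
  g <- sim$groups[[id]]
  if (is.null(g)) stop(sprintf("unknown group '%s'", id), call. = FALSE)
  valid <- monitorable_vars(g$model)
  bad <- setdiff(variables, valid)
  if (length(bad) > 0) {
    stop(sprintf(
      "group '%s' has no monitorable variable(s) %s; available: %s",
      id, paste(sQuote(bad), collapse = ", "), paste(valid, collapse = ", ")
    ), call. = FALSE)
  }
  sim$monitors[[id]] <- union(sim$monitors[[id]], variables)
  invisible(sim)
}

#' @rdname set_monitor
#' @export
get_monitored_results <- function(sim, id, var = NULL) {
  stopifnot(inherits(sim, "snn_sim"))
  tr <- sim$traces[[id]]
  if (is.null(tr)) {
    stop(sprintf("no monitored results for group '%s'", id), call. = FALSE)
  }
  if (is.null(var)) tr else tr[[var]]
}
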