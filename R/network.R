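#' Build a network of groups
#'
#' A network is an ordered collection of *groups* — sets of components that
#' share one model. Neuron groups are added with an explicit component count
#' `n`; synaptic groups name their `source` and `target` groups, from which
#' their own component count `n_src * n_tgt` and the network topology are
#' derived automatically.
#'
#' @param net A network object from `new_network()`.
#' @param model Model name (see [list_models()]) or a model object.
#' @param id Unique group identifier string.
#' @param n Component count (neuron/relay groups only).
#' @param source,target Group ids (synaptic groups only).
#' @param delay Output delay of this group's connection, in time units
#'   (discretized to `round(delay/dt)` engine steps at init).
#' @param ... Model parameters: scalars, arrays, or generator functions
#'   `function(batch_size, shape, rng)` (see [resolve_param()]).
#' @return The updated network object.
#' @export
#' @examples
#' net <- new_network() |>
#'   add_group("input", "in", n = 3) |>
#'   add_group("ls1", "syn", source = "in", target = "out",
#'     tau_alpha = 8, w = matrix(c(0.3, 0.5, 0.8), 3, 1)) |>
#'   add_group("lif", "out", n = 1, tau_beta = 64)
#' net
new_network <- function() {
  structure(
    list(groups = list(), input_id = NULL, output_id = NULL),
    class = "snn_network"
  )
}

#' @rdname new_network
#' @export
add_group <- function(net, model, id, n = NULL, source = NULL, target = NULL,
                      delay = 0, ...) {
  stopifnot(inherits(net, "snn_network"))
  if (id %in% names(net$groups)) {
    stop(sprintf("group id '%s' already present", id), call. = FALSE)
  }
  model_obj <- if (inherits(model, "snn_model")) model else get_model(model)
  params <- list(...)
  if (model_obj$kind == "synapse") {
    if (is.null(source) || is.null(target)) {
      stop(sprintf(
        "synaptic group '%s' must name source and target groups", id
      ), call. = FALSE)
    }
    for (ref in c(source, target)) {
      if (!ref %in% names(net$groups)) {
        stop(sprintf(
          "group '%s' references unknown group '%s'", id, ref
        ), call. = FALSE)
      }
      if (net$groups[[ref]]$kind == "synapse") {
        stop(sprintf(
          "group '%s': source/target '%s' is itself a synaptic group",
          id, ref
        ), call. = FALSE)
      }
    }
    n <- net$groups[[source]]$n * net$groups[[target]]$n
  } else {
    if (is.null(n) || n < 1) {
      stop(sprintf("group '%s' needs a positive component count n", id),
        call. = FALSE
      )
    }
    source <- target <- NULL
  }
  known <- unique(c(model_obj$required, names(model_obj$defaults)))
  unknown <- setdiff(names(params), known)
  if (length(unknown) > 0) {
    stop(sprintf(
      "group '%s': unknown parameter(s) %s; valid names: %s",
      id, paste(sQuote(unknown), collapse = ", "),
      paste(known, collapse = ", ")
    ), call. = FALSE)
  }
  net$groups[[id]] <- list(
    id = id, model = model_obj$name, model_obj = model_obj,
    kind = model_obj$kind, n = as.integer(n),
    source = source, target = target, delay = delay, params = params
  )
  net
}

#' @rdname new_network
#' @param name Parameter name to amend (includes `"delay"` and, for neuron
#'   groups, `"n"`).
#' @param value New value; takes effect at the next [init_network()].
#' @export
set_param <- function(net, id, name, value) {
  stopifnot(inherits(net, "snn_network"))
  gr <- net$groups[[id]]
  if (is.null(gr)) {
    stop(sprintf("unknown group '%s'", id), call. = FALSE)
  }
  if (name == "delay") {
    gr$delay <- value
  } else if (name == "n" && gr$kind != "synapse") {
    gr$n <- as.integer(value)
  } else {
    known <- unique(c(gr$model_obj$required, names(gr$model_obj$defaults)))
    if (!name %in% known) {
      stop(sprintf(
        "group '%s' has no parameter '%s'; valid names: %s",
        id, name, paste(c(known, "delay"), collapse = ", ")
      ), call. = FALSE)
    }
    gr$params[[name]] <- value
  }
  net$groups[[id]] <- gr
  net
}

#' @rdname new_network
#' @param input,output Group ids to use as the network's input and output
#'   ports. Defaults (when never set): first-added group is the input port,
#'   last-added the output port.
#' @export
set_ports <- function(net, input = NULL, output = NULL) {
  stopifnot(inherits(net, "snn_network"))
  for (ref in c(input, output)) {
    if (!ref %in% names(net$groups)) {
      stop(sprintf("unknown port group '%s'", ref), call. = FALSE)
    }
  }
  if (!is.null(input)) net$input_id <- input
  if (!is.null(output)) net$output_id <- output
  net
}

net_input_id <- function(net) {
  if (!is.null(net$input_id)) net$input_id else names(net$groups)[1]
}

net_output_id <- function(net) {
  if (!is.null(net$output_id)) {
    net$output_id
  } else {
    names(net$groups)[length(net$groups)]
  }
}

# Component shape of a group: n for neurons, c(n_src, n_tgt) for synapses.
group_shape <- function(net, id) {
  gr <- net$groups[[id]]
  if (gr$kind == "synapse") {
    c(net$groups[[gr$source]]$n, net$groups[[gr$target]]$n)
  } else {
    gr$n
  }
}

# Output width of a group.
group_out_n <- function(net, id) {
  gr <- net$groups[[id]]
  if (gr$kind == "synapse") net$groups[[gr$target]]$n else gr$n
}

# Directed edges (source -> target group id) of the dataflow graph, with the
# delay carried by each edge (= the source group's output delay).
net_edges <- function(net) {
  edges <- list()
  for (gr in net$groups) {
    if (gr$kind == "synapse") {
      edges[[length(edges) + 1L]] <- list(
        from = gr$source, to = gr$id, delay = net$groups[[gr$source]]$delay
      )
      edges[[length(edges) + 1L]] <- list(
        from = gr$id, to = gr$target, delay = gr$delay
      )
    }
  }
  edges
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("<snn_network: %d groups>\n", length(x$groups)))
  for (gr in x$groups) {
    wiring <- if (gr$kind == "synapse") {
      sprintf("  %s -> %s", gr$source, gr$target)
    } else {
      ""
    }
    cat(sprintf(
      "  %-12s %-12s n=%-6d%s\n", gr$id,
      sprintf("[%s]", gr$model), gr$n, wiring
    ))
  }
  if (length(x$groups) > 0) {
    cat(sprintf(
      "  ports: input=%s output=%s\n", net_input_id(x), net_output_id(x)
    ))
  }
  invisible(x)
}

#' Weight access for synaptic groups
#'
#' Weights are dense `[n_src, n_tgt]` matrices; zeros encode pruned
#' connections. `set_weights()` accepts a matrix (or scalar) and installs it
#' on the network spec; retrieval round-trips exactly.
#'
#' @param net Network object.
#' @param id Synaptic group id.
#' @param w Weight matrix `[n_src, n_tgt]` or scalar.
#' @return `get_weights()` returns the stored weights; `set_weights()` the
#'   updated network.
#' @export
set_weights <- function(net, id, w) {
  gr <- net$groups[[id]]
  if (is.null(gr) || gr$kind != "synapse") {
    stop(sprintf("'%s' is not a synaptic group", id), call. = FALSE)
  }
  shape <- group_shape(net, id)
  if (length(w) != 1L && !(is.matrix(w) && all(dim(w) == shape))) {
    stop(sprintf(
      "weights for '%s' must be scalar or a [%d x %d] matrix",
      id, shape[1], shape[2]
    ), call. = FALSE)
  }
  set_param(net, id, "w", w)
}

#' @rdname set_weights
#' @export
get_weights <- function(net, id) {
  gr <- net$groups[[id]]
  if (is.null(gr) || gr$kind != "synapse") {
    stop(sprintf("'%s' is not a synaptic group", id), call. = FALSE)
  }
  gr$params$w
}

#' Save / load weight matrices as CSV
#'
#' @param w Weight matrix.
#' @param path File path.
#' @return `read_weights_csv()` returns the matrix.
#' @export
write_weights_csv <- function(w, path) {
  utils::write.table(w, path,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Serialize a network to / from a YAML-able configuration list
#'
#' Round-trips the group structure, numeric parameters (matrices included)
#' and ports. Generator-function parameters cannot be serialized and raise
#' an error; install concrete arrays first.
#'
#' @param net Network object, or (for reading) a file path / config list.
#' @param path Optional YAML file to write to / read from.
#' @return `network_to_config()` a plain list (written to `path` when
#'   given); `network_from_config()` the reconstructed network.
#' @export
network_to_config <- function(net, path = NULL) {
  groups <- lapply(net$groups, function(gr) {
    params <- gr$params
    for (nm in names(params)) {
      p <- params[[nm]]
      if (is.function(p)) {
        stop(sprintf(
          "group '%s': generator-function parameter '%s' cannot be serialized",
          gr$id, nm
        ), call. = FALSE)
      }
      params[[nm]] <- if (is.matrix(p)) {
        list(matrix = as.vector(p), nrow = nrow(p), ncol = ncol(p))
      } else {
        as.vector(p)
      }
    }
    out <- list(model = gr$model, id = gr$id)
    if (gr$kind == "synapse") {
      out$source <- gr$source
      out$target <- gr$target
    } else {
      out$n <- gr$n
    }
    if (!identical(gr$delay, 0)) out$delay <- gr$delay
    if (length(params) > 0) out$params <- params
    out
  })
  cfg <- list(
    groups = unname(groups),
    ports = list(input = net_input_id(net), output = net_output_id(net))
  )
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path, precision = 15L)
  }
  cfg
}

#' @rdname network_to_config
#' @export
network_from_config <- function(net, path = NULL) {
  cfg <- if (is.character(net)) yaml::read_yaml(net) else net
  if (!is.null(path)) cfg <- yaml::read_yaml(path)
  out <- new_network()
  for (g in cfg$groups) {
    params <- g$params %||% list()
    for (nm in names(params)) {
      p <- params[[nm]]
      if (is.list(p) && !is.null(p$matrix)) {
        params[[nm]] <- matrix(unlist(p$matrix), p$nrow, p$ncol)
      } else {
        params[[nm]] <- unlist(p)
      }
    }
    out <- do.call(add_group, c(
      list(
        net = out, model = g$model, id = g$id, n = g$n,
        source = g$source, target = g$target, delay = g$delay %||% 0
      ),
      params
    ))
  }
  if (!is.null(cfg$ports)) {
    out <- set_ports(out, input = cfg$ports$input, output = cfg$ports$output)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
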