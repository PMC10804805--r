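#' Resolve a parameter specification to a numeric array
#'
#' Group parameters may be given as scalars, arrays, or *generator functions*.
#' A generator receives `(batch_size, shape, rng)` — `rng` being a seed
#' integer for the parameter's private sub-stream — and must return an array
#' broadcastable to `[batch_size, shape...]`. This is how, for example, a
#' membrane time constant can be swept across the parallel batch simulations
#' (10 ms for batch 1, 20 ms for batch 2, ...).
#'
#' Accepted return/input shapes for a group of component shape `shape`:
#' a single scalar; an array shaped `shape` (shared across the batch); or an
#' array shaped `c(batch_size, shape)` (per-batch values). A plain vector of
#' length `prod(shape)` is taken as `shape`-shaped.
#'
#' @param spec Scalar, numeric array, or `function(batch_size, shape, rng)`.
#' @param batch_size Number of parallel simulations (>= 1).
#' @param shape Integer vector: component shape of the owning group
#'   (`n` for neurons, `c(n_src, n_tgt)` for synapses).
#' @param rng Integer seed for the parameter's sub-stream (see
#'   [substream_seed()]); generator functions are called exactly once under
#'   this seed and are therefore deterministic given the seed.
#' @param group,name Identifiers used in error messages.
#' @return The resolved numeric value: scalar, `shape` array, or
#'   `c(batch_size, shape)` array.
#' @export
#' @examples
#' resolve_param(0.5, batch_size = 4, shape = 3)
#' gen <- function(batch_size, shape, rng) 10 * seq_len(batch_size)
#' resolve_param(gen, batch_size = 10, shape = 1)
resolve_param <- function(spec, batch_size, shape, rng = 0L,
                          group = "?", name = "?") {
  stopifnot(batch_size >= 1)
  shape <- as.integer(shape)
  if (is.function(spec)) {
    value <- with_substream(rng, c(group, name), spec(batch_size, shape, rng))
  } else {
    value <- spec
  }
  if (!is.numeric(value)) {
    stop(sprintf(
      "parameter '%s' of group '%s' did not resolve to a numeric value",
      name, group
    ), call. = FALSE)
  }
  n_comp <- prod(shape)
  if (length(value) == 1L) {
    return(as.double(value))
  }
  d <- dim(value)
  if (is.null(d)) {
    if (length(value) == n_comp) {
      return(array(as.double(value), shape))
    }
    if (length(value) == batch_size && length(shape) == 1L && shape == 1L) {
      return(array(as.double(value), c(batch_size, 1L)))
    }
  } else {
    if (length(d) == length(shape) && all(d == shape)) {
      return(array(as.double(value), shape))
    }
    if (length(d) == length(shape) + 1L && d[1] == batch_size &&
      all(d[-1] == shape)) {
      return(array(as.double(value), c(batch_size, shape)))
    }
  }
  stop(sprintf(
    paste0(
      "parameter '%s' of group '%s' is not broadcastable to ",
      "[batch=%d, %s]: got length %d%s"
    ),
    name, group, batch_size, paste(shape, collapse = "x"),
    length(value),
    if (is.null(d)) "" else sprintf(" with dim [%s]", paste(d, collapse = ","))
  ), call. = FALSE)
}

# Broadcast a resolved parameter against per-element arrays of dim
# c(B, shape). Scalars stay scalar (fast path); shape-arrays are expanded
# over the batch axis once at init time.
bcast_full <- function(value, batch_size, shape) {
  if (length(value) == 1L) {
    return(value)
  }
  d <- dim(value)
  if (length(d) == length(shape) && all(d == shape)) {
    return(array(rep(value, each = batch_size), c(batch_size, shape)))
  }
  array(value, c(batch_size, shape))
}

# TRUE when a resolved parameter carries a batch axis.
param_has_batch <- function(value, shape) {
  d <- dim(value)
  !is.null(d) && length(d) == length(shape) + 1L
}
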