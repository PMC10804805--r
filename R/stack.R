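#' Compute the execution stack of a network
#'
#' The clock-driven engine evaluates all groups once per time-step, in a
#' fixed linear order (the *stack*). For feedforward networks any
#' topological order works; for recurrent topologies some connection must
#' point "backwards" in the order, and its target then reads the value the
#' source wrote in the *previous* engine step (one implicit step of
#' latency).
#'
#' The order is chosen by enumerating candidate permutations and scoring
#' each with the delay-substituted directed adjacency matrix (DAM): entry
#' `[r, c]` holds the connection delay from the group at position `r` to the
#' group at position `c`, and `-eps` (a negative infinitesimal,
#' `1e-9 * dt`) for non-connections, so that zero-valued delays remain
#' distinguishable from absent connections. The permutation minimizing the
#' lower-triangular sum (LTS) wins; ties go to the earliest permutation in
#' lexicographic order over the order groups were added. Orderings are
#' never rejected: when a connection with a zero-step delay lands in the
#' lower triangle it simply carries the one implicit engine step of latency,
#' and a warning reports it. Connections with a positive delay absorb the
#' implicit step into their delay budget (see [allocate_buffers()]), so
#' their delivery time is exact wherever they land.
#'
#' Exhaustive enumeration covers up to 8 groups (40,320 orders); larger
#' networks must opt into a greedy heuristic (iterated topological sort,
#' breaking cycles at the largest-delay back edge).
#'
#' @param net Network object.
#' @param dt Engine time-step size (used to scale `eps` and to discretize
#'   delays for the zero-delay warning).
#' @param heuristic Allow the greedy ordering for networks of more than 8
#'   groups.
#' @return An object of class `"snn_stack"`: `order` (group ids), `dam`
#'   (the delay-substituted DAM of the chosen order), `lts`, `eps`.
#' @export
compute_stack <- function(net, dt = 1, heuristic = FALSE) {
  ids <- names(net$groups)
  n <- length(ids)
  if (n == 0) stop("network is empty", call. = FALSE)
  edges <- net_edges(net)
  eps <- 1e-9 * dt
  from <- vapply(edges, function(e) match(e$from, ids), 1L)
  to <- vapply(edges, function(e) match(e$to, ids), 1L)
  delay <- vapply(edges, function(e) as.double(e$delay), 1)

  if (n > 8L && !heuristic) {
    stop(
      "more than 8 groups: exhaustive ordering is disabled; ",
      "call with heuristic = TRUE to use greedy ordering",
      call. = FALSE
    )
  }

  if (n > 8L) {
    perm <- greedy_order(n, from, to, delay)
    best <- lts_of_perm(perm, from, to, delay, eps, n)
  } else {
    perms <- perms_lex(n)
    best <- Inf
    perm <- perms[1L, ]
    for (r in seq_len(nrow(perms))) {
      v <- lts_of_perm(perms[r, ], from, to, delay, eps, n)
      if (is.infinite(best) || v < best - 1e-15 * max(1, abs(best))) {
        best <- v
        perm <- perms[r, ]
      }
    }
  }

  pos <- integer(n)
  pos[perm] <- seq_len(n)
  zero_feedback <- which(pos[from] > pos[to] & round(delay / dt) == 0)
  if (length(zero_feedback) > 0) {
    warning(sprintf(
      paste0(
        "zero-delay connection(s) %s fall in the lower triangle of the ",
        "stack and will carry one engine step of implicit latency"
      ),
      paste(sprintf(
        "%s->%s", ids[from[zero_feedback]], ids[to[zero_feedback]]
      ), collapse = ", ")
    ), call. = FALSE)
  }

  dam <- matrix(-eps, n, n, dimnames = list(ids[perm], ids[perm]))
  diag(dam) <- 0
  for (e in seq_along(from)) {
    dam[pos[from[e]], pos[to[e]]] <- delay[e]
  }
  structure(
    list(order = ids[perm], dam = dam, lts = best, eps = eps, dt = dt),
    class = "snn_stack"
  )
}

#' @export
print.snn_stack <- function(x, ...) {
  cat(sprintf(
    "<snn_stack: %s  (LTS = %g)>\n",
    paste(x$order, collapse = " -> "), x$lts
  ))
  invisible(x)
}

# LTS of one permutation: sum of lower-triangular connection delays plus
# -eps for each of the remaining lower-triangular (non-connection) cells.
lts_of_perm <- function(perm, from, to, delay, eps, n) {
  pos <- integer(n)
  pos[perm] <- seq_len(n)
  lower <- pos[from] > pos[to]
  sum(delay[lower]) - eps * (n * (n - 1) / 2 - sum(lower))
}

# All permutations of 1..n in lexicographic order (rows).
perms_lex <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- perms_lex(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Greedy ordering for large networks: Kahn's topological sort; when stuck in
# a cycle, drop the remaining edge with the largest delay (it is the
# cheapest to push into the lower triangle), preferring earlier-added nodes.
greedy_order <- function(n, from, to, delay) {
  alive <- rep(TRUE, length(from))
  remaining <- rep(TRUE, n)
  order <- integer(0)
  while (length(order) < n) {
    indeg <- integer(n)
    for (e in which(alive)) {
      if (remaining[from[e]] && remaining[to[e]]) {
        indeg[to[e]] <- indeg[to[e]] + 1L
      }
    }
    ready <- which(remaining & indeg == 0L)
    if (length(ready) > 0) {
      nxt <- ready[1L]
      order <- c(order, nxt)
      remaining[nxt] <- FALSE
    } else {
      cand <- which(alive & remaining[from] & remaining[to])
      drop <- cand[which.max(delay[cand])]
      alive[drop] <- FALSE
    }
  }
  order
}

#' Plan the engine's temporary-storage buffers
#'
#' One storage slot (a short ring buffer over recent time-steps) is
#' pre-allocated per group output; every reader's input address aliases its
#' source's output slot, so per-step I/O reduces to indexed reads and one
#' write per group. The read offset (in steps) of each connection is
#' `round(delay/dt)`, raised to 1 for feedback (lower-triangular) reads:
#' the implicit step of a feedback read realizes the first step of the
#' delay, and a zero-delay feedback connection therefore observes the value
#' written in the previous engine step — the defined recurrence semantics.
#'
#' @param stack A stack from [compute_stack()].
#' @param net The network the stack was computed for.
#' @param dt Engine time-step size.
#' @return An object of class `"snn_buffer_plan"`: `slots` (data.frame of
#'   id, output width, ring length) and `read_map` (per group, its source
#'   slots and read offsets).
#' @export
allocate_buffers <- function(stack, net, dt = stack$dt) {
  ids <- names(net$groups)
  pos <- match(ids, stack$order)
  names(pos) <- ids
  read_map <- stats::setNames(vector("list", length(ids)), ids)
  max_off <- stats::setNames(integer(length(ids)), ids)
  for (e in net_edges(net)) {
    steps <- as.integer(round(e$delay / dt))
    feedback <- pos[e$from] > pos[e$to]
    offset <- max(steps, if (feedback) 1L else 0L)
    read_map[[e$to]] <- c(read_map[[e$to]], list(list(
      src = e$from, offset = offset, feedback = feedback
    )))
    max_off[e$from] <- max(max_off[e$from], offset)
  }
  slots <- data.frame(
    id = ids,
    n_out = vapply(ids, function(g) group_out_n(net, g), 1L),
    len = pmax(1L, max_off + 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(slots = slots, read_map = read_map),
    class = "snn_buffer_plan"
  )
}
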