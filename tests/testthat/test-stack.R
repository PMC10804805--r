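two_layer_loop <- function(d_Ix, d_xO, d_Oy, d_yI) {
  # input layer I and output layer O, bidirectionally coupled by synapse
  # groups x (I -> O) and y (O -> I); delays sit on the outgoing edges
  net <- new_network()
  net <- add_group(net, "input", "I", n = 1, delay = d_Ix)
  net <- add_group(net, "li", "O", n = 1, tau_beta = 10, delay = d_Oy)
  net <- add_group(net, "ls1", "x",
    source = "I", target = "O",
    tau_alpha = 5, w = 1, delay = d_xO
  )
  net <- add_group(net, "ls1", "y",
    source = "O", target = "I",
    tau_alpha = 5, w = 1, delay = d_yI
  )
  set_ports(net, input = "I", output = "O")
}

test_that("a feedforward chain is stacked in topological order", {
  net <- new_network()
  net <- add_group(net, "input", "in", n = 2)
  net <- add_group(net, "li", "out", n = 2, tau_beta = 10)
  net <- add_group(net, "ls1", "s",
    source = "in", target = "out",
    tau_alpha = 5, w = 1
  )
  st <- compute_stack(net, dt = 1)
  expect_lt(match("in", st$order), match("s", st$order))
  expect_lt(match("s", st$order), match("out", st$order))
  # no connection entry in the lower triangle: LTS is pure -eps filler
  expect_equal(st$lts, -3 * st$eps, tolerance = 1e-20)
})

test_that("delay substitution ranks the orders of the two-layer loop", {
  # every order must break the cycle somewhere; with zero-delay connections
  # present the minimum puts exactly one of them in the lower triangle
  # (0 - 5 eps beats any positive-delay break). Frozen from oracle_stack.
  net1 <- two_layer_loop(0, 1, 0, 3)
  ref1 <- oracle_stack(net1, dt = 1)
  st1 <- suppressWarnings(compute_stack(net1, dt = 1))
  expect_identical(st1$order, ref1$order)
  expect_equal(st1$lts, ref1$lts, tolerance = 1e-20)
  expect_identical(ref1$order, c("x", "O", "y", "I"))
  expect_equal(ref1$lts, -5e-9, tolerance = 1e-20)

  net2 <- two_layer_loop(0, 2, 0, 0)
  ref2 <- oracle_stack(net2, dt = 1)
  st2 <- suppressWarnings(compute_stack(net2, dt = 1))
  expect_identical(st2$order, ref2$order)
  expect_identical(ref2$order, c("I", "x", "O", "y"))
  expect_equal(ref2$lts, -5e-9, tolerance = 1e-20)

  # with no zero-delay edges the smallest positive delay is pushed back:
  # breaking at x (delay 1) beats breaking at y (delay 3)
  net3 <- two_layer_loop(1, 1, 1, 3)
  ref3 <- oracle_stack(net3, dt = 1)
  st3 <- compute_stack(net3, dt = 1)
  expect_identical(st3$order, ref3$order)
  expect_identical(ref3$order, c("O", "y", "I", "x"))
  expect_equal(ref3$lts, 1 - 5e-9, tolerance = 1e-20)
})

test_that("zero-delay feedback is reported as implicit latency", {
  expect_warning(
    compute_stack(two_layer_loop(0, 0, 0, 0), dt = 1),
    "implicit latency"
  )
})

test_that("compute_stack matches the exhaustive oracle on random networks", {
  for (k in 1:200) {
    n_neuron <- sample(2:3, 1)
    n_syn <- sample(1:3, 1)
    net <- random_small_net(n_neuron, n_syn, seed = 1000 + k)
    ref <- oracle_stack(net, dt = 1)
    st <- suppressWarnings(compute_stack(net, dt = 1))
    expect_equal(st$lts, ref$lts, tolerance = 1e-18)
    expect_identical(st$order, ref$order)
  }
})

test_that("any DAG is stacked with zero connection contribution to the LTS", {
  for (k in 1:30) {
    set.seed(2000 + k)
    n_layers <- sample(2:4, 1)
    net <- new_network()
    for (l in seq_len(n_layers)) {
      net <- add_group(net, "li", paste0("n", l), n = 1, tau_beta = 10)
    }
    s <- 0
    for (l in seq_len(n_layers - 1)) {
      for (m in (l + 1):n_layers) {
        if (s < 8 - n_layers && runif(1) < 0.7) {
          s <- s + 1
          net <- add_group(net, "ls1", paste0("s", s),
            source = paste0("n", l), target = paste0("n", m),
            tau_alpha = 5, w = 0.1, delay = sample(0:3, 1)
          )
        }
      }
    }
    if (s == 0) next
    st <- compute_stack(net, dt = 1)
    n_g <- length(net$groups)
    # all lower-triangular cells hold the -eps non-connection filler
    expect_equal(st$lts, -st$eps * n_g * (n_g - 1) / 2, tolerance = 1e-18)
  }
})

test_that("large networks require the explicit greedy-ordering flag", {
  net <- new_network()
  for (k in 1:9) {
    net <- add_group(net, "li", paste0("n", k), n = 1, tau_beta = 10)
  }
  expect_error(compute_stack(net, dt = 1), "heuristic")
  st <- compute_stack(net, dt = 1, heuristic = TRUE)
  expect_setequal(st$order, paste0("n", 1:9))
  # a feedforward chain of 9 groups + synapses stays topological
  net2 <- new_network()
  for (k in 1:5) {
    net2 <- add_group(net2, "li", paste0("n", k), n = 1, tau_beta = 10)
  }
  for (k in 1:4) {
    net2 <- add_group(net2, "ls1", paste0("s", k),
      source = paste0("n", k), target = paste0("n", k + 1),
      tau_alpha = 5, w = 1
    )
  }
  st2 <- compute_stack(net2, dt = 1, heuristic = TRUE)
  lower <- st2$dam[lower.tri(st2$dam)]
  expect_true(all(lower < 0))
})

test_that("buffer planning aliases one slot per group with feedback offsets", {
  net <- two_layer_loop(0, 1, 0, 3)
  st <- suppressWarnings(compute_stack(net, dt = 1))
  plan <- allocate_buffers(st, net, dt = 1)
  expect_identical(nrow(plan$slots), length(net$groups))
  # each reader's slot is its source's write slot
  expect_identical(
    vapply(plan$read_map[["O"]], function(r) r$src, ""), "x"
  )
  expect_identical(
    vapply(plan$read_map[["x"]], function(r) r$src, ""), "I"
  )
  pos <- match(c("I", "O", "x", "y"), st$order)
  names(pos) <- c("I", "O", "x", "y")
  for (id in names(plan$read_map)) {
    for (rd in plan$read_map[[id]]) {
      steps <- round(net$groups[[rd$src]]$delay / 1)
      expected <- max(steps, if (pos[rd$src] > pos[id]) 1L else 0L)
      expect_identical(rd$offset, as.integer(expected))
    }
  }
})

test_that("a feedback reader observes the previous-step value", {
  # 2-group loop: relay reads its own output back through a synapse with
  # unit weight and no integration decay worth tracking; hand-stepped.
  net <- new_network()
  net <- add_group(net, "input", "a", n = 1)
  net <- add_group(net, "ls1", "s",
    source = "a", target = "a",
    tau_alpha = 5, w = 1
  )
  net <- set_ports(net, input = "a", output = "a")
  sim <- suppressWarnings(init_network(net, dt = 1, batch_size = 1, seed = 0))
  set_monitor(sim, "s", "O")
  x <- array(0, c(1, 6, 1))
  x[1, 1, 1] <- 1
  y <- run_network(sim, x)
  # hand-stepped oracle: a(t) = x(t) + s_out(t-1) (feedback, one step late);
  # s sees a(t) same-step, outputs phi * I(t) * a2 from pre-update state
  a1 <- exp(-1 / 5)
  a2 <- 5 * (1 - a1)
  a_ref <- numeric(6)
  s_ref <- numeric(6)
  I <- 0
  s_prev <- 0
  for (t in 1:6) {
    a_ref[t] <- x[1, t, 1] + s_prev
    s_ref[t] <- I * a2
    I <- I * a1 + a_ref[t]
    s_prev <- s_ref[t]
  }
  expect_equal(as.vector(unclass(y)), a_ref, tolerance = 1e-12)
  expect_equal(
    as.vector(get_monitored_results(sim, "s", "O")), s_ref,
    tolerance = 1e-12
  )
})
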