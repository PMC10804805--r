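test_that("the surrogate keeps the exact forward and the stated backward", {
  expect_identical(surrogate_spike(1, theta = 1), 1)
  expect_identical(surrogate_spike(1 - 1e-6, theta = 1), 0)
  expect_identical(surrogate_grad(1, theta = 1, beta = 5), 1)
  for (beta in c(1, 10, 50)) {
    expect_equal(surrogate_grad(1 + 1 / beta, 1, beta), 1 / 4, tolerance = 1e-12)
    expect_equal(surrogate_grad(1 - 1 / beta, 1, beta), 1 / 4, tolerance = 1e-12)
  }
  expect_error(surrogate_grad(0, 1, beta = -1))
})

test_that("readout logits are the per-neuron membrane maxima", {
  u <- array(0, c(2, 10, 2))
  u[1, , 1] <- seq(0, 0.9, length.out = 10) # monotone: final value
  u[1, 7, 2] <- 0.9 # interior peak
  u[2, , 1] <- -(1:10)
  logits <- readout_logits(u)
  expect_equal(logits[1, 1], 0.9)
  expect_equal(logits[1, 2], 0.9)
  expect_identical(attr(logits, "which")[1, 2], 7L)
  expect_equal(logits[2, 1], -1)
})

test_that("the log-likelihood loss has the textbook limits", {
  expect_equal(nll_loss(matrix(0, 3, 10), c(1L, 5L, 10L)), log(10),
    tolerance = 1e-12
  )
  hot <- matrix(0, 2, 4)
  hot[cbind(1:2, c(2L, 3L))] <- 50
  expect_lt(nll_loss(hot, c(2L, 3L)), 1e-12)
  # permuting the class order leaves the scalar unchanged
  set.seed(2)
  z <- matrix(rnorm(12), 3, 4)
  y <- c(2L, 4L, 1L)
  perm <- sample(4)
  expect_equal(nll_loss(z, y), nll_loss(z[, perm], match(y, perm)),
    tolerance = 1e-12
  )
  expect_error(nll_loss(z, c(0L, 1L, 2L)), "out of range")
})

test_that("BPTT gradients match central finite differences on the readout", {
  net <- toy_readout_net(seed = 1)
  sim <- init_network(net, dt = 1, batch_size = 2, seed = 0)
  pm <- pair_trainer(sim, "syn")
  T_run <- 30
  b <- 2
  set.seed(5)
  x <- array(rbinom(b * T_run * 4, 1, 0.2), c(b, T_run, 4))
  labels <- c(1L, 3L)
  bound <- list("in" = x)
  ctx <- snnsim:::tail_context(pm, b)
  res <- snnsim:::tail_loss_grad(pm, ctx, T_run, b, bound, NULL, labels)
  g <- res$gw$syn
  eps <- 1e-6
  fd <- matrix(0, 4, 3)
  for (i in 1:4) {
    for (j in 1:3) {
      wp <- pm$weights
      wp$syn[i, j] <- wp$syn[i, j] + eps
      wm <- pm$weights
      wm$syn[i, j] <- wm$syn[i, j] - eps
      lp <- snnsim:::tail_loss_grad(pm, ctx, T_run, b, bound, NULL, labels,
        weights = wp, gradient = FALSE
      )$loss
      lm <- snnsim:::tail_loss_grad(pm, ctx, T_run, b, bound, NULL, labels,
        weights = wm, gradient = FALSE
      )$loss
      fd[i, j] <- (lp - lm) / (2 * eps)
    }
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
})

test_that("pairing validates the trainable set and the readout model", {
  net <- toy_readout_net()
  sim <- init_network(net, dt = 1, batch_size = 2, seed = 0)
  expect_error(pair_trainer(sim, "out"), "not a synaptic group")
  # spiking output port is rejected with a pointer to LI
  net2 <- new_network()
  net2 <- add_group(net2, "input", "in", n = 2)
  net2 <- add_group(net2, "lif", "out", n = 2, tau_beta = 20)
  net2 <- add_group(net2, "ls1", "s",
    source = "in", target = "out",
    tau_alpha = 8, w = 0.1
  )
  net2 <- set_ports(net2, "in", "out")
  sim2 <- init_network(net2, dt = 1, batch_size = 1, seed = 0)
  expect_error(pair_trainer(sim2, "s"), "non-spiking \\(li\\)")
})

test_that("only paired weight groups receive gradients and updates", {
  set.seed(3)
  net <- new_network()
  net <- add_group(net, "input", "in", n = 6)
  net <- add_group(net, "lif", "hid", n = 8, tau_beta = 30, theta = 1)
  net <- add_group(net, "li", "out", n = 2, tau_beta = 30)
  net <- add_group(net, "ls1", "s1",
    source = "in", target = "hid",
    tau_alpha = 8, w = matrix(runif(48, 0, 0.2), 6, 8)
  )
  net <- add_group(net, "ls1", "s2",
    source = "hid", target = "out",
    tau_alpha = 8, w = matrix(runif(16, -0.1, 0.1), 8, 2)
  )
  net <- set_ports(net, "in", "out")
  sim <- init_network(net, dt = 1, batch_size = 4, seed = 0)
  pm <- pair_trainer(sim, "s2")
  ds <- gen_rate_classes(
    n_classes = 2, n_channels = 6, n_per_class = 8,
    n_steps = 40, seed = 31
  )
  fit <- train_snn(pm, ds, epochs = 2, batch_size = 4, lr = 1e-2, seed = 1)
  expect_identical(names(fit$weights), "s2")
  # the frozen group's stored weights are untouched
  expect_identical(get_weights(fit$pm$net, "s1"), get_weights(net, "s1"))
  expect_false(identical(fit$weights$s2, pm$weights$s2))
})

test_that("zero learning rate leaves weights and accuracy unchanged", {
  net <- toy_readout_net(seed = 2)
  sim <- init_network(net, dt = 1, batch_size = 4, seed = 0)
  pm <- pair_trainer(sim, "syn")
  ds <- gen_rate_classes(
    n_classes = 3, n_channels = 4, n_per_class = 6,
    n_steps = 30, seed = 17
  )
  fit <- train_snn(pm, ds, epochs = 3, batch_size = 4, lr = 0, seed = 1)
  expect_identical(fit$weights$syn, pm$weights$syn)
  expect_equal(
    fit$history$train_acc,
    rep(fit$history$train_acc[1], 3)
  )
})

test_that("the training-time forward pass equals plain inference exactly", {
  # spiking hidden layer: surrogate machinery must not alter the forward
  set.seed(9)
  net <- new_network()
  net <- add_group(net, "input", "in", n = 5)
  net <- add_group(net, "lif", "hid", n = 7, tau_beta = 25, theta = 0.8)
  net <- add_group(net, "li", "out", n = 3, tau_beta = 25)
  net <- add_group(net, "ls2", "s1",
    source = "in", target = "hid",
    tau_alpha_plus = 15, tau_alpha_minus = 5,
    w = matrix(runif(35, 0, 0.15), 5, 7)
  )
  net <- add_group(net, "ls1", "s2",
    source = "hid", target = "out",
    tau_alpha = 8, w = matrix(runif(21, -0.1, 0.1), 7, 3)
  )
  net <- set_ports(net, "in", "out")
  b <- 3
  T_run <- 50
  x <- array(rbinom(b * T_run * 5, 1, 0.25), c(b, T_run, 5))
  sim <- init_network(net, dt = 1, batch_size = b, seed = 0)
  set_monitor(sim, "hid", "O")
  y_engine <- run_network(sim, x)
  hid_engine <- get_monitored_results(sim, "hid", "O")
  pm <- pair_trainer(sim, c("s1", "s2"))
  ctx <- snnsim:::tail_context(pm, b)
  fwd <- snnsim:::tail_forward(pm, ctx, T_run, b, bound = list("in" = x))
  expect_identical(fwd$rec_out$out, array(unclass(y_engine), dim(y_engine)))
  expect_identical(fwd$rec_out$hid, hid_engine)
})

test_that("loss decreases on a separable task for a majority of seeds", {
  wins <- 0L
  for (s in 1:3) {
    net <- toy_readout_net(seed = s)
    sim <- init_network(net, dt = 1, batch_size = 6, seed = 0)
    pm <- pair_trainer(sim, "syn")
    ds <- gen_rate_classes(
      n_classes = 3, n_channels = 4, n_per_class = 10,
      n_steps = 40, seed = 100 + s
    )
    fit <- train_snn(pm, ds, epochs = 6, batch_size = 6, lr = 5e-3, seed = s)
    if (fit$history$loss[6] < fit$history$loss[1]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("training through a spiking hidden layer reaches the easy task", {
  set.seed(2)
  ds <- gen_rate_classes(
    n_classes = 2, n_channels = 8, n_per_class = 20,
    n_steps = 60, seed = 9
  )
  net <- new_network()
  net <- add_group(net, "input", "in", n = 8)
  net <- add_group(net, "lif", "hid", n = 12, tau_beta = 30, theta = 1)
  net <- add_group(net, "li", "out", n = 2, tau_beta = 30)
  net <- add_group(net, "ls2", "s1",
    source = "in", target = "hid",
    tau_alpha_plus = 15, tau_alpha_minus = 5,
    w = matrix(runif(96, -0.04, 0.06), 8, 12)
  )
  net <- add_group(net, "ls1", "s2",
    source = "hid", target = "out",
    tau_alpha = 8, w = matrix(runif(24, -0.1, 0.1), 12, 2)
  )
  net <- set_ports(net, "in", "out")
  sim <- init_network(net, dt = 1, batch_size = 8, seed = 0)
  pm <- pair_trainer(sim, c("s1", "s2"))
  fit <- train_snn(pm, ds, epochs = 15, batch_size = 8, lr = 5e-3, seed = 3)
  expect_gte(fit$history$train_acc[15], 0.9)
})
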