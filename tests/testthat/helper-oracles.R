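# Independent single-component reference implementations and brute-force
# oracles used by the property tests. These deliberately share no code with
# the package's vectorized models.

# scalar LIF trajectory: returns list(u, spikes) over the input drive
scalar_lif <- function(S, tau_beta, theta = 1, u_r = 0, rho = 0, dt = 1) {
  n <- length(S)
  u <- numeric(n)
  spikes <- numeric(n)
  u_cur <- u_r
  gate <- 1
  tss <- rho
  for (t in seq_len(n)) {
    u_new <- u_cur * exp(-dt / tau_beta) + gate * S[t]
    if (u_new >= theta) {
      spikes[t] <- 1
      u_new <- u_r
      gate <- if (rho > 0) 0 else 1
      tss <- 0
    } else {
      tss <- tss + dt
      if (tss >= rho) gate <- 1
    }
    u[t] <- u_new
    u_cur <- u_new
  }
  list(u = u, spikes = spikes)
}

scalar_li <- function(S, tau_beta, dt = 1) {
  u <- numeric(length(S))
  u_cur <- 0
  for (t in seq_along(S)) {
    u_cur <- u_cur * exp(-dt / tau_beta) + S[t]
    u[t] <- u_cur
  }
  u
}

scalar_izh <- function(S, a = 0.02, b = 0.2, cc = -65, d = 8, theta = 30,
                       h = 1) {
  k <- ceiling(1 / h)
  v <- cc
  u <- b * cc
  vs <- numeric(length(S))
  spikes <- numeric(length(S))
  for (t in seq_along(S)) {
    for (s in seq_len(k)) {
      v1 <- v + h * (0.04 * v * v + 5 * v + 140 - u + S[t])
      u <- (1 - h * a) * u + h * a * b * v
      v <- v1
    }
    if (v >= theta) {
      spikes[t] <- 1
      v <- cc
      u <- u + d
    }
    vs[t] <- v
  }
  list(v = vs, spikes = spikes)
}

# scalar first-order leaky synapse (single source/target pair)
scalar_ls1 <- function(spikes, tau_alpha, w, phi = 1, dt = 1) {
  a1 <- exp(-dt / tau_alpha)
  a2 <- tau_alpha * (1 - a1)
  I <- 0
  O <- numeric(length(spikes))
  for (t in seq_along(spikes)) {
    O[t] <- phi * I * a2
    I <- I * a1 + w * spikes[t]
  }
  O
}

# Brute-force stack oracle: enumerates every permutation (in lexicographic
# order over the group add order), builds the delay-substituted DAM as a
# literal matrix, and returns the first order attaining the minimal
# lower-triangular sum. Mirrors the ranking rule, not the package code.
oracle_stack <- function(net, dt = 1) {
  ids <- names(net$groups)
  n <- length(ids)
  edges <- list()
  for (gr in net$groups) {
    if (gr$kind == "synapse") {
      edges <- c(edges, list(
        c(gr$source, gr$id, net$groups[[gr$source]]$delay),
        c(gr$id, gr$target, gr$delay)
      ))
    }
  }
  eps <- 1e-9 * dt
  all_perms <- function(v) {
    if (length(v) <= 1) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  best <- Inf
  best_order <- NULL
  for (ord in all_perms(ids)) {
    dam <- matrix(-eps, n, n, dimnames = list(ord, ord))
    diag(dam) <- 0
    for (e in edges) {
      dam[e[1], e[2]] <- as.numeric(e[3])
    }
    lts <- sum(dam[lower.tri(dam)])
    if (lts < best - 1e-12) {
      best <- lts
      best_order <- ord
    }
  }
  list(order = best_order, lts = best)
}

# random small network (neuron groups + random synapses, random delays)
random_small_net <- function(n_neuron, n_syn, seed, p_zero_delay = 0.5) {
  set.seed(seed)
  net <- new_network()
  for (k in seq_len(n_neuron)) {
    net <- add_group(net, "li", paste0("n", k), n = 1, tau_beta = 10)
  }
  for (k in seq_len(n_syn)) {
    src <- sample(n_neuron, 1)
    tgt <- sample(n_neuron, 1)
    dly <- if (stats::runif(1) < p_zero_delay) 0 else sample(1:4, 1)
    net <- add_group(net, "ls1", paste0("s", k),
      source = paste0("n", src), target = paste0("n", tgt),
      tau_alpha = 5, w = 0.1, delay = dly
    )
  }
  set_ports(net, input = "n1", output = paste0("n", n_neuron))
}

# readout-only toy network used by the gradient tests
toy_readout_net <- function(seed = 1) {
  set.seed(seed)
  net <- new_network()
  net <- add_group(net, "input", "in", n = 4)
  net <- add_group(net, "li", "out", n = 3, tau_beta = 20)
  net <- add_group(net, "ls1", "syn",
    source = "in", target = "out",
    tau_alpha = 8, w = matrix(stats::rnorm(12, 0, 0.2), 4, 3)
  )
  set_ports(net, "in", "out")
}

# small LSM classification task under one master seed; returns fitted model
# and the splits (used by trainer tests and acceptance)
small_lsm_task <- function(seed, epochs = 30) {
  ds <- gen_rate_classes(
    n_classes = 3, n_channels = 20, n_per_class = 80,
    n_steps = 100, dt = 1, rate_active = 100, rate_background = 5,
    seed = seed
  )
  sp <- split_dataset(ds, 0.85, seed = seed)
  net <- build_lsm(
    n_in = 20, n_res = 60, n_out = 3, nnz_in = 160, nnz_res = 600,
    seed = seed + 1000
  )
  sim <- suppressWarnings(init_network(net, dt = 1, batch_size = 16, seed = seed))
  pm <- pair_trainer(sim, "syn_out")
  fit <- train_snn(pm, sp$train, sp$test,
    epochs = epochs, batch_size = 16,
    lr = 1e-3, seed = seed
  )
  list(fit = fit, train = sp$train, test = sp$test)
}
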