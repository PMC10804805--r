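lif_one <- function(u0, S, tau_beta = 64, theta = 1, u_r = 0, rho = 0, dt = 1) {
  m <- model_lif()
  p <- list(tau_beta = tau_beta, theta = theta, u_r = u_r, rho = rho)
  cache <- m$time_dep(p, dt, 1, 1)
  st <- list(
    u = matrix(u0, 1, 1), Pi = matrix(1, 1, 1),
    t_since_spike = matrix(rho, 1, 1)
  )
  m$step(st, matrix(S, 1, 1), p, cache)
}

test_that("the LIF update matches its closed-form one-step solution", {
  # u' = u exp(-dt/tau) + S, evaluated directly
  r <- lif_one(0.5, 0.1)
  expect_equal(as.vector(r$state$u), 0.5 * exp(-1 / 64) + 0.1,
    tolerance = 1e-12
  )
  expect_equal(as.vector(r$state$u), 0.592248, tolerance = 1e-6)
  expect_identical(as.vector(r$output), 0)

  # 0.99 exp(-1/64) + 0.2 = 1.174652 >= theta: spike, reset to u_r
  r2 <- lif_one(0.99, 0.2)
  expect_true(0.99 * exp(-1 / 64) + 0.2 >= 1)
  expect_identical(as.vector(r2$output), 1)
  expect_identical(as.vector(r2$state$u), 0)

  # equality spikes (threshold comparison is >=)
  m <- model_lif()
  p <- list(tau_beta = 64, theta = 1, u_r = 0, rho = 0)
  cache <- m$time_dep(p, 1, 1, 1)
  st <- list(
    u = matrix(0, 1, 1), Pi = matrix(1, 1, 1),
    t_since_spike = matrix(0, 1, 1)
  )
  expect_identical(as.vector(m$step(st, matrix(1, 1, 1), p, cache)$output), 1)
})

test_that("a resting LIF with zero drive is a fixed point", {
  m <- model_lif()
  p <- list(tau_beta = 64, theta = 1, u_r = 0, rho = 0)
  cache <- m$time_dep(p, 1, 1, 1)
  st <- m$init_state(p, cache, 1, 1)
  for (t in 1:20) {
    r <- m$step(st, matrix(0, 1, 1), p, cache)
    st <- r$state
    expect_identical(as.vector(r$output), 0)
  }
  expect_identical(as.vector(st$u), 0)
})

test_that("time_dep caches are idempotent in dt", {
  m <- model_lif()
  p <- list(tau_beta = 64, theta = 1, u_r = 0, rho = 0)
  expect_identical(m$time_dep(p, 1, 4, 3), m$time_dep(p, 1, 4, 3))
  expect_equal(m$time_dep(p, 1, 1, 1)$decay, exp(-1 / 64), tolerance = 1e-12)
})

test_that("a vectorized LIF group reproduces per-component scalar runs", {
  set.seed(11)
  n <- 5
  T_run <- 60
  tau <- runif(n, 5, 50)
  theta <- runif(n, 0.5, 1.5)
  S <- matrix(runif(T_run * n, 0, 0.3), T_run, n)
  m <- model_lif()
  p <- list(
    tau_beta = matrix(tau, 1, n), theta = matrix(theta, 1, n),
    u_r = 0, rho = 0
  )
  cache <- m$time_dep(p, 1, 1, n)
  st <- m$init_state(p, cache, 1, n)
  u_grp <- matrix(0, T_run, n)
  s_grp <- matrix(0, T_run, n)
  for (t in seq_len(T_run)) {
    r <- m$step(st, matrix(S[t, ], 1, n), p, cache)
    st <- r$state
    u_grp[t, ] <- r$state$u
    s_grp[t, ] <- r$output
  }
  for (i in seq_len(n)) {
    ref <- scalar_lif(S[, i], tau[i], theta[i])
    expect_equal(u_grp[, i], ref$u, tolerance = 1e-12)
    expect_identical(s_grp[, i], ref$spikes)
  }
  expect_true(all(s_grp %in% c(0, 1)))
  expect_true(all(u_grp >= 0)) # S >= 0 and u_r = 0 keep u non-negative
})

test_that("the leaky integrator decays, converges, and never spikes", {
  m <- model_li()
  p <- list(tau_beta = 20)
  cache <- m$time_dep(p, 1, 1, 1)
  # pure decay from u = 1
  st <- list(u = matrix(1, 1, 1))
  r <- m$step(st, matrix(0, 1, 1), p, cache)
  expect_equal(as.vector(r$state$u), exp(-1 / 20), tolerance = 1e-12)
  # geometric-series fixed point under constant drive
  st <- m$init_state(p, cache, 1, 1)
  for (t in 1:2000) st <- m$step(st, matrix(0.3, 1, 1), p, cache)$state
  expect_equal(as.vector(st$u), 0.3 / (1 - exp(-1 / 20)), tolerance = 1e-9)
  # tau -> infinity limit: perfect integrator
  p2 <- list(tau_beta = 1e12)
  c2 <- m$time_dep(p2, 1, 1, 1)
  st <- m$init_state(p2, c2, 1, 1)
  for (t in 1:10) st <- m$step(st, matrix(0.1, 1, 1), p2, c2)$state
  expect_equal(as.vector(st$u), 1, tolerance = 1e-9)
  # output is the membrane itself
  expect_equal(
    as.vector(m$step(st, matrix(0, 1, 1), p2, c2)$output),
    as.vector(m$step(st, matrix(0, 1, 1), p2, c2)$state$u)
  )
})

test_that("the Izhikevich step evaluates the printed Euler update", {
  m <- model_izhikevich()
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, theta = 30, h = 1)
  cache <- m$time_dep(p, 1, 1, 1)
  # from (v, u) = (-65, -13): dv = 0.04*4225 - 325 + 140 + 13 = -3
  st <- list(v = matrix(-65, 1, 1), u = matrix(-13, 1, 1))
  r <- m$step(st, matrix(0, 1, 1), p, cache)
  expect_equal(as.vector(r$state$v), -68, tolerance = 1e-12)
  expect_equal(as.vector(r$state$u), 0.98 * (-13) + 0.02 * 0.2 * (-65),
    tolerance = 1e-12
  )
  expect_equal(as.vector(r$state$u), -13, tolerance = 1e-9)
  # rest fixed point: root of 0.04 v^2 + (5 - b) v + 140 = 0 at v = -70
  st0 <- list(v = matrix(-70, 1, 1), u = matrix(0.2 * -70, 1, 1))
  r0 <- m$step(st0, matrix(0, 1, 1), p, cache)
  expect_equal(as.vector(r0$state$v), -70, tolerance = 1e-9)
  expect_error(m$time_dep(list(h = 0), 1, 1, 1), "0 < h <= 1")
  expect_error(m$time_dep(list(h = 1.5), 1, 1, 1), "0 < h <= 1")
})

test_that("Izhikevich sub-step refinement converges at first order", {
  # halving h changes the one-step result by O(h) on the canonical set
  res <- vapply(c(1, 0.5, 0.25, 0.125), function(h) {
    r <- scalar_izh(rep(5, 1), h = h)
    r$v[1]
  }, 1)
  d1 <- abs(res[2] - res[1])
  d2 <- abs(res[3] - res[2])
  d3 <- abs(res[4] - res[3])
  expect_lt(d2, d1)
  expect_lt(d3, d2)
  expect_lt(d3, 0.75 * d2) # contraction consistent with O(h)
})

test_that("vectorized Izhikevich matches the scalar oracle", {
  set.seed(4)
  S <- runif(80, 0, 12)
  m <- model_izhikevich()
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, theta = 30, h = 0.5)
  cache <- m$time_dep(p, 1, 1, 1)
  st <- m$init_state(p, cache, 1, 1)
  v <- numeric(80)
  sp <- numeric(80)
  for (t in 1:80) {
    r <- m$step(st, matrix(S[t], 1, 1), p, cache)
    st <- r$state
    v[t] <- r$state$v
    sp[t] <- r$output
  }
  ref <- scalar_izh(S, h = 0.5)
  expect_equal(v, ref$v, tolerance = 1e-10)
  expect_identical(sp, ref$spikes)
})

test_that("refractoriness gates integration for exactly rho after a spike", {
  # near-perfect integrator so the drive alone controls spike timing
  m <- model_lif()
  p <- list(tau_beta = 1e9, theta = 1, u_r = 0, rho = 5)
  cache <- m$time_dep(p, 1, 1, 1)
  st <- m$init_state(p, cache, 1, 1)
  spikes <- integer(0)
  gate <- numeric(40)
  for (t in 1:40) {
    r <- m$step(st, matrix(1.5, 1, 1), p, cache)
    st <- r$state
    if (r$output == 1) spikes <- c(spikes, t)
    gate[t] <- st$Pi
  }
  # strong constant drive: interval = 5 gated steps + 1 integration step
  expect_true(all(diff(spikes) == 6))
  # gate closed during steps t+1 .. t+rho exactly
  t1 <- spikes[1]
  expect_identical(gate[t1:(t1 + 4)], rep(0, 5))
  expect_identical(gate[t1 + 5], 1)
  # no two spikes closer than rho
  expect_true(min(diff(spikes)) > 5)
})

test_that("the refractory decorator is a no-op at rho = 0 and rejects LI", {
  wrapped <- refractory_wrap(model_izhikevich())
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, theta = 30, h = 1, rho = 0)
  cw <- wrapped$time_dep(p, 1, 1, 1)
  cu <- model_izhikevich()$time_dep(p, 1, 1, 1)
  sw <- wrapped$init_state(p, cw, 1, 1)
  su <- model_izhikevich()$init_state(p, cu, 1, 1)
  set.seed(8)
  S <- runif(60, 0, 15)
  for (t in seq_along(S)) {
    rw <- wrapped$step(sw, matrix(S[t], 1, 1), p, cw)
    ru <- model_izhikevich()$step(su, matrix(S[t], 1, 1), p, cu)
    sw <- rw$state
    su <- ru$state
    expect_identical(rw$output, ru$output)
  }
  expect_error(refractory_wrap(model_li()), "non-spiking")
})

test_that("refractory-wrapped Izhikevich enforces the minimum interval", {
  wrapped <- refractory_wrap(model_izhikevich())
  p <- list(a = 0.02, b = 0.2, c = -65, d = 8, theta = 30, h = 1, rho = 8)
  cw <- wrapped$time_dep(p, 1, 1, 1)
  st <- wrapped$init_state(p, cw, 1, 1)
  spikes <- integer(0)
  for (t in 1:200) {
    r <- wrapped$step(st, matrix(20, 1, 1), p, cw)
    st <- r$state
    if (r$output == 1) spikes <- c(spikes, t)
  }
  expect_gt(length(spikes), 2)
  expect_true(min(diff(spikes)) > 8)
})
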