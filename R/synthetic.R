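#' Synthetic rate-coded classification datasets
#'
#' Generates labeled spike rasters whose class identity is carried by the
#' channel-rate structure: each class drives its own subset of channels at
#' `rate_active` (Hz) while all other channels emit `rate_background`
#' spikes. This emulates the structure of rate-encoded sensory datasets
#' (e.g. cochlear-filtered audio after intensity-to-rate conversion)
#' without any download: classes are linearly separable from per-channel
#' spike counts, which makes the task a clean testbed for readout training.
#'
#' @param n_classes Number of classes.
#' @param n_channels Input channels; partitioned into `n_classes` disjoint
#'   active sets.
#' @param n_per_class Samples per class.
#' @param n_steps Time-steps per sample.
#' @param dt Step size in ms.
#' @param rate_active,rate_background Firing rates in Hz.
#' @param seed Dataset seed (fixed seed -> identical dataset).
#' @return A dataset list: `x` spike array `[n, n_steps, n_channels]`, `y`
#'   integer labels in `1..n_classes`, `n_classes`, `dt`.
#' @export
#' @examples
#' ds <- gen_rate_classes(n_classes = 2, n_channels = 8, n_per_class = 3,
#'   n_steps = 50, seed = 1)
#' dim(ds$x)
gen_rate_classes <- function(n_classes = 3, n_channels = 20, n_per_class = 80,
                             n_steps = 100, dt = 1, rate_active = 100,
                             rate_background = 5, seed = 0) {
  stopifnot(n_channels >= n_classes)
  sets <- split(
    seq_len(n_channels),
    rep_len(seq_len(n_classes), n_channels)
  )
  n <- n_classes * n_per_class
  y <- rep(seq_len(n_classes), each = n_per_class)
  x <- array(0, c(n, n_steps, n_channels))
  p_bg <- rate_background * dt / 1000
  p_act <- rate_active * dt / 1000
  with_substream(seed, "gen_rate_classes", {
    for (s in seq_len(n)) {
      p <- rep(p_bg, n_channels)
      p[sets[[y[s]]]] <- p_act
      x[s, , ] <- (matrix(
        stats::runif(n_steps * n_channels), n_steps, n_channels
      ) < rep(p, each = n_steps)) * 1
    }
  })
  list(x = x, y = y, n_classes = n_classes, dt = dt)
}

#' Split a dataset into train and test partitions
#'
#' Seeded, class-stratified random split (default 85% train).
#'
#' @param ds Dataset list (`x`, `y`, ...).
#' @param train_frac Fraction assigned to the training partition.
#' @param seed Split seed.
#' @return `list(train =, test =)` of dataset lists.
#' @export
split_dataset <- function(ds, train_frac = 0.85, seed = 0) {
  stopifnot(train_frac > 0, train_frac < 1)
  idx_tr <- with_substream(seed, "split_dataset", {
    unlist(lapply(split(seq_along(ds$y), ds$y), function(ii) {
      sample(ii, round(length(ii) * train_frac))
    }))
  })
  take <- function(ii) {
    out <- ds
    out$x <- ds$x[ii, , , drop = FALSE]
    out$y <- ds$y[ii]
    out
  }
  list(train = take(sort(idx_tr)), test = take(setdiff(seq_along(ds$y), idx_tr)))
}

#' Synthetic sensor-sweep analog dataset
#'
#' Emulates the structure of a linear tactile sensor array swept over an
#' embossed pattern: each class is a smooth spatial bump pattern traversed
#' in time, so a sample is an analog `[sensors, samples]` trace with a
#' class-dependent spatio-temporal signature. Feed through
#' [spline_upscale()] and [delta_encode()] for the full sensing pipeline.
#'
#' @param n_classes Classes (distinct bump layouts).
#' @param n_sensors Sensor channels.
#' @param t_raw Raw temporal samples per trace.
#' @param n_per_class Samples per class.
#' @param noise_sd Additive Gaussian measurement noise.
#' @param seed Dataset seed.
#' @return List: `traces` (list of `[n_sensors, t_raw]` matrices), `y`
#'   labels.
#' @export
gen_sensor_sweep <- function(n_classes = 3, n_sensors = 28, t_raw = 28,
                             n_per_class = 10, noise_sd = 0.01, seed = 0) {
  n <- n_classes * n_per_class
  y <- rep(seq_len(n_classes), each = n_per_class)
  centers <- seq(0.2, 0.8, length.out = n_classes) * n_sensors
  traces <- vector("list", n)
  with_substream(seed, "gen_sensor_sweep", {
    for (s in seq_len(n)) {
      cls <- y[s]
      speed <- 0.5 + 0.5 * cls / n_classes
      jitter <- stats::rnorm(1, 0, 0.5)
      m <- matrix(0, n_sensors, t_raw)
      for (t in seq_len(t_raw)) {
        mu <- centers[cls] + jitter + speed * (t - t_raw / 2) / 2
        m[, t] <- exp(-((seq_len(n_sensors) - mu)^2) / (2 * (1.5 + 0.3 * cls)^2))
      }
      traces[[s]] <- m + matrix(
        stats::rnorm(n_sensors * t_raw, 0, noise_sd), n_sensors, t_raw
      )
    }
  })
  list(traces = traces, y = y, n_classes = n_classes)
}

#' Three-input demo network and fixture
#'
#' A minimal two-layer network — 3 input relays, one 3x1 first-order leaky
#' synapse group, and a single LIF output neuron — simulated across 10
#' parallel batches whose membrane time constant is swept by a generator
#' function from 10 ms to 100 ms in 10 ms steps. The same fixed seeded
#' Poisson raster drives every batch, so the monitored membrane traces
#' isolate the effect of the time constant.
#'
#' @param n_steps Raster length in steps (dt = 1 ms).
#' @param seed Raster seed.
#' @return List: `net` (network), `input` (`[10, n_steps, 3]` raster),
#'   `tau_values` (the swept constants).
#' @export
demo_three_input_fixture <- function(n_steps = 200, seed = 7) {
  tau_gen <- function(batch_size, shape, rng) {
    array(10 * seq_len(batch_size), c(batch_size, shape))
  }
  net <- new_network()
  net <- add_group(net, "input", "in", n = 3)
  net <- add_group(net, "lif", "out", n = 1, tau_beta = tau_gen, theta = 1)
  net <- add_group(net, "ls1", "syn",
    source = "in", target = "out",
    tau_alpha = 8, w = matrix(c(0.02, 0.03, 0.04), 3, 1)
  )
  net <- set_ports(net, input = "in", output = "out")
  one <- unclass(rate_encode(c(0.3, 0.4, 0.5),
    n_steps = n_steps, dt = 1, seed = seed
  ))
  input <- array(0, c(10L, n_steps, 3L))
  for (b in 1:10) input[b, , ] <- one[1, , ]
  list(net = net, input = input, tau_values = 10 * (1:10))
}
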