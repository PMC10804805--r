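#' Thresholded linear intensity-to-rate spike encoding
#'
#' Converts a vector of channel intensities in `[0, 1]` to a spike raster.
#' Intensities at or below `threshold_frac` of the dynamic range are
#' silenced; above it the firing rate grows linearly, reaching `f_max` at
#' intensity 1 (the defaults reproduce the classic "20% threshold, 0-500 Hz"
#' front-end). Spikes are drawn as an independent Bernoulli process with
#' per-step probability `rate * dt / 1000` (rates in Hz, `dt` in ms), or
#' placed at regular intervals with `regular = TRUE`.
#'
#' @param x Intensity vector (one value per channel), in `[0, 1]`.
#' @param n_steps Number of time-steps.
#' @param dt Time-step size in ms.
#' @param f_max Maximum firing rate in Hz.
#' @param threshold_frac Silent fraction of the dynamic range, in `[0, 1)`.
#' @param seed Seed for the Bernoulli draws.
#' @param regular Deterministic regular-interval spikes instead of
#'   Bernoulli draws.
#' @return A spike [signal_tensor()] `[1, n_steps, length(x)]`.
#' @export
#' @examples
#' r <- rate_encode(c(0, 0.5, 1), n_steps = 100, seed = 1)
#' apply(r, 3, sum)
rate_encode <- function(x, n_steps, dt = 1, f_max = 500,
                        threshold_frac = 0.2, seed = 0, regular = FALSE) {
  stopifnot(f_max > 0, threshold_frac >= 0, threshold_frac < 1)
  rate <- ifelse(
    x <= threshold_frac, 0,
    f_max * (x - threshold_frac) / (1 - threshold_frac)
  )
  p <- rate * dt / 1000
  if (any(p > 1)) {
    warning("rate * dt exceeds one spike per step; clamping (saturation)",
      call. = FALSE
    )
    p <- pmin(p, 1)
  }
  C <- length(x)
  raster <- if (regular) {
    m <- matrix(0, n_steps, C)
    for (ch in seq_len(C)) {
      if (p[ch] > 0) {
        m[unique(pmin(n_steps, ceiling(seq_len(floor(n_steps * p[ch])) / p[ch]))), ch] <- 1
      }
    }
    m
  } else {
    with_substream(seed, "rate_encode", {
      matrix(stats::runif(n_steps * C) < rep(p, each = n_steps), n_steps, C) * 1
    })
  }
  signal_tensor(array(raster, c(1L, n_steps, C)), "spike")
}

#' Temporal spline upscaling of analog traces
#'
#' Interpolates each channel of an analog trace onto a finer uniform time
#' grid with a cubic spline (endpoints preserved exactly; the spline passes
#' through every original sample). Traces with fewer than 4 samples fall
#' back to linear interpolation with a warning.
#'
#' @param values Matrix `[channels, samples]`.
#' @param t_out Output sample count (`>= ncol(values)`).
#' @return Matrix `[channels, t_out]`.
#' @export
spline_upscale <- function(values, t_out) {
  stopifnot(is.matrix(values), ncol(values) >= 2)
  t_raw <- ncol(values)
  if (t_out < t_raw) stop("t_out must be >= the raw sample count", call. = FALSE)
  x_in <- seq(0, 1, length.out = t_raw)
  x_out <- seq(0, 1, length.out = t_out)
  if (t_raw < 4) {
    warning("fewer than 4 samples: falling back to linear interpolation",
      call. = FALSE
    )
    return(t(apply(values, 1, function(y) {
      stats::approx(x_in, y, xout = x_out)$y
    })))
  }
  t(apply(values, 1, function(y) {
    stats::spline(x_in, y, xout = x_out, method = "fmm")$y
  }))
}

#' Delta-modulation spike encoding
#'
#' Converts analog channel traces into spikes fired on signal *changes*,
#' the scheme used by event-driven sensor front-ends. Two interpretations
#' are provided:
#'
#' * `"bipolar"` — per channel, an accumulator tracks the signal; when the
#'   signal exceeds it by `delta` an UP spike fires (accumulator
#'   `+= delta`), and symmetrically a DOWN spike on falls. Output channels:
#'   `2 * C` (all UP channels, then all DOWN channels), e.g. 28 sensors ->
#'   56 spike channels.
#' * `"thermometer"` — a graded multi-bit scheme: channel `m` of `k` fires
#'   when the per-step change magnitude reaches `m * delta`, giving
#'   `k * C` output channels (4 channels with `k = 3` -> 12).
#'
#' Both are invariant to a constant signal offset.
#'
#' @param values Analog trace matrix `[channels, T]`.
#' @param delta Change threshold (> 0).
#' @param mode `"bipolar"` or `"thermometer"`.
#' @param levels Number of graded levels `k` (thermometer mode).
#' @return A spike [signal_tensor()] `[1, T, C_out]`.
#' @export
delta_encode <- function(values, delta = 0.01,
                         mode = c("bipolar", "thermometer"), levels = 3) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), delta > 0, levels >= 1)
  C <- nrow(values)
  T_len <- ncol(values)
  if (mode == "bipolar") {
    out <- array(0, c(1L, T_len, 2L * C))
    for (ch in seq_len(C)) {
      acc <- values[ch, 1]
      for (t in seq_len(T_len)) {
        if (values[ch, t] > acc + delta) {
          out[1L, t, ch] <- 1
          acc <- acc + delta
        } else if (values[ch, t] < acc - delta) {
          out[1L, t, C + ch] <- 1
          acc <- acc - delta
        }
      }
    }
  } else {
    out <- array(0, c(1L, T_len, levels * C))
    diffs <- cbind(0, t(apply(values, 1, diff)))
    for (ch in seq_len(C)) {
      for (m in seq_len(levels)) {
        out[1L, , (ch - 1L) * levels + m] <- (abs(diffs[ch, ]) >= m * delta) * 1
      }
    }
  }
  signal_tensor(out, "spike")
}
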