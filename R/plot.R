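#' Quick plots for rasters and monitored traces
#'
#' `plot_raster()` draws a spike raster (one row per component);
#' `plot_trace()` overlays the per-batch time courses of a monitored
#' scalar variable. Base-graphics convenience wrappers for interactive
#' inspection.
#'
#' @param x A `[1, T, C]` or `[T, C]` spike raster, or for `plot_trace()`
#'   a `[B, T, n]` monitored trace array.
#' @param component Component index to plot (trace).
#' @param dt Step size used to scale the time axis.
#' @param ... Passed to the underlying plot call.
#' @return Invisibly, the input.
#' @export
plot_raster <- function(x, dt = 1, ...) {
  if (length(dim(x)) == 3L) x <- matrix(x[1, , ], dim(x)[2], dim(x)[3])
  idx <- which(x == 1, arr.ind = TRUE)
  graphics::plot(idx[, 1] * dt, idx[, 2],
    pch = "|", cex = 0.6,
    xlab = "time", ylab = "component", yaxt = "n",
    xlim = c(0, nrow(x) * dt), ylim = c(0.5, ncol(x) + 0.5), ...
  )
  graphics::axis(2, at = seq_len(ncol(x)))
  invisible(x)
}

#' @rdname plot_raster
#' @export
plot_trace <- function(x, component = 1, dt = 1, ...) {
  stopifnot(length(dim(x)) == 3L)
  B <- dim(x)[1]
  tt <- seq_len(dim(x)[2]) * dt
  graphics::matplot(tt, t(matrix(x[, , component], B, dim(x)[2])),
    type = "l", lty = 1, xlab = "time", ylab = "value", ...
  )
  invisible(x)
}
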