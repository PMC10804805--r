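#' Signal tensors
#'
#' The universal currency between groups is a dense numeric array with axes
#' ordered exactly `[batch, time, components]`. Spike-kind tensors contain
#' only 0/1 values; analog tensors are unrestricted reals. A signal tensor is
#' a plain array with a `"kind"` attribute, so all base-R array tooling keeps
#' working.
#'
#' @param data Numeric array `[B, T, N]`, or matrix `[T, N]` (promoted to
#'   batch size 1).
#' @param kind `"spike"` or `"analog"`.
#' @return The validated array of class `"signal_tensor"`.
#' @export
#' @examples
#' x <- signal_tensor(array(0, c(2, 10, 3)), "spike")
#' dim(x)
signal_tensor <- function(data, kind = c("analog", "spike")) {
  kind <- match.arg(kind)
  if (is.matrix(data)) {
    data <- array(data, c(1L, nrow(data), ncol(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("signal tensor must be a [batch, time, components] array", call. = FALSE)
  }
  if (!is.numeric(data)) stop("signal tensor must be numeric", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("signal tensor contains non-finite values", call. = FALSE)
  }
  if (kind == "spike" && !all(data %in% c(0, 1))) {
    stop("spike-kind signal tensor must contain only values in {0, 1}",
      call. = FALSE
    )
  }
  structure(data, kind = kind, class = c("signal_tensor", "array"))
}

#' @export
print.signal_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<signal_tensor kind=%s  batch=%d  steps=%d  components=%d>\n",
    attr(x, "kind"), d[1], d[2], d[3]
  ))
  invisible(x)
}

#' Test whether an array is a valid spike raster
#'
#' @param x Array `[B, T, N]`.
#' @return `TRUE` when every value is 0 or 1.
#' @export
is_spike_raster <- function(x) {
  is.numeric(x) && length(dim(x)) == 3L && all(x == 0 | x == 1)
}

# Coerce external input to a [B, T, N] array (no copy for conforming arrays).
as_input_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("external input must be a [batch, time, components] array", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Write / read a single-sample raster or trace as CSV
#'
#' One row per time-step, one column per component; the time-step size is
#' kept in a `# dt=<value>` header comment so files round-trip.
#'
#' @param x Matrix `[T, N]` or a `[1, T, N]` array.
#' @param path File path.
#' @param dt Time-step size stored in the header.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a list with elements `values` (a `[T, N]` matrix) and `dt`.
#' @export
write_trace_csv <- function(x, path, dt = 1) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[1] != 1L) stop("CSV export is per-sample; batch must be 1", call. = FALSE)
    x <- matrix(x[1, , ], dim(x)[2], dim(x)[3])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g", dt), con)
  utils::write.table(x,
    con,
    sep = ",", row.names = FALSE,
    col.names = paste0("c", seq_len(ncol(x)))
  )
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 1L)
  dt <- 1
  if (grepl("^# dt=", header)) {
    dt <- as.numeric(sub("^# dt=", "", header))
  }
  values <- as.matrix(utils::read.csv(path, comment.char = "#"))
  dimnames(values) <- NULL
  list(values = values, dt = dt)
}
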