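#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows through named sub-streams derived from
#' one user-supplied integer seed, so that e.g. attaching a monitor or adding
#' an unrelated group never perturbs the draws of another component.
#'
#' @param seed Integer master seed.
#' @param ... Character labels identifying the consumer (group id, operation
#'   name, ...). Coerced with `as.character()`.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "reservoir", "weights")
substream_seed <- function(seed, ...) {
  labels <- as.character(unlist(list(...)))
  h <- as.double(seed) %% 2147483647
  for (lab in labels) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 131 + code) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a derived sub-stream seed, restoring the caller's RNG
# state afterwards.
with_substream <- function(seed, labels, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, labels))
  expr
}
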