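#' Stochastic weight quantization onto equidistant levels
#'
#' Emulates storing trained weights on multi-level analog memory (e.g.
#' memristive conductances): each weight is snapped to the nearest of
#' `n_levels` equidistant levels spanning the symmetric, signed range
#' `[-w_max, +w_max]`, then perturbed by a Gaussian write error whose
#' standard deviation is one sixth of the level spacing — adjacent level
#' distributions then cross at 3 sigma, i.e. a stored weight is read as a
#' neighboring level with probability `pnorm(-3) ~ 0.135%` per side (a
#' ~0.3% total overlap).
#'
#' @param w Weight matrix (or array/scalar).
#' @param bits Bit width; `n_levels = 2^bits`.
#' @param n_levels Number of levels (>= 2); overrides `bits`.
#' @param w_max Level range half-width; defaults to `max(abs(w))`
#'   (data-derived, making noiseless quantization scale-equivariant).
#' @param noise Apply the Gaussian write error (disable for the pure
#'   nearest-level snap, which is idempotent).
#' @param seed Seed for the write-error draws.
#' @return The quantized weights, same shape as `w`.
#' @export
#' @examples
#' quantize_weights(c(-1, -0.2, 0.4, 1), n_levels = 4, noise = FALSE)
quantize_weights <- function(w, bits = NULL, n_levels = 2^bits,
                             w_max = NULL, noise = TRUE, seed = 0) {
  if (is.null(n_levels)) stop("give bits or n_levels", call. = FALSE)
  stopifnot(n_levels >= 2)
  if (!all(is.finite(w))) stop("weights must be finite", call. = FALSE)
  if (is.null(w_max)) w_max <- max(abs(w))
  if (w_max == 0) {
    warning("all weights are zero: quantization range undefined, no-op",
      call. = FALSE
    )
    return(w)
  }
  delta <- 2 * w_max / (n_levels - 1)
  wq <- pmin(pmax(round((w + w_max) / delta), 0), n_levels - 1) * delta - w_max
  if (noise) {
    wq <- wq + with_substream(seed, "quantize", {
      stats::rnorm(length(w), 0, delta / 6)
    })
  }
  out <- w
  out[] <- wq
  out
}

#' Power-law conductance drift of stored weights
#'
#' Applies a parameterized retention model for analog weight storage: each
#' stored magnitude relaxes as `|w|(t) = |w|(t0) * (t/t0)^(-nu)`, with the
#' drift exponent `nu` drawn per weight from a Normal(`nu_mean`, `nu_sd`)
#' truncated at zero (signs are preserved; magnitudes never grow). This is
#' a synthetic stand-in for device-calibrated drift compact models, kept
#' deliberately generic: choose `nu_mean`/`nu_sd` to match a target
#' technology.
#'
#' @param w Weight matrix.
#' @param t_elapsed Time since storage (same units as `t0`), `>= t0`.
#' @param nu_mean,nu_sd Drift-exponent distribution parameters.
#' @param t0 Reference (storage) time, > 0.
#' @param seed Seed for the per-weight exponent draws.
#' @return The drifted weights.
#' @export
#' @examples
#' drift_weights(1, t_elapsed = 100, nu_mean = 0.1, nu_sd = 0) # 0.631
drift_weights <- function(w, t_elapsed, nu_mean = 0.1, nu_sd = 0.02,
                          t0 = 1, seed = 0) {
  stopifnot(t0 > 0)
  if (t_elapsed < t0) {
    stop("t_elapsed must be >= the storage reference time t0", call. = FALSE)
  }
  nu <- if (nu_sd == 0) {
    rep(nu_mean, length(w))
  } else {
    with_substream(seed, "drift", {
      # inverse-CDF sampling of the at-zero-truncated normal
      lo <- stats::pnorm(0, nu_mean, nu_sd)
      stats::qnorm(lo + stats::runif(length(w)) * (1 - lo), nu_mean, nu_sd)
    })
  }
  out <- w
  out[] <- sign(w) * abs(w) * (t_elapsed / t0)^(-nu)
  out
}

#' Post-training robustness sweeps
#'
#' `sweep_quantization()` re-evaluates a trained model after stochastic
#' quantization of its synaptic weights, for each candidate bit width and
#' over several independent write-noise trials, reporting the mean /
#' min / max accuracy per bit width. `sweep_drift()` analogously
#' re-evaluates after power-law drift for each elapsed time, reporting
#' mean and standard deviation over random drift-exponent draws. Both
#' always simulate the full network (quantization and drift touch every
#' selected group, reservoir included).
#'
#' @param fit A trained model from [train_snn()].
#' @param dataset Evaluation dataset.
#' @param bits Integer vector of bit widths to test.
#' @param trials Independent noisy quantizations per bit width.
#' @param times Elapsed-time values (units of `t0`).
#' @param iterations Random drift iterations per time value.
#' @param groups Synaptic group ids to perturb; default: every synaptic
#'   group of the network.
#' @param nu_mean,nu_sd,t0 Passed to [drift_weights()].
#' @param seed Master seed for the perturbation draws.
#' @param chunk Samples per evaluation batch.
#' @return A data.frame: per bit width `accuracy_mean/min/max`, or per
#'   time `accuracy_mean/sd`.
#' @export
sweep_quantization <- function(fit, dataset, bits = 1:8, trials = 5,
                               groups = NULL, seed = 0, chunk = 64) {
  if (length(bits) == 0) stop("empty bits list", call. = FALSE)
  base_w <- model_weights(fit, groups)
  rows <- lapply(bits, function(b) {
    acc <- vapply(seq_len(trials), function(k) {
      wq <- lapply(names(base_w), function(id) {
        quantize_weights(base_w[[id]],
          n_levels = 2^b,
          seed = substream_seed(seed, "quant", b, k, id)
        )
      })
      names(wq) <- names(base_w)
      evaluate_snn(fit, dataset, weights = wq, chunk = chunk)$accuracy
    }, 1)
    data.frame(
      bits = b, n_levels = 2^b, accuracy_mean = mean(acc),
      accuracy_min = min(acc), accuracy_max = max(acc)
    )
  })
  do.call(rbind, rows)
}

#' @rdname sweep_quantization
#' @export
sweep_drift <- function(fit, dataset, times, iterations = 20,
                        groups = NULL, nu_mean = 0.1, nu_sd = 0.02, t0 = 1,
                        seed = 0, chunk = 64) {
  if (length(times) == 0) stop("empty times list", call. = FALSE)
  base_w <- model_weights(fit, groups)
  rows <- lapply(times, function(tt) {
    acc <- vapply(seq_len(iterations), function(k) {
      wd <- lapply(names(base_w), function(id) {
        drift_weights(base_w[[id]], tt,
          nu_mean = nu_mean, nu_sd = nu_sd,
          t0 = t0, seed = substream_seed(seed, "drift", k, id)
        )
      })
      names(wd) <- names(base_w)
      evaluate_snn(fit, dataset, weights = wd, chunk = chunk)$accuracy
    }, 1)
    data.frame(
      t = tt, accuracy_mean = mean(acc),
      accuracy_sd = stats::sd(acc)
    )
  })
  do.call(rbind, rows)
}

# full weight set of a trained model: trained matrices plus the static
# weights of every other synaptic group
model_weights <- function(fit, groups = NULL) {
  pm <- if (inherits(fit, "snn_fit")) fit$pm else fit
  net <- pm$net
  syn_ids <- names(net$groups)[vapply(
    net$groups, function(g) g$kind == "synapse", TRUE
  )]
  if (is.null(groups)) groups <- syn_ids
  out <- list()
  for (id in groups) {
    out[[id]] <- if (inherits(fit, "snn_fit") && id %in% names(fit$weights)) {
      fit$weights[[id]]
    } else {
      w <- net$groups[[id]]$params$w
      if (length(w) == 1L) array(w, group_shape(net, id)) else w
    }
  }
  out
}
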