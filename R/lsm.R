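#' Build a liquid state machine network
#'
#' Assembles the classic three-layer reservoir-computing SNN: an input
#' relay layer, a recurrently connected LIF reservoir, and a non-spiking
#' (LI) readout layer, wired by three first-order leaky synapse groups.
#' With the defaults the group sizes reproduce the canonical 50/125/10
#' architecture: a 6,250-component input-to-reservoir synapse group with
#' exactly `nnz_in` non-zero weights, a 15,625-component
#' reservoir-to-reservoir group with `nnz_res` non-zero weights, and a
#' dense 1,250-component reservoir-to-output group (the one typically
#' trained).
#'
#' A fraction `exc_frac` of reservoir neurons is marked excitatory;
#' recurrent weights leaving inhibitory neurons are negative. Non-zero
#' positions and magnitudes are drawn uniformly under `seed` and installed
#' as static matrices, so the wiring is identical however the network is
#' later batched or re-initialized.
#'
#' @param n_in,n_res,n_out Layer sizes.
#' @param tau_neuron Membrane time constant of reservoir and readout (ms).
#' @param tau_syn Synaptic time constant (ms).
#' @param nnz_in Non-zero input-to-reservoir weights.
#' @param nnz_res Non-zero recurrent weights (approximately 2,300 in the
#'   reference architecture).
#' @param exc_frac Excitatory fraction of the reservoir (default 80%).
#' @param theta Reservoir spike threshold.
#' @param w_in,w_res Magnitude ranges `c(lo, hi)` for input and recurrent
#'   weights.
#' @param w_out Range of the uniform readout initialization.
#' @param seed Wiring seed.
#' @return A network with groups `in`, `syn_in`, `res`, `syn_res`,
#'   `syn_out`, `out` (ports `in` -> `out`).
#' @export
#' @examples
#' net <- build_lsm(seed = 1)
#' net$groups$syn_res$n # 15625
build_lsm <- function(n_in = 50, n_res = 125, n_out = 10,
                      tau_neuron = 64, tau_syn = 8,
                      nnz_in = 200, nnz_res = 2300, exc_frac = 0.8,
                      theta = 1, w_in = c(0.02, 0.06), w_res = c(0.005, 0.02),
                      w_out = c(-0.1, 0.1), seed = 0) {
  stopifnot(n_in > 0, n_res > 0, n_out > 0)
  if (nnz_in > n_in * n_res) {
    stop("nnz_in exceeds the input-to-reservoir group size", call. = FALSE)
  }
  if (nnz_res > n_res * n_res) {
    stop("nnz_res exceeds the recurrent group size", call. = FALSE)
  }
  wiring <- with_substream(seed, "build_lsm", {
    w_in_mat <- matrix(0, n_in, n_res)
    w_in_mat[sample.int(n_in * n_res, nnz_in)] <-
      stats::runif(nnz_in, w_in[1], w_in[2])
    excitatory <- seq_len(n_res) %in%
      sample.int(n_res, round(exc_frac * n_res))
    w_res_mat <- matrix(0, n_res, n_res)
    pos <- sample.int(n_res * n_res, nnz_res)
    mag <- stats::runif(nnz_res, w_res[1], w_res[2])
    sign_src <- ifelse(excitatory[(pos - 1L) %% n_res + 1L], 1, -1)
    w_res_mat[pos] <- mag * sign_src
    w_out_mat <- matrix(
      stats::runif(n_res * n_out, w_out[1], w_out[2]), n_res, n_out
    )
    list(w_in = w_in_mat, w_res = w_res_mat, w_out = w_out_mat)
  })
  net <- new_network()
  net <- add_group(net, "input", "in", n = n_in)
  net <- add_group(net, "lif", "res",
    n = n_res,
    tau_beta = tau_neuron, theta = theta
  )
  net <- add_group(net, "li", "out", n = n_out, tau_beta = tau_neuron)
  net <- add_group(net, "ls1", "syn_in",
    source = "in", target = "res",
    tau_alpha = tau_syn, w = wiring$w_in
  )
  net <- add_group(net, "ls1", "syn_res",
    source = "res", target = "res",
    tau_alpha = tau_syn, w = wiring$w_res
  )
  net <- add_group(net, "ls1", "syn_out",
    source = "res", target = "out",
    tau_alpha = tau_syn, w = wiring$w_out
  )
  set_ports(net, input = "in", output = "out")
}
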