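#' Parameters of the additive pair-based STDP rule
#'
#' Constructs and validates the parameter set of the nearest-neighbor
#' spike-timing-dependent plasticity rule: when neuron j fires at time
#' \eqn{t_j}, every incoming weight \eqn{W_{ji}} is potentiated by
#' \eqn{p\,e^{-\delta_{ji}/\tau_p}} and every outgoing weight \eqn{W_{ij}}
#' depressed by \eqn{d\,e^{-\delta_{ji}/\tau_d}}, where
#' \eqn{\delta_{ji} = t_j - t_i^{\mathrm{last}}} is the time since partner
#' i's most recent spike.  Weights are hard-bounded to \eqn{[0,1]}.
#'
#' The closed-form locking theory (see [g1_stdp()], [g2_stdp()]) assumes the
#' symmetric-amplitude, depression-biased regime `p == d` and
#' `tau_p <= tau_d`; those functions check it via [assert_symmetric_stdp()].
#'
#' @param p potentiation amplitude (dimensionless, much smaller than 1).
#' @param d depression amplitude (default equal to `p`).
#' @param tau_p potentiation learning window (time units).
#' @param tau_d depression learning window (time units).
#' @return an object of class `stdp_params`.
#' @export
#' @examples
#' stdp_params(p = 0.001, tau_p = pi / 3, tau_d = pi)
stdp_params <- function(p = 0.001, d = p, tau_p = pi / 3, tau_d = pi) {
  stopifnot(is.numeric(p), length(p) == 1, p > 0,
            is.numeric(d), length(d) == 1, d > 0,
            is.numeric(tau_p), length(tau_p) == 1, tau_p > 0,
            is.numeric(tau_d), length(tau_d) == 1, tau_d > 0)
  structure(list(p = p, d = d, tau_p = tau_p, tau_d = tau_d),
            class = "stdp_params")
}

#' @export
print.stdp_params <- function(x, ...) {
  cat(sprintf("STDP rule: p = %g, d = %g, tau_p = %g, tau_d = %g\n",
              x$p, x$d, x$tau_p, x$tau_d))
  invisible(x)
}

#' Assert the parameter regime of the analytic locking theory
#'
#' The closed-form thresholds and tongue boundaries are derived for equal
#' potentiation/depression amplitudes (`p == d`) with a depression-biased
#' window ordering (`tau_p <= tau_d`, strict where a function requires it).
#'
#' @param params an [stdp_params()] object.
#' @param strict_windows require `tau_p < tau_d` strictly.
#' @return `params`, invisibly.
#' @export
assert_symmetric_stdp <- function(params, strict_windows = FALSE) {
  stopifnot(inherits(params, "stdp_params"))
  if (params$p != params$d) {
    stop("the analytic theory assumes equal amplitudes p == d")
  }
  if (strict_windows) {
    if (params$tau_p >= params$tau_d) {
      stop("this boundary is derived for tau_p < tau_d (depression bias); ",
           "tau_p >= tau_d is outside its regime")
    }
  } else if (params$tau_p > params$tau_d) {
    stop("the analytic theory assumes tau_p <= tau_d")
  }
  invisible(params)
}

#' Validate a synaptic weight matrix
#'
#' A weight matrix is square with entries in \eqn{[0,1]}; row i holds the
#' incoming weights of postsynaptic neuron i (entry `W[i, j]` is the strength
#' of the link from presynaptic j to postsynaptic i) and the diagonal
#' (autapses) is identically zero.
#'
#' @param W a numeric matrix.
#' @return `W`, invisibly, after validation.
#' @export
weight_matrix <- function(W) {
  stopifnot(is.matrix(W), is.numeric(W), nrow(W) == ncol(W))
  if (any(W < 0 | W > 1)) stop("weights must lie in [0, 1]")
  if (any(diag(W) != 0)) stop("autaptic weights W[i, i] must be zero")
  invisible(W)
}

#' Apply the STDP update triggered by one spike
#'
#' Reference (pure R) implementation of the pair-based update applied when
#' neuron `j` fires at time `t`: for every other neuron i that has already
#' fired, the incoming weight `W[j, i]` is potentiated and the outgoing
#' weight `W[i, j]` depressed according to the exponential learning windows,
#' then hard-clipped into \eqn{[0,1]}.  Neurons that have never fired
#' contribute no update.  The compiled event engine applies the identical
#' rule internally.
#'
#' @param W weight matrix (see [weight_matrix()]).
#' @param params an [stdp_params()] object.
#' @param j index of the firing neuron.
#' @param t spike time.
#' @param last_fire numeric vector of each neuron's most recent spike time,
#'   with `NA` for neurons that have never fired.
#' @return the updated weight matrix.
#' @export
apply_spike_update <- function(W, params, j, t, last_fire) {
  weight_matrix(W)
  stopifnot(inherits(params, "stdp_params"),
            length(last_fire) == nrow(W),
            j >= 1, j <= nrow(W))
  for (i in seq_len(nrow(W))) {
    if (i == j || is.na(last_fire[i])) next
    delta <- t - last_fire[i]
    if (delta < 0) {
      stop("spike at t = ", t, " precedes recorded last firing of neuron ", i)
    }
    W[j, i] <- min(1, max(0, W[j, i] + params$p * exp(-delta / params$tau_p)))
    W[i, j] <- min(1, max(0, W[i, j] - params$d * exp(-delta / params$tau_d)))
  }
  W
}
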