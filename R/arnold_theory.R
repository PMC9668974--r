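#' Per-cycle STDP weight budget in the multi-spike locked mode
#'
#' In the locked mode with unidirectional slow-to-fast coupling the fast
#' neuron (period \eqn{T_1}) fires n times per period \eqn{T_2} of the slow
#' neuron, the first firing lagging the slow neuron's spike by `deltaT`.
#' Summing the pair-based STDP increments over the n + 1 events of one
#' synchronization cycle gives the net per-cycle drifts of the two weights:
#' \deqn{\Delta\bar W_{12} = p\sum_{j=0}^{n-1} e^{-(jT_1+\Delta T)/\tau_p}
#'   - d\, e^{-(T_2-(n-1)T_1-\Delta T)/\tau_d},}
#' \deqn{\Delta\bar W_{21} = p\, e^{-(T_2-(n-1)T_1-\Delta T)/\tau_p}
#'   - d\sum_{j=0}^{n-1} e^{-(jT_1+\Delta T)/\tau_d}.}
#' The slow-to-fast link is stable when \eqn{\Delta\bar W_{12} > 0} and
#' \eqn{\Delta\bar W_{21} < 0}.
#'
#' @param T1,T2 natural periods of the fast and slow neuron (`T1 < T2`).
#' @param n winding integer (fast spikes per slow period), \eqn{n \ge 1}.
#' @param deltaT lag of the fast neuron's first spike after the slow spike;
#'   must satisfy \eqn{0 \le \Delta T < T_1} and
#'   \eqn{(n-1)T_1 + \Delta T < T_2}.
#' @param params an [stdp_params()] object.
#' @return named vector `c(dW12, dW21)` of per-cycle weight changes.
#' @export
weight_budget_mode_i <- function(T1, T2, n, deltaT, params) {
  stopifnot(inherits(params, "stdp_params"), n >= 1, n == round(n),
            deltaT >= 0, deltaT < T1, (n - 1) * T1 + deltaT < T2)
  j <- seq_len(n) - 1
  tail_gap <- T2 - (n - 1) * T1 - deltaT
  dW12 <- params$p * sum(exp(-(j * T1 + deltaT) / params$tau_p)) -
    params$d * exp(-tail_gap / params$tau_d)
  dW21 <- params$p * exp(-tail_gap / params$tau_p) -
    params$d * sum(exp(-(j * T1 + deltaT) / params$tau_d))
  c(dW12 = dW12, dW21 = dW21)
}

#' Per-cycle STDP weight budget in the one-to-one locked mode
#'
#' With unidirectional fast-to-slow coupling both neurons fire once per
#' period \eqn{T_1} of the fast neuron, the slow neuron lagging by `deltaT`:
#' \deqn{\Delta\bar W_{12} = p\, e^{-(T_1-\Delta T)/\tau_p}
#'   - d\, e^{-\Delta T/\tau_d}, \qquad
#'   \Delta\bar W_{21} = p\, e^{-\Delta T/\tau_p}
#'   - d\, e^{-(T_1-\Delta T)/\tau_d}.}
#' The fast-to-slow link is stable when \eqn{\Delta\bar W_{12} < 0} and
#' \eqn{\Delta\bar W_{21} > 0}.
#'
#' @inheritParams weight_budget_mode_i
#' @return named vector `c(dW12, dW21)`.
#' @export
weight_budget_mode_ii <- function(T1, deltaT, params) {
  stopifnot(inherits(params, "stdp_params"), deltaT >= 0, deltaT < T1)
  dW12 <- params$p * exp(-(T1 - deltaT) / params$tau_p) -
    params$d * exp(-deltaT / params$tau_d)
  dW21 <- params$p * exp(-deltaT / params$tau_p) -
    params$d * exp(-(T1 - deltaT) / params$tau_d)
  c(dW12 = dW12, dW21 = dW21)
}

#' Stability threshold of the slow-to-fast link under STDP
#'
#' For equal amplitudes (`p == d`) and `tau_p <= tau_d` the per-cycle
#' budget of the multi-spike mode stays stabilizing exactly while
#' \eqn{\Delta T / T_1 < Q_1} with
#' \deqn{Q_1 = \frac{1}{1+\tau_d/\tau_p}\left\{\frac{T_2}{T_1}-n+1+
#'   \frac{\tau_d}{T_1}\ln\left[\sum_{j=0}^{n-1}
#'   e^{-jT_1/\tau_p}\right]\right\}.}
#'
#' @inheritParams weight_budget_mode_i
#' @param tau_p,tau_d STDP learning windows with `tau_p <= tau_d`.
#' @return the threshold \eqn{Q_1} (dimensionless).
#' @export
q1_threshold <- function(T1, T2, n, tau_p, tau_d) {
  stopifnot(T1 > 0, T2 > 0, n >= 1, n == round(n), tau_p > 0, tau_d > 0)
  if (tau_p > tau_d) stop("Q1 is derived under tau_p <= tau_d")
  j <- seq_len(n) - 1
  (T2 / T1 - n + 1 + tau_d / T1 * log(sum(exp(-j * T1 / tau_p)))) /
    (1 + tau_d / tau_p)
}

#' Stability threshold of the fast-to-slow link under STDP
#'
#' For `p == d` and `tau_p <= tau_d` the one-to-one mode's budget is
#' stabilizing while \eqn{\Delta T / T_2 < Q_2} with
#' \eqn{Q_2 = \frac{1}{1+\tau_d/\tau_p}\frac{T_1}{T_2}}.
#'
#' @inheritParams q1_threshold
#' @export
q2_threshold <- function(T1, T2, tau_p, tau_d) {
  stopifnot(T1 > 0, T2 > 0, tau_p > 0, tau_d > 0)
  if (tau_p > tau_d) stop("Q2 is derived under tau_p <= tau_d")
  (T1 / T2) / (1 + tau_d / tau_p)
}

#' Stationary phase of a periodically kicked QIF neuron
#'
#' A QIF neuron of period `T_response` receiving pulses of strength `g` at
#' intervals `T_drive` obeys the exact circle map
#' \eqn{\varphi^{(k+1)} = 2\,\mathrm{arccot}[\cot((\varphi^{(k)} +
#' \omega T_{\mathrm{drive}})/2) - 2g/\omega]}.  Its fixed points are
#' \deqn{\bar\varphi = \pi + 2\arctan\left(G \pm \sqrt{G^2 - 1 -
#'   2G\cot(\pi T_{\mathrm{drive}}/T_{\mathrm{response}})}\right),
#'   \quad G = g/\omega,}
#' the "+" root being the stable one.  When the radicand is negative no
#' fixed point exists (no locking at this coupling).
#'
#' @param T_drive interval between incoming pulses.
#' @param T_response natural period of the kicked neuron.
#' @param g pulse strength, \eqn{g > 0}.
#' @param branch `"stable"` (the + root) or `"unstable"` (the - root).
#' @return the stationary phase in \eqn{(0, 2\pi)}, or `NA_real_` when no
#'   fixed point exists.
#' @export
stationary_phase_qif <- function(T_drive, T_response, g,
                                 branch = c("stable", "unstable")) {
  branch <- match.arg(branch)
  stopifnot(T_drive > 0, T_response > 0, g > 0)
  omega <- 2 * pi / T_response
  G <- g / omega
  radicand <- G^2 - 1 - 2 * G / tan(pi * T_drive / T_response)
  if (radicand < 0) return(NA_real_)
  root <- sqrt(radicand)
  pi + 2 * atan(G + if (branch == "stable") root else -root)
}

#' Tongue boundary for the slow-to-fast locked mode, fixed weights
#'
#' Minimal coupling at which the slow neuron (period `T2`) entrains the
#' fast one (period `T1`) at winding number n/1 with a frozen unit
#' slow-to-fast weight:
#' \eqn{g_1 = \omega_1\cot[\tfrac{\pi}{2}(T_2/T_1 - n + 1)]} for
#' \eqn{n - 1 < T_2/T_1 \le n}.
#'
#' @param T1,T2 natural periods, `T2 > T1`.
#' @param n winding integer; default the tongue containing `T2/T1`,
#'   i.e. `ceiling(T2/T1)`.
#' @return the boundary coupling strength (nonnegative).
#' @export
g1_fixed <- function(T1, T2, n = ceiling(T2 / T1)) {
  stopifnot(T1 > 0, T2 > T1, n >= 2)
  r <- T2 / T1 - n + 1
  if (r <= 0 || r > 1) stop("n must satisfy n - 1 < T2/T1 <= n")
  (2 * pi / T1) / tan(pi / 2 * r)
}

#' Tongue boundary for the one-to-one locked mode, fixed weights
#'
#' Minimal coupling at which the fast neuron entrains the slow one at 1/1
#' with a frozen unit fast-to-slow weight:
#' \eqn{g_2 = \omega_2\cot(\tfrac{\pi}{2} T_1/T_2)}.
#'
#' @inheritParams g1_fixed
#' @export
g2_fixed <- function(T1, T2) {
  stopifnot(T1 > 0, T2 >= T1)
  (2 * pi / T2) / tan(pi / 2 * T1 / T2)
}

#' Tongue boundary for the slow-to-fast locked mode under STDP
#'
#' Plasticity shrinks (or preserves) the fixed-weight tongue: the boundary
#' is unchanged while the stationary phase on the fixed-weight boundary
#' already satisfies the STDP stability condition
#' (\eqn{Q_1 \ge (T_2/T_1 - n + 1)/2}); otherwise the binding constraint is
#' the stability condition itself,
#' \deqn{\bar g_1 = \omega_1\left\{2\sin^2(\pi Q_1)\left[\cot(\pi Q_1) -
#'   \cot(\pi T_2/T_1)\right]\right\}^{-1}.}
#' Requires the symmetric regime `p == d`, `tau_p <= tau_d`.
#'
#' @inheritParams g1_fixed
#' @param params an [stdp_params()] object.
#' @export
g1_stdp <- function(T1, T2, params, n = ceiling(T2 / T1)) {
  assert_symmetric_stdp(params)
  stopifnot(T1 > 0, T2 > T1, n >= 2)
  Q1 <- q1_threshold(T1, T2, n, params$tau_p, params$tau_d)
  r <- T2 / T1 - n + 1
  if (Q1 >= r / 2) return(g1_fixed(T1, T2, n))
  omega1 <- 2 * pi / T1
  omega1 / (2 * sin(pi * Q1)^2 * (1 / tan(pi * Q1) - 1 / tan(pi * T2 / T1)))
}

#' Tongue boundary for the one-to-one locked mode under STDP
#'
#' With the depression-biased windows (`tau_d > tau_p`) the STDP stability
#' condition always binds on the 1/1 tongue, giving
#' \deqn{\bar g_2 = \omega_2\left\{2\sin^2(\pi Q_2)\left[\cot(\pi Q_2) -
#'   \cot(\pi T_1/T_2)\right]\right\}^{-1} > g_2.}
#'
#' @inheritParams g1_stdp
#' @export
g2_stdp <- function(T1, T2, params) {
  assert_symmetric_stdp(params, strict_windows = TRUE)
  stopifnot(T1 > 0, T2 >= T1)
  Q2 <- q2_threshold(T1, T2, params$tau_p, params$tau_d)
  omega2 <- 2 * pi / T2
  omega2 / (2 * sin(pi * Q2)^2 * (1 / tan(pi * Q2) - 1 / tan(pi * T1 / T2)))
}

#' Parabolic summary of a phase response curve near its peak
#'
#' Holds the three numbers that determine near-resonance locking for an
#' arbitrary class I neuron: the PRC maximum `Z_max`, the phase `phi_max`
#' of the maximum (on the \eqn{(0, 2\pi]} scale with phase
#' \eqn{2\pi} at the membrane-potential maximum), and the curvature
#' `alpha` of the parabola \eqn{Z(\varphi) = Z_{max} -
#' \alpha(\varphi - \varphi_{max})^2}.
#'
#' @param Z_max positive PRC maximum.
#' @param phi_max phase of the maximum, in \eqn{(0, 2\pi)}.
#' @param alpha positive curvature coefficient.
#' @return an object of class `prc_fit`.
#' @export
prc_fit <- function(Z_max, phi_max, alpha) {
  stopifnot(is.numeric(Z_max), Z_max > 0,
            is.numeric(phi_max), phi_max > 0, phi_max < 2 * pi,
            is.numeric(alpha), alpha > 0)
  structure(list(Z_max = Z_max, phi_max = phi_max, alpha = alpha),
            class = "prc_fit")
}

#' @export
print.prc_fit <- function(x, ...) {
  cat(sprintf("PRC parabolic fit: Z_max = %.4g at phi = %.4g, alpha = %.4g\n",
              x$Z_max, x$phi_max, x$alpha))
  invisible(x)
}

#' Near-resonance tongue boundary with fixed weights
#'
#' For period ratio \eqn{T_2/T_1 = n + \varepsilon} close to a resonance,
#' the fixed-weight tongue boundary of any class I neuron depends only on
#' the PRC maximum: \eqn{g_1 = -2\pi\varepsilon/Z^{max}} for the
#' slow-to-fast mode (\eqn{\varepsilon < 0}, \eqn{n \ge 2}) and
#' \eqn{g_2 = 2\pi\varepsilon/Z^{max}} for the one-to-one mode
#' (\eqn{\varepsilon > 0}, \eqn{n = 1}).
#'
#' @param Z_max PRC maximum of the driven neuron.
#' @param epsilon detuning \eqn{T_2/T_1 - n}; its sign must match the mode.
#' @param mode `"i"` (slow drives fast) or `"ii"` (fast drives slow).
#' @export
resonance_g_fixed <- function(Z_max, epsilon, mode = c("i", "ii")) {
  mode <- match.arg(mode)
  stopifnot(Z_max > 0)
  if (mode == "i") {
    if (epsilon > 0) stop("mode i requires epsilon <= 0 (ratio below n)")
    -2 * pi * epsilon / Z_max
  } else {
    if (epsilon < 0) stop("mode ii requires epsilon >= 0 (ratio above 1)")
    2 * pi * epsilon / Z_max
  }
}

#' Near-resonance tongue boundary under STDP
#'
#' STDP multiplies the fixed-weight near-resonance boundary by
#' \eqn{(1+\beta)} where \eqn{\beta = B^2\alpha/Z^{max}} if the margin
#' \eqn{B} is positive and 0 otherwise.  For the slow-to-fast mode
#' \deqn{B_1 = 2\pi - \varphi^{max} - \frac{2\pi}{1+\tau_d/\tau_p}
#'   \left\{1 + \frac{\tau_d}{T_1}\ln\left[\sum_{j=0}^{n-1}
#'   e^{-jT_1/\tau_p}\right]\right\},}
#' and for the one-to-one mode
#' \eqn{B_2 = 2\pi/(1+\tau_p/\tau_d) - \varphi^{max}}.
#'
#' @param fit a [prc_fit()] for the driven neuron.
#' @param epsilon detuning \eqn{T_2/T_1 - n}.
#' @param n winding integer (\eqn{\ge 2} for mode i; 1 for mode ii).
#' @param T1 natural period of the fast neuron.
#' @param params an [stdp_params()] object with `p == d`,
#'   `tau_p <= tau_d`.
#' @param mode `"i"` or `"ii"`.
#' @param max_detuning reject \eqn{|\varepsilon|} beyond this value (the
#'   expansion is local to the resonance).
#' @export
resonance_g_stdp <- function(fit, epsilon, n, T1, params,
                             mode = c("i", "ii"), max_detuning = 0.25) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "prc_fit"), T1 > 0)
  assert_symmetric_stdp(params)
  if (abs(epsilon) > max_detuning) {
    stop("|epsilon| = ", abs(epsilon), " is outside the near-resonance ",
         "regime (max_detuning = ", max_detuning, ")")
  }
  if (mode == "i") {
    stopifnot(n >= 2, n == round(n))
    j <- seq_len(n) - 1
    B <- 2 * pi - fit$phi_max -
      2 * pi / (1 + params$tau_d / params$tau_p) *
        (1 + params$tau_d / T1 * log(sum(exp(-j * T1 / params$tau_p))))
  } else {
    B <- 2 * pi / (1 + params$tau_p / params$tau_d) - fit$phi_max
  }
  beta <- if (B <= 0) 0 else B^2 * fit$alpha / fit$Z_max
  (1 + beta) * resonance_g_fixed(fit$Z_max, epsilon, mode)
}

#' One iterate of the general pulse-driven circle map
#'
#' For a neuron with arbitrary nonnegative PRC `Z` driven by pulses of
#' strength `g` every `T_drive` time units, the phase just after successive
#' pulses obeys \eqn{\varphi^{(k+1)} = \varphi^{(k)} + \omega T_{drive} +
#' g\,Z(\varphi^{(k)} + \omega T_{drive})}, reduced modulo \eqn{2\pi}.
#'
#' @param phi current phase.
#' @param omega natural angular frequency of the driven neuron.
#' @param T_drive drive period.
#' @param g pulse strength.
#' @param Z a function of phase (vectorized, nonnegative on
#'   \eqn{[0, 2\pi]}).
#' @return the next phase in \eqn{[0, 2\pi)}.
#' @export
general_map_step <- function(phi, omega, T_drive, g, Z) {
  stopifnot(is.function(Z), omega > 0, T_drive > 0, g >= 0)
  drifted <- (phi + omega * T_drive) %% (2 * pi)
  (drifted + g * Z(drifted)) %% (2 * pi)
}
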