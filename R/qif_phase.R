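#' Natural period of a quadratic integrate-and-fire neuron
#'
#' A free QIF neuron \eqn{\dot v = v^2 + \eta} with peak/reset at
#' \eqn{\pm\infty} fires periodically with period \eqn{T = \pi/\sqrt{\eta}}
#' for any excitability \eqn{\eta > 0}.  Non-positive \eqn{\eta} puts the
#' neuron in the excitable (non-oscillatory) regime and is rejected.
#'
#' @param eta excitability parameter; must be positive.
#' @return the natural period \eqn{\pi/\sqrt{\eta}}.
#' @seealso [qif_eta()] for the inverse map.
#' @export
#' @examples
#' qif_period(1)     # pi
#' qif_period(0.25)  # 2*pi
qif_period <- function(eta) {
  stopifnot(is.numeric(eta))
  if (any(eta <= 0)) {
    stop("eta must be positive: eta <= 0 is the excitable (non-spiking) regime")
  }
  pi / sqrt(eta)
}

#' Excitability parameter for a desired natural period
#'
#' @param period natural period; must be positive.
#' @return \eqn{\eta = (\pi/T)^2}.
#' @export
qif_eta <- function(period) {
  stopifnot(is.numeric(period), all(period > 0))
  (pi / period)^2
}

#' Map a QIF membrane potential to its phase
#'
#' The change of variables \eqn{v = -\sqrt{\eta}\cot(\varphi/2)} turns the
#' QIF voltage equation into a phase oscillator.  The inverse map used here is
#' \eqn{\varphi = 2\,\mathrm{arccot}(-v/\sqrt{\eta})} with the arccot branch
#' on \eqn{(0,\pi)}, so the phase lies in \eqn{(0, 2\pi)}; \eqn{v \to +\infty}
#' maps to \eqn{2\pi} (firing) and \eqn{v \to -\infty} to 0 (reset).
#'
#' @param v membrane potential (may be `Inf` or `-Inf`).
#' @param eta positive excitability parameter.
#' @return phase in \eqn{[0, 2\pi]}.
#' @export
voltage_to_phase <- function(v, eta) {
  stopifnot(is.numeric(v), is.numeric(eta), all(eta > 0))
  # arccot(x) = pi/2 - atan(x), range (0, pi); handles +-Inf
  phi <- 2 * (pi / 2 - atan(-v / sqrt(eta)))
  phi[v == Inf] <- 2 * pi
  phi[v == -Inf] <- 0
  phi
}

#' Map a QIF phase to its membrane potential
#'
#' Exact inverse of [voltage_to_phase()].  The endpoint phases 0 and
#' \eqn{2\pi} correspond to infinite voltages; set `allow_infinite = TRUE`
#' to return signed infinities there instead of raising an error.
#'
#' @param phi phase in \eqn{(0, 2\pi)} (endpoints only with
#'   `allow_infinite = TRUE`).
#' @param eta positive excitability parameter.
#' @param allow_infinite return `-Inf`/`Inf` at the endpoints.
#' @return membrane potential \eqn{-\sqrt{\eta}\cot(\varphi/2)}.
#' @export
phase_to_voltage <- function(phi, eta, allow_infinite = FALSE) {
  stopifnot(is.numeric(phi), is.numeric(eta), all(eta > 0))
  at_end <- phi <= 0 | phi >= 2 * pi
  if (any(at_end) && !allow_infinite) {
    stop("phi must lie strictly inside (0, 2*pi); the endpoints map to ",
         "infinite voltage (set allow_infinite = TRUE to get signed Inf)")
  }
  v <- -sqrt(eta) / tan(phi / 2)
  v[phi <= 0] <- -Inf
  v[phi >= 2 * pi] <- Inf
  v
}

#' Phase response curve of the QIF neuron
#'
#' \eqn{Z(\varphi) = 2[1 - \cos\varphi]/\omega}: nonnegative (class I), zero
#' at \eqn{\varphi = 0} and maximal, \eqn{4/\omega}, at \eqn{\varphi = \pi}.
#'
#' @param phi phase (radians).
#' @param omega positive natural angular frequency \eqn{2\pi/T}.
#' @export
#' @examples
#' qif_prc(pi, omega = 1)  # 4
qif_prc <- function(phi, omega) {
  stopifnot(is.numeric(phi), is.numeric(omega), all(omega > 0))
  2 * (1 - cos(phi)) / omega
}

#' Exact phase update of a QIF neuron after free drift and a pulse
#'
#' Advances a phase by free drift over `dt` and then applies an instantaneous
#' excitatory pulse of strength `kick` (typically the coupling strength times
#' the synaptic weight) exactly, through the voltage representation:
#' \deqn{\varphi' = 2\,\mathrm{arccot}\left[\cot\left(
#'   \frac{\varphi + \omega\,dt}{2}\right) - \frac{2\,\mathrm{kick}}{\omega}
#'   \right].}
#' The arccot branch on \eqn{(0,\pi)} keeps the result in \eqn{(0, 2\pi)} and
#' guarantees the class I property that a positive pulse can only advance the
#' phase.
#'
#' @param phi phase in \eqn{[0, 2\pi)}; the drifted phase
#'   `phi + omega*dt` must not exceed \eqn{2\pi}.
#' @param omega positive natural angular frequency.
#' @param dt nonnegative elapsed drift time (default 0).
#' @param kick nonnegative pulse strength (default 0).
#' @return updated phase in \eqn{[0, 2\pi)}.
#' @export
phase_jump <- function(phi, omega, dt = 0, kick = 0) {
  stopifnot(is.numeric(phi), is.numeric(omega), all(omega > 0),
            all(dt >= 0), all(kick >= 0))
  n <- max(length(phi), length(omega), length(dt), length(kick))
  phi2 <- rep_len(phi + omega * dt, n)
  omega <- rep_len(omega, n)
  kick <- rep_len(kick, n)
  if (any(phi2 > 2 * pi + 1e-12)) {
    stop("drifted phase exceeds 2*pi; the neuron should have fired first")
  }
  out <- 2 * (pi / 2 - atan(1 / tan(phi2 / 2) - 2 * kick / omega))
  # at reset the PRC vanishes, and a zero kick is exact free drift
  unchanged <- phi2 <= 0 | kick == 0
  out[unchanged] <- phi2[unchanged]
  out
}
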