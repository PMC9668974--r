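#' Wang-Buzsaki neuron parameters
#'
#' Conductance-based hippocampal-interneuron model with state
#' \eqn{(v, h, n)}: a fast sodium current with instantaneous activation
#' \eqn{m_\infty(v)}, a delayed-rectifier potassium current and a leak.
#' Class I: spiking sets in through a saddle-node-on-invariant-circle
#' bifurcation as the direct current `I` is raised.  Defaults are the
#' standard set \eqn{(g_K, g_{Na}, g_L) = (9, 35, 0.1)} mS/cm^2,
#' \eqn{(v_K, v_{Na}, v_L) = (-90, 55, -65)} mV, gating rate scale
#' \eqn{\phi = 5}, \eqn{C_m = 1} uF/cm^2.
#'
#' @param C_m membrane capacitance (uF/cm^2).
#' @param g_K,g_Na,g_L maximal conductances (mS/cm^2).
#' @param v_K,v_Na,v_L reversal potentials (mV).
#' @param phi_gate gating rate scale (dimensionless).
#' @param I direct current (uA/cm^2).
#' @return an object of class `wb_params` (also `neuron_model`).
#' @export
wb_params <- function(C_m = 1, g_K = 9, g_Na = 35, g_L = 0.1,
                      v_K = -90, v_Na = 55, v_L = -65, phi_gate = 5,
                      I = 0.162677) {
  structure(list(kind = 1L, C_m = C_m, g_K = g_K, g_Na = g_Na, g_L = g_L,
                 v_K = v_K, v_Na = v_Na, v_L = v_L, phi_gate = phi_gate,
                 I = I,
                 par_vec = c(C_m, g_K, g_Na, g_L, v_K, v_Na, v_L,
                             phi_gate, I),
                 state0 = c(v = -64, h = 0.78, n = 0.09),
                 v_threshold = 0, period_guess = 500),
            class = c("wb_params", "neuron_model"))
}

#' Morris-Lecar neuron parameters
#'
#' Two-dimensional conductance-based class I model with state
#' \eqn{(v, n)}: instantaneous calcium activation, a potassium recovery
#' variable and a leak.  The per-neuron time-scaling factor `eta_scale`
#' multiplies both right-hand sides, so a neuron with `eta_scale = `
#' \eqn{T_{ref}/T} oscillates with period \eqn{T}, where \eqn{T_{ref}} is
#' the period at `eta_scale = 1`.  Defaults are the standard set
#' \eqn{(g_{Ca}, g_K, g_L) = (4, 8, 2)} mS/cm^2,
#' \eqn{(v_{Ca}, v_K, v_L) = (120, -80, -60)} mV, shape voltages
#' \eqn{(-1.2, 18, 12, 17.4)} mV, \eqn{I_0 = 40} uA/cm^2,
#' \eqn{C_m = 5} uF/cm^2, \eqn{\phi = 1/15} ms^-1.
#'
#' @param C_m membrane capacitance (uF/cm^2).
#' @param g_Ca,g_K,g_L maximal conductances (mS/cm^2).
#' @param v_Ca,v_K,v_L reversal potentials (mV).
#' @param v1,v2,v3,v4 activation-shape voltages (mV).
#' @param I0 direct current (uA/cm^2).
#' @param phi_rate recovery rate scale (ms^-1).
#' @param eta_scale per-neuron time-scaling factor.
#' @return an object of class `ml_params` (also `neuron_model`).
#' @export
ml_params <- function(C_m = 5, g_Ca = 4, g_K = 8, g_L = 2,
                      v_Ca = 120, v_K = -80, v_L = -60,
                      v1 = -1.2, v2 = 18, v3 = 12, v4 = 17.4,
                      I0 = 40, phi_rate = 1 / 15, eta_scale = 1) {
  structure(list(kind = 2L, C_m = C_m, g_Ca = g_Ca, g_K = g_K, g_L = g_L,
                 v_Ca = v_Ca, v_K = v_K, v_L = v_L,
                 v1 = v1, v2 = v2, v3 = v3, v4 = v4, I0 = I0,
                 phi_rate = phi_rate, eta_scale = eta_scale,
                 par_vec = c(C_m, g_Ca, g_K, g_L, v_Ca, v_K, v_L,
                             v1, v2, v3, v4, I0, phi_rate, eta_scale),
                 state0 = c(v = -30, n = 0.1),
                 v_threshold = 10, period_guess = 90 / eta_scale),
            class = c("ml_params", "neuron_model"))
}

#' QIF voltage-equation parameters with finite peak and reset
#'
#' The voltage form \eqn{\dot v = v^2 + \eta} with spike/reset at finite
#' thresholds \eqn{v_{peak} = -v_{reset}}.  Used to validate the numerical
#' PRC-extraction pipeline against the analytic QIF phase response curve.
#'
#' @param eta excitability parameter (> 0 for spiking).
#' @param v_peak spike peak (the spike time is the upward crossing).
#' @param v_reset reset voltage after a spike.
#' @return an object of class `qifv_params` (also `neuron_model`).
#' @export
qifv_params <- function(eta = 1, v_peak = 100, v_reset = -100) {
  stopifnot(eta > 0, v_peak > 0, v_reset < 0)
  structure(list(kind = 3L, eta = eta, v_peak = v_peak, v_reset = v_reset,
                 par_vec = c(eta, v_peak, v_reset),
                 state0 = c(v = 0),
                 v_threshold = v_peak, period_guess = pi / sqrt(eta)),
            class = c("qifv_params", "neuron_model"))
}

#' Integrate a neuron model
#'
#' Adaptive Dormand-Prince (RK45) integration of the model equations,
#' returning the state at the requested output times.  For the QIF voltage
#' model, threshold crossings and resets are handled inside the integrator.
#'
#' @param model a `neuron_model` ([wb_params()], [ml_params()],
#'   [qifv_params()]).
#' @param state0 initial state (defaults to the model's standard start).
#' @param times nondecreasing output times (the first entry is the start).
#' @param rtol,atol relative and absolute integration tolerances.
#' @return a matrix of states, one row per output time, with named columns.
#' @export
integrate_neuron <- function(model, times, state0 = model$state0,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "neuron_model"), is.numeric(times),
            !is.unsorted(times))
  out <- ode_states_cpp(model$kind, model$par_vec, unname(state0),
                        times[1], times, rtol, atol)
  colnames(out) <- names(model$state0)
  out
}

#' Spike times of a neuron model
#'
#' Integrates the model and returns the times of membrane-potential maxima
#' above the model's spike threshold (for the QIF voltage model, the
#' threshold-crossing/reset times).  Maxima are refined inside each
#' integration step by cubic Hermite interpolation.
#'
#' @inheritParams integrate_neuron
#' @param t_span `c(t0, t1)` integration window.
#' @param max_spikes stop after this many spikes.
#' @return a list with `times` (spike times), `states` (matrix of states at
#'   the maxima), `y_end` and `t_end`.
#' @export
neuron_spike_times <- function(model, t_span, state0 = model$state0,
                               rtol = 1e-8, atol = 1e-10,
                               max_spikes = 100000L) {
  stopifnot(inherits(model, "neuron_model"), length(t_span) == 2,
            t_span[2] > t_span[1])
  res <- ode_spikes_cpp(model$kind, model$par_vec, unname(state0),
                        t_span[1], t_span[2], rtol, atol,
                        as.integer(max_spikes))
  list(times = res$spike_times, states = res$spike_states,
       y_end = res$y_end, t_end = res$t_end)
}

#' Steady-state oscillation period of a neuron model
#'
#' Integrates until the interspike interval has settled: at least
#' `transient_cycles` initial cycles are discarded and the last two
#' intervals must agree to `settle_tol` relative.  Returns `NA` (with
#' attribute `"quiescent"`) when no spike occurs within `horizon_cap`.
#'
#' @inheritParams integrate_neuron
#' @param transient_cycles cycles discarded before measuring.
#' @param settle_tol relative agreement required between the last two
#'   interspike intervals.
#' @param horizon_cap give up (declare quiescence) after this much
#'   simulated time with no spikes (ms).
#' @return the period, with attribute `anchor_state` holding the state at
#'   the last membrane-potential maximum (phase zero on the limit cycle),
#'   or `NA_real_` if quiescent.
#' @export
measure_period <- function(model, state0 = model$state0,
                           transient_cycles = 10, settle_tol = 1e-6,
                           rtol = 1e-8, atol = 1e-10, horizon_cap = 2e4) {
  stopifnot(inherits(model, "neuron_model"))
  need <- transient_cycles + 3
  chunk <- max(model$period_guess * (need + 2), 50)
  t0 <- 0
  y <- unname(state0)
  times <- numeric(0)
  states <- NULL
  repeat {
    res <- ode_spikes_cpp(model$kind, model$par_vec, y, t0, t0 + chunk,
                          rtol, atol, 100000L)
    times <- c(times, res$spike_times)
    states <- rbind(states, res$spike_states)
    t0 <- res$t_end
    y <- res$y_end
    if (length(times) >= need) break
    if (length(times) == 0 && t0 >= horizon_cap) {
      out <- NA_real_
      attr(out, "quiescent") <- TRUE
      return(out)
    }
    if (t0 >= 20 * horizon_cap) {
      stop("period did not settle within ", 20 * horizon_cap, " time units")
    }
  }
  isi <- diff(times)
  last2 <- utils::tail(isi, 2)
  if (abs(diff(last2)) > settle_tol * mean(last2)) {
    stop("interspike interval has not settled to within ", settle_tol,
         " relative; increase transient_cycles")
  }
  period <- last2[2]
  attr(period, "anchor_state") <- states[nrow(states), ]
  attr(period, "anchor_time") <- times[length(times)]
  period
}

#' Locate the saddle-node-on-invariant-circle current
#'
#' Bisects the direct current between a quiescent and a spiking value on
#' the predicate "fires in the second half of the test horizon": below the
#' bifurcation the neuron relaxes to rest (at most a transient spike),
#' above it it fires periodically, with a period diverging like
#' \eqn{(I - I_{SNIC})^{-1/2}} at the onset.
#'
#' @param model a `wb_params` model (the current entry `I` is overridden).
#' @param bracket `c(lo, hi)` currents straddling the onset.
#' @param tol bisection tolerance on the current.
#' @param horizon test-integration length per probe (ms); must exceed the
#'   interspike period at distance `tol` from the onset.
#' @param rtol,atol integration tolerances (the predicate is topological,
#'   so moderate tolerances suffice).
#' @return the bifurcation current (midpoint of the final bracket).
#' @export
find_snic_current <- function(model, bracket = c(0.1, 0.2), tol = 1e-4,
                              horizon = 8000, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "wb_params"), length(bracket) == 2,
            bracket[1] < bracket[2], tol > 0)
  spiking <- function(I) {
    m <- model
    m$par_vec[9] <- I
    res <- ode_spikes_cpp(m$kind, m$par_vec, unname(m$state0), 0, horizon,
                          rtol, atol, 1000L)
    any(res$spike_times > horizon / 2)
  }
  lo <- bracket[1]
  hi <- bracket[2]
  if (spiking(lo) || !spiking(hi)) {
    stop("bracket does not straddle the onset: need quiescent at ",
         lo, " and spiking at ", hi)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spiking(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Numerical phase response curve of a neuron model
#'
#' Direct perturbation method: the limit cycle and period are measured
#' first; then, for each grid phase (origin: phase 0 at the
#' membrane-potential maximum, increasing with time), the on-cycle state is
#' perturbed by an instantaneous increment `kick` of the membrane
#' potential, the trajectory is integrated for `n_wait` further periods,
#' and the asymptotic advance of its spike times relative to the
#' unperturbed trajectory is converted to a phase shift.  The PRC value is
#' the shift per unit voltage perturbation; for a synaptic pulse entering
#' the current-balance equation the corresponding voltage increment is the
#' pulse strength divided by the membrane capacitance.
#'
#' @inheritParams integrate_neuron
#' @param n_phases number of grid phases over \eqn{(0, 2\pi]}.
#' @param kick voltage perturbation (mV for the conductance-based models);
#'   small enough for the linear regime (check with `linearity_check`).
#' @param n_wait periods to wait before reading off the asymptotic shift.
#' @param linearity_check also compute the curve's peak value at `kick/2`
#'   and record the relative deviation as attribute `linearity_dev`.
#' @return an object of class `prc_curve`: a data frame with columns
#'   `phase` and `Z`, with attributes `period` and (optionally)
#'   `linearity_dev`.
#' @export
compute_prc <- function(model, n_phases = 200, kick = 0.01, n_wait = 10,
                        rtol = 1e-8, atol = 1e-10,
                        linearity_check = FALSE) {
  stopifnot(inherits(model, "neuron_model"), n_phases >= 8, kick > 0)
  period <- measure_period(model, rtol = rtol, atol = atol)
  if (is.na(period)) stop("model is quiescent at these parameters")
  anchor <- attr(period, "anchor_state")

  horizon <- (n_wait + 1.5) * period
  # unperturbed spike times measured from the anchor (phase-0) state
  ref <- ode_spikes_cpp(model$kind, model$par_vec, anchor, 0, horizon,
                        rtol, atol, 100000L)
  ref_times <- ref$spike_times

  phases <- 2 * pi * seq_len(n_phases) / n_phases
  t_grid <- phases / (2 * pi) * period
  cycle_states <- ode_states_cpp(model$kind, model$par_vec, anchor, 0,
                                 t_grid, rtol, atol)

  shift_at <- function(k, kk) {
    y <- cycle_states[k, ]
    y[1] <- y[1] + kk
    pert <- ode_spikes_cpp(model$kind, model$par_vec, y, 0,
                           horizon - t_grid[k], rtol, atol, 100000L)
    pt <- pert$spike_times
    rt <- ref_times[ref_times > t_grid[k]] - t_grid[k]
    m <- min(length(pt), length(rt))
    if (m == 0) return(NA_real_)
    dphi <- 2 * pi * (rt[m] - pt[m]) / period
    # spike pairing can slip by one full cycle right at the firing phase;
    # the physical asymptotic shift is far below a cycle, so wrap it
    dphi - 2 * pi * round(dphi / (2 * pi))
  }

  Z <- vapply(seq_len(n_phases), function(k) shift_at(k, kick) / kick,
              numeric(1))
  curve <- structure(data.frame(phase = phases, Z = Z),
                     class = c("prc_curve", "data.frame"))
  attr(curve, "period") <- as.numeric(period)
  attr(curve, "kick") <- kick
  if (linearity_check) {
    k_star <- which.max(Z)
    z_half <- shift_at(k_star, kick / 2) / (kick / 2)
    attr(curve, "linearity_dev") <- abs(z_half - Z[k_star]) / Z[k_star]
  }
  curve
}

#' Parabolic fit to a phase response curve near its maximum
#'
#' Least-squares fit of \eqn{Z(\varphi) = Z_{max} - \alpha(\varphi -
#' \varphi_{max})^2} over the grid points whose value is at least
#' `window_fraction` of the curve maximum.  The window is widened
#' automatically (in 0.05 steps) if it holds fewer than `min_points`
#' points.
#'
#' @param curve a `prc_curve` from [compute_prc()], or any data frame with
#'   columns `phase` and `Z`.
#' @param window_fraction fit window as a fraction of the peak value.
#' @param min_points minimum number of points required in the window.
#' @return a [prc_fit()] object, with attribute `window_fraction` recording
#'   the window actually used.
#' @export
fit_parabola <- function(curve, window_fraction = 0.9, min_points = 5) {
  stopifnot(is.data.frame(curve), all(c("phase", "Z") %in% names(curve)),
            window_fraction > 0, window_fraction < 1)
  ok <- is.finite(curve$Z)
  phase <- curve$phase[ok]
  Z <- curve$Z[ok]
  zmax <- max(Z)
  wf <- window_fraction
  repeat {
    sel <- Z >= wf * zmax
    if (sum(sel) >= min_points) break
    wf <- wf - 0.05
    if (wf <= 0) stop("cannot find ", min_points, " points near the peak")
  }
  co <- stats::coef(stats::lm(Z[sel] ~ phase[sel] + I(phase[sel]^2)))
  a <- co[[1]]; b <- co[[2]]; c2 <- co[[3]]
  if (c2 >= 0) stop("fitted curvature is not concave near the peak")
  phi_max <- -b / (2 * c2)
  out <- prc_fit(Z_max = a - b^2 / (4 * c2), phi_max = phi_max,
                 alpha = -c2)
  attr(out, "window_fraction") <- wf
  out
}
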