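#' Configuration of a pulse-coupled network simulation
#'
#' Bundles everything the event-driven simulator needs: natural periods,
#' global coupling strength, STDP parameters, initial weights and phases,
#' the horizon and the weight-saturation stopping rule.
#'
#' Initial phases default to an almost-identical stagger
#' \eqn{\varphi_i = 10^{-3}\, 2\pi i / N}, which breaks exact firing ties
#' without biasing the asymptotic state.
#'
#' @param periods vector of natural periods \eqn{T_i > 0} (one per neuron).
#' @param g global excitatory coupling strength, \eqn{g \ge 0}.
#' @param stdp an [stdp_params()] object, or `NULL` to freeze the weights.
#' @param W0 initial weight matrix (defaults to all-to-all weight 1/2).
#' @param phases0 initial phases in \eqn{[0, 2\pi)}; default stagger above.
#' @param t_max simulation horizon (time units).
#' @param prc optional tabulated phase response curves for non-QIF neurons:
#'   a list with `phases` (increasing grid over \eqn{[0, 2\pi]}) and
#'   `values` (matrix, one column per neuron, nonnegative).  When `NULL`
#'   the exact QIF phase update is used.
#' @param conv_tol weight-saturation tolerance: a weight counts as saturated
#'   when within `conv_tol` of 0 or 1.  Links pinned at a hard bound keep
#'   bouncing by one or two update quanta (`p`, `d`) per locking cycle, and
#'   near-balance links can linger slightly off the bound while decaying
#'   very slowly, so the band must be wider than a few quanta; the default
#'   equals the connectivity threshold used by [threshold_graph()], making
#'   "saturated" and "link present/absent" coincide.
#' @param conv_patience number of periods of the slowest neuron for which
#'   all weights must stay saturated before the run stops early; set to 0
#'   to disable early stopping.
#' @param trace_stride record a full weight snapshot every `trace_stride`
#'   spike events (0 disables the trace beyond the initial/final states).
#' @param record_phases keep the post-event phase vector of every event
#'   (needed for map-consistency diagnostics; memory-heavy for long runs).
#' @param max_events hard cap on the number of spike events.
#' @return an object of class `network_config`.
#' @export
network_config <- function(periods, g, stdp = NULL, W0 = NULL, phases0 = NULL,
                           t_max = 1e4, prc = NULL, conv_tol = 0.05,
                           conv_patience = 50, trace_stride = 0,
                           record_phases = FALSE, max_events = 5e6) {
  stopifnot(is.numeric(periods), all(periods > 0), length(periods) >= 1,
            is.numeric(g), length(g) == 1, g >= 0,
            is.numeric(t_max), length(t_max) == 1, t_max > 0)
  n <- length(periods)
  if (!is.null(stdp)) stopifnot(inherits(stdp, "stdp_params"))
  if (is.null(W0)) {
    W0 <- matrix(0.5, n, n)
    diag(W0) <- 0
  }
  weight_matrix(W0)
  stopifnot(nrow(W0) == n)
  if (is.null(phases0)) {
    phases0 <- 2 * pi * seq_len(n) / n * 1e-3
  }
  stopifnot(length(phases0) == n, all(phases0 >= 0), all(phases0 < 2 * pi))
  if (!is.null(prc)) {
    stopifnot(is.list(prc), is.numeric(prc$phases),
              is.matrix(prc$values), ncol(prc$values) == n,
              nrow(prc$values) == length(prc$phases),
              !is.unsorted(prc$phases, strictly = TRUE),
              all(prc$values >= 0))
  }
  structure(list(periods = periods, omega = 2 * pi / periods, g = g,
                 stdp = stdp, W0 = W0, phases0 = phases0, t_max = t_max,
                 prc = prc, conv_tol = conv_tol,
                 conv_patience = conv_patience, trace_stride = trace_stride,
                 record_phases = record_phases,
                 max_events = as.integer(max_events)),
            class = "network_config")
}

#' Next firing event of a pulse-coupled network
#'
#' Each phase drifts linearly at its natural frequency, so the time for
#' neuron i to reach the firing phase \eqn{2\pi} is
#' \eqn{\Delta t_i = (2\pi - \varphi_i)/\omega_i}.  The next event is the
#' minimum over neurons; exact ties go to the lowest index.
#'
#' @param phases current phases in \eqn{[0, 2\pi)}.
#' @param omegas natural angular frequencies.
#' @return a list with `j` (index of the next firing neuron) and `dt`
#'   (time until it fires).
#' @export
next_event <- function(phases, omegas) {
  stopifnot(length(phases) == length(omegas), all(omegas > 0),
            all(phases >= 0), all(phases <= 2 * pi))
  dts <- (2 * pi - phases) / omegas
  j <- which.min(dts)  # which.min takes the first minimum: lowest index
  list(j = j, dt = dts[j])
}

#' Run the event-driven network simulation
#'
#' Simulates the pulse-coupled phase network exactly, event by event: the
#' next firing neuron is located analytically, all phases drift to that
#' instant, the firing neuron's spike kicks every other neuron (exact QIF
#' update, or first-order tabulated-PRC update), the STDP rule adjusts the
#' weights, and the firing phase resets to zero.  A kick that carries some
#' phase to \eqn{2\pi} triggers an immediate same-instant firing (zero-delay
#' cascade, processed in ascending index order).  With plasticity enabled
#' the run stops early once every weight has saturated near 0 or 1 for
#' `conv_patience` slow periods.
#'
#' @param config a [network_config()] object.
#' @return an object of class `spike_log`: a list with `spikes` (data frame
#'   of `t`, `neuron`), `final_W`, `weight_trace` (data frame of `t`, `i`,
#'   `j`, `w` snapshots), `converged`, `sat_time` (when the weights entered
#'   their final saturation band, or `NA`), `t_end`, `phases` (optional
#'   per-event phase matrix) and the originating `config`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  has_stdp <- !is.null(config$stdp)
  s <- if (has_stdp) config$stdp else stdp_params(p = 1, tau_p = 1, tau_d = 1)
  prc_phases <- NULL
  prc_values <- NULL
  if (!is.null(config$prc)) {
    prc_phases <- config$prc$phases
    prc_values <- config$prc$values
  }
  patience_time <- config$conv_patience * max(config$periods)
  res <- sim_network_cpp(
    omega = config$omega, g = config$g, W0 = config$W0,
    p = s$p, d = s$d, tau_p = s$tau_p, tau_d = s$tau_d,
    plastic = has_stdp, phi0 = config$phases0, t_max = config$t_max,
    conv_tol = config$conv_tol, conv_patience = patience_time,
    trace_stride = as.integer(config$trace_stride),
    max_events = config$max_events, record_phases = config$record_phases,
    prc_phases_ = prc_phases, prc_values_ = prc_values)

  n <- length(config$periods)
  trace <- NULL
  if (length(res$trace_t) > 0) {
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    trace <- data.frame(
      t = rep(res$trace_t, each = n * n),
      i = rep(idx$i, times = length(res$trace_t)),
      j = rep(idx$j, times = length(res$trace_t)),
      w = as.vector(t(res$trace_W)))
  }
  structure(list(
    spikes = data.frame(t = res$spike_t, neuron = res$spike_id),
    final_W = res$final_W,
    weight_trace = trace,
    converged = res$converged,
    sat_time = if (res$sat_time >= 0) res$sat_time else NA_real_,
    t_end = res$t_end,
    n_events = res$n_events,
    phases = res$phases,
    config = config), class = "spike_log")
}

#' @export
print.spike_log <- function(x, ...) {
  cat(sprintf(
    "spike_log: %d neurons, %d spikes over t = [0, %.4g]%s\n",
    length(x$config$periods), nrow(x$spikes), x$t_end,
    if (isTRUE(x$converged)) " (weights converged)" else ""))
  invisible(x)
}

#' Interspike intervals of one neuron
#'
#' @param log a `spike_log` from [simulate_network()].
#' @param neuron neuron index.
#' @return numeric vector of consecutive spike-time differences (empty, with
#'   a warning, if the neuron fired fewer than twice).
#' @export
interspike_intervals <- function(log, neuron) {
  stopifnot(inherits(log, "spike_log"))
  st <- log$spikes$t[log$spikes$neuron == neuron]
  if (length(st) < 2) {
    warning("neuron ", neuron, " fired fewer than twice; no intervals")
    return(numeric(0))
  }
  diff(st)
}

#' Start of the post-transient analysis window
#'
#' The later of (a) the time the weights entered their final saturation band
#' and (b) 80 percent of the simulated time; with frozen weights only (b)
#' applies.
#' @noRd
post_transient_start <- function(log, frac = 0.8) {
  t0 <- frac * log$t_end
  if (!is.na(log$sat_time)) t0 <- max(t0, log$sat_time)
  t0
}

#' Winding number of a locked pair
#'
#' Estimates the asymptotic winding number n/1 (spikes of the fast neuron
#' per period of the slow neuron) over the last `window` slow-neuron
#' periods.  The pair is reported as locked only when (a) every slow-neuron
#' interspike interval in the window contains the same integer number of
#' fast-neuron spikes and (b) the delay from each slow spike to the next
#' fast spike has converged (successive values within `tol_phase` of the
#' slow period) -- slow drift is thereby not mistaken for locking.
#'
#' @param log a `spike_log`.
#' @param fast,slow neuron indices of the faster and slower neuron.
#' @param window number of slow-neuron periods to analyze.
#' @param tol_phase relative delay-convergence tolerance.
#' @return a list with `locked` (logical), and when locked `n` and `m`
#'   (the reduced ratio n/m, here always m = 1) plus the mean `delay`; when
#'   unlocked, the raw spike-count `ratio`.
#' @export
winding_number <- function(log, fast = 1, slow = 2, window = 100,
                           tol_phase = 1e-4) {
  stopifnot(inherits(log, "spike_log"), window >= 2)
  ts_slow <- log$spikes$t[log$spikes$neuron == slow]
  ts_fast <- log$spikes$t[log$spikes$neuron == fast]
  if (length(ts_slow) < window + 1) {
    stop("analysis window (", window, " slow periods) exceeds the ",
         length(ts_slow), " slow-neuron spikes recorded")
  }
  edges <- utils::tail(ts_slow, window + 1)
  if (length(ts_fast) == 0) return(list(locked = FALSE, ratio = 0))
  counts <- vapply(seq_len(window), function(k) {
    sum(ts_fast > edges[k] & ts_fast <= edges[k + 1])
  }, integer(1))
  T_slow <- mean(diff(edges))
  delays <- vapply(seq_len(window), function(k) {
    nxt <- ts_fast[ts_fast > edges[k]]
    if (length(nxt) == 0) NA_real_ else nxt[1] - edges[k]
  }, numeric(1))
  same_count <- length(unique(counts)) == 1 && counts[1] >= 1
  delay_conv <- all(is.finite(delays)) &&
    max(abs(diff(delays))) <= tol_phase * T_slow
  if (same_count && delay_conv) {
    list(locked = TRUE, n = counts[1], m = 1L, delay = mean(delays))
  } else {
    list(locked = FALSE, ratio = sum(counts) / window)
  }
}

#' Classify the asymptotic state of a two-neuron plastic pair
#'
#' The three asymptotic modes of two mutually coupled class I neurons under
#' STDP are: mode "i" -- unidirectional link from the slow to the fast
#' neuron (\eqn{W_{12} \approx 1}, \eqn{W_{21} \approx 0}) with winding
#' number \eqn{n/1}, \eqn{n \ge 2}; mode "ii" -- the opposite link with 1/1
#' locking; mode "iii" -- both weights near zero and no locking.  Anything
#' else (unconverged weights, saturated weights without locking, ...) is
#' "other".  Neuron 1 is the faster neuron.
#'
#' @param log a two-neuron `spike_log`.
#' @param eps_w weight tolerance for "approximately 0/1".
#' @param window slow periods used for the locking test.
#' @return one of `"i"`, `"ii"`, `"iii"`, `"other"`.
#' @export
classify_mode <- function(log, eps_w = 0.05, window = 50) {
  stopifnot(inherits(log, "spike_log"))
  if (length(log$config$periods) != 2) stop("mode classification needs N = 2")
  W12 <- log$final_W[1, 2]
  W21 <- log$final_W[2, 1]
  wn <- tryCatch(winding_number(log, fast = 1, slow = 2, window = window),
                 error = function(e) list(locked = FALSE, ratio = NA))
  if (W12 > 1 - eps_w && W21 < eps_w && wn$locked && wn$n >= 2) return("i")
  if (W12 < eps_w && W21 > 1 - eps_w && wn$locked && wn$n == 1) return("ii")
  if (W12 < eps_w && W21 < eps_w && !wn$locked) return("iii")
  "other"
}
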