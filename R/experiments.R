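#' Canonical two-neuron STDP parameter set
#'
#' The reference parameters used throughout the two-neuron studies:
#' `p = d = 0.001`, `tau_p = pi/3`, `tau_d = pi` (time units of a fast
#' neuron with period `2*pi`).
#' @export
default_stdp <- function() stdp_params(p = 0.001, tau_p = pi / 3, tau_d = pi)

#' Two coupled plastic QIF neurons: the three asymptotic presets
#'
#' Runs the canonical two-neuron demonstrations of the three asymptotic
#' modes.  All presets share `T1 = 2*pi` and the [default_stdp()] rule;
#' they differ in the detuning, the coupling and the initial weights
#' `(W12, W21)`:
#' \describe{
#'   \item{`"slow-pacemaker"`}{`T2 = 1.85*T1`, `g = 0.7`, start (0.9, 0.1):
#'     converges to mode i -- the slow neuron enslaves the fast one
#'     (weights (1, 0)), which fires twice per slow period.}
#'   \item{`"fast-pacemaker"`}{`T2 = 1.05*T1`, `g = 0.15`, start
#'     (0.1, 0.9): converges to mode ii -- weights (0, 1), both neurons
#'     firing with the fast period.}
#'   \item{`"decoupled"`}{same parameters, start (0.5, 0.5): both weights
#'     decay to zero and the neurons run free (mode iii).}
#' }
#' The starting weights of the last two presets are implementation
#' choices found by a basin search, not uniquely determined quantities.
#'
#' @param preset which demonstration to run.
#' @param t_max simulation horizon.
#' @param conv_patience slow periods of weight saturation before stopping.
#' @param W0 optionally override the preset's initial `(W12, W21)`.
#' @param trace_stride weight-snapshot stride (events).
#' @return a list with the `spike_log` (`log`), the classified `mode` and
#'   the `winding` estimate.
#' @export
run_two_neuron <- function(preset = c("slow-pacemaker", "fast-pacemaker",
                                      "decoupled"),
                           t_max = 5e4, conv_patience = 120, W0 = NULL,
                           trace_stride = 25) {
  preset <- match.arg(preset)
  T1 <- 2 * pi
  setup <- switch(preset,
    "slow-pacemaker" = list(T2 = 1.85 * T1, g = 0.7, w = c(0.9, 0.1)),
    "fast-pacemaker" = list(T2 = 1.05 * T1, g = 0.15, w = c(0.1, 0.9)),
    "decoupled"      = list(T2 = 1.05 * T1, g = 0.15, w = c(0.5, 0.5)))
  if (is.null(W0)) {
    W0 <- matrix(0, 2, 2)
    W0[1, 2] <- setup$w[1]
    W0[2, 1] <- setup$w[2]
  }
  # for a pair, the bound-bounce amplitude is a couple of update quanta,
  # so a tight saturation band is attainable and gives cleaner asymptotics
  cfg <- network_config(periods = c(T1, setup$T2), g = setup$g,
                        stdp = default_stdp(), W0 = W0, t_max = t_max,
                        conv_patience = conv_patience, conv_tol = 5e-3,
                        trace_stride = trace_stride)
  log <- simulate_network(cfg)
  wind <- tryCatch(winding_number(log, window = 50),
                   error = function(e) list(locked = FALSE))
  list(log = log, mode = classify_mode(log), winding = wind)
}

#' Arnold-tongue scan by direct simulation
#'
#' Maps the locked region of a two-neuron system on a grid of period
#' ratios and coupling strengths by running the event-driven simulator at
#' every grid point and testing for frequency locking.  Two probes are
#' available under STDP.  The `"attraction"` probe starts inside the
#' candidate mode's basin with a weight margin (mode i from `(W12, W21) =
#' (1 - margin, margin)`, mode ii mirrored) and requires full convergence;
#' because the per-cycle weight budget vanishes linearly at the analytic
#' boundary, this probe needs ever longer horizons near the edge and reads
#' slightly high at any finite horizon.  The `"stability"` probe starts
#' exactly at the saturated mode configuration and asks whether plasticity
#' keeps it there -- the quantity the closed-form boundaries describe --
#' and resolves the boundary to one grid step at moderate horizons.
#' Frozen scans (`stdp = NULL`) pin the weights at exactly (1, 0) or
#' (0, 1).  Attraction runs whose weights have not saturated at the
#' horizon are marked undecided and retried once at four times the
#' horizon; still-undecided points stay `NA`.
#'
#' @param T1 fast neuron's natural period.
#' @param ratios vector of period ratios `T2/T1` (> 1).
#' @param gs vector of coupling strengths.
#' @param stdp an [stdp_params()] object, or `NULL` for a frozen-weight
#'   scan.
#' @param mode `"i"` (slow drives fast) or `"ii"` (fast drives slow).
#' @param n_periods horizon in slow-neuron periods per grid point.
#' @param window slow periods for the locking test.
#' @param margin basin margin for the attraction probe's initial weights.
#' @param probe `"attraction"` or `"stability"` (ignored for frozen
#'   scans).
#' @return an object of class `tongue_scan`: list with `ratios`, `gs`,
#'   `locked` (logical matrix, ratios x gs), `winding` (integer matrix),
#'   `mode`, `with_stdp`.
#' @export
scan_tongue <- function(T1, ratios, gs, stdp = NULL, mode = c("i", "ii"),
                        n_periods = 2000, window = 40, margin = 0.1,
                        probe = c("attraction", "stability")) {
  mode <- match.arg(mode)
  probe <- match.arg(probe)
  stopifnot(all(ratios > 1), all(gs >= 0), T1 > 0)
  if (!is.null(stdp)) assert_symmetric_stdp(stdp)
  locked <- matrix(NA, length(ratios), length(gs))
  wind <- matrix(NA_integer_, length(ratios), length(gs))

  probe_point <- function(ratio, g, horizon_periods) {
    T2 <- ratio * T1
    W0 <- matrix(0, 2, 2)
    attraction <- !is.null(stdp) && probe == "attraction"
    if (attraction) {
      if (mode == "i") { W0[1, 2] <- 1 - margin; W0[2, 1] <- margin }
      else             { W0[1, 2] <- margin;     W0[2, 1] <- 1 - margin }
    } else {
      if (mode == "i") W0[1, 2] <- 1 else W0[2, 1] <- 1
    }
    cfg <- network_config(periods = c(T1, T2), g = g, stdp = stdp, W0 = W0,
                          t_max = horizon_periods * T2,
                          conv_patience = if (attraction) window + 10 else 0)
    log <- simulate_network(cfg)
    if (attraction && !log$converged) return(NULL)  # undecided
    wn <- tryCatch(winding_number(log, window = window),
                   error = function(e) list(locked = FALSE))
    n_expect <- if (mode == "i") round(ratio) else 1L
    is_locked <- wn$locked && wn$n == n_expect
    if (!is.null(stdp)) {
      md <- classify_mode(log, window = window)
      is_locked <- is_locked && md == mode
    }
    list(locked = is_locked, n = if (wn$locked) wn$n else NA_integer_)
  }

  for (a in seq_along(ratios)) {
    for (b in seq_along(gs)) {
      res <- probe_point(ratios[a], gs[b], n_periods)
      if (is.null(res)) res <- probe_point(ratios[a], gs[b], 4 * n_periods)
      if (!is.null(res)) {
        locked[a, b] <- res$locked
        wind[a, b] <- res$n
      }
    }
  }
  structure(list(ratios = ratios, gs = gs, locked = locked, winding = wind,
                 mode = mode, with_stdp = !is.null(stdp)),
            class = "tongue_scan")
}

#' Lowest locking coupling per ratio in a tongue scan
#'
#' @param scan a `tongue_scan`.
#' @return numeric vector (per ratio) of the smallest scanned `g` that
#'   locked, `NA` if none did.
#' @export
tongue_boundary <- function(scan) {
  stopifnot(inherits(scan, "tongue_scan"))
  apply(scan$locked, 1, function(row) {
    hit <- which(row)
    if (length(hit) == 0) NA_real_ else scan$gs[min(hit)]
  })
}

#' Recipe for a two-group (fast/slow) plastic network
#'
#' Builds the canonical heterogeneous network: `n_fast` fast neurons with
#' natural periods equidistant over `fast_range` followed by `n_slow`
#' slow neurons over `slow_range` (periods ascending with index, both
#' endpoints included).  Two initialization schemes for the weights:
#' \describe{
#'   \item{`"structured"`}{within-group weights uniform on \[0, 1\];
#'     cross-group weights deterministic -- fast-to-slow links 0.05,
#'     slow-to-fast links 0.9.}
#'   \item{`"random"`}{every off-diagonal weight uniform on \[0, 1\].}
#' }
#'
#' @param n_fast,n_slow group sizes.
#' @param fast_range,slow_range closed period intervals for the groups.
#' @param g coupling strength.
#' @param stdp an [stdp_params()] object.
#' @param init initialization scheme.
#' @param seed RNG seed for the random weights.
#' @return a list of class `network_recipe`.
#' @export
group_network_recipe <- function(n_fast = 20, n_slow = 5,
                                 fast_range = c(6.28, 6.61),
                                 slow_range = c(12.31, 12.56),
                                 g = 0.25, stdp = default_stdp(),
                                 init = c("structured", "random"),
                                 seed = 1L) {
  init <- match.arg(init)
  stopifnot(n_fast >= 1, n_slow >= 1, fast_range[2] < slow_range[1])
  periods <- c(seq(fast_range[1], fast_range[2], length.out = n_fast),
               seq(slow_range[1], slow_range[2], length.out = n_slow))
  structure(list(n_fast = n_fast, n_slow = n_slow, periods = periods,
                 g = g, stdp = stdp, init = init, seed = as.integer(seed)),
            class = "network_recipe")
}

#' Initial weight matrix of a network recipe
#' @param recipe a `network_recipe`.
#' @return the seeded initial weight matrix.
#' @export
recipe_initial_weights <- function(recipe) {
  stopifnot(inherits(recipe, "network_recipe"))
  n <- recipe$n_fast + recipe$n_slow
  fast <- seq_len(recipe$n_fast)
  slow <- recipe$n_fast + seq_len(recipe$n_slow)
  # draw under the recipe seed without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(recipe$seed)
  W <- matrix(stats::runif(n * n), n, n)
  if (recipe$init == "structured") {
    W[slow, fast] <- 0.05  # fast presynaptic -> slow postsynaptic
    W[fast, slow] <- 0.9   # slow presynaptic -> fast postsynaptic
  }
  diag(W) <- 0
  W
}

#' Run a two-group plastic network to convergence
#'
#' Simulates the recipe, thresholds the final weights, measures actual
#' periods and extracts the cluster/pacemaker report.
#'
#' @param recipe a [group_network_recipe()].
#' @param t_max simulation horizon.
#' @param conv_patience slow periods of saturation before stopping.
#' @param eps_w saturation tolerance for the connectivity graph.
#' @return a list with `log` (`spike_log`), `graph`
#'   (`connectivity_graph`), `periods` (from [actual_periods()]) and
#'   `report` (`pattern_report`).
#' @export
run_group_network <- function(recipe, t_max = 8e5, conv_patience = 50,
                              eps_w = 0.05) {
  stopifnot(inherits(recipe, "network_recipe"))
  W0 <- recipe_initial_weights(recipe)
  cfg <- network_config(periods = recipe$periods, g = recipe$g,
                        stdp = recipe$stdp, W0 = W0, t_max = t_max,
                        conv_patience = conv_patience)
  log <- simulate_network(cfg)
  graph <- threshold_graph(log$final_W, eps_w = eps_w,
                           periods = recipe$periods)
  per <- actual_periods(log)
  report <- find_clusters(graph, per)
  list(log = log, graph = graph, periods = per, report = report)
}

#' Validate the near-resonance boundary formulas
#'
#' Compares the closed-form near-resonance tongue boundaries under STDP
#' with boundaries measured by direct simulation.  For the exact QIF case
#' (`prc = NULL`) the simulation route is replaced by the exact closed
#' forms ([g1_stdp()]/[g2_stdp()]); with a tabulated PRC the boundary is
#' bisected on the coupling strength using the event engine with that PRC,
#' starting from the saturated mode configuration (the stability probe of
#' [scan_tongue()]).
#'
#' @param T1 fast neuron's natural period.
#' @param stdp an [stdp_params()] object.
#' @param epsilons detunings \eqn{T_2/T_1 - n} to probe (signs per mode).
#' @param mode `"i"` or `"ii"`.
#' @param n winding integer (mode i); ignored for mode ii.
#' @param prc optional `prc_curve` of the driven neuron; `NULL` selects
#'   the exact QIF comparison.
#' @param fit optional [prc_fit()]; computed from `prc` (or taken
#'   analytic for QIF) when missing.
#' @param n_periods simulation horizon (slow periods) per bisection probe.
#' @param bisect_iter bisection iterations on g.
#' @return data frame with `epsilon`, `g_formula`, `g_reference`,
#'   `rel_dev`.
#' @export
validate_resonance <- function(T1, stdp, epsilons, mode = c("i", "ii"),
                               n = 2L, prc = NULL, fit = NULL,
                               n_periods = 600, bisect_iter = 12) {
  mode <- match.arg(mode)
  assert_symmetric_stdp(stdp)
  omega1 <- 2 * pi / T1
  if (mode == "ii") n <- 1L
  if (is.null(fit)) {
    fit <- if (is.null(prc)) {
      # analytic QIF peak, evaluated at resonance (T2 = n*T1) where the
      # driven neuron's frequency equals omega1 up to O(epsilon)
      prc_fit(Z_max = 4 / omega1, phi_max = pi, alpha = 1 / omega1)
    } else {
      fit_parabola(prc)
    }
  }

  ref_boundary <- function(eps) {
    T2 <- (n + eps) * T1
    if (is.null(prc)) {
      if (mode == "i") g1_stdp(T1, T2, stdp, n) else g2_stdp(T1, T2, stdp)
    } else {
      g_formula <- resonance_g_stdp(fit, eps, n, T1, stdp, mode)
      lo <- 0.2 * g_formula
      hi <- 5 * g_formula
      prc_tab <- list(phases = c(0, prc$phase),
                      values = cbind(c(0, pmax(prc$Z, 0)),
                                     c(0, pmax(prc$Z, 0))))
      locks <- function(g) {
        # stability probe: start at the saturated mode configuration
        W0 <- matrix(0, 2, 2)
        if (mode == "i") W0[1, 2] <- 1 else W0[2, 1] <- 1
        cfg <- network_config(periods = c(T1, T2), g = g, stdp = stdp,
                              W0 = W0, t_max = n_periods * T2,
                              prc = prc_tab, conv_patience = 0)
        log <- simulate_network(cfg)
        identical(classify_mode(log, window = 20), mode)
      }
      if (!locks(hi)) return(NA_real_)
      for (it in seq_len(bisect_iter)) {
        mid <- (lo + hi) / 2
        if (locks(mid)) hi <- mid else lo <- mid
      }
      (lo + hi) / 2
    }
  }

  g_formula <- vapply(epsilons, function(eps)
    resonance_g_stdp(fit, eps, n, T1, stdp, mode), numeric(1))
  g_reference <- vapply(epsilons, ref_boundary, numeric(1))
  data.frame(epsilon = epsilons, g_formula = g_formula,
             g_reference = g_reference,
             rel_dev = abs(g_formula - g_reference) / g_reference)
}
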