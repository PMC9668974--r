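# Independent oracles used across the suite.  None of these call the
# closed-form boundary/threshold functions they are used to check; they are
# built on the elementary phase update (itself cross-checked against the
# voltage transform) and on brute-force iteration/bisection.

# Pure-R reference event engine working entirely through the voltage
# representation (transform, add the kick, transform back).
ref_simulate <- function(periods, g, W, stdp, phi, t_max) {
  N <- length(periods)
  omega <- 2 * pi / periods
  eta <- (pi / periods)^2
  t <- 0
  last <- rep(NA_real_, N)
  sp_t <- numeric(0)
  sp_i <- integer(0)
  repeat {
    dts <- (2 * pi - phi) / omega
    j <- which.min(dts)
    dt <- max(dts[j], 0)
    if (t + dt > t_max) break
    t <- t + dt
    phi <- phi + omega * dt
    sp_t <- c(sp_t, t)
    sp_i <- c(sp_i, j)
    for (i in seq_len(N)) {
      if (i == j || phi[i] <= 0) next
      kick <- g * W[i, j]
      if (kick > 0) {
        v <- -sqrt(eta[i]) / tan(phi[i] / 2)
        phi[i] <- 2 * (pi / 2 - atan(-(v + kick) / sqrt(eta[i])))
      }
    }
    if (!is.null(stdp)) {
      for (i in seq_len(N)) {
        if (i == j || is.na(last[i])) next
        d <- t - last[i]
        W[j, i] <- min(1, max(0, W[j, i] + stdp$p * exp(-d / stdp$tau_p)))
        W[i, j] <- min(1, max(0, W[i, j] - stdp$d * exp(-d / stdp$tau_d)))
      }
    }
    last[j] <- t
    phi[j] <- 0
  }
  list(t = sp_t, id = sp_i, W = W)
}

# One iterate of the exact pulse-driven QIF circle map.
map_iterate <- function(phi, omega, T_drive, g) {
  phase_jump((phi + omega * T_drive) %% (2 * pi), omega, 0, g)
}

# Iterate the map to a fixed point; NA if not converged within the cap.
map_fixed_point <- function(omega, T_drive, g, phi0 = 3.0, cap = 5000,
                            tol = 1e-13) {
  phi <- phi0
  for (k in seq_len(cap)) {
    phi2 <- map_iterate(phi, omega, T_drive, g)
    if (abs(phi2 - phi) < tol && k > 10) return(phi2)
    phi <- phi2
  }
  NA_real_
}

# Existence oracle: an n/1 fixed point of the kicked-rotation map exists
# iff the maximal single-kick phase advance covers the per-drive-period
# phase deficit 2*pi*n - omega*T_drive.
max_advance <- function(omega, g) {
  stats::optimize(function(ph) phase_jump(ph, omega, 0, g) - ph,
                  interval = c(1e-9, 2 * pi - 1e-9),
                  maximum = TRUE, tol = 1e-12)$objective
}

lock_exists <- function(omega, T_drive, g, n) {
  deficit <- 2 * pi * n - omega * T_drive
  if (deficit <= 0) return(TRUE)
  max_advance(omega, g) >= deficit
}

# Bisection oracle for the fixed-weight tongue boundary.
g_fixed_oracle <- function(T_resp, T_drive, n, lo = 1e-8, hi = 50,
                           rel_tol = 1e-9) {
  omega <- 2 * pi / T_resp
  stopifnot(!lock_exists(omega, T_drive, lo, n),
            lock_exists(omega, T_drive, hi, n))
  while (hi - lo > rel_tol * hi) {
    mid <- (lo + hi) / 2
    if (lock_exists(omega, T_drive, mid, n)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Bisection oracle for the STDP tongue boundary: the smallest g at which
# the map's stable fixed point satisfies the stability condition
# phi_bar > 2*pi*(1 - Q).
g_stdp_oracle <- function(T1, T2, stdp, mode) {
  if (mode == "i") {
    omega <- 2 * pi / T1
    T_drive <- T2
    n <- ceiling(T2 / T1)
    Q <- q1_threshold(T1, T2, n, stdp$tau_p, stdp$tau_d)
  } else {
    omega <- 2 * pi / T2
    T_drive <- T1
    n <- 1
    Q <- q2_threshold(T1, T2, stdp$tau_p, stdp$tau_d)
  }
  ok <- function(g) {
    if (!lock_exists(omega, T_drive, g, n)) return(FALSE)
    fp <- map_fixed_point(omega, T_drive, g)
    !is.na(fp) && fp > 2 * pi * (1 - Q)
  }
  lo <- 1e-8
  hi <- 50
  stopifnot(!ok(lo), ok(hi))
  while (hi - lo > 1e-9 * hi) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

canonical_stdp <- function() stdp_params(p = 0.001, tau_p = pi / 3,
                                         tau_d = pi)
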