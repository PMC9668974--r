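T1 <- 2 * pi

test_that("stability thresholds reduce to their closed special cases", {
  expect_equal(q1_threshold(T1, 1.3 * T1, 1, tau_p = 2, tau_d = 2), 1.3 / 2)
  expect_equal(q1_threshold(T1, 1.3 * T1, 1, tau_p = 1, tau_d = 3), 1.3 / 4)
  expect_equal(q2_threshold(T1, T1, tau_p = 2, tau_d = 2), 1 / 2)
  expect_equal(q2_threshold(T1, T1, tau_p = 1, tau_d = 3), 1 / 4)
  expect_equal(q2_threshold(T1, 1.05 * T1, 1, 3), (1 / 1.05) / 4)
  expect_error(q1_threshold(T1, 2 * T1, 2, tau_p = 2, tau_d = 1), "tau_p")
  expect_error(q2_threshold(T1, 2 * T1, tau_p = 2, tau_d = 1), "tau_p")
})

test_that("per-cycle weight budgets match replayed STDP increments", {
  # oracle: run the frozen locked pair, replay the pair rule over one
  # asymptotic cycle and accumulate the signed increments
  s <- canonical_stdp()
  T2 <- 1.85 * T1
  W0 <- matrix(0, 2, 2); W0[1, 2] <- 1
  log <- simulate_network(network_config(c(T1, T2), g = 0.7, W0 = W0,
                                         t_max = 3000, conv_patience = 0))
  sp <- log$spikes
  t2 <- sp$t[sp$neuron == 2]
  k <- length(t2) - 1
  cycle <- sp[sp$t > t2[k - 1] & sp$t <= t2[k], ]
  expect_identical(cycle$neuron, c(1L, 1L, 2L))  # winding 2/1
  deltaT <- cycle$t[1] - t2[k - 1]
  # replay the nearest-neighbor increments without clipping; only the
  # driver's cycle-start spike time is needed as prior history
  last <- c(NA_real_, t2[k - 1])
  dW12 <- 0; dW21 <- 0
  for (r in seq_len(nrow(cycle))) {
    tj <- cycle$t[r]; j <- cycle$neuron[r]; i <- 3 - j
    d <- tj - last[i]
    if (j == 1) {
      dW12 <- dW12 + s$p * exp(-d / s$tau_p)
      dW21 <- dW21 - s$d * exp(-d / s$tau_d)
    } else {
      dW21 <- dW21 + s$p * exp(-d / s$tau_p)
      dW12 <- dW12 - s$d * exp(-d / s$tau_d)
    }
    last[j] <- tj
  }
  bud <- weight_budget_mode_i(T1, T2, 2, deltaT, s)
  expect_equal(bud[["dW12"]], dW12, tolerance = 1e-9)
  expect_equal(bud[["dW21"]], dW21, tolerance = 1e-9)
  # and the stationary delay matches the stationary phase
  phi_bar <- stationary_phase_qif(T2, T1, 0.7)
  expect_equal(deltaT, (2 * pi - phi_bar) / 1, tolerance = 1e-8)
})

test_that("budget sign changes occur exactly at the thresholds", {
  s <- canonical_stdp()
  T2 <- 1.85 * T1
  Q1 <- q1_threshold(T1, T2, 2, s$tau_p, s$tau_d)
  root <- stats::uniroot(function(dT)
    weight_budget_mode_i(T1, T2, 2, dT, s)[["dW12"]],
    c(1e-9, 0.85 * T1 - 1e-9), tol = 1e-15)$root
  expect_equal(root / T1, Q1, tolerance = 1e-12)
  T2b <- 1.05 * T1
  Q2 <- q2_threshold(T1, T2b, s$tau_p, s$tau_d)
  root2 <- stats::uniroot(function(dT)
    weight_budget_mode_ii(T1, dT, s)[["dW21"]],
    c(1e-9, T1 - 1e-9), tol = 1e-15)$root
  expect_equal(root2 / T2b, Q2, tolerance = 1e-12)
  # single-term budget: symmetric point of the 1/1 cycle with equal
  # windows balances potentiation and depression exactly
  se <- stdp_params(p = 0.001, tau_p = 1, tau_d = 1)
  bud <- weight_budget_mode_ii(T1, T1 / 2, se)
  expect_equal(bud[["dW12"]], -bud[["dW21"]], tolerance = 1e-18)
  expect_equal(bud[["dW12"]], 0, tolerance = 1e-18)
})

test_that("stationary phase matches brute-force map iteration", {
  for (case in list(c(1.85, 0.7), c(1.6, 1.2), c(1.3, 2.2))) {
    T2 <- case[1] * T1
    fp <- stationary_phase_qif(T2, T1, case[2])
    expect_equal(fp, map_fixed_point(1, T2, case[2]), tolerance = 1e-10)
  }
  # below the tongue no fixed point exists
  expect_true(is.na(stationary_phase_qif(1.85 * T1, T1, 0.1)))
  expect_true(is.na(map_fixed_point(1, 1.85 * T1, 0.1)))
  # on the boundary the stationary phase takes its closed-form value
  g1 <- g1_fixed(T1, 1.85 * T1)
  phiA <- 2 * pi * (1 - (1.85 - 2 + 1) / 2)
  expect_equal(stationary_phase_qif(1.85 * T1, T1, g1 * (1 + 1e-12)), phiA,
               tolerance = 1e-4)
})

test_that("fixed-weight boundaries have the right anchors and limits", {
  expect_equal(g1_fixed(T1, 1.5 * T1), 1, tolerance = 1e-12)  # cot(pi/4)=1
  expect_lt(g1_fixed(T1, 1.999 * T1), 0.002)
  expect_gt(g1_fixed(T1, 1.001 * T1), 600)
  expect_equal(g2_fixed(T1, T1), 0, tolerance = 1e-12)
  expect_equal(g2_fixed(T1, 2 * T1), 0.5, tolerance = 1e-12) # omega2*cot(pi/4)
  expect_error(g1_fixed(T1, 1.5 * T1, n = 3), "n - 1")
})

test_that("all four boundary families agree with bisection oracles", {
  s <- canonical_stdp()
  ratios_i <- seq(1.55, 1.97, length.out = 20)
  for (r in ratios_i) {
    T2 <- r * T1
    expect_equal(g1_fixed(T1, T2), g_fixed_oracle(T1, T2, 2),
                 tolerance = 1e-6)
    expect_equal(g1_stdp(T1, T2, s), g_stdp_oracle(T1, T2, s, "i"),
                 tolerance = 1e-6)
  }
  ratios_ii <- seq(1.02, 1.45, length.out = 20)
  for (r in ratios_ii) {
    T2 <- r * T1
    expect_equal(g2_fixed(T1, T2), g_fixed_oracle(T2, T1, 1),
                 tolerance = 1e-6)
    expect_equal(g2_stdp(T1, T2, s), g_stdp_oracle(T1, T2, s, "ii"),
                 tolerance = 1e-6)
  }
})

test_that("plastic boundaries contain the fixed-weight boundaries", {
  s <- canonical_stdp()
  for (r in seq(1.1, 1.95, by = 0.05)) {
    T2 <- r * T1
    if (r > 1.5) expect_gte(g1_stdp(T1, T2, s), g1_fixed(T1, T2))
    expect_gte(g2_stdp(T1, T2, s), g2_fixed(T1, T2))
  }
  # with near-equal windows the two mode-i boundaries can coincide
  se <- stdp_params(p = 0.001, tau_p = pi * 0.99, tau_d = pi)
  expect_equal(g1_stdp(T1, 1.9 * T1, se), g1_fixed(T1, 1.9 * T1))
})

test_that("near-resonance formulas recover the QIF limits", {
  # fixed weights: g1 = -(omega1/2)*pi*eps, g2 = omega2*pi*eps/2
  w1 <- 1
  expect_equal(resonance_g_fixed(4 / w1, -0.02, "i"), (w1 / 2) * pi * 0.02)
  T2 <- 1.02 * T1
  w2 <- 2 * pi / T2
  expect_equal(resonance_g_fixed(4 / w2, 0.02, "ii"), w2 * pi * 0.02 / 2)
  expect_equal(resonance_g_fixed(4, 0, "i"), 0)
  expect_error(resonance_g_fixed(4, 0.1, "i"), "epsilon")
  expect_error(resonance_g_fixed(4, -0.1, "ii"), "epsilon")
  # agreement with the exact boundary improves toward the resonance
  devs <- sapply(c(0.04, 0.02, 0.01), function(e)
    abs(resonance_g_fixed(4, -e, "i") / g1_fixed(T1, (2 - e) * T1) - 1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 1e-4)
})

test_that("plastic near-resonance boundary matches its validity regime", {
  # mild window asymmetry: the linearized (1 + beta) form converges to the
  # exact boundary
  s2 <- stdp_params(p = 0.001, tau_p = pi / 1.2, tau_d = pi)
  fit <- prc_fit(4, pi, 1)
  for (e in c(0.02, 0.01)) {
    expect_equal(resonance_g_stdp(fit, -e, 2, T1, s2, "i") /
                   g1_stdp(T1, (2 - e) * T1, s2), 1, tolerance = 5e-3)
    expect_equal(resonance_g_stdp(fit, e, 1, T1, s2, "ii") /
                   g2_stdp(T1, (1 + e) * T1, s2), 1, tolerance = 5e-2)
  }
  # strongly asymmetric windows: the linearization saturates at the
  # predictable plateau (1 + beta) * sin^2(pi * Q1) instead of 1
  s <- canonical_stdp()
  B1 <- 2 * pi - pi - (2 * pi / 4) *
    (1 + (s$tau_d / T1) * log(1 + exp(-T1 / s$tau_p)))
  beta <- B1^2 / 4
  Q1 <- q1_threshold(T1, 2 * T1, 2, s$tau_p, s$tau_d)
  plateau <- (1 + beta) * sin(pi * Q1)^2
  ratio <- resonance_g_stdp(fit, -0.005, 2, T1, s, "i") /
    g1_stdp(T1, 1.995 * T1, s)
  expect_equal(ratio, plateau, tolerance = 0.01)
  # the zero-margin branch reduces to the fixed-weight formula
  fit_low <- prc_fit(4, 6.1, 1)   # peak so late that B1 <= 0
  expect_equal(resonance_g_stdp(fit_low, -0.02, 2, T1, s, "i"),
               resonance_g_fixed(4, -0.02, "i"))
  expect_error(resonance_g_stdp(fit, -0.3, 2, T1, s, "i"), "near-resonance")
})

test_that("the general circle map reduces to rotation and the QIF map", {
  Zq <- function(ph) qif_prc(ph, 1)
  expect_equal(general_map_step(1, 1, 3, 0, Zq), (1 + 3) %% (2 * pi))
  # with the QIF PRC it is the first-order version of the exact map
  phi <- seq(0.3, 6, length.out = 12)
  g <- 0.01
  exact <- map_iterate(phi, 1, 1.85 * T1, g) %% (2 * pi)
  approx <- sapply(phi, general_map_step, omega = 1, T_drive = 1.85 * T1,
                   g = g, Z = Zq)
  expect_equal(approx, exact, tolerance = 1e-3)
  # iterating the parabolic-PRC map converges to the closed-form root
  fitZ <- function(ph) pmax(4 - (ph - pi)^2, 0)
  eps <- -0.02
  g <- 1.2 * resonance_g_fixed(4, eps, "i")
  phi <- 3
  for (k in 1:5000) phi <- general_map_step(phi, 1, (2 + eps) * T1, g, fitZ)
  closed <- pi - 2 * pi * eps + sqrt((2 * pi * eps / g + 4) / 1)
  expect_equal(phi, closed %% (2 * pi), tolerance = 1e-8)
})
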