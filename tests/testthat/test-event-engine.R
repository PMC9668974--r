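test_that("next_event picks the earliest firing with index tie-break", {
  expect_equal(next_event(c(pi, 0), c(1, 1)), list(j = 1L, dt = pi))
  expect_equal(next_event(c(0, 0), c(2, 1)), list(j = 1L, dt = pi))
  expect_equal(next_event(c(pi, pi), c(1, 1))$j, 1L)
  expect_equal(next_event(c(0.2, 5), c(1, 1))$j, 2L)
})

test_that("a free neuron spikes at exact multiples of its period", {
  cfg <- network_config(periods = 2 * pi, g = 0, t_max = 20 * pi + 0.1,
                        phases0 = 0, conv_patience = 0)
  log <- simulate_network(cfg)
  st <- log$spikes$t
  expect_length(st, 10)
  expect_equal(st, 2 * pi * (1:10), tolerance = 1e-12)
})

test_that("the compiled engine reproduces the voltage-route reference exactly", {
  set.seed(7)
  periods <- c(2 * pi, 1.4 * 2 * pi, 2.3 * 2 * pi)
  W0 <- matrix(runif(9), 3, 3); diag(W0) <- 0
  s <- stdp_params(p = 0.01, d = 0.01, tau_p = 1, tau_d = 2.5)
  phi0 <- 2 * pi * (1:3) / 3 * 1e-3
  cfg <- network_config(periods, g = 0.4, stdp = s, W0 = W0,
                        phases0 = phi0, t_max = 500, conv_patience = 0)
  log <- simulate_network(cfg)
  ref <- ref_simulate(periods, 0.4, W0, s, phi0, 500)
  expect_equal(nrow(log$spikes), length(ref$t))
  expect_equal(log$spikes$t, ref$t, tolerance = 1e-11)
  expect_identical(log$spikes$neuron, ref$id)
  expect_equal(log$final_W, ref$W, tolerance = 1e-12)
})

test_that("phases sampled at driver spikes obey the exact circle map", {
  W0 <- matrix(0, 2, 2); W0[1, 2] <- 1
  cfg <- network_config(c(2 * pi, 1.85 * 2 * pi), g = 0.7, W0 = W0,
                        t_max = 2000, record_phases = TRUE,
                        conv_patience = 0)
  log <- simulate_network(cfg)
  i2 <- which(log$spikes$neuron == 2)
  ph1 <- log$phases[i2, 1]
  pred <- map_iterate(ph1[-length(ph1)], 1, 1.85 * 2 * pi, 0.7)
  expect_equal(pred, ph1[-1], tolerance = 1e-12)
})

test_that("interspike intervals summarize the spike log", {
  cfg <- network_config(periods = pi, g = 0, t_max = 10 * pi,
                        phases0 = 0, conv_patience = 0)
  log <- simulate_network(cfg)
  expect_equal(interspike_intervals(log, 1), rep(pi, 9), tolerance = 1e-12)
  log$spikes <- data.frame(t = c(0, 2, 5), neuron = c(1L, 1L, 1L))
  expect_equal(interspike_intervals(log, 1), c(2, 3))
  expect_warning(iv <- interspike_intervals(log, 2), "fewer than twice")
  expect_length(iv, 0)
})

test_that("winding number distinguishes locking from drift", {
  # frozen unidirectional drive well inside the 2/1 tongue
  W0 <- matrix(0, 2, 2); W0[1, 2] <- 1
  cfg <- network_config(c(2 * pi, 1.85 * 2 * pi), g = 0.7, W0 = W0,
                        t_max = 3000, conv_patience = 0)
  wn <- winding_number(simulate_network(cfg), window = 50)
  expect_true(wn$locked)
  expect_equal(wn$n, 2L)
  # uncoupled irrational ratio never locks
  cfg0 <- network_config(c(2 * pi, sqrt(2) * 2 * pi), g = 0,
                         t_max = 3000, conv_patience = 0)
  wn0 <- winding_number(simulate_network(cfg0), window = 50)
  expect_false(wn0$locked)
  # asymptotic two-interval structure: adjacent intervals of the driven
  # neuron differ but sum to the driver period
  log <- simulate_network(network_config(c(2 * pi, 1.85 * 2 * pi), g = 0.7,
                                         W0 = W0, t_max = 4000,
                                         conv_patience = 0))
  iv <- utils::tail(interspike_intervals(log, 1), 20)
  expect_gt(abs(iv[1] - iv[2]), 0.1)
  sums <- iv[seq(1, 19, by = 2)] + iv[seq(2, 20, by = 2)]
  expect_equal(sums, rep(1.85 * 2 * pi, 10), tolerance = 1e-6)
})

test_that("the three asymptotic modes are classified from their presets", {
  r1 <- run_two_neuron("slow-pacemaker", t_max = 3e4)
  expect_identical(r1$mode, "i")
  expect_gt(r1$log$final_W[1, 2], 0.95)
  expect_lt(r1$log$final_W[2, 1], 0.05)
  expect_equal(r1$winding$n, 2L)

  r2 <- run_two_neuron("fast-pacemaker")
  expect_identical(r2$mode, "ii")
  expect_lt(r2$log$final_W[1, 2], 0.01)
  expect_gt(r2$log$final_W[2, 1], 0.99)
  # period lock: asymptotic intervals of both neurons equal T1 up to the
  # residual bound-bounce of the saturated weight (~1e-5 relative)
  for (i in 1:2) {
    iv <- utils::tail(interspike_intervals(r2$log, i), 50)
    expect_equal(iv, rep(2 * pi, 50), tolerance = 2e-5)
  }
  # with the weights frozen at the saturated configuration the lock is
  # exact to solver precision
  W0 <- matrix(0, 2, 2); W0[2, 1] <- 1
  lgf <- simulate_network(network_config(c(2 * pi, 1.05 * 2 * pi),
                                         g = 0.15, W0 = W0, t_max = 2e4,
                                         conv_patience = 0))
  ivf <- utils::tail(interspike_intervals(lgf, 2), 50)
  expect_equal(ivf, rep(2 * pi, 50), tolerance = 1e-10)

  r3 <- run_two_neuron("decoupled", t_max = 3e4)
  expect_identical(r3$mode, "iii")
  expect_lt(max(r3$log$final_W), 0.05)

  # boundary weight configuration is neither saturated nor locked
  W <- matrix(0, 2, 2); W[1, 2] <- 0.5; W[2, 1] <- 0.5
  lg <- structure(list(final_W = W, config = list(periods = c(1, 2)),
                       spikes = data.frame(t = numeric(0),
                                           neuron = integer(0)),
                       t_end = 1, sat_time = NA_real_, converged = FALSE),
                  class = "spike_log")
  expect_identical(classify_mode(lg), "other")
})

test_that("a tabulated class I PRC reproduces the weak-coupling QIF dynamics", {
  # the first-order Winfree kick with the analytic QIF curve should match
  # the exact update closely at small coupling
  phases <- seq(0, 2 * pi, length.out = 2001)
  Z <- cbind(qif_prc(phases, 1), qif_prc(phases, 1 / 1.85))
  W0 <- matrix(0, 2, 2); W0[1, 2] <- 1
  T12 <- c(2 * pi, 1.85 * 2 * pi)
  g <- 0.02
  exact <- simulate_network(network_config(T12, g = g, W0 = W0,
                                           t_max = 500, conv_patience = 0))
  tab <- simulate_network(network_config(T12, g = g, W0 = W0, t_max = 500,
                                         prc = list(phases = phases,
                                                    values = Z),
                                         conv_patience = 0))
  expect_identical(tab$spikes$neuron, exact$spikes$neuron)
  expect_equal(tab$spikes$t, exact$spikes$t, tolerance = 1e-4)
})

test_that("identical configurations give bit-identical logs", {
  rec <- group_network_recipe(n_fast = 5, n_slow = 2, seed = 42)
  W1 <- recipe_initial_weights(rec)
  W2 <- recipe_initial_weights(rec)
  expect_identical(W1, W2)
  cfg <- network_config(rec$periods, g = rec$g, stdp = rec$stdp, W0 = W1,
                        t_max = 2000, conv_patience = 0)
  a <- simulate_network(cfg)
  b <- simulate_network(cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$final_W, b$final_W)
})
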