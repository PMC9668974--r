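test_that("thresholding a converged weight matrix yields the link graph", {
  # six-neuron configuration: three fast (1-3), three slow (4-6);
  # 4 disconnected, 5 drives 6, chain inside the fast group, and the
  # slow 6 drives every fast neuron
  W <- matrix(0, 6, 6)
  W[2, 1] <- W[3, 1] <- W[3, 2] <- 1   # 1 -> 2, 1 -> 3, 2 -> 3
  W[6, 5] <- 1                         # 5 -> 6
  W[1, 6] <- W[2, 6] <- W[3, 6] <- 1   # 6 -> {1, 2, 3}
  g <- threshold_graph(W, eps_w = 0.05)
  expect_true(g$converged)
  el <- igraph::as_edgelist(g$graph)
  got <- sort(paste(el[, 1], el[, 2], sep = "->"))
  expect_identical(got, sort(c("1->2", "1->3", "2->3", "5->6",
                               "6->1", "6->2", "6->3")))
  expect_equal(unname(igraph::degree(g$graph)[4]), 0)

  expect_equal(igraph::ecount(threshold_graph(matrix(0, 3, 3))$graph), 0)

  Wm <- matrix(0, 3, 3); Wm[1, 2] <- 0.5
  gm <- threshold_graph(Wm)
  expect_false(gm$converged)
  expect_identical(gm$unconverged,
                   data.frame(i = 1L, j = 2L, w = 0.5))
})

test_that("actual periods report raw and cycle-aligned values", {
  # synthetic log: neuron 1 alternates two intervals summing to 10,
  # neuron 2 fires regularly at 10, neuron 3 is silent
  t1 <- c(0, cumsum(rep(c(4, 6), 30)))
  t2 <- seq(10, 300, by = 10)
  log <- structure(list(
    spikes = rbind(data.frame(t = t1, neuron = 1L),
                   data.frame(t = t2, neuron = 2L)),
    config = list(periods = c(5, 10, 7)), t_end = 300,
    sat_time = NA_real_, converged = FALSE), class = "spike_log")
  per <- actual_periods(log, t_start = 0)
  expect_equal(per$winding[1], 2L)
  expect_equal(per$cycle_period[1], 10)
  expect_equal(per$mean_isi[1], 5)
  expect_equal(per$winding[2], 1L)
  expect_equal(per$cycle_period[2], 10)
  expect_true(is.na(per$cycle_period[3]))
  expect_equal(per$n_spikes[3], 0L)
})

test_that("free neurons keep their natural periods", {
  cfg <- network_config(periods = c(3, 5), g = 0, t_max = 600,
                        conv_patience = 0)
  per <- actual_periods(simulate_network(cfg), t_start = 100)
  expect_equal(per$cycle_period, c(3, 5), tolerance = 1e-9)
})

test_that("clusters, pacemakers and isolated neurons are identified", {
  # two clusters plus an isolated node, with periods from a locked state
  W <- matrix(0, 5, 5)
  W[2, 1] <- 1          # 1 -> 2 (fast pair, 2/1 enslaved by nothing slow)
  W[4, 3] <- W[5, 3] <- 1  # 3 -> {4, 5}
  nat <- c(2.0, 2.1, 6.0, 6.2, 6.4)
  g <- threshold_graph(W, periods = nat)
  per <- data.frame(neuron = 1:5, n_spikes = 100,
                    mean_isi = c(2.0, 2.0, 6.0, 6.0, 3.0),
                    winding = c(1L, 1L, 1L, 1L, 2L),
                    cycle_period = c(2.0, 2.0, 6.0, 6.0, 6.0))
  rep <- find_clusters(g, per)
  expect_length(rep$clusters, 2)
  expect_identical(rep$clusters[[1]]$members, c(1L, 2L))
  expect_identical(rep$clusters[[1]]$pacemaker, 1L)
  expect_identical(rep$clusters[[2]]$members, c(3L, 4L, 5L))
  expect_identical(rep$clusters[[2]]$pacemaker, 3L)
  expect_equal(rep$clusters[[2]]$period, 6.0)
  expect_identical(rep$isolated, integer(0))
  expect_false(rep$transient)

  # a member whose mean interval is incommensurate breaks consistency
  per_bad <- per
  per_bad$mean_isi[4] <- 5.1
  rep_bad <- find_clusters(g, per_bad)
  expect_false(rep_bad$clusters[[2]]$consistent)
  expect_true(is.na(rep_bad$clusters[[2]]$pacemaker))

  # a pacemaker candidate with an incoming edge is rejected
  W2 <- W; W2[3, 4] <- 1
  g2 <- threshold_graph(W2, periods = nat)
  rep2 <- find_clusters(g2, per)
  expect_false(rep2$clusters[[2]]$consistent)
})

test_that("an uncoupled network thresholds to an empty, all-isolated graph", {
  cfg <- network_config(periods = c(2, 2 * sqrt(2), pi), g = 0,
                        stdp = stdp_params(), t_max = 500,
                        conv_patience = 0)
  log <- simulate_network(cfg)
  g <- threshold_graph(log$final_W, periods = log$config$periods)
  expect_equal(igraph::ecount(g$graph), 0)
  rep <- find_clusters(g, actual_periods(log, t_start = 100))
  expect_length(rep$clusters, 0)
  expect_identical(rep$isolated, 1:3)
})

test_that("a fast-pacemaker pair forms one cluster led by the faster neuron", {
  r <- run_two_neuron("fast-pacemaker")
  g <- threshold_graph(r$log$final_W, periods = r$log$config$periods)
  rep <- find_clusters(g, actual_periods(r$log))
  expect_length(rep$clusters, 1)
  expect_identical(rep$clusters[[1]]$pacemaker, 1L)
  expect_equal(rep$clusters[[1]]$period, 2 * pi, tolerance = 1e-4)
})
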