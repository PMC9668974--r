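#' Thresholded connectivity graph of a converged weight matrix
#'
#' After plasticity has run its course the weights of a pulse-coupled
#' network saturate at 0 or 1; the surviving links form a directed graph
#' with an edge j -> i wherever `W[i, j] > 1 - eps_w`.  Entries strictly
#' between `eps_w` and `1 - eps_w` are not saturated; they are collected
#' in the `unconverged` table and flagged, so a transient matrix is never
#' silently thresholded.
#'
#' @param W weight matrix (rows = postsynaptic).
#' @param eps_w saturation tolerance, in (0, 0.5).
#' @param periods optional natural periods attached to the vertices.
#' @return a list of class `connectivity_graph` with `graph` (an
#'   [igraph][igraph::graph_from_adjacency_matrix] directed graph),
#'   `unconverged` (data frame `i`, `j`, `w`) and `converged` (logical).
#' @export
threshold_graph <- function(W, eps_w = 0.05, periods = NULL) {
  weight_matrix(W)
  stopifnot(eps_w > 0, eps_w < 0.5)
  n <- nrow(W)
  mid <- which(W > eps_w & W < 1 - eps_w, arr.ind = TRUE)
  unconv <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
  if (nrow(mid) > 0) {
    unconv <- data.frame(i = mid[, 1], j = mid[, 2],
                         w = W[mid], row.names = NULL)
  }
  adj <- t(W > 1 - eps_w)  # edge pre j -> post i
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "directed")
  if (!is.null(periods)) {
    stopifnot(length(periods) == n)
    igraph::V(g)$period <- periods
  }
  structure(list(graph = g, unconverged = unconv,
                 converged = nrow(unconv) == 0, eps_w = eps_w),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("connectivity graph: %d neurons, %d links%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (x$converged) "" else
                sprintf(" [%d unconverged weights]", nrow(x$unconverged))))
  invisible(x)
}

#' Asymptotic firing periods of every neuron
#'
#' Computes, from the post-transient part of a spike log, each neuron's
#' raw mean interspike interval and its cycle-aligned period: a neuron
#' locked at winding n/1 to a slower driver fires at n unequal
#' sub-intervals that repeat every driver cycle, so the cycle-aligned
#' period is the (constant) sum of each block of n consecutive intervals.
#' The block length n is detected as the smallest n for which those block
#' sums are constant to `tol` relative; an unlocked or solitary neuron
#' gets n = 1 and cycle period equal to its raw mean interval.
#'
#' @param log a `spike_log` from [simulate_network()].
#' @param t_start start of the analysis window; defaults to the later of
#'   80 percent of the simulated time and the weight-saturation time.
#' A neuron locked at n/1 may also fire at n *equal* sub-intervals (common
#' in densely driven networks); block detection then reports winding 1 with
#' the sub-interval as cycle period, and the driver-cycle alignment is
#' recovered by [find_clusters()] through integer-multiple matching.
#'
#' @param max_winding largest winding integer tried in block detection.
#' @param tol relative tolerance for "constant" block sums; residual
#'   bounce of bound-pinned weights perturbs interspike intervals at the
#'   1e-4 level, so the default is 1e-3.
#' @return a data frame with one row per neuron: `neuron`, `n_spikes`,
#'   `mean_isi`, `winding`, `cycle_period` (NA for silent neurons).
#' @export
actual_periods <- function(log, t_start = NULL, max_winding = 6,
                           tol = 1e-3) {
  stopifnot(inherits(log, "spike_log"))
  if (is.null(t_start)) t_start <- post_transient_start(log)
  n <- length(log$config$periods)
  out <- data.frame(neuron = seq_len(n), n_spikes = 0L,
                    mean_isi = NA_real_, winding = NA_integer_,
                    cycle_period = NA_real_)
  for (i in seq_len(n)) {
    st <- log$spikes$t[log$spikes$neuron == i & log$spikes$t >= t_start]
    out$n_spikes[i] <- length(st)
    if (length(st) < 3) next
    isi <- diff(st)
    out$mean_isi[i] <- mean(isi)
    for (k in seq_len(max_winding)) {
      nb <- length(isi) %/% k
      if (nb < 2) break
      blocks <- colSums(matrix(isi[seq_len(nb * k)], nrow = k))
      if (max(blocks) - min(blocks) <= tol * mean(blocks)) {
        out$winding[i] <- k
        out$cycle_period[i] <- mean(blocks)
        break
      }
    }
    if (is.na(out$winding[i])) {
      out$winding[i] <- 1L
      out$cycle_period[i] <- out$mean_isi[i]
    }
  }
  out
}

#' Synchronized clusters and their pacemakers
#'
#' Partitions the thresholded connectivity graph into weakly connected
#' components and checks each against the pacemaker picture: every member
#' of a synchronized cluster fires commensurately with one common cluster
#' period (its cycle period times a small integer equals the common
#' period, within `period_tol` relative -- a fast member may emit n
#' equally or unequally spaced spikes per cluster cycle), and the cluster
#' is paced by the member whose natural period equals that common period
#' and which receives no edge from inside the cluster.  Ties between
#' period-consistent candidates are broken toward the smallest natural
#' period.  Components violating the picture are flagged `inconsistent`
#' rather than guessed at.
#'
#' @param graph a `connectivity_graph` from [threshold_graph()] built with
#'   `periods` attached.
#' @param periods a data frame from [actual_periods()] (cycle-aligned
#'   periods of the same simulation).
#' @param period_tol relative tolerance for period agreement.  Weights
#'   pinned at the zero bound keep bouncing by one update quantum, so even
#'   a "disconnected" neuron receives a residual drive of order
#'   `N * p * g` per cycle that shifts measured periods by about 1e-3
#'   relative in a 25-neuron network; the default leaves room for it.
#' @return a list of class `pattern_report` with `clusters` (list of
#'   `members`, `pacemaker`, `period`, `consistent`), `isolated` (neurons
#'   with no edges either way), `transient` (TRUE when the weight matrix
#'   had unconverged entries).
#' @export
find_clusters <- function(graph, periods, period_tol = 5e-3) {
  stopifnot(inherits(graph, "connectivity_graph"),
            is.data.frame(periods), "cycle_period" %in% names(periods))
  g <- graph$graph
  nat <- igraph::V(g)$period
  if (is.null(nat)) stop("graph has no natural periods; build it with ",
                         "threshold_graph(..., periods = )")
  deg <- igraph::degree(g, mode = "all")
  isolated <- which(deg == 0)
  comp <- igraph::components(g, mode = "weak")
  clusters <- list()
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) < 2) next
    # mean interspike intervals are robust to the interval-pattern jitter
    # that residual bound-bouncing weights induce; an n/1-locked member has
    # mean interval = common period / n for a small integer n
    mi <- periods$mean_isi[members]
    consistent <- all(is.finite(mi))
    common <- NA_real_
    pacemaker <- NA_integer_
    if (consistent) {
      common <- max(mi)
      mult <- round(common / mi)
      consistent <- all(mult >= 1) &&
        all(abs(mi * mult - common) <= period_tol * common)
    }
    if (consistent) {
      sub <- igraph::induced_subgraph(g, members)
      indeg <- igraph::degree(sub, mode = "in")
      cand <- members[abs(nat[members] - common) <= period_tol * common &
                        indeg == 0]
      if (length(cand) > 0) {
        pacemaker <- cand[which.min(nat[cand])]
      } else {
        consistent <- FALSE
      }
    }
    clusters[[length(clusters) + 1]] <-
      list(members = members, pacemaker = pacemaker,
           period = if (consistent) common else NA_real_,
           consistent = consistent)
  }
  structure(list(clusters = clusters, isolated = isolated,
                 transient = !graph$converged),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(sprintf("pattern report: %d cluster(s), %d isolated neuron(s)%s\n",
              length(x$clusters), length(x$isolated),
              if (x$transient) " [transient: weights not converged]" else ""))
  for (cl in x$clusters) {
    cat(sprintf("  cluster {%s}: %s\n",
                paste(cl$members, collapse = ","),
                if (cl$consistent)
                  sprintf("pacemaker %d, period %.6g", cl$pacemaker,
                          cl$period)
                else "inconsistent"))
  }
  invisible(x)
}
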