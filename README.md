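# plastlock

Event-driven simulation and closed-form locking theory for pulse-coupled
class I neurons with spike-timing-dependent plasticity (STDP).

## What this package is for

Class I neurons (quadratic integrate-and-fire and its biophysical
relatives) have purely phase-advancing response curves, so excitatory
pulses can only speed them up.  When two or more such neurons are coupled
by plastic synapses, the synchronization mode and the synaptic weights
co-evolve.  Besides the familiar outcomes — the faster neuron enslaving
the slower one at 1:1, or all links dying — there is a synchronous mode in
which the *slower* neuron keeps its single link onto the faster one, which
then fires `n ≥ 2` spikes per slow period.  In larger plastic networks
this mode lets slow neurons become pacemakers of large low-frequency
clusters.

`plastlock` implements, for R users:

* an exact event-driven simulator for `N` pulse-coupled phase neurons
  (QIF, via the change of variables `v = -sqrt(eta) * cot(phi/2)`, or any
  tabulated class I PRC) with the additive nearest-neighbor pair-based
  STDP rule `W[j,i] += p*exp(-delta/tau_p)`, `W[i,j] -= d*exp(-delta/tau_d)`
  and hard bounds `0 <= W <= 1` (compiled core; no time stepping);
* the two-neuron locking theory: per-cycle weight budgets, the stability
  thresholds `Q1`, `Q2`, and the Arnold-tongue boundaries with fixed
  weights, `g1 = omega1 * cot[(pi/2) (T2/T1 - n + 1)]` and
  `g2 = omega2 * cot[(pi/2) T1/T2]`, and under STDP (`g1_stdp()`,
  `g2_stdp()`), plus the near-resonance generalization
  `g = ±(2*pi/Z_max) (1 + beta) * epsilon` for arbitrary class I PRCs
  summarized by a parabolic peak fit `(Z_max, phi_max, alpha)`;
* Wang–Buzsáki and Morris–Lecar conductance-based models: adaptive RK45
  integration with in-step spike refinement, steady-period measurement,
  localization of the SNIC onset current, numerical PRC extraction, and
  parabolic peak fitting;
* network pattern analysis: thresholded connectivity graphs, per-neuron
  cycle-aligned periods, synchronized clusters and their pacemakers.

See the methods vignette (`vignettes/locking-and-plasticity.Rmd`) for the
model details, conventions and numerical choices.

## A worked example

Two QIF neurons with `T1 = 2*pi`, `T2 = 1.85*T1`, coupling `g = 0.7`,
STDP with `p = d = 0.001`, `tau_p = pi/3`, `tau_d = pi`, starting from
weights `(W12, W21) = (0.9, 0.1)`:

```r
library(plastlock)
res <- run_two_neuron("slow-pacemaker")
res$log
#> spike_log: 2 neurons, 2188 spikes over t = [0, 8426] (weights converged)
res$mode
#> [1] "i"
res$log$final_W[1, 2]; res$log$final_W[2, 1]
#> [1] 1
#> [1] 0
res$winding[c("n", "m")]
#> $n
#> [1] 2
#> $m
#> [1] 1
tail(interspike_intervals(res$log, 1), 4)
#> [1] 5.3407 6.2832 5.3407 6.2832
```

The weights converge to the slow-to-fast unidirectional configuration
(`W12 = 1`, `W21 = 0`): the slow neuron has enslaved the fast one, which
now fires twice per slow period (`winding 2/1`) at two alternating
intervals whose sum, `11.6239`, is exactly the slow period `1.85 * 2*pi`.
The closed-form tongue boundary for this mode,
`g1_stdp(2*pi, 1.85*2*pi, default_stdp())`, is `0.403`, so the chosen
`g = 0.7` sits comfortably inside the plastic tongue.

The same pipeline applies to the biophysical models:

```r
prc <- compute_prc(wb_params(), n_phases = 200)  # ~0.5 s
fit_parabola(prc)
#> PRC parabolic fit: Z_max = 4.852 at phi = 3.308, alpha = 1.115
```

## Command line

A thin wrapper over the package functions ships in
`inst/scripts/plastlock-cli` (subcommands `simulate`, `two-neuron`,
`tongue-scan`, `network`, `prc`, `snic`, `validate-resonance`; YAML
configuration via `load_config()`; outputs written with a checksummed
manifest).

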