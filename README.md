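# ip3rgating

Twelve-state Markov modeling of IP3 receptor (IP3R) single-channel
gating under wild-type and familial Alzheimer's disease (FAD) mutant
presenilin-1, with dwell-time theory, maximum-likelihood fitting of
gating records, a synthetic gating-record generator, and a hybrid
stochastic reaction–diffusion simulation of local Ca²⁺ release (puffs
and blips) at a ten-channel cluster.

## The problem

FAD-causing presenilin mutants (such as PS1-M146L) enhance IP3R channel
gating: the channel spends more time in its high-activity (H) gating
mode and less in its low-activity (L) mode, raising open probability at
subsaturating IP3 and driving exaggerated intracellular Ca²⁺ signals.
This package implements the quantitative machinery needed to analyse
that enhancement from single-channel data and to propagate it to local
Ca²⁺ release events:

* **Model core** — the twelve-state chain (states `XmnM`: closed/open,
  `m` Ca²⁺ and `n` IP3 bound, mode `M` ∈ {L, I, H}).  State occupancies
  are `K·C^m·I^n`; transition rates are reversible pair fluxes divided
  by source occupancies, so the stationary distribution of the
  generator is exactly the normalized occupancy vector.  Equilibrium
  observables: open probability `Po = Zo/Z`, modal prevalences
  `pi_M = Z^M/Z`, open/closed exchange flux `J`, mean times
  `tau_o = Zo/J`, `tau_c = Zc/J`, modal lifetimes `tau_M = Z^M/J_M`.
* **Dwell-time theory** — closed-form densities
  `f_X(t) = pi_X exp(Q_XX t) Q_XY u_Y` for the open/closed partition
  and for arbitrary aggregates, including per-mode sub-chains.
* **Likelihood fitting** — the aggregated-Markov likelihood of
  idealized dwell sequences (final dwell censored, underflow-safe
  propagation in compiled code) and the two-stage fit: least-squares
  occupancy fit to `(Po, pi_L, pi_I, pi_H)`, then Nelder–Mead maximum
  likelihood over flux parameters with occupancies fixed.
* **Synthetic gating records** — exact stochastic simulation of the
  chain, idealization to dwell sequences, burst filtering and modal
  segmentation with the critical durations T_b = 100 ms,
  T_g = 200 ms, and empirical gating summaries with bootstrap errors.
* **Cluster simulation** — ten channels, 120 nm spacing, each with a
  radial buffered-diffusion field for free Ca²⁺ and dye (implicit
  finite volumes on a nonuniform grid), point-source channel flux
  (0.05 pA), superposed local Ca²⁺ driving each channel's gating;
  event detection and puff/blip statistics.

Both printed parameter sets (PS1-WT and PS1-M146L) ship with the
package (`occupancy_params()`, `flux_params()`, and YAML fixtures under
`inst/extdata/`).

## Worked example

```r
library(ip3rgating)

occ <- occupancy_params("M146L")
flx <- flux_params("M146L")
equilibrium_summary(occ, flx, ca = 1, ip3 = 0.1)
#> IP3R equilibrium (M146L) at Ca = 1 uM, IP3 = 0.1 uM
#>   Po = 0.8123; tau_o = 17.99 ms, tau_c = 4.157 ms
#>   prevalence: L 0.059, I 0.104, H 0.836
#>   modal lifetimes (ms): L 552.1, I 392.5, H 2378

equilibrium_summary(occupancy_params("WT"), flux_params("WT"),
                    ca = 1, ip3 = 0.1)
#> IP3R equilibrium (WT) at Ca = 1 uM, IP3 = 0.1 uM
#>   Po = 0.2895; tau_o = 11.52 ms, tau_c = 28.27 ms
#>   prevalence: L 0.518, I 0.139, H 0.343
#>   modal lifetimes (ms): L 3221, I 348.1, H 651.8
```

At the calibration condition (1 µM Ca²⁺, 100 nM IP3) the mutant spends
84% of its time in the H mode versus 34% for wild type, and its mean
closed time collapses from 28 ms to 4.2 ms — the gain-of-function
enhancement expressed through mode switching.  Simulating and
re-analysing a gating record:

```r
G  <- build_generator(occ, flx, ca = 1, ip3 = 0.1)
tr <- to_idealized(simulate_trajectory(G, duration_ms = 30000, seed = 1))
segment_modes(tr)                      # L/I/H stretches of the record
trace_loglik(tr, G)                    # dwell-sequence log-likelihood
```

A desk-scale local-release simulation:

```r
run <- run_cluster(occ, flx, ip3 = 0.1, duration_s = 10, seed = 42)
event_statistics(detect_events(run))[c("puff_freq_hz", "blip_freq_hz")]
```

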