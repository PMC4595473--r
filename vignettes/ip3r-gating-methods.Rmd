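---
title: "Modeling IP3R modal gating and local calcium release: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling IP3R modal gating and local calcium release: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ip3rgating)
```

## The model

The inositol 1,4,5-trisphosphate receptor (IP3R) is the main
endoplasmic-reticulum Ca2+ release channel.  Single-channel records show
that it gates in three modes under constant ligand conditions: a
low-activity L mode (brief openings separated by long quiescent
stretches), an intermediate I mode (rapid flicker), and a high-activity
H mode (long bursts).  `ip3rgating` implements a twelve-state aggregated
Markov model of this behaviour for channels regulated by wild-type
presenilin-1 ("WT") and by the familial Alzheimer's disease mutant
M146L, together with everything needed to analyse and regenerate the
kind of data such a model is calibrated on.

Each state `XmnM` is closed (`C`) or open (`O`), carries `m` bound Ca2+
and `n` bound IP3, and belongs to mode `M`.  There are nine closed and
three open states:

```{r}
ip3r_states()
```

**Occupancies.** At ligand condition $(\mathcal{C}, \mathcal{I})$ (both
in µM), each state has unnormalized equilibrium occupancy
$Z_s = K_s\,\mathcal{C}^m \mathcal{I}^n$, where $K_s$ is the product of
equilibrium association constants along any path from the unliganded
reference state C00L (for which $K = 1$).  The total occupancy
$Z = Z_o + Z_c$ normalizes these into probabilities; the open
probability is $P_o = Z_o / Z$ and the prevalence of mode $M$ is
$\pi^M = Z^M / Z$.  The two packaged parameter sets
(`occupancy_params()`, `flux_params()`) differ in exactly four
occupancies (KC32L, KO14I, KO24H, KO24I) and two pair fluxes (j0414II,
j2424HH); this small difference reproduces the mutant's mode switch
from L to H and its left-shifted IP3 sensitivity.

**Rates.** Every reversible transition pair carries a symmetric
equilibrium flux $\phi_{SU}(\mathcal{C}, \mathcal{I})$ built from the
flux parameters; the transition rate is the pair flux over the source
occupancy, $r(S \to U) = \phi_{SU} / Z_S$.  Composite pathways that pass
through low-occupancy intermediate states combine their per-step fluxes
harmonically (`rsr()`, the reciprocal of the sum of reciprocals).  Two
transitions (C04I–C24I and C00L–C20L) reuse the C04I–C24H pathway flux.

A deliberate design choice lives here.  The published rate table writes
three backward rates with a *nearby* occupancy constant in the
denominator rather than the destination state's own (KC24H in place of
KC24I, and in place of KC04I·KC20L), exploiting the numerical
near-coincidence KC24I ≈ KC24H ≈ KC04I·KC20L.  Taken literally, those
denominators break detailed balance at the 1e-4 level, which caps the
agreement between the chain's stationary distribution and the occupancy
vector at the same level.  We instead divide each backward rate by the
destination state's own occupancy.  This reproduces every printed rate
to ≲ 2e-4 relative (asserted in the test suite) and makes detailed
balance — and hence stationarity of the normalized occupancy vector —
exact by construction.  Exactness matters downstream: the likelihood
propagator diagonalizes the sub-generators in the symmetrized
(occupancy-weighted) basis, which requires a reversible chain.

```{r}
G <- build_generator(occupancy_params("M146L"), flux_params("M146L"),
                     ca = 1, ip3 = 0.1)
range(rowSums(G$Q))
max(abs(stationary_distribution(G) - G$Z / sum(G$Z)))
```

**Equilibrium observables.** `equilibrium_summary()` collects $P_o$,
$\pi^M$, the open–closed exchange flux $J$, the mean open/closed times
$\tau_o = Z_o / J$, $\tau_c = Z_c / J$ (so that
$P_o = \tau_o/(\tau_o + \tau_c)$ holds identically), and the modal
lifetimes $\tau^M = Z^M / J_M$ with $J_M$ the flux out of the mode's
state aggregate.  The mean-time definition uses the unnormalized flux
throughout: this is the only reading that is dimensionally consistent
and self-consistent with $P_o$.

## Dwell-time theory

For a partition of the chain (or of a mode-restricted sub-chain) into
aggregates X and Y, the dwell density in X is
$f_X(t) = \pi_X e^{Q_{XX} t} Q_{XY} u_Y$, where $\pi_X \propto
z_Y^\top Q_{YX}$ is the distribution over X states at the moment of
entry and $u_Y$ is a ones vector.  `dwell_partition()` builds the
blocks; mode-restricted partitions zero all out-of-mode transitions and
rebalance the diagonal, so the mode sub-generator is internally
consistent.  The closed-form mean is $-\pi_X Q_{XX}^{-1} u_X$.

Matrix exponentials are evaluated through an eigendecomposition of the
sub-generator, verified at build time against a scaling-and-squaring
exponential (`Matrix::expm`); if the eigenbasis is unreliable (a
sub-generator can in principle be defective) every evaluation falls
back to the direct exponential.  The distribution function uses the
survivor form $1 - \pi_X e^{Q_{XX}t} u_X$, which keeps Kolmogorov–
Smirnov checks against simulated dwells cheap.

## Likelihood and the two-stage fit

An idealized record is an alternating dwell sequence
$t_{c1}, t_{o1}, \dots, t_{cn}, t_{on}$.  Its log-likelihood propagates
the equilibrium closed-entry distribution through alternating
sub-generator exponentials and switching blocks; the final open dwell
is censored (survival factor only) because the record ends while the
channel is open.  The state row vector is renormalized after every
factor, with log norms accumulated, so records of any length cannot
underflow.  Because the chain is exactly reversible, each block
exponential reduces to a symmetric eigenproblem in the
occupancy-weighted basis; the per-dwell work is a few 9×9
multiplications, done in compiled code.

Fitting follows the calibration procedure of the underlying study in
two stages:

1. `fit_occupancy()`: least squares of the model's
   $(P_o, \pi^L, \pi^I, \pi^H)$ against measured values across ligand
   conditions, over log10-transformed free occupancies (Nelder–Mead
   with restarts).  Unweighted least squares, matching the generic
   least-squares routine the study cites.
2. `fit_flux()`: maximum likelihood over log10-transformed free flux
   parameters with occupancies held fixed (Nelder–Mead, tolerance 1e-6,
   ≤ 5000 iterations, restarts from the incumbent; all deterministic).

For a mutant-vs-wild-type fit the conventional free sets are the four
variant occupancies and the two variant fluxes.

**Identifiability.** At a single Ca2+ concentration the occupancies of
O14I ($K\mathcal{C}\mathcal{I}^4$) and O24I
($K\mathcal{C}^2\mathcal{I}^4$) scale identically along IP3, so data
collected only at Ca2+ = 1 µM constrain only
$K_{O14I} + K_{O24I}$.  Closure experiments that fit at a single Ca2+
therefore pin KO14I and free {KC32L, KO24H, KO24I}; recovering all four
requires data at several Ca2+ concentrations.

**Silent records.** The L mode contains a deep trap: at 1 µM Ca2+ the
only exits from C32L have time constants of roughly 700 s at 100 nM
IP3 and 6500 s at 33 nM — far longer than a 30 s record.  A finite
record therefore either never opens (it sampled the trap) or gates
throughout.  Silent records are kept as single all-closed dwells: they
carry real weight in empirical open probabilities and prevalences
(dropping them biases $P_o$ upward several-fold at low IP3), but they
cannot enter the dwell-sequence likelihood and are excluded from it.
This trap also sets the statistical limits of parameter recovery at
the study's ensemble size (30 records × 30 s per condition): the
ensemble standard error of $\pi^L$ translates into tens of percent of
uncertainty in KC32L, which no fitting procedure can beat.

## Synthetic gating records and modal segmentation

`simulate_trajectory()` is an exact continuous-time Markov chain
simulation started from the stationary distribution;
`to_idealized()` collapses it to what an idealized current record
resolves (conductance classes), trimming to the closed-leading,
open-trailing form.  Everything is seeded through R's RNG, so ensembles
are reproducible byte-for-byte.

`segment_modes()` implements the critical-duration rule used for modal
analysis of real records: closings shorter than `t_short` are removed
by burst filtering; closed gaps of at least `t_g_crit` = 200 ms are
L-mode stretches; the burst between gaps is H if it lasts at least
`t_b_crit` = 100 ms and I otherwise.  Ties go to the longer-duration
class.  `t_short` defaults to 10 ms — an order of magnitude below the
criticals and above the intra-burst flicker — and is configurable; the
reference study removes short closings without stating its threshold.

Within the model the burst rule is a biased estimator of the
state-defined prevalences: the I mode's lifetime (~350 ms at the
calibration condition) exceeds the 100 ms burst critical, so I-mode
stretches parse as H bursts, and measured $\pi^H$ exceeds the
equilibrium $\pi^H$ by ~0.1–0.2 at 1 µM Ca2+ and 100 nM IP3.  The test
suite freezes this computed behaviour (overestimate, bounded) rather
than assuming the rule is unbiased.  What passing tests show is that
the generator, the theory, and the analysis chain are mutually
consistent — not that the burst rule would be unbiased on real data,
where kinetic separation between modes may differ.

## The ten-channel cluster simulation

`run_cluster()` couples ten channels on a planar 2 × 5 array with
120 nm spacing through buffered Ca2+ diffusion.  Each channel owns a
hemispherically symmetric radial field for free Ca2+ and free dye,
solved by finite volumes on a shared nonuniform grid (innermost cell =
the 2.5 nm source shell, widths growing geometrically to the 5 µm
domain edge; 160 cells by default).  Per step: channel states advance
by exact exponential-clock jumps with rates frozen over the step, the
open channels' sources enter the backward-Euler right-hand side, the
tridiagonal diffusion systems are solved implicitly (factorizations
precomputed), and the dye reaction is applied with a
positivity-preserving semi-implicit update that keeps free dye within
$[0, B_d]$.  The local Ca2+ of channel $i$ is
$c_\mathrm{rest} + \sum_j \Delta c_j(r_{ij})$, each channel's field
storing its excess over rest, with the self term evaluated at the
source-shell radius.  Counting rest once (rather than once per
channel's field) is the only physical reading of the superposition.
Exact-jump gating inside a step removes any stability constraint from
the gating side; the default field step of 20 µs resolves the
microdomain kinetics at desk scale, and halving it changes solutions
by a few percent (asserted in the tests).

The open-channel source is $I/(2F\,\delta V)$ within the source shell,
with $I$ = 0.05 pA and $\delta V$ the hemisphere of the pore radius
(default 2.5 nm).  With the buffer disabled, the steady-state excess
concentration reproduces the hemispherical point-source law
$\Delta c = \tfrac{I/(2F)}{2\pi D_c}\left(\tfrac1r - \tfrac1R\right)$
to better than 5% over 10 nm–1 µm.  Pump and leak fluxes are omitted as
slow on these time scales; each channel's field is solved independently
and superposed, which linearizes buffer competition between sources —
an approximation inherited from the modeling scheme this follows, not
corrected here.

**Buffer defaults are placeholders.**  The reference buffer and
diffusion constants for this scheme are not in the public text, so the
package documents its own: $D_c$ = 220 µm²/s, $D_d$ = 32 µm²/s,
$B_d$ = 40 µM, $k^f_d$ = 150 µM⁻¹s⁻¹, $k^r_d$ = 300 s⁻¹,
$c_\mathrm{rest}$ = 70 nM — standard Ca2+-microdomain values for a
mobile indicator dye.  Every quantitative event statistic depends on
them.

**Event semantics and what they imply.**  `detect_events()` defines an
event as a maximal interval with at least one open channel, bridging
all-closed gaps shorter than `t_sep` (default 20 ms, well above
intra-burst closings and well below inter-event intervals at ~10 s⁻¹
event rates); a blip peaks at one open channel, a puff at two or more.
Amplitudes are reported both as peak open-channel count and as peak
Ca2+/bound-dye at the cluster center, since the observable used for
the published amplitude distributions is not stated.  A consequence
worth stating plainly: the mutant's resting $P_o$ at 70 nM Ca2+ and
100 nM IP3 is ≈ 0.105 per channel, so a ten-channel mutant site has at
least one channel open about two-thirds of the time *before any
Ca2+ feedback*.  Under the ≥ 1-open event definition the mutant
therefore produces fewer, much longer release events than wild type at
desk scale — its amplitude and life-time distributions stochastically
dominate wild type's, but its *event frequency* cannot exceed wild
type's several-fold.  Frequency contrasts like those reported for
puffs require amplitude-thresholded detection on the fluorescence
signal and the reference buffer constants, both outside this package's
scope.

## Numerical choices, sizes, and limitations

* Stationary distributions are computed by Grassmann–Taksar–Heyman
  elimination (no subtractions), keeping componentwise relative
  accuracy even where occupancies span 13 decades; a plain null-space
  solve loses up to 10% relative accuracy at ligand-grid corners and is
  used only as a cross-check on benign chains.
* Zero-ligand conditions are handled analytically: ligand powers common
  to a pair flux and the source occupancy are cancelled before
  evaluation, so binding rates vanish and unbinding rates stay finite
  at $\mathcal{C} = 0$ or $\mathcal{I} = 0$.
* Problem sizes in the tests are chosen for a laptop-scale run:
  dwell-law checks use ~4,000 s of simulated gating (~10⁵ dwells),
  pipeline-closure runs use the study's 30 records × 30 s × 3
  conditions, and cluster property checks use 100 s runs per variant;
  all stochastic tests fix their seeds.
* The synthetic generator emulates stationarity, alternation, censored
  final dwells, and the model's modal structure.  It does not emulate
  missed events (dead time), baseline drift, or idealization errors of
  real recordings; the likelihood assumes perfectly idealized records
  with no dead-time correction.
* The per-channel radial fields assume hemispherical symmetry and
  independent superposition; there is no full 3-D solve and no ER
  luminal depletion.
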