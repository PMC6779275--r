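---
title: "riposim: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riposim: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

riposim simulates the initiation of extrinsic apoptosis in single cells:
death-ligand binding to death receptors (TNFR1, DR4, DR5), the random
assembly of DISC/RIPoptosome signalling platforms, stochastic activation of
Caspase-8 on those platforms, and the downstream effector-caspase feedback
loop that commits the cell to death. The model is a hybrid: platform
chemistry runs as an exact continuous-time Markov jump process (direct
Gillespie SSA), while the caspase cascade — fast, high-copy-number chemistry —
is integrated deterministically, the two coupled by fixed-step operator
splitting. This vignette documents the model, its assumptions, the tunable
parameters and the numerical decisions, in the spirit of a methods section.

## 1. Receptor engagement and clustering

Ligand–receptor binding is far faster than platform assembly, so bound
receptors are taken at the rapid-equilibrium fixed point,

$$[RL] = \frac{[R_{tot}]}{K_d/[L] + 1},$$

per receptor species with its own $K_d$; doses in ng/mL convert to nM via the
ligand monomer mass (default 19.6 kDa). The signalling-competent unit is the
receptor trimer; `trimer_count()` floors $[RL]/3$ once (keeping $[RL]$
real-valued until then avoids double rounding). Each trimer nucleates exactly
one platform origin seeded with one RIP1 molecule, and all three receptor
species feed a single origin pool: DISC and RIPoptosome origins are treated
identically downstream.

Origins are then assigned to membrane clusters by drawing cluster sizes
i.i.d. from a configurable size distribution until the trimer budget is
exhausted (the remainder forms one final, smaller cluster). Within a cluster,
ProCaspase-8 monomers on *different* platforms can trans-dimerize; with
clustering disrupted every origin is a singleton and trans-activation is
impossible — that is the "disrupted clustering" scenario, implemented by
zeroing the trans propensity.

The shipped size distribution over $\{1,2,3,5,8,20\}$ trimers (probabilities
$0.50, 0.21, 0.12, 0.095, 0.06, 0.015$) is a documented placeholder: the
measured distribution it stands in for is not reproducible from the text we
model, so we chose a mass function whose bulk is small clusters with a thin
tail of high-order clusters (a 20-trimer cluster is 60 receptors, within the
range reported by super-resolution imaging of death-receptor clusters). The
tail matters scientifically: which clusters a given cell happens to draw is
frozen for that cell's lifetime, and this quenched geometric lottery — not
any extrinsic parameter noise — is what differentiates otherwise identical
cells. Cells that draw efficient cluster configurations activate Caspase-8
faster, die early, and show high ramp noise; cells that do not must wait for
the slow deterministic feedback. This is the mechanism behind the bimodal
death-delay distribution at low dose (Section 6).

## 2. Stochastic platform assembly

Each platform carries composition counts (RIP1, RIP3, FADD, ProCasp8,
cFLIP~L~, cFLIP~S~, bound DED1-DED2) plus one terminal-site flag; the full
filament sequence is not tracked, because every model output (mass,
per-origin counts, end-blocking) is a function of counts, and the reduced
state space keeps exact master-equation validation tractable. The reaction
channels per platform are:

* RIP1 elongation at the open filament end, and terminal RIP1 loss;
* RIP3 recruitment to filament RIP1 via the RHIM motif (each recruitment
  increments the RIP1–RIP3 heterodimer counter, the necroptosis-propensity
  readout) and its reverse;
* FADD binding to filament RIP1 (one DED site per bound FADD) and unbinding
  of unoccupied FADD;
* competitive DED-site binding of ProCasp8, cFLIP~L~, cFLIP~S~ and free
  DED1-DED2, with reverse dissociations;
* filament-end capping by ProCasp8 or DED1-DED2, which blocks RIP1
  recruitment until it falls off;
* cis-dimerization of two ProCasp8 on one platform; trans-dimerization of
  ProCasp8 on two platforms of one cluster (pair-combinatoric propensities);
* dead-end heterodimerization of a bound ProCasp8 with a bound cFLIP
  isoform or bound DED1-DED2 (the cleaved prodomain acts as a catalytically
  dead competitor);
* activation of an intact dimer, releasing one active Caspase-8 dimer to the
  cytosol plus one free DED1-DED2, or its unproductive dissociation.

Dimer activation is two-stage (dimerize, then cleave/activate at
`k_dimer_activation_min`), reflecting sequential inter/intra-dimer cleavage.
ProCasp8–cFLIP~L~ heterodimers are inactive by default; the literature is
divided on residual activity, so `cflipl_hetero_active` can switch them to
activatable. Filament growth is not capped by any physical volume limit.
Species conservation is enforced by explicit ledgers (free pool +
platform-bound + capped + in-dimers + heterodimers + released) that the
engine can verify every 1024 events (`validate = TRUE`).

The production implementation is compiled (Rcpp): per-platform channel
weights live in Fenwick trees so each event costs $O(\log P)$, and all
randomness comes from a seeded 64-bit Mersenne Twister with explicit
inverse-transform draws, making trajectories bit-reproducible for a given
seed. A pure-R reference path (`build_propensities()`, `gillespie_step()`,
`simulate_assembly_r()`) implements the identical channel list and is
cross-validated against both the compiled engine and an exact
chemical-master-equation solution of a one-origin, 19-state network
(`tiny_network_cme()`).

## 3. The effector-caspase cascade

The deterministic module tracks, in nM: the active Caspase-8 dimer and its
cleaved (inert) monomer, ProCasp3/Casp3\*, ProCasp6/Casp6\*, free XIAP and
the XIAP·Casp3 complex, cumulative degraded Casp3, the intact/cleaved FRET
substrate, and the free ProCasp8 pool shared with the stochastic module.
Mass-action terms: Casp8\*-dimer cleavage of ProCasp3; Casp3\* autocatalysis;
Casp3\* cleavage of ProCasp6; Casp6\* cleavage of *free* ProCasp8 to the
cleaved monomer; very slow second-order monomer dimerization to the active
dimer, with first-order dimer dissociation back; reversible XIAP·Casp3
binding with `kcat_ub`-driven degradation of the complex (XIAP regenerated —
a catalytic-inhibitor cycle, switchable); basal ubiquitin-dependent
degradation of free Casp3\*; and Casp8\*-dimer cleavage of the FRET
substrate. Pro-forms of Casp3/Casp6 are treated as pre-formed dimer pools.
Only the active dimer is catalytic.

Two constants are fixed by measurement rather than calibration: the
XIAP-driven Casp3 ubiquitination rate (1.75 min⁻¹) against the basal
ubiquitin-dependent rate (0.04 min⁻¹), and the mean HeLa XIAP level (63 nM).
The balance `kon_xiap * [XIAP]` versus `k_casp3_auto * [ProCasp3]` is
deliberately close: free XIAP capture outruns Casp3 autocatalysis by a
modest margin, so small XIAP reductions collapse the margin and produce the
ultra-sensitive switch from late to early death (`parameter_scan()` on
`xiap_total` reproduces a ≥3-fold delay reduction below ~40 nM, and a steady
delay increase above 63 nM). Raising `kcat_ub` returns XIAP to the free pool
faster and therefore only ever delays death.

## 4. Hybrid coupling and the death criterion

`simulate_cell_hybrid()` advances the SSA over fixed windows of
`dt_sync_min` (default 0.1 min) with the cascade frozen; active Caspase-8
dimers released in a window become a piecewise-constant source (preserving
counts exactly) for an embedded Cash–Karp RK45 integration of the cascade
over the same window. The shared free ProCasp8 pool is reconciled each
window: ProCasp8 cleaved by Casp6\* is debited from the stochastic pool via
a fractional accumulator; a debit that would drive the pool negative is
clamped at zero and logged (`clamp_events`, zero in routine runs). Because
windows are short relative to every propensity's timescale, redrawing the
exponential clock at window boundaries (exact for unchanged propensities) is
the only splitting approximation; halving `dt_sync` moves ensemble-mean
death times by well under 2%.

Death is recorded the first time the FRET-probe cleavage rate
$k_{fret}\,[\mathrm{Casp8}^*][\mathrm{FRET}_{intact}]$ reaches the threshold
`death_threshold_rate_nm_min`, linearly interpolated inside the crossing
window; a trace touching the threshold exactly at a grid point dies there.
The threshold value is not a measured quantity; it was calibrated once so
that essentially all high-dose (50 ng/mL, clustered) cells die within the
first hour and the low-dose regimes reproduce the published delay ranges,
and it is flagged as calibrated-not-printed in the config metadata.

`simulate_cell_full_ssa()` removes the deterministic approximation entirely
— cascade species become molecule counts with the same rate constants scaled
by the volume factor — and serves as the validation reference: death-delay
samples from the two simulators at 50 ng/mL are indistinguishable by a
two-sample Kolmogorov–Smirnov test. `deterministic_full_model()` is the
opposite limit: mean-field rate equations for the average platform (with
trans-activation entering through the size-biased mean cluster size) chained
into the cascade; its initiation kinetics match the SSA ensemble mean within
ten percent at high dose, and it drives the parameter scans.

## 5. Parameters and units

All concentrations are nM, times minutes; bimolecular rates configured in
nM⁻¹min⁻¹ are divided by $N_A V \cdot 10^{-9}$ on load (volume default
$2.5\times10^{-12}$ L, a typical HeLa cell, so 1 nM ≈ 1506 molecules).
Receptor counts (905/769/926 per cell) and the XIAP constants above are
fixed inputs. Every other concentration and rate constant is a documented
placeholder (`$metadata$placeholder_keys`): literature-scale values
calibrated once, before the test suite was frozen, so that the simulator
reproduces the published dynamic regime — FADD never exceeding ~10 molecules
per origin in two hours, 2 MDa platforms within five minutes, ProCasp8
occupancy saturating after about two hours with RIP1 always the dominant
subunit, death delays spanning one to ten hours (clustered) and up to
twenty-two hours (disrupted) at 5 ng/mL, the noise–delay law, and the
bimodality pattern. They are calibrated quantities of this artifact, not
measurements, and the configuration schema rejects unknown keys so every
deviation from the defaults is explicit. Subunit masses (RIP1 76, RIP3 57,
FADD 23, ProCasp8 55, cFLIP~L~ 55, cFLIP~S~ 26, DED1-DED2 26 kDa) follow
canonical database values so that platform masses — and the 2 MDa
observation, reached by 27 RIP1 subunits — are testable.

## 6. What the ensembles show (and do not show)

Within a cell, the only randomness is the platform chemistry itself: cluster
assignment, filament-size lottery (capping times), occupancy fluctuations
and discrete dimer releases. There is no extrinsic noise — no cell-to-cell
variation in protein levels or receptor counts — so any population structure
the ensembles show is attributable to stochastic assembly alone, which is
the point of the model. Consequences of this choice, all visible in
`run_ensemble()` output:

* the ramp (pre-death) phase of the FRET cleavage rate is a noisy plateau
  whose per-cell level is set by the frozen cluster/filament geometry;
* cells whose geometry puts the plateau near the death threshold cross it
  early, during or shortly after the loading transient — their ramp
  coefficient of variation (`ramp_cv()`, std/mean over $[0,$ death$)$) is
  high, and every cell with CV > 0.5 dies within two hours;
* cells below the fluctuation band wait for the slow feedback creep
  (Casp6-driven monomer accumulation plus slow dimerization), which
  concentrates their deaths late — at low dose with clustering this yields a
  bimodal death-delay histogram (`delay_histogram()` flags it via the dip
  test), and breaking clustering removes the early mode and the bimodality;
* the negative rank correlation between ramp CV and death delay is
  reproduced in the clustered scenarios and at high dose. In the disrupted
  low-dose scenario our calibration produces creep-dominated deaths whose
  CV trend component grows with delay, so the rank correlation there comes
  out positive — a known limitation of this parameterisation, asserted
  honestly (and left failing) in the acceptance suite rather than patched.

Bimodality is assessed with a dip statistic — the L∞ distance between the
empirical CDF and the nearest unimodal (convex–concave) CDF, minimised over
the mode — calibrated against Monte-Carlo draws from the uniform null; this
is the construction of Hartigan's dip test, implemented here directly
because no dip-test implementation is available among the package's
dependencies. Ashman's D from a two-component Gaussian fit (mclust) is
reported alongside as a separation score.

Across-cell coefficients of variation of cumulative Caspase-8 activation are
reported for $t \ge 30$ min; at the first few grid points the mean count is
near zero and CV estimates degenerate (for Poisson-like counts CV
$\to 1/\sqrt{\text{mean}}$), so early points say nothing about the
low-variance regime the statistic is meant to demonstrate.

## 7. Numerical choices and problem sizes

* SSA: direct method; family-factorised propensities with Fenwick-tree
  selection; float-drift guards snap selections to the nearest active entry.
* Cascade integration: embedded Cash–Karp RK45 (relative tolerance 1e-6)
  inside the engine; `deSolve::lsoda` (rtol 1e-8) for the R-level module and
  the mean-field model. Halving tolerances moves terminal FRET cleavage by
  < 1e-6 relative.
* Degenerate inputs: zero dose yields zero origins and no death; empty
  propensity sets return an infinite waiting time and a frozen state;
  negative concentrations, malformed configs and unknown keys raise typed
  errors (`riposim_bad_value`, `riposim_missing_key`, ...).
* Reproducibility: per-cell streams derive from the master seed and cell
  index, so ensembles are order-independent and exactly repeatable.
* Default study sizes: 100-cell ensembles at a 24 h horizon for death-delay
  statistics (the published study used up to 600 cells; 100 is the package's
  default desk scale and the acceptance tolerance class assumes it),
  100-cell two-hour ensembles for platform composition, 20 + 20 cells for
  the hybrid/full-SSA comparison, and exact CME validation on a 19-state
  network against 4000 engine replicates.

## 8. Known limitations

* All kinetic constants other than the receptor counts and the XIAP pair are
  calibrated placeholders; absolute times and concentrations should be read
  as regime-level, not measurement-level, statements.
* No post-MOMP biology: the simulation ends at the FRET-rate threshold.
* Necroptosis is a counter (RIP1–RIP3 heterodimers), not an executed fate.
* Platform topology is composition-level; spatial filament structure,
  membrane diffusion and physical growth limits are out of scope.
* The disrupted-clustering noise–delay correlation has the wrong sign under
  this calibration (Section 6).

```{r}
library(riposim)
cfg <- default_model_config()
cell <- simulate_cell_hybrid(cfg, dose_ng_ml = 5, seed = 1)
cell$death
ens <- run_ensemble(cfg, 5, clustering = TRUE, n_cells = 100, master_seed = 1)
summary(ens)
delay_histogram(ens)$bimodal
```
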