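---
title: "Spatially resolved kinetic Monte Carlo modeling of NK-cell synapse signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially resolved kinetic Monte Carlo modeling of NK-cell synapse signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nksynapse)
```

## The model

`nksynapse` simulates membrane-proximal signaling at the immunological
synapse between a natural killer (NK) cell and a ligand-presenting surface.
The synapse is a quasi-three-dimensional box of 15 µm × 15 µm divided into
square chambers of edge $l_0 = 0.5$ µm (30 × 30 chambers); membrane-resident
molecules occupy a layer of thickness $l_0$ and cytosolic molecules a layer
of $2 l_0$. Molecules are well mixed within a chamber; chemistry is
chamber-local and transport happens by hops between nearest-neighbor
chambers. An outer rim two chambers wide feeds a slow influx of
ligand-bound receptor into the box.

Two receptor arms are modeled:

* **Activating arm.** NKG2D/DAP10 binds its stress ligand ULBP3; Src-family
  kinase (SFK, a single lumped species) phosphorylates DAP10; Vav1 binds
  phospho-DAP10 and is phosphorylated in turn. Total phospho-Vav1 (pVav1) is
  the activation readout.
* **Inhibitory arm.** KIR2DL2 binds HLA-C; phosphorylated ITIMs recruit
  SHP-1, which dephosphorylates pVav1 (free or complex-bound) residing in
  the same chamber.

Ligand unbinding implements **kinetic proofreading**: the complex fully
dissociates and the receptor resets to its unphosphorylated state. Released
Vav1 keeps its phospho-state, so free pVav1 exists and is subject to a
first-order background dephosphorylation.

Bimolecular rates $k_{on}$ (µM⁻¹s⁻¹) become per-pair chamber propensities
$k_{on}/(N_A v)$ where $v$ is the encounter volume: $l_0^2 \times 2$ nm for
receptor–ligand, $l_0^2 \times 10$ nm for receptor–SFK, $l_0^2 \times 2 l_0$
for cytosol–membrane, and $l_0^3$ for the membrane-proximal Vav1 pool.

### Spatial rules and the positive feedback

Three rules couple space to chemistry:

1. **Microcluster formation.** Each chamber carries a potential
   $E_i = \min(-x_i^2, -x_{j_1}^2, \dots, -x_{j_4}^2)$ over its pVav1-moiety
   count $x$ and its four periodic neighbors. A ligand-bound receptor
   complex hops toward a neighbor with logistic acceptance
   $\min\{1, e^{\beta(E_i - E_j)}/(1 + e^{\beta(E_i - E_j)})\}$, so
   complexes aggregate where pVav1 is abundant.
2. **Centripetal transport.** All copies of a complex species in a chamber
   hop together at rate $k^{\text{cluster-move}}$, with direction
   probabilities mixing a centripetal component (weight $w$) and an
   unbiased component ($1-w$):
   $p_{\text{left/right}} = \tfrac14 (1 \pm s(x/R - 1)) w + \tfrac14 (1-w)$
   and analogously in $y$. The saturation $s = T/(K + T)$ depends on the
   **total** pVav1 $T$, so transport switches on only once signaling has
   produced pVav1 — the spatial positive feedback: pVav1 → clustering →
   locally concentrated signaling → more pVav1.
3. **Influx.** Rim chambers run only ligand binding/unbinding; bound
   complexes enter the box at rate $k^{\text{influx}}$ per complex.

Free monomers diffuse by nearest-neighbor hops at $D/l_0^2$ per direction
($D = 0.01$ µm²/s membrane, 10 µm²/s cytosol), which reproduces the lattice
mean-squared displacement $4Dt$ exactly. Cytosolic diffusion is ~10³-fold
faster than every other process, so instead of simulating it explicitly the
cytosolic pools are re-homogenized across the box at intervals
$\tau_h = L^2/(4 D_{\text{cyt}}) \approx 5.6$ s, a scheduled deterministic
event.

### Model variants

| Variant | Co-clustering of Vav1 | pVav1-dependent transport |
|---------|----------------------|---------------------------|
| Model 1 | no (Vav1 cytosolic)  | yes |
| Model 2 | yes (membrane pool)  | yes |
| Model 3 | yes                  | no ($s \equiv 1$) |

**Case A** additionally disables formation hops, cluster hops and
co-clustering (an in-silico analogue of blocking actin polymerization);
Case B is the full rule set. In Model 2 and 3 the Vav1/pVav1 pool is
membrane-proximal: it diffuses at the membrane rate, binds through the
$l_0^3$ volume factor, is **not** homogenized, and is carried along the hop
of the dominant complex species of its chamber. In Model 1 Vav1/pVav1 are
cytosolic and homogenized, which is why clustering cannot increase their
encounter rate there — the mechanistic discriminator the Case A/B
comparison exposes.

## Parameters

Kinetic defaults are the fitted values of the respective variant
(`nk_rates(model)`, `nk_params(model)`); the inhibitory-arm rates are fixed
literature-derived constants, e.g. KIR2DL2:HLA-C $k_{on} = k_{off}/K_D =
1.0/0.036 \approx 27.7$ µM⁻¹s⁻¹. The fitted spatial parameters that matter
most:

* `beta` (0.01–0.1): inverse scale of the formation potential; larger
  values make cluster growth more deterministic.
* `k_cluster_move` (0.1–5 s⁻¹): attempt rate of collective cluster hops;
  sets both centripetal speed and cluster diffusivity.
* `K` (102–1581 molecules): pVav1 half-saturation of transport.
* `w` (0.79–1): centripetal vs random weight.
* `k_influx` (10⁻⁵–10⁻² s⁻¹): boundary influx.

Copy numbers follow measured densities (NKG2D 8/µm² → exactly 2 per
chamber, SFK 698/µm², Vav1 114/µm³, SHP1 2090/µm³, KIR2DL2 106/µm²,
HLA-C 98/µm²). ULBP3 is seeded in blocks of 3 molecules per chamber with
probability `f`; `f = 3462/3468` reproduces the fitted box+rim total.

### Numerical choices

* The engine is an exact event-driven kinetic Monte Carlo: exponential
  waiting times on the total propensity, events proportional to propensity.
  Direction choice, the formation sigmoid and excluded-volume checks are
  applied by *thinning* (the attempt rate is a constant upper bound and
  rejected attempts leave the state unchanged), which keeps the sampled
  process exact while making every cached propensity a local function of
  chamber counts. Chamber totals live in a binary sum tree (O(log n)
  updates); a cached-vs-recomputed total check guards the bookkeeping.
* Excluded volume: at most `N_thres = 400` membrane-layer molecules and
  `N_NKG2D_max = 50` NKG2D moieties per chamber (both configurable).
  Cytosolic pools do not count toward the cap: they occupy the thicker
  layer, are homogenized anyway, and counting them would contradict the
  published densities (~520 SHP1 per chamber at t = 0).
* Rule-15 attempt rate: the published acceptance probability needs an
  attempt frequency; we use the membrane hop rate $D/l_0^2$ per direction
  (formation moves are diffusion-like hops filtered by acceptance),
  configurable as `base_formation_rate`.
* Boundaries: free monomers wrap periodically; complex hops that would
  leave the box are rejected (centripetal drift makes this rare).
* Immobile microclusters: chambers flagged by `place_clusters_from_field()`
  pin KIR2DL2 and co-clustered SFK and emit no formation/cluster hops; free
  monomers still diffuse through them, since absorbing every passing
  kinase would be unphysical.
* The KIR2DL2 microcluster threshold defaults to mean + 2 s.d. of the
  nonzero placed counts, and 25% of SFK is co-clustered — both
  unconstrained by published values and configurable.
* Free-pVav1 dephosphorylation defaults to the complex-bound rate (no
  separate constant is established).
* Ties and degenerate inputs: an all-zero field normalizes to itself with
  a flag and has undefined (error) fitting cost; an empty annulus or
  all-zero placement field is an error; zero total propensity freezes the
  state until the horizon.

## Pattern statistics and fitting

Fields are compared after normalization $S = n/n_{\max}$ through the mean
$\mu$, population variance $\sigma^2$, and the periodic two-point
correlation
$C(r) = N^{-1}\sum_i \sum_{r_x^2+r_y^2=r^2} (S_i - \mu)(S_{i+(r_x,r_y)} - \mu)$
evaluated at exact lattice separations $r \le L/2$. As printed, the per-$r$
sum is **not** divided by the number of displacement vectors; comparisons
use $C(r)/C(0)$, which cancels global conventions but not multiplicity, so
both fields must be evaluated on the identical $r$-grid (a
multiplicity-normalized variant is available as an option). The fitting
cost is the equally weighted squared relative mismatch of $\mu$, $\sigma$,
and the $C(r)/C(0)$ profile.

Fitting uses asynchronous particle swarm optimization in log₁₀ parameter
space with inertia 0.5, personal weight 2.5, global weight 1.5, positions
clipped to bounds, and the global best updated after every evaluation. One
(noise seed, initial state) pair is used per evaluation — ensemble
averaging inside the optimizer would be prohibitively expensive, so
intrinsic noise is handled afterwards: the cost at the optimum is
re-evaluated under an ensemble of noise seeds, and all evaluations with
cost below $C_{\min} + 2\sigma_C$ form the accepted parameter cloud. The
cloud (scaled to the unit cube) is clustered by density peaks (cutoff
$d_c$ from the 2% mean-neighbor rule, Gaussian-kernel local density,
centers = joint $\rho$/$\delta$ outliers of the decision graph); the
per-parameter standard deviation within the cluster containing the optimum
is the reported uncertainty. Velocity initialization is uniform in a tenth
of the box per dimension, and constraint handling is clipping — both
choices unconstrained by any published prescription.

## Synthetic targets and what the tests show

No imaging data ships with the package. `generate_synthetic_target()`
produces clustered intensity fields (Gaussian bumps + background +
truncated noise, normalized) whose mean, variance and correlation decay
length sit in the regime of coarse-grained TIRF images of NKG2D
microclusters: correlations decay within a few µm. These fixtures emulate
the *statistics* of real images, not their biology: there is no
photophysics, no cell spreading or retraction, no integrin co-signaling.
Passing tests therefore demonstrate that the machinery (simulation,
statistics, optimization, uncertainty) is correct and self-consistent, not
that the fitted constants are those of any particular cell.

## Problem sizes used by the test-suite experiments

The packaged experiments run at desk scale, chosen so the full suite
completes on one CPU:

* scenario comparisons (clustering ablation, inhibition, dose response):
  full 30×30 box, 1 simulated minute, 20 replicates per condition with
  3-standard-error directional margins (production analyses would use
  50–200 replicates);
* rebinding decay: 200 replicate initial configurations;
* parameter recovery: Model 2 target on a reduced 25×25 box at t = 60 s,
  swarm 24 × 20 iterations, 50-seed noise ensembles, three independent
  repeats (production scale: full box, 200 particles × 100 iterations with
  400-seed ensembles). The recovery truth is an interior point of the
  search bounds: a truth on a bound (such as the fitted `w` = 1.0) clips
  the estimate and has no two-sided recovery interval. At desk scale the
  single-realization cost has intrinsic scatter comparable to its
  landscape contrast, so recovery of all four spatial parameters at once
  is marginal by construction; the experiment asks for three of four
  within their 2σ uncertainty intervals in two of three repeats.

## Known limitations

* Single lumped SFK species; no Grb2, PI3K, LFA-1/ICAM-1, or receptor
  degradation; no partial phospho-states.
* No cell spreading or retraction, so the model describes the first ~3
  simulated minutes of synapse organization.
* The actin cytoskeleton appears only through the coarse-grained pVav1
  coupling of the transport rules.
* Several fitted parameters are weakly identified by pattern statistics
  alone (the accepted cloud is broad along compensating directions, e.g.
  cluster-hop rate against centripetal weight); the uncertainty report is
  designed to expose exactly this.

## A small worked example

```{r example, eval = FALSE}
cfg <- init_homogeneous(seed = 1)
cfg <- seed_ulbp3(cfg, seed = 2)
traj <- run_kmc(cfg, nk_rates(2), nk_params(2), nk_variant(2),
                t_end = 60, snapshot_times = c(0, 30, 60), seed = 3)
traj$series                      # pVav1 and central NKG2D over time
st <- spatial_statistics(unclass(normalize_field(nkg2d_field(traj$final))))
head(st$correlation)
```
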