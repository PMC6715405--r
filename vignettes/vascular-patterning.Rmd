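---
title: "Stochastic reaction–diffusion modeling of stem vascular patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic reaction–diffusion modeling of stem vascular patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascpat)
```

## The model

Vascular bundles in plant stems appear, in cross-section, as discrete spots
of tissue expressing a vascular-initiation regulator (an HD-ZIP III–class
transcription factor; here the activator **H**). `vascpat` models their
emergence with an activator–substrate (Gray–Scott–Schnakenberg) Turing
mechanism, simulated as a continuous-time Markov jump process on a voxel
lattice — the reaction–diffusion master equation (RDME) — rather than as a
deterministic PDE. Molecule counts in developing tissue are small enough
that intrinsic noise matters; the stochastic treatment also breaks the
symmetry of the uniform state without artificial perturbations.

The core two-species kinetics are

$$\partial_t [H] = D_H \nabla^2 [H] + k_1 [H]^2[B] + k_4 - k_5 [H],$$
$$\partial_t [B] = D_B \nabla^2 [B] - k_1 [H]^2[B] + k_2 - k_3 [B],$$

with the dimeric autocatalysis $2H + B \to 3H$ as the pattern-forming
channel. The stochastic representation uses five mass-action channels
(`X1`–`X5`); the dimeric channel fires at the combinatorial rate
$k_1\,n_H (n_H - 1)\, n_B$, which recovers the $k_1[H]^2[B]$ term to
$O(1/n_H)$ at large counts. Concentrations are identified with molecule
counts per voxel (voxel volume 1). Model variants add:

* **HBP** — an efflux carrier **P** (diffusion 0), produced by `H`
  (`X6: H -> H + P`, decayed by `X7`), that facilitates *longitudinal*
  movement of `H`. In a voxel holding $n_P$ carriers, each cargo molecule
  gains an extra longitudinal movement propensity $\alpha\, n_P$ on top of
  its passive hop rates, so the probability that a molecule leaving an
  interior voxel moves along the stem axis is
  $$\Pr(\uparrow\downarrow) \;=\; \frac{2 D_H + \alpha [P]}{6 D_H + \alpha [P]}
    \;=\; \frac{1}{3} + \frac{2}{3}\cdot\frac{[P]}{6 D_H/\alpha + [P]},$$
  i.e. a Michaelis–Menten excess over the passive baseline $1/3$ with
  $V_{\max} = 2/3$ and $K_m = 6 D_H / \alpha$. This single rule turns the
  isotropic spot pattern into longitudinally oriented vessels.
* **HBPM** — a peripheral inhibitor **M** (the miRNA165/166 analog),
  produced only in the cortical shell (the outer 4 % annulus of each
  cross-section, channel `X9`), diffusing inward and annihilating with `H`
  (`X11`), optionally also with `B` (`X12`, off by default). `M` confines
  bundles to the stem center and creates the bundle-free annulus ("zone B")
  between cortex and pith.
* **HBPMA** — a source–sink variant: an apically produced hormone **A**
  (auxin analog, produced only in the top z-layer) is the transported cargo
  instead of `H`, moved by `P` basipetally only, and coupled to `H` by a
  configurable feedback pair (`A -> A + H` plus, by default, the repressive
  `H + A -> H`; an activating `H -> H + A` form is selectable). The exact
  feedback stoichiometry is a free design choice here: the package exposes
  both standard forms rather than fixing one.

## The simulator

`simulate_ssa()` draws exact trajectories of the RDME: waiting times are
exponential in the total propensity, and one reaction, diffusion hop, or
facilitated-transport hop fires per event. Event selection uses the direct
Gillespie method over a per-voxel aggregated propensity tree (a Fenwick
tree), giving $O(\log n_\text{voxels})$ updates per event — an
exact-equivalent organization of the next-subvolume family of methods.
Approximate accelerations (tau-leaping and the like) are deliberately
absent: every result in the package is produced by the exact sampler.

Domains are 2D discs (stem cross-sections) and 3D right circular cylinders
(stems), discretized into unit voxels whose centers lie within the radius.
Zero-flux (reflective Neumann) boundaries are realized *by omission*:
out-of-domain neighbors simply do not exist, so no event can move a molecule
outside, and conservation of molecules under pure movement is structural
rather than enforced. Face adjacency only (4 neighbors in 2D, 6 in 3D); the
6-direction denominator in the transport law above presupposes exactly this
topology and unit voxel spacing, which is why diffusion coefficients are
interpreted as per-direction hop rates on the unit lattice. At boundary
voxels the facilitated propensity toward a missing longitudinal neighbor is
dropped, consistent with omission-based zero flux.

All species start at zero molecules; the production channels bootstrap the
system. Time units are arbitrary — the rate constants set the scale — and
runs stop on an event-count or model-time budget, or cleanly in an absorbing
state.

Reproducibility contract: one seeded generator drives the whole run, and a
trajectory carries its generator state and a configuration hash. A resumed
checkpoint therefore replays the *identical* event sequence — same events,
same order, identical final counts. Simulation times of a resumed run agree
with an uninterrupted one only to floating-point rounding (about 1 ulp),
because the propensity tree is rebuilt exactly at resume; the package
documents times as reproducible to `1e-12` relative tolerance while counts
and event order are bit-identical. Checkpoints are single self-describing
RDS files (counts, time, event counter, RNG state, config hash) — R's native
serialization is the idiomatic container for this in an R package.

## Calibrated preset kinetics

Rate constants for the named presets are **calibrated-to-regime defaults**,
chosen once through the linear-stability analysis (`dispersion_relation()`)
and then frozen; they are not transcriptions of any particular published
parameter table. The baseline HB set

```{r}
unlist(vascpat:::hb_base_params())
homogeneous_steady_state(vascpat:::hb_base_params())
```

was chosen so that (i) the homogeneous steady state sits at
$H^* = 40$, $B^* = 10$ molecules per voxel — large enough that Poisson noise
rarely crosses the spot threshold, small enough that desk-scale runs
pattern in minutes; (ii) the critical substrate/activator diffusion ratio is
$\approx 260$, so a ratio of 10 is deeply stable while 1000 is strongly
Turing-unstable — matching the qualitative contrast studied across ratios;
and (iii) at $D_H = 0.05$, $D_B/D_H = 1000$ the fastest-growing wavelength
is a few voxels on a radius-30 disc:

```{r}
d <- dispersion_relation(c(vascpat:::hb_base_params(), list(D_H = 0.05, D_B = 50)))
attr(d, "unstable_band")
```

The HBPM inhibitor constants (`k9 = 400` per shell voxel, `k10 = 0.05`,
`k11 = 0.05`, `D_M = 7.5`) were calibrated so that `M` floods a narrow stem
(radius ~5) but is consumed before reaching the center of a wide one
(radius ~14), reproducing the stem-diameter effect with *identical kinetics*
in both geometries.

## Pattern quantification

* **Spots** (`detect_spots()`): connected components of voxels strictly above
  a count threshold, 4-connected by default (matching the diffusion
  topology; 8-connectivity available as a sensitivity check). The
  "diameter" of an irregular region is its equivalent-circle diameter
  $2\sqrt{A/\pi}$, since a plotted bundle diameter is otherwise undefined.
* **Threshold**: the classic criterion is an absolute count per voxel
  (hundreds of molecules at full scale). Because the criterion is
  scale-dependent, the package states it either as a fraction of the field
  maximum (`threshold_from_field()`, default 50 %) or — the default used in
  the package's own experiments — as a multiple of the deterministic
  homogeneous steady state (`spot_threshold()`, default $3 H^*$, i.e. 120
  molecules/voxel for the baseline kinetics). An unpatterned field
  fluctuates around $H^*$ and essentially never sustains $3 H^*$.
* **Persistence** (`persistent_spots()`): at desk scale the Turing spots are
  near lattice-scale, so transient noise excursions and true bundles are
  separated by *time*, not size: supra-threshold masks from the last few
  snapshots (default here: three snapshots, ten time units apart — tens of
  activator lifetimes) are intersected before labeling. The minimum spot
  size defaults to one voxel for the same reason.
* **Stationarity** (`stationarity()`): "the pattern stopped changing" is
  operationalized as constant spot count plus Jaccard similarity of
  consecutive supra-threshold masks at or above 0.9 — the qualitative
  published criterion made checkable.
* **Zonation** (`zonation()`): radial profile plus the width of the
  bundle-free annulus, measured inward from the shell boundary
  $r_{\text{shell}} = (1 - f) R$ to the outermost interior spot voxel.

## The deterministic reference

`pde_integrate()` is a forward-Euler integrator with the 5-/7-point graph
Laplacian on exactly the same lattice and boundary treatment as the
stochastic engine. It exists as the mean-field oracle: single-voxel
trajectories are checked against an independent Runge–Kutta solve to
$10^{-4}$ relative error, and its linearization (`dispersion_relation()`)
predicts, by the sign of the growth rate, which stochastic parameter sets
form spots. `dt` must satisfy $dt < 1/(2 d \max(D_H, D_B))$; a violation is
refused up front, and a negative or non-finite concentration aborts with the
step index rather than being clipped — silent clipping would distort the
dynamics precisely when the step size is invalid. Deterministic patterned
runs start from the homogeneous steady state with a 1 % random perturbation
(`perturbed_steady_field()`), since without intrinsic noise nothing else
breaks the symmetry. Interdigitated (plectostele-like) banded patterns are
reproduced qualitatively with Gray–Scott-type parameters supplied in config;
no claim is made to any specific published parameter file.

## What the tests do and do not show

The test suite checks *exactness* (stationary birth–death counts are
Poisson; empirical longitudinal hop fractions match the transport law within
binomial 99 % intervals; a Michaelis–Menten fit of the measured excess
recovers $V_{\max} \in [0.6, 0.74]$ and $K_m/(6D/\alpha) \in [0.85, 1.15]$),
*structural invariants* (conservation under movement, region-restricted
channels firing only in their regions, zero flux), *reproducibility* (seeded
bit-identity; checkpoint/resume event-identity), and *scaled-down pattern
experiments*: on a radius-30 disc, a diffusion ratio of 1000 yields many
persistent spots while a ratio of 10 yields essentially none; with identical
HBPM kinetics a radius-14 stem forms central bundles while a radius-5 stem
forms none (majority over three seeds each).

These desk-scale experiments (runs of order $10^8$ events, tens of seconds
each) reproduce the *directions* of the published effects, not their
absolute magnitudes: full-scale counterparts ran days and hundreds of
billions of events, and absolute spot counts and diameters depend on lattice
size and threshold conventions that are not portable. At this scale
individual spots span only a few voxels, so spot-diameter trends are
shallow; they are asserted as replicate-majority outcomes only. The
synthetic data generated by the presets emulate the study conditions
(geometry, zero initialization, kinetics regimes), not any empirical stem
anatomy: passing tests validate the simulator and its analysis chain, not a
fitted model of real plants.

## Numerical choices and limitations

* Counts are 64-bit internally; propensities are doubles, and the propensity
  tree is rebuilt from per-voxel sums every $2^{20}$ events to keep
  floating-point drift from accumulating.
* Within-voxel channel order (reactions, then per-species/per-direction
  hops, then transport) is fixed, which makes event selection reproducible;
  a floating-point spill past the last channel falls back to the last
  positive channel.
* The problem sizes used by the tests (disc radius 30 for the
  diffusion-ratio experiment, radii 14/5 for the stem-size experiment, 40
  time units per run) are the package's chosen desk-scale study conditions.
* Not modeled: growing or tapered domains, cell division, subcellular
  compartments, non-cylindrical organs, delays, and enzyme-sequestration
  transport kinetics; GUI and movie encoding are out of scope (PNG frame
  sequences are written instead).
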