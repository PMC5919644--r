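---
title: "Modelling dose painting by numbers in hypoxic virtual tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dose painting by numbers in hypoxic virtual tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Hypoxic tumor subvolumes are radioresistant: at low oxygen partial pressure
(pO2) a given dose kills far fewer cells than under aerobic conditions.
Dose painting by numbers (DPBN) responds by prescribing a non-uniform dose
per voxel — boosting the radioresistant regions while lowering the dose
elsewhere so that the mean dose per fraction stays at the conventional
2 Gy. Whether this redistribution actually improves tumor control depends
on how the tumor's microenvironment evolves *during* the treatment:
killed cells stop consuming oxygen, dead cells are resorbed, the tumor
shrinks and its vasculature concentrates, so yesterday's hypoxic map is not
tomorrow's. `dpbnsim` implements a voxel-based multiscale model of this
interplay and uses it to compare adaptive replanning strategies in silico.

# Model components

## Oxygen-dependent cell survival

Cell kill follows the linear-quadratic (LQ) model with oxygen enhancement
ratios (OER) modulating the hypoxic radiosensitivities:

$$\mathrm{SF}(d, p) = \exp\!\big[-\alpha_h\,\mathrm{OER}_\alpha(p)\,d
  - \beta_h\,(\mathrm{OER}_\beta(p)\,d)^2\big],
\qquad \mathrm{OER}(p) = \frac{k + p\,\mathrm{OER}_{max}}{p + k},$$

with $\alpha_h = \alpha/\mathrm{OER}_{\alpha,max}$ and
$\beta_h = \beta/\mathrm{OER}_{\beta,max}^2$, so the fully aerobic limit
recovers plain LQ kill with $\alpha, \beta$. Defaults are head-and-neck
values: $\alpha = 0.35$/Gy, $\beta = 0.035$/Gy², population SD
$\sigma_\alpha = 0.05$/Gy, $\mathrm{OER}_{\alpha,max} = 2.5$,
$\mathrm{OER}_{\beta,max} = 3$, $k = 3.28$ mmHg. Note that this OER
saturates slowly: even at the capillary pO2 of 40 mmHg,
$\mathrm{OER}_\alpha = 2.41 < 2.5$, which caps the effective aerobic
radiosensitivity the model can express (a limitation discussed below).

The expected surviving cells of a tumor are summed over voxels and over the
16 bins of each voxel's pO2 histogram (`totalSurvivors()`); this double sum
is the survival bookkeeping every other module consumes.

## Microscopic oxygenation (`solvePO2Field`, `buildOxygenLookup`)

Within one voxel, pO2 is far from uniform: it is the most hypoxic cells
that govern radioresistance. The oxygenation model solves a steady-state
reaction-diffusion equation on a 2-D cross-section of the voxel (parallel
vessels reduce the 3-D problem to 2-D): randomly placed, non-overlapping
vessel disks are clamped at the intravascular pO2 and viable cells consume
oxygen with Michaelis-Menten kinetics
$M(p) = M_{max}\, s\, p/(p + k_m)$, where $s$ is the volume fraction of
consuming (viable) cells. Defaults: 40 mmHg intravascular pO2, 10 µm vessel
radius, diffusivity 2000 µm²/s, $k_m = 2.5$ mmHg, 1124 µm domain matching
the voxel side, 112 grid points per side. The solve uses a red-black SOR
kernel (C++) with the sink linearized about the current iterate; vessels
narrower than the pixel spacing occupy the nearest pixels such that the
pixelated vessel area equals $\pi r^2$ at every resolution.

$M_{max}$ is the single calibrated scalar. It was set to 8 mmHg/s at full
packing density so that a 6% vascular fraction is well oxygenated (median
pO2 well above 10 mmHg — the study treats vf = 6% as a tissue where the
oxygen effect is marginal) while sub-1% vascular fractions are
radiobiologically hypoxic.

Fields are condensed to 16-bin histograms over the extravascular area: one
explicit anoxic bin $[0, 0.01)$ mmHg plus 15 log-spaced bins up to the
intravascular pO2, resolving the critical 0–10 mmHg range. Because the top
log bins are wide, bin centers are not taken at geometric midpoints but as
the area-weighted mean pO2 of the field values that fell into each bin
during lookup construction; geometric centers would map fully oxygenated
tissue to ~30 mmHg and systematically understate its radiosensitivity.
Histograms are pre-tabulated on a (vf, s) grid — vf from 0 to 0.30, s from
0 to 1, averaged over several vessel placements — and retrieved by
renormalized bilinear interpolation with clipping at the grid edges
(`lookupHistogram()`).

Choosing *s* = viable cells / voxel capacity (rather than the dead-cell
share of the tumor cells) makes consumption track the actual density of
consuming cells: as kill and resorption empty a voxel its oxygenation
rises, which is the consumption side of treatment reoxygenation. With the
dead-cell-share definition, resorption of dead cells would paradoxically
*lower* oxygenation again.

## Tumor response dynamics (`stepDay`)

Per calendar day, in this order: radiation kill (if a fraction is
scheduled), proliferation, angiogenesis, vascular collapse, dead-cell
resorption, cell exchange, oxygenation refresh. The ordering is fixed and
config-documented; at a 24 h step the results are insensitive to it.

* **Proliferation** — viable cells grow as $2^{\Delta t/t_p}$ with
  $t_p = 1200$ h at treatment start, switching to 120 h after two weeks
  (accelerated repopulation). Growth is space-limited: a voxel may fill to
  10% above its packing capacity $\mu\,a^3$ ($\mu = 10^6$ cells/mm³,
  $a = 1.124$ mm); the excess is redistributed by exchange.
* **Angiogenesis** — capillary cells double with $t_a = 612$ h in voxels
  whose histogram median pO2 is below 5 mmHg (threshold exposed in the
  configuration; the study only states "hypoxia-induced").
* **Vascular collapse** — capillaries halve with $t_{collapse} = 400$ h in
  voxels crowded beyond 90% of capacity whose tissue is predominantly
  viable, at a rate scaled by the current proliferation rate (solid stress
  comes from growing tissue). This reconstructed process is what carves the
  low-vf hypoxic core out of the initially well-perfused host while a
  virtual tumor grows; making it moderately faster than angiogenesis lets
  hypoxic cores deepen instead of equilibrating exactly at the angiogenesis
  threshold.
* **Radiation kill** — expected survivors per voxel follow the
  oxygen-averaged LQ survival; voxels below $10^4$ viable cells draw
  binomial survivors (cell-killing stochasticity matters when numbers are
  small). In expected-value mode a voxel whose expected survivors fall
  below one whole cell is emptied — a voxel cannot hold a fraction of a
  cell, and without this truncation the deterministic planning trajectory
  would never reach control at finite dose.
* **Resorption** — dead cells decay with half time $t_r = 168$ h.
* **Exchange** — two conservative moves. Over-capacity voxels push their
  excess tumor cells to neighbors in proportion to free space (invasion;
  vessels do not invade). Under-capacity tumor voxels absorb their deficit
  from neighboring tumor tissue that is strictly less occupied, moving
  viable, dead and capillary cells in the donor's proportions (cohesive
  compaction: the sparse dying boundary collapses into the denser
  interior). Compaction refills resorbed space within about a day
  (pull rate 1/day), so the tumor volume tracks cell loss and the
  vasculature of absorbed tissue concentrates — the second, vascular side
  of treatment reoxygenation. The strict up-gradient rule keeps uniform
  regions static and means compaction can never seed new tumor voxels.
* **Oxygenation refresh** — every tumor voxel's histogram is re-read from
  the lookup at its current (vf, s).

The vascular fraction is geometric, vf = capillary volume / voxel volume,
which is also what the oxygenation model's vessel density means.

## Virtual tumors (`growReferenceTumor`, `makeVariant`)

The reference tumor T1 is *grown* by the same stepper from a single cell
placed in vascularized host tissue (host vf 6%), with a growth doubling
time of 120 h (the macroscopic 1200 h value reflects Gompertzian slowing;
early growth is faster). Growth stops the first day the tumor holds 3888
voxels (≈2 cm sphere; the outermost nearly-empty frontier voxels are
trimmed to reach the count exactly). The emergent tumor has a packed
center at ~10⁶ cells/mm³ falling to ~5×10⁵ at the border, and a ~1 cm
hypoxic core (median pO2 < 5 mmHg, vf ~1%) surrounded by a better-perfused
rim — the radial structure the study prescribes, produced by the model
itself rather than painted on.

Variants share T1's mask and total cell count exactly: T2 (uniform density
and vf), T3 (uniform density, T1's vf profile), T4 (T1's density profile,
uniform vf). Uniform vf is 6%, representative of well-oxygenated tumors.

## Schedules, optimization and outcome

Fractions of 2 Gy are delivered weekdays only, starting on a Monday.
Adaptive schemes re-optimize the dose distribution at the start only (1F),
plus after two weeks (2F, fraction 11), plus after three weeks (3F,
fraction 16), or before every fraction of the first three (FBF3W) or four
(FBF4W) weeks; plans persist until replaced and every fraction beyond the
scheme's window is uniform 2 Gy.

Two objectives are optimized under a fixed 2 Gy mean over the tumor voxels
and a ±25% box (1.5–2.5 Gy): minimizing the expected surviving cells
(OF_surv) or minimizing the standard deviation of per-voxel survivors
(OF_std). OF_surv is separable and convex over the box, and the production
solver is a dual method: per-voxel safeguarded Newton on the marginal-kill
equation with bisection on the mean-dose multiplier. An independent
augmented-Lagrangian L-BFGS-B solver with analytic gradients handles
arbitrary objectives; it serves as a cross-check for OF_surv and as the
solver for the non-convex OF_std (five multi-starts, uniform plus seeded
perturbations, ties broken toward the plan closest to uniform). Solver
failures fall back to the uniform plan with a warning; emitted plans always
satisfy the constraints to 1e-6. A noteworthy property of OF_surv,
verified against exhaustive search: while radiosensitive (oxic) cells are
plentiful they receive the boost — the marginal kill per Gy is largest
there — and the boost only moves to the hypoxic compartment once hypoxic
cells dominate survival, which they do after the first fractions.

Tumor control probability is estimated by simulating 30 virtual patients
per dose level (dose escalated by fraction count, not fraction size), each
drawing $\alpha \sim N(0.35, 0.05)$/Gy truncated at 0.05/Gy, with plans
pre-computed once on the population-mean-$\alpha$ trajectory. A patient is
controlled iff no viable cell remains at the end of the course. Control
rates are fitted with univariate logistic regression on the total dose;
D50 = $-b_0/b_1$; uncertainties are two standard deviations of a
within-level bootstrap (1000 replicates by default); treatment gain is
D50(uniform) − D50(painted). Perfectly separated data are flagged rather
than silently fitted, and the analysis pipeline then falls back to the
empirical midpoint estimator.

# Numerical choices and degenerate inputs

* SOR convergence: max update < 1e-3 mmHg (non-convergence is an error
  with the residual reported); fully aerobic evaluations use p = 10⁶ mmHg
  with a documented 1e-3 tolerance on the OER plateau.
* Histogram weights must sum to 1 within 1e-9; interpolated weights are
  renormalized; out-of-grid queries are clipped.
* Zero-vessel voxels are anoxic; zero-consumption voxels sit at the
  intravascular pO2; an empty extravascular region is an error.
* Dose plans: per-fraction doses outside [0, 10] Gy are rejected; plan and
  lattice shapes must match; tumor voxels missing from a plan receive the
  prescription mean (2 Gy).
* Empty tumors cannot be optimized (error); optimizing a converged plan
  again changes the objective by < 1e-9.
* Deterministic runs are exactly reproducible; every stochastic step takes
  an explicit seed.

# What the generator emulates — and what it does not

The virtual tumors emulate the radial density/vf structure, the common
total cell number, and the reoxygenation phenotypes of the four-tumor
study design; passing tests show the *model's* internal consistency and
its qualitative orderings (hypoxic tumors need more dose; reoxygenation
capability ranks T2 < T3 < T1 < T4; survival-minimizing painting beats
heterogeneity-minimizing painting; more adaptations gain more). They are
not patient images: no anatomical asymmetry, no necrosis-driven cavities,
one tumor-cell phenotype, no stem-cell subpopulation, no vessel
directionality beyond the parallel-vessel reduction, and shrinkage by
cohesive compaction rather than imaged deformation.

Two quantitative limitations are worth stating plainly. First, the OER
formula caps the aerobic radiosensitivity below its nominal maximum at any
physiological pO2 (OER(40 mmHg) = 2.41 of 2.5), which shifts the
absolute D50 scale of all simulated treatments upward by a few Gy relative
to an idealized fully-oxic LQ tumor; comparisons *between* treatments
(gains, orderings) are unaffected. Second, consumption-driven
reoxygenation is fast here — hypoxia largely resolves within the first
treatment week — so painted-vs-uniform gains are smaller than they would
be in a tumor whose hypoxia persists longer; the adaptive-scheme ranking
is preserved.

# Problem sizes

The acceptance script simulates the full study conditions: the standard
lookup (112-point solver grid, 8 vessel placements per node), the 3888-
voxel tumors and 30 patients per dose level. The test suite runs the same
pipelines with the standard lookup but trims the dose levels to the
informative range (52–82 Gy) and uses 20 patients per level for the gain
orderings — sizes chosen
so the whole suite completes in well under half an hour while the compared
quantities keep Monte-Carlo errors small against the tested differences;
common random numbers (the same virtual patients across schemes) sharpen
the gain comparisons further.
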