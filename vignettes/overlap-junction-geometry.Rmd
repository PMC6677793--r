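---
title: "Measuring coiled-coil overlap geometry, thermal stability, and ligand stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coiled-coil overlap geometry, thermal stability, and ligand stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmjunction)
```

Tropomyosin polymerizes head to tail along actin: the C-terminal end of one
coiled-coil dimer and the N-terminal end of the next interlock in a 4-helix
overlap junction. Small molecules that lodge in this junction during
co-polymerization change three measurable things: the junction's
coiled-coil radius (the helices splay to accommodate the ligand), its
bend, and its twist. This vignette documents the models behind each
analysis in the package, the tunable parameters, and the choices made
where the design was genuinely open.

## Ideal coiled-coil backbones

`build_ideal_coiled_coil()` places alpha carbons on the Crick curve: a
minor helix of radius $R_1$ wound around a superhelical path of radius
$R_0$ and pitch $P$ along $+z$,

$$
\begin{aligned}
x(t) &= R_0\cos\phi_0 + R_1\left(\cos\phi_0\cos\phi_1
        - \cos\alpha\,\sin\phi_0\sin\phi_1\right),\\
y(t) &= R_0\sin\phi_0 + R_1\left(\sin\phi_0\cos\phi_1
        + \cos\alpha\,\cos\phi_0\sin\phi_1\right),\\
z(t) &= h\,t - R_1\sin\alpha\,\sin\phi_1,
\end{aligned}
$$

with $\phi_0 = \omega_0 t$ the superhelical phase
($\omega_0 = \pm 2\pi h/P$, negative for the left-handed default),
$\phi_1 = \omega_1 t + \phi$ the minor-helix phase, $h$ the axial rise per
residue and $\tan\alpha = 2\pi R_0/P$ the pitch angle. Additional chains
are rigid copies rotated about $z$ by their phase offsets, so the default
0/180 dimer has exact C2 symmetry.

Defaults (`crick_parameters()`): $R_0 = 4.9$ Å, $R_1 = 2.26$ Å,
$h = 1.495$ Å/residue, $P = 140$ Å, left-handed superhelix, and 3.5
residues per minor-helix turn. These are canonical values for a parallel
two-stranded coiled coil, chosen as design defaults rather than fitted to
any particular structure. The periodicity deserves a note: in this
parameterization $\omega_1$ is measured in the superhelix-following frame,
where the heptad repeat makes exactly 2 turns per 7 residues
(3.5 residues/turn). Using the laboratory-frame alpha-helical periodicity
(3.6–3.62) here would shorten consecutive CA distances to ~3.68 Å; with
3.5 the builder produces 3.75–3.84 Å, inside the physical band it
enforces (3.6–4.0 Å as a hard error). $R_0 = 0$ degenerates cleanly to a
straight helix.

## Local axes, radius, bend and twist

**Local axes.** `fit_local_axes()` uses the three-point bisector
construction: at interior residue $i$ the unit bisector of the
CA$_{i-1}$–CA$_i$–CA$_{i+1}$ angle points at the local helix axis. Two
consecutive bisectors fix the local axis direction, and the local helix
radius $r_1$ is solved by requiring the displacement between consecutive
axis points to be parallel to that direction (a linear least-squares
condition). The axis point of residue $i$ is CA$_i + r_1 b_i$. Terminal
residues carry no axis point; collinear CA triples are a hard error. The
widely used per-residue coiled-coil analysis tools follow the same
family of constructions; this package fixes the recipe above and
validates it by round trip against the builder (radius within 0.1 Å,
rise within 0.01 Å/residue), not by bit-for-bit agreement with any
external program.

**Radius.** `radius_profile()` defines the coiled-coil radius of helix
$k$ at aligned residue $i$ as the distance from that helix's axis point
to the bundle's central-axis point (the mean of the member helices' axis
points). Both helix-averaged and per-helix profiles are provided because
a widened junction is asymmetric: when one chain moves outward by
$\delta$, the two-chain bundle centre moves by $\delta/2$ and both
per-helix radii grow by $\delta/2$. Multi-frame structures are
summarized as per-residue mean and SD over a frame window; the default
window, `"last_third"`, generalizes the common practice of averaging
over the converged tail of a production run.

**Bend and twist.** For `overlap_angles()` the junction is described by
the two chains of each flanking coiled coil and a flanking residue
window on each side (`junction_spec()`, windows of at least 5 residues
so a total-least-squares line through the bisector axis points is
meaningful). The bending angle $\omega$ is the angle between the two
flank axis directions, both oriented by increasing residue number —
i.e. C→N along the polymer — so a straight junction reads
$\omega = 0$ and $\omega \ge 0$ always. The twisting angle $\theta$ is
the signed angle, about the overall central axis (mean of the two flank
directions, oriented C→N), from the N-flank inter-helix vector to the
C-flank inter-helix vector. Each inter-helix vector (second minus first
paired chain, evaluated at the flank residue nearest the junction) is
first carried into the plane perpendicular to the overall axis by the
*minimal rotation* taking its flank direction onto that axis, rather
than by bare orthogonal projection. The two recipes agree for straight
bundles, but bare projection distorts azimuths by up to ~1° when the
bend is large (30°); parallel transport keeps the bend and twist
readouts exactly decoupled, which the synthetic round trip confirms to
numerical precision. The published bend/twist definitions this mirrors
are cited, not restated, in the original work; the recipe above is this
package's documented interpretation, and comparisons across packages
should be made on *changes* in the angles, not their absolute zero
points. Two sign facts worth knowing: mirror-imaging a structure negates
$\theta$, and swapping the pair order within one flank shifts $\theta$
by 180°; swapping both flanks consistently leaves $\theta$ unchanged.

## Homology-style model assembly

`assemble_overlap()` reproduces the fragment-replacement step of
homology modelling a junction: the incoming fragment's mapping window is
superposed (CA Kabsch) onto the scaffold's equal-length window, the
whole fragment is moved, and the scaffold is replaced inside the window
and on the replaced side, with the fragment renumbered into the
scaffold's numbering. Window-fit RMSD and the per-chain CA–CA splice
gaps are recorded in metadata rather than regularized away; a fit above
5 Å records a warning. `thread_sequence()` renames residues to a target
sequence without moving an atom (side chains beyond CB are dropped — the
package models at CA/backbone level, since downstream refinement by
molecular dynamics is out of scope). `extend_termini()` grows a
structure with an ideal segment anchored by a 5-residue superposition;
the segment is built with its minor-helix phase advanced to match the
anchor position, because a rigid rotation can absorb superhelical phase
but not minor-helix phase. The numbering offset between fragment and
scaffold (e.g. a window mapping residues 6–34 onto 1–29) is always
explicit user input: author-numbering conventions differ between
deposited structures and are never guessed.

## Superposition

`superpose()` is the Kabsch algorithm: SVD of the cross-covariance of
the centered point sets with the determinant sign correction that
forbids reflections. The test suite checks it against two independent
references: an exhaustive 1°-resolution search over ZYZ Euler-angle
rotations (the centered objective is linear in the rotation through
$\mathrm{tr}(R\,M)$, an identity the tests verify literally before
using it), and the reference implementation in bio3d.
`best_pairing_rmsd()` handles crystal structures with several equivalent
chains by trying every ordered chain pairing over the residue range and
reporting the best fit, pairing only residues resolved in both
structures — terminal residues are routinely missing from density.

## Thermal melts

The melt model is operational, not thermodynamic: the paper-shaped
experiment records ellipticity at 222 nm over 20–65 °C, and the package
extracts peak positions of the smoothed derivative. The pipeline order
is fixed as **normalize → smooth → differentiate → fit** (the source
experiment describes smoothing, differentiation, then Gaussian fitting;
a figure caption lists the operations in a different order, which is
treated as a wording inconsistency). Choices:

- `normalize_melt()` fits linear folded/unfolded baselines over the
  first and last 10% of points (configurable) and reports fraction
  unfolded, clipped to $[-0.05, 1.05]$; a min/max mode is provided
  because the source's normalization is not elaborated. Baseline fitting
  requires the grid to actually contain both plateaus — a transition
  whose tails are cut by the temperature window cannot be normalized
  reliably by any method.
- `smooth_derivative()` is Savitzky–Golay (default 5-point window,
  order 2, via the signal package) followed by central differences
  (one-sided at the ends). With order ≥ 2 on a uniform grid, quadratics
  differentiate exactly at interior points.
- `fit_peaks()` fits a sum of Gaussians plus a constant baseline by
  Levenberg–Marquardt (minpack.lm), initialized at the largest local
  maxima. The number of components is always user-specified — the
  source fits "multiple" Gaussians without stating how many — and
  centers within 0.5 °C of each other raise a degeneracy warning.
  $T_m$ is a fitted center; `delta_tm()` differences centers between
  conditions with propagated fit uncertainty.

The two-state generator uses logistic transitions
$f(T) = \sum_k a_k/(1+e^{-(T-T_{m,k})/w_k})$ plus a linear baseline and
Gaussian noise — a pragmatic stand-in, not a claim about unfolding
thermodynamics. The derivative of a logistic is symmetric about its
midpoint, so fitting it with a Gaussian recovers the center without
bias even though the tail shapes differ; this is why the pipeline's
noiseless Tm recovery is essentially exact when the plateaus are
sampled, and why recovery degrades when they are not.

## Radioligand binding

Counts convert to molar amounts through the specific activity:
amount(mmol) = (cpm/efficiency) / (SA(mCi/mmol) × 2.22×10⁹ dpm/mCi).
`fit_one_site()` fits $B(L) = B_\text{max} L/(K_d+L)$ with $L$ the free
ligand concentration (measured from supernatant counts in the source
experiment, so no depletion correction is applied by default; a fixed-
$B_\text{max}$ mode exists). Fits whose apparent $K_d$ exceeds three
times the largest sampled concentration are flagged ill-conditioned.
`molar_ratio_per_junction()` divides bound ligand by dimer
concentration times junctions-per-dimer; the default of one junction
per dimer reflects a continuous head-to-tail co-polymer, with the
finite-filament correction $(n-1)/n$ left as an explicit parameter.
`compare_conditions()` interpolates pre-/post-incubation isotherms onto
their shared concentration range and flags the post condition as
background-level when it stays below 20% (configurable) of the
pre-condition $B_\text{max}$.

The isotherm generator Poisson-samples expected counts (bound amount →
dpm through the specific activity, plus constant background) on a
2-fold serial dilution from 0.25 to 64 µM at 5 µM dimer, the design of
the source experiment. At 125 mCi/mmol and 25 µL counted volume the
expected counts are in the tens of thousands, so counting noise is of
order 1% — which is why the $K_d$ estimator shows negligible bias over
repeated simulations.

## What the generators do and do not emulate

The synthetic trajectories interpolate bend/twist to a target by a
convergence frame and then fluctuate with Gaussian angular noise —
emulating the observation that a junction perturbed by a bound ligand
settles quickly onto a new stable geometry. They do not emulate
force-field physics, solvent, correlated motions, or helix fraying; the
melt generator does not produce realistic CD spectral shapes below
210 nm; the isotherm generator assumes ideal mixing and a single site
class. Passing round trips therefore demonstrate that the *measurement*
pipelines are correct and well-conditioned at realistic noise levels,
not that the underlying physical models of real data are complete. One
deliberate calibration: the bundle generator nulls the baseline twist
of its reference geometry (the superhelix accumulates ~4°/residue of
phase along the C-side window, so even an untransformed bundle has a
nonzero raw $\theta$), making imposed twists absolute offsets from a
zero-reading reference.

## Problem sizes and numerical tolerances

The test and acceptance workloads use 30-residue flanks, 30-frame
trajectories, 91-point melt grids, 9-concentration × 4-replicate
isotherms and 200-simulation bias estimates — sizes at which every
analysis is over-determined while the full suite runs in seconds.
Fixed numerical choices: bisector construction requires ≥ 4 CA and
non-collinear triples; flank windows ≥ 5 residues; builder CA spacing
hard-bounded to 3.6–4.0 Å; superposition requires ≥ 3 points; Gaussian
widths bounded to [0.05, range] °C; nonlinear fits run up to 500 LM
iterations and non-convergence is an error, never a silent fallback.
All seeded generators draw from an isolated RNG state (`withr`), so
identical configurations are bit-reproducible and library calls never
perturb session randomness.

## Known limitations

- Backbone/CA-level modelling only: no side-chain building, rotamers,
  or energetics; splice discontinuities are reported, not repaired.
- Absolute bend/twist values are convention-dependent (flank windows,
  reference residues, transport recipe); compare changes, not zeros,
  across implementations.
- The apparent $K_d$ of a co-polymerization assay is not an equilibrium
  constant when the ligand becomes trapped in the polymer; the package
  reports the one-site fit without equilibrium interpretation.
- Insertion codes are unsupported (an explicit error), and biological
  assemblies are not expanded; chains are taken as deposited.
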