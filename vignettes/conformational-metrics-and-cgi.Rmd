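---
title: "Conformational metrics and Crooks-Gaussian-Intersection free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational metrics and Crooks-Gaussian-Intersection free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmetrics)
```

`trajmetrics` implements the computational readouts used to ask whether a
mutation at the GEF-binding surface of a small GTPase (the motivating case is
acetyl-mimicking substitutions of KRAS Lys104 on a G12D background) changes
the conformation of the α2/α3 helix pair and the free energy of GEF binding.
This vignette explains the models behind each stage, the parameters that
matter, the numerical policies at the edges, and what the synthetic
generators do and do not emulate.

## Superposition and RMSD

Each frame is superposed onto a reference by a weighted least-squares rigid
fit (`kabsch_fit()`): with weights $w_i$, the proper rotation $R$ and
translation $t$ minimise $\sum_i w_i |R x_i + t - y_i|^2$. The solution is
obtained from the SVD of the weighted covariance matrix; when the optimal
orthogonal matrix would be a reflection ($\det = -1$), the singular
direction with the smallest singular value is negated, so the result is
always a proper rotation. Point sets whose second singular value is
numerically zero (collinear geometry) are rejected rather than silently
fitted. The test suite cross-checks the fit against two independent routes:
Horn's quaternion eigenvalue method (agreement to 1e-8 Å) and a brute-force
minimisation over Euler angles (1e-6 Å).

`compute_rmsd()` then evaluates, per frame,

$$\mathrm{RMSD}(t) = \left[\frac{1}{M}\sum_{i=1}^{N} m_i\,
  \lvert r_i(t) - r_i^{\mathrm{ref}}\rvert^2\right]^{1/2},
  \qquad M = \sum_i m_i,$$

with $m_i$ the atomic masses (set $m_i = 1$ via `mass_weighted = FALSE`).
Whether the original analyses weighted the fit by mass is not knowable from
a typical methods section; the package defaults to a mass-weighted fit so
that fit and metric use the same weights, and exposes both choices. The fit
selection and the RMSD selection are the same atom set by default. The
reported `mean_value` averages the full series by default; a `mean_window`
argument restricts it (useful when the first few hundred ps of a production
run are treated as re-equilibration).

## RMSF and B-factors

`compute_rmsf()` measures each atom's fluctuation about its window-mean
position,

$$\mathrm{RMSF}_i = \left[\frac{1}{T}\sum_{t_j}
  \lvert r_i(t_j) - \bar r_i\rvert^2\right]^{1/2},$$

over a stated time window (MD practice uses a short trailing window, e.g.
the last 2 ns of a run, so that the mean structure is an equilibrated
reference). With `fit = TRUE`, rigid-body motion is removed first by one
fixed-point iteration: frames are fitted to the first in-window frame, the
mean structure is formed, and frames are refitted to that mean. One
iteration is sufficient because the mean structure changes negligibly on the
second pass for near-equilibrated windows; iterating to convergence would
change RMSF values well below their statistical error.

`rmsf_to_bfactor()` applies the Debye–Waller identity
$B_i = \tfrac{8}{3}\pi^2\,\mathrm{RMSF}_i^2$ exactly — it is stored as an
algebraic transform of the profile, so the identity holds to machine
precision on every produced object. For isotropic Gaussian jitter of
per-axis standard deviation $\sigma$, $\mathrm{RMSF} \to \sigma\sqrt{3}$;
the suite verifies recovery within 2% at $10^4$ frames and the $1/\sqrt{F}$
convergence rate.

## The four-Cα pseudo-dihedral

Helix–helix orientation is reduced to one internal coordinate: the torsion
over four Cα atoms, two on each helix. The canonical quadruple is
Cα(67) → Cα(74) → Cα(104) → Cα(87) — residues 67/74 sit on the α2 helix and
104/87 on the α3 helix of a RAS-numbered GTPase. The evaluation order is
exactly the listed order; since a torsion of the reversed sequence is equal
by symmetry, the only consequential choice is which atoms are the central
pair, and the listed order puts the inter-helix "virtual bond" between
Cα(74) and Cα(104), the two residues closest to the helix junction. The
order is overridable via `dihedral_quadruple()`.

The torsion uses the standard atan2 formulation with the IUPAC sign
convention and range (−180°, 180°]. It is a pure internal coordinate:
invariant under rigid motion (no superposition needed) and negated by
mirror-imaging, both property-tested. Frames in which three consecutive
points become collinear make the angle undefined; this is an error naming
the frame rather than a silent `NaN`.

## Circular summaries and distribution shifts

Angle ensembles are summarised on a fixed histogram grid anchored at 0° with
a default bin width of 1° — fine enough to resolve shifts of a few degrees,
and coarse enough that 3000-frame windows fill bins. Because angles are
directional, the headline location statistic is the circular mean (the
arithmetic mean on the (−180°, 180°] branch is also reported; the two
coincide for ensembles concentrated away from the branch cut, e.g. near
−55°, but the pair {179°, −179°} illustrates the artifact: circular mean
180°, arithmetic mean 0°). Spread is the circular standard deviation
$\sqrt{-2\ln \bar R}$. The mode is reported as the centre of the
most-populated bin, with ties broken toward the bin nearest the circular
mean so output is deterministic.

`compare_distributions(x, reference)` reports the shortest signed difference
of circular means and modes (x minus reference), the ratio of circular
standard deviations, and the overlap coefficient of the normalised
histograms. A mean shift more negative than 0.5° sets the `left_shifted`
flag — the reading used when a mutant ensemble moves to smaller torsions
than the wild type. The 0.5° tolerance is far below any shift of interest
(~5–7°) but above the sampling error of a 3000-frame circular mean (~0.15°).

## CGI and BAR free-energy estimates

The free-energy stage consumes bidirectional nonequilibrium work samples:
forward work for the alchemical switch λ 0 → 1 and backward work for 1 → 0,
in kJ/mol (kcal/mol converted on read, × 4.184). By the Crooks fluctuation
relation, the densities of forward work and negated backward work cross at
ΔG. The Crooks–Gaussian-Intersection estimator (`cgi_estimate()`) fits a
Gaussian to each (sample mean, unbiased SD) and solves for the crossing:

* equal variances (relative difference below 1e-8): the crossing is the
  midpoint of the means, used directly;
* unequal variances: the quadratic from equating log-densities has two real
  roots; the root lying between the two means is the physical one. If
  neither root lies between the means (possible for pathological moment
  combinations), the root nearest the midpoint is used and a diagnostic
  note recorded;
* both variances zero (zero dissipation): the common value is ΔG — the
  delta-function limit; unequal zero-variance means fall back to the
  midpoint with a diagnostic.

The Bhattacharyya coefficient of the two fitted Gaussians is recorded as an
overlap diagnostic; below 0.01 the crossing is an extrapolation far outside
the sampled region and a warning is raised (the estimate is still returned —
the caller sees both). `bar_estimate()` implements the Bennett
acceptance-ratio maximum-likelihood equation, solved by a bracketing root
finder; it serves as an independent cross-check, and on Crooks-consistent
Gaussian work the two agree within 0.2 kJ/mol at large n (tested at
n = 10^4). Temperature defaults to 298.15 K with
$k_B = 0.0083144626$ kJ/mol/K; it is configurable and recorded in every
estimate.

Errors come from a seeded nonparametric bootstrap (`bootstrap_error()`):
each direction is resampled with replacement, the estimator re-run, and the
replicate SD and 2.5/97.5 percentiles reported. Coverage of the planted
truth is verified at ≥ 85% over 200 seeded replications at n = 100 per
direction — nominal 95% coverage degrades a little at that sample size
because the percentile interval inherits the skew of the replicate
distribution.

`double_difference()` carries the binding interpretation. In a
double-system/single-box setup both legs of the thermodynamic cycle share
one box, so the measured ΔG *is* ΔΔG of binding; in two-leg mode
ΔΔG = ΔG1 (bound) − ΔG2 (free) with errors combined in quadrature. Positive
ΔΔG destabilises binding; negative stabilises.

## What the synthetic generators emulate

Every stage is testable without archived trajectories because the package
generates inputs with the statistical structure the estimators assume:

* `build_ideal_helix()` / `build_two_helix_system()` — fixture geometry at
  textbook α-helix parameters (rise 1.5 Å, twist 100°, radius 2.3 Å). The
  two-helix system places an α2-like segment (residues 67–74) and an
  α3-like segment (residues 87–104) so the canonical quadruple's torsion
  equals the requested hinge angle *exactly* (the second segment is rotated
  about the central virtual bond); it is the exact inverse of
  `compute_pseudo_dihedral()` and is used to pin the torsion code to 1e-6°.
  The α3-like segment spans 18 residues so that both residues 87 and 104
  exist on it; this is fixture bookkeeping, not structural biology.
* `simulate_fluctuations()` — i.i.d. Gaussian displacements about a base
  structure, optionally under a rigid drift. This emulates the *magnitude*
  of atomic fluctuation, not its physics: real MD displacements are
  correlated in time and anisotropic, so recovery tests validate the
  estimators, not any force field.
* `simulate_angle_trajectory()` — i.i.d. von Mises draws (Best–Fisher
  sampler). Defaults for comparative runs use κ = 50 (circular SD ≈ 8°,
  matching the visual width of well-behaved torsion histograms) and
  n = 3000 frames (a 30-ns window sampled every 10 ps). Real torsion series
  are autocorrelated; i.i.d. draws make mean-recovery tests *conservative*
  in the sense that the effective sample size of real data would be lower.
* `simulate_work()` — forward ~ N(ΔG + d, σ²), backward ~ N(−(ΔG − d), σ²).
  With `crooks_consistent = TRUE`, σ² = 2d/β, which makes the Gaussian pair
  satisfy the Crooks relation exactly in distribution, so the planted ΔG is
  identifiable by construction; d defaults to 3 kJ/mol, a mild-dissipation
  regime where 100+100 samples determine ΔG to a few tenths of kJ/mol.

All generators draw from a substream derived from (seed, operation name), so
composed pipelines are bit-reproducible regardless of call order, and the
same seed never silently couples two different generators.

Passing these tests shows the estimators are correct on data satisfying
their own assumptions (Gaussian work, stationary angle ensembles,
uncorrelated jitter). It does not validate sampling quality, force fields,
or convergence of any particular MD run — with real trajectories those
remain the user's responsibility.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: 100+100 work
samples (the standard snapshot count for fast-growth protocols) with
1000-replicate bootstraps, 3000-frame angle ensembles, 10^4-frame jitter
trajectories for convergence checks, and 200-seed coverage sweeps. These
sizes put sampling error well below the tolerances being asserted while the
whole suite completes in well under a minute of CPU.

Edge policies worth knowing: selections that match zero atoms are errors
(metrics never silently run on an empty set); multi-MODEL PDB files with
inconsistent atom counts name the offending model; PDB coordinates at or
beyond 10^4 Å cannot be written in fixed width and are a format error;
altloc conflicts resolve to the highest-occupancy conformer (ties to "A");
trajectory times must be strictly increasing, and multi-model files without
time information default to 0, 1, 2, … ps.

## Known limitations

* Atom correspondence between mobile and reference is positional; there is
  no sequence alignment or atom matching between different molecules.
* No topology, solvent, or periodic-boundary handling: inputs are expected
  to be whole, imaged molecules.
* The B-factor identity maps fluctuation to crystallographic B exactly but
  ignores static disorder and lattice contributions, so absolute values are
  comparable between simulations, not with experimental B columns.
* CGI inherits the Gaussian work assumption; for strongly non-Gaussian work
  distributions BAR (also provided) is the safer estimator, and a large
  CGI–BAR discrepancy is itself a useful diagnostic.
* Region-level B-factor reporting (e.g. a specific helix of the partner
  protein) takes user-supplied residue ranges; the package does not assign
  secondary structure.
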