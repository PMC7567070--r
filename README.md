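# trajmetrics

Tidy conformational metrics and nonequilibrium free-energy estimates for
molecular-dynamics trajectories of small GTPase/GEF complexes.

Point mutations and post-translational modifications of RAS-family GTPases —
for example acetylation-mimicking substitutions at KRAS lysine 104 on a G12D
background — can reorient the α2/α3 helix pair that forms part of the
GEF-binding surface, and thereby change how well the exchange factor can
engage the GTPase. `trajmetrics` packages the standard computational readouts
for that question so they can be run, tested and compared as one pipeline:

* **RMSD(t)** after weighted least-squares (Kabsch) superposition of each
  frame onto a reference:
  `RMSD(t) = [ (1/M) Σᵢ mᵢ |rᵢ(t) − rᵢ^ref|² ]^½`, with `M = Σᵢ mᵢ`
  (mass-weighted by default, uniform weights available).
* **RMSF / B-factor profiles** — per-atom fluctuation about the window-mean
  position, converted to Debye–Waller factors by `B = (8/3) π² RMSF²`.
* **A four-Cα pseudo-dihedral** — the torsion over Cα(67) → Cα(74) →
  Cα(104) → Cα(87) that tracks the mutual orientation of the α2 and α3
  helices — with windowed circular statistics (circular mean/SD, mode bin,
  histogram) and pairwise distribution-shift summaries.
* **Crooks–Gaussian-Intersection (CGI) ΔG / ΔΔG** from bidirectional
  fast-switching work samples: Gaussians are fitted to the forward work and
  the negated backward work, and ΔG is the abscissa where the two densities
  cross. In a double-system/single-box setup this value *is* the binding
  ΔΔG = ΔG1 − ΔG2 of a mutation (positive = destabilizing). A Bennett
  acceptance-ratio (BAR) estimator and seeded bootstrap errors are included
  as cross-checks.

Because production MD trajectories are rarely archived, the package ships
seeded synthetic generators (ideal helices, two-helix systems with an exact
hinge torsion, Gaussian-jitter trajectories, von Mises angle ensembles,
Crooks-consistent work samples) so that every stage is testable against
planted ground truth.

All result objects are tidy: they wrap tibbles and support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Estimate a binding ΔΔG from synthetic work samples planted at 6.14 kJ/mol
(100 samples per direction, Crooks-consistent, 3 kJ/mol dissipation):

```r
library(trajmetrics)

ws <- simulate_work(dg_true = 6.14, dissipation = 3, seed = 42)
dd <- double_difference(ws, n_boot = 1000, seed = 1)
dd
#> <ddg_estimate> ddG = 5.774 +/- 0.333 kJ/mol [single_box, destabilizing]
```

The point estimate (5.77 kJ/mol) sits within one standard error of the
planted truth, the 95% bootstrap CI (5.12–6.45) covers it, and the positive
sign is read as *destabilizing* — the mutation hampers GEF binding.

Compare two helix-orientation ensembles (a wild-type-like torsion ensemble
centred at −55.3° against a K104Q-like one at −62.0°):

```r
wt <- summarize_angles(simulate_angle_trajectory(-55.3, kappa = 50, seed = 101))
kq <- summarize_angles(simulate_angle_trajectory(-62.0, kappa = 50, seed = 104))
wt
#> <angle_distribution> n = 3000, circular mean -55.3 deg (sd 8.3), mode bin -54.5 deg
compare_distributions(kq, wt)
#> <angle_shift> d(mean) = -6.73 deg, d(mode) = -8.00 deg, sd ratio 0.97, overlap 0.669 [left-shifted]
```

The mutant ensemble is flagged as left-shifted by ~7°, the reading used to
call a reorientation of the α2/α3 pair.

Trajectory metrics run off the same containers:

```r
base <- build_two_helix_system(-55.3)          # quadruple torsion is exactly -55.3 deg
traj <- simulate_fluctuations(base, sigma = 0.4, n_frames = 500, seed = 7)
glance(compute_rmsd(traj, selection = "calpha"))
#> # A tibble: 1 × 6
#>   mean_rmsd n_frames fitted mass_weighted window_start window_end
#>       <dbl>    <int> <lgl>  <lgl>                <dbl>      <dbl>
#> 1     0.928      500 TRUE   TRUE                     0        499

head(tidy(rmsf_to_bfactor(compute_rmsf(traj, "calpha"))), 3)
#> # A tibble: 3 × 7
#>   index serial name  resid chain  rmsf bfactor
#>   <int>  <int> <chr> <int> <chr> <dbl>   <dbl>
#> 1     1      1 CA       67 A     0.667    11.7
#> 2     2      2 CA       68 A     0.675    12.0
#> 3     3      3 CA       69 A     0.659    11.4
```

Real data enter through `read_pdb()` (multi-MODEL PDB → trajectory),
`read_xyz_table()` (plain-text frame tables) and `read_work_file()`
(labelled two-column or pmx-like work files). A comparative multi-system run
(metrics → shifts → ΔΔG table, with TSV/JSON artifacts) is orchestrated by
`run_pipeline()` / `read_pipeline_config()`, also reachable from the shell
via `inst/scripts/trajmetrics-cli.R` (subcommands `rmsd`, `rmsf`,
`dihedral`, `cgi`, `simulate`, `report`).

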