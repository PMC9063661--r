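# lieaffinity

Linear interaction energy (LIE) analysis of inhibitor binding to
amyloid-beta protofibrils.

Finding small molecules that bind amyloid-beta (Aβ) oligomers and fibrils
is a long-standing goal in Alzheimer's research, and screening candidate
ligands demands a binding-affinity estimate that is both reasonably
accurate and far cheaper than alchemical free-energy methods. The LIE
approach estimates the absolute binding free energy of a ligand from just
two simulation legs — the ligand bound to the solvated protofibril and the
ligand free in solvent — as a linear combination of the changes in its
average nonbonded interaction energies:

```
ΔG_LIE = α (⟨V_vdW⟩_bound − ⟨V_vdW⟩_free) + β (⟨V_elec⟩_bound − ⟨V_elec⟩_free) + γ
```

Here `⟨V_vdW⟩` and `⟨V_elec⟩` are time-averaged ligand–surroundings van der
Waals and electrostatic interaction energies (kcal/mol), `α` and `β` scale
the nonpolar and polar contributions, and `γ` is a constant offset
absorbing hydrophobic/desolvation effects. For the Aβ protofibril the
literature-standard coefficients (α = 0.18, β = 0.5) fail, and the
parameters must be recalibrated by least squares against experimental
affinities; the recalibrated set (α = 0.288, β = −0.049, γ = −5.880
kcal/mol) is built in as `abeta_lie_parameters()`.

This package is for computational chemists who have (or simulate) such
energy time series and want a tested, reproducible pipeline for the whole
analysis:

* **energy I/O** — read GROMACS-style `.xvg` or CSV traces, discard
  equilibration, average across replicas (`read_xvg()`,
  `discard_equilibration()`, `replica_average()`,
  `assemble_complex_energies()`);
* **the LIE model** — predict, calibrate by OLS, validate on held-out
  ligands, convert Ki to ΔG, and compare methods' ΔG columns against
  experiment (`lie_predict()`, `fit_lie()`, `evaluate_lie()`,
  `ki_to_dg()`, `compare_methods()`);
* **a desk-scale nonbonded kernel** — pairwise Lennard-Jones + truncated
  Coulomb energies from coordinates, so the full pipeline runs end-to-end
  on toy systems without an MD engine (`interaction_energy()`,
  `trajectory_energy_series()`);
* **structural analysis** — Kabsch-superposed Cα RMSD, geometric
  hydrogen-bond detection (D–A < 3.5 Å, A–H–D > 135°), and hydrophobic
  non-bonded contact counting (ligand C/S within 2.9–3.9 Å of any peptide
  atom) on multi-model PDB trajectories (`ca_rmsd_series()`,
  `detect_hbonds()`, `count_nbc()`);
* **a synthetic-data generator** — AR(1) energy traces, LIE datasets with
  known ground truth, and toy complexes with constructed geometries, so
  every stage is testable without simulations (`gen_energy_traces()`,
  `gen_lie_dataset()`, `gen_toy_complex()`, `write_fixture_bundle()`).

## Worked example

Calibrate on 20 synthetic complexes with known ground truth
(α = 0.288, β = −0.049, γ = −5.880, residual scale 0.95 kcal/mol) and
validate on the 10 held out:

```r
library(lieaffinity)

tab <- gen_lie_dataset(n_ligands = 30, seed = 7)   # complex table + dg_exp
sp  <- random_split(tab, n_train = 20, seed = 8)

fit <- fit_lie(sp$train)
fit
#> <lie_fit> n = 20 complexes
#>   alpha = 0.2436, beta = -0.0210, gamma = -6.6766 kcal/mol
#>   Pearson R = 0.799, standard error (rmse) = 0.934 kcal/mol

evaluate_lie(sp$test, fit$params)
#> <lie_fit> n = 10 complexes
#>   alpha = 0.2436, beta = -0.0210, gamma = -6.6766 kcal/mol
#>   Pearson R = 0.952, standard error (rmse) = 0.538 kcal/mol

evaluate_lie(tab, standard_lie_parameters())$r   # uncalibrated control
#> [1] 0.3439436
```

The fitted coefficients land within sampling error of the generating
values, the training correlation (R = 0.80) and error (0.93 kcal/mol) sit
at the scale the generator encodes, and the literature-standard
parameters — sensible for enzymes with a defined binding pocket but not
for a protofibril surface — correlate far worse than the refit.

Structure-level criteria work on any (multi-model) PDB; here a toy
complex built with one ideal hydrogen bond:

```r
toy <- gen_toy_complex(12, 4, "hbond_ideal", seed = 5)
detect_hbonds(toy$structures[[1]])
#>   donor_idx h_idx acceptor_idx distance_A angle_deg
#> 1        13    14            4        2.9       180
```

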