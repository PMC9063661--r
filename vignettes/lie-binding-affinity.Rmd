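---
title: "Methods: LIE binding-affinity analysis for amyloid-beta protofibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LIE binding-affinity analysis for amyloid-beta protofibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lieaffinity)
```

## The model

The linear interaction energy (LIE) method is an end-point estimate of the
absolute binding free energy of a ligand. Two simulation legs are run: the
ligand bound to the solvated receptor (here a dodecameric amyloid-beta
protofibril) and the ligand free in solvent. From each leg the
ligand–surroundings van der Waals and electrostatic interaction energies
are recorded per frame and averaged, and the binding free energy is
modelled as

$$\Delta G = \alpha\,(\langle V_\mathrm{vdW}\rangle_b -
\langle V_\mathrm{vdW}\rangle_f) + \beta\,(\langle V_\mathrm{elec}\rangle_b -
\langle V_\mathrm{elec}\rangle_f) + \gamma,$$

with $\alpha$ and $\beta$ dimensionless scalings of the nonpolar and polar
energy differences and $\gamma$ a constant offset (kcal/mol) absorbing
hydrophobic and desolvation effects. More negative $\Delta G$ means
stronger binding, throughout.

The model's key assumptions are (i) linear response — the free-energy cost
of turning on ligand–surroundings interactions is proportional to their
average — and (ii) transferability of $(\alpha, \beta, \gamma)$ across the
ligand panel. For receptors with a defined pocket the literature-standard
coefficients ($\alpha = 0.18$, $\beta$ in 0.33–0.50) often suffice; a
protofibril surface offers no unique pocket, ligand electrostatics are
typically *weakened* on binding, and the standard coefficients fail. The
package therefore treats $(\alpha, \beta, \gamma)$ as quantities to
recalibrate by ordinary least squares against experimental affinities,
with the protofibril calibration $\alpha = 0.288$, $\beta = -0.049$,
$\gamma = -5.880$ kcal/mol available as `abeta_lie_parameters()` and the
standard set (with $\gamma = 0$, since no offset accompanies the standard
coefficients) as `standard_lie_parameters()` for use as a negative
control.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `t_equil` | 5 | ns | Cα RMSD of these systems plateaus within 5 ns of a 20 ns run; frames at $t \le$ `t_equil` are discarded (strict inequality, one consistent convention). |
| replicas | 4 | — | Four independent runs per complex; replica means are combined with equal weight (the symmetric choice for exchangeable replicas — the aggregation rule is otherwise underdetermined; for equal-length replicas it equals frame pooling). |
| `temperature` | 300 | K | Used only to convert inhibition constants, $\Delta G = RT\ln K_i$ at 1 M standard state; 300 K is the simulation-typical choice. Explicit `dg_exp` values take precedence over `ki_molar`. |
| `se_definition` | `"rmse"` | — | Reported "standard errors" in this literature are ambiguous; both $\sqrt{\sum r^2/n}$ (`rmse`) and $\sqrt{\sum r^2/(n-k)}$ (`dof_corrected`, $k = 3$ for a fresh fit, 0 when evaluating frozen parameters) are implemented, and every report names the convention used. |
| `cutoff` | 10 | Å | Nonbonded kernel truncation, matching the 1.0 nm van der Waals cutoff typical of the production simulations. |

Energies are kcal/mol internally; `.xvg` input is assumed kJ/mol (the
GROMACS default) and divided by 4.184 on read, with time converted from ps
to ns. The `.xvg` energy column defaults to column 2 and is selectable,
since GROMACS energy extractions can hold several terms per row.

## Calibration and validation

`fit_lie()` regresses `dg_exp` on the two energy differences with
$\gamma$ as a free intercept, requiring at least 4 complexes (one more
than the parameter count). The solution uses the QR decomposition
(`stats::lm`), not raw normal equations; a design matrix with condition
number above 1e10 is rejected as collinear rather than silently
pseudo-inverted. `evaluate_lie()` applies frozen parameters to a new
table with no refitting, and charges zero fitted degrees of freedom in
its error. `compare_methods()` correlates any number of per-method
$\Delta G$ columns with experiment and ranks them by Pearson $R$ — the
primary accuracy metric — with RMSE as the accompanying error.
`random_split()` produces the deterministic 20/10-style train/test
partitions used for validation.

## The nonbonded kernel

The `nonbonded` module computes ligand–surroundings interaction energies
directly from coordinates: a 12-6 Lennard-Jones term with
Lorentz–Berthelot combination (the Amber-family convention) plus a
Coulomb term with $k_e = 332.0636$ kcal Å mol⁻¹ e⁻², summed over all
ligand × environment pairs within a hard cutoff (closed at the cutoff, no
switching function), with minimum-image distances when an orthorhombic
box is supplied. Because ligand and environment are distinct molecules,
every cross pair is full strength (no 1–4 scaling or exclusions).
Truncated Coulomb is an approximation to the Ewald treatment a production
engine would use: this module exists so the full trace-to-fit pipeline can
be exercised on toy systems, not to reproduce engine energies. Atom pairs
closer than 1e-6 Å are reported as errors with the offending pair rather
than returning a divergent energy.

## Structural criteria

* **Cα RMSD** is computed per frame against the initial configuration
  after Kabsch superposition (closed-form SVD solution constrained to a
  proper rotation). Measuring without alignment would conflate rigid-body
  diffusion with deformation, so alignment is applied even though plain
  trajectory RMSD tools differ on this point.
* **Hydrogen bonds** use the geometric gates donor–acceptor distance
  < 3.5 Å and acceptor–hydrogen–donor angle > 135°, both strict, exactly
  as stated inequalities. The geometry gives only the gate, not the
  chemistry, so the package adds minimal chemistry: hydrogens are
  assigned to the nearest N/O/S within 1.2 Å, donors are N/O/S carrying
  at least one such hydrogen, acceptors are N/O. Only ligand–peptide
  pairs count, scanned in both donor directions; waters and counter-ions
  are excluded. Structures without explicit hydrogens raise an error
  instead of silently returning zero bonds.
* **Non-bonded contacts** count ligand C/S atoms within 2.9–3.9 Å of any
  peptide atom. The interval is treated as closed at both ends (the
  stated range carries no open/closed marking; the closed reading is
  documented and tested at both endpoints). Each qualifying atom pair
  counts once.
* Multi-model PDB files are treated as trajectories with the frame index
  as time; alternate locations other than blank/`A` are dropped; HETATM
  non-water records become the ligand group.

## The synthetic generator

The generator exists so every stage is testable without simulation
output, and its defaults encode the study design the package targets:

* **Energy traces** are stationary AR(1) series,
  $v_t = \mu + \phi(v_{t-1} - \mu) + \eta_t$, the minimal model of
  autocorrelated MD observables, with $\phi = 0.9$ at 10 ps sampling and
  marginal sd 2 kcal/mol. The closed-form moments (mean $\mu$, sd, lag-1
  autocorrelation $\phi$) are what the tests check.
* **LIE datasets** draw per-ligand energy differences uniformly —
  $\Delta V_\mathrm{vdW} \in [-20, -5]$,
  $\Delta V_\mathrm{elec} \in [-5, +25]$ kcal/mol — and set
  $\Delta G = \alpha\Delta V_\mathrm{vdW} + \beta\Delta V_\mathrm{elec} +
  \gamma + \mathcal N(0, 0.95^2)$ with the protofibril calibration as
  ground truth. The signs encode the regime observed for this receptor:
  van der Waals dominated, electrostatics mostly weakened on binding.
  The vdW range was chosen so the resulting experimental affinities fall
  in a realistic nanomolar-to-micromolar window (about $-7$ to $-12$
  kcal/mol) and the fitted correlation lands near 0.8 at the 0.95
  kcal/mol residual scale — the regime reported for this receptor; a much
  wider spread would make the calibration trivially accurate
  ($R > 0.95$) and imply unphysically strong binders.
* **Toy complexes** build a miniature N/CA/C/O backbone plus a small
  ligand in one of three controlled geometries: `contact` (ligand carbons
  3.0–3.5 Å from peptide atoms, inside the contact window), `separated`
  (beyond 12 Å, outside any cutoff), and `hbond_ideal` (exactly one
  O–H···O bond at 2.9 Å / 180°). Constructions guarantee the detector
  outcomes, which is what makes them useful oracles.
* **`write_fixture_bundle()`** materialises a full study to disk — the
  `paper_like` preset is 30 ligands split 20/10, with 4 replicas × 2
  components × 2 states × 2001 frames (480 `.xvg` traces) — with a JSON
  manifest recording seeds and ground truth. All generators are
  bit-reproducible given their seed.

What the generator does **not** emulate: the joint distribution of vdW
and electrostatic differences across real ligand panels (components are
drawn independently), ligand-specific chemistry, conformational
switching, or drift. Consequently a passing suite demonstrates that the
machinery is correct and that calibration recovers known ground truth at
the study's noise level — not that the LIE assumptions hold for any given
real system. One visible consequence: the *magnitude* of the
standard-parameter control's (negative-to-near-zero) correlation depends
on the real data's joint vdW/elec structure, so the synthetic control
reproduces its direction and its collapse relative to the refit, not a
specific value.

## Numerical choices and degenerate inputs

* OLS via QR; collinearity gate at condition number 1e10.
* Kabsch: the reflection case is handled by sign-correcting the smallest
  singular vector; collinear references (rank < 2 after centring) are
  errors.
* Frames at exactly `t_equil` are discarded; an equilibration window
  consuming an entire trace is an error, not an empty average.
* Replica-count mismatches against the declared design warn but do not
  fail; metadata mismatches (ligand, component, state) are errors.
* Energy traces require strictly increasing times and finite values at
  construction, so downstream code never re-validates.
* Permutation/identity edge cases (single replica, single frame,
  zero-noise traces) are defined and tested rather than excluded.

## Problem sizes

The test suite runs the statistical checks at sizes chosen to make the
sampling bands tight while keeping the whole suite fast on one CPU:
AR(1) moment checks at $10^5$ frames, residual-scale checks at $10^4$
ligands, parameter-recovery bias over 500 seeds at $n = 20$, nonbonded
oracle agreement up to 100 atoms, and the trace-to-fit loop closure on 12
ligands × 16 traces × 401 frames. The acceptance script runs the full
design (30 ligands × 16 traces × 2001 frames) in seconds.

## Known limitations

* Truncated Coulomb (no Ewald/PME) in the desk-scale kernel; it is a
  pipeline-exercising tool, not an engine replacement.
* Hydrogen-bond chemistry is the minimal N/O/S heuristic; no bond-order
  or aromaticity perception.
* No extended LIE variants (SASA terms, split $\beta_b/\beta_f$,
  intramolecular energies); the three-parameter form is the model.
* FEP and MM/PBSA energies are consumed as columns for comparison only;
  the package does not compute them.
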