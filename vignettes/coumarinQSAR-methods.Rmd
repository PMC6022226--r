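---
title: "Methods: descriptors, model fitting and validation in coumarinQSAR"
author: "coumarinQSAR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, model fitting and validation in coumarinQSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

coumarinQSAR models the anti-proliferative activity of a series of
seventeen coumarin-6-sulfonamide derivatives assayed against HepG2
(hepatocellular carcinoma), MCF-7 (breast) and Caco-2 (colon) cancer cell
lines.  Activity is expressed as pIC50 = −log10(IC50 in µM), and the
modelling question is the standard 2D-QSAR one: which computable
molecular properties explain the variation in potency across the series,
and how well does a small multiple linear regression (MLR) over those
properties predict held-out compounds?

The package covers the full pipeline: structure input (SMILES/SDF), 3D
conformer generation, molecular descriptors (topological, electronic,
surface, shape), genetic-algorithm descriptor selection, MLR fitting with
leave-one-out (LOO) cross-validation, and application of the two fixed
published regression equations for HepG2 and Caco-2 that ship as model
files with the package.

## Data model and fixtures

Structures are held in a plain `qsar_molecule` object: an ordered atom
table (element, formal charge, implicit-H count, Bondi van der Waals
radius, standard atomic mass, optional partial charge and coordinates)
plus a bond list.  The 17 compounds were encoded as SMILES from their
systematic names; the test suite verifies every hydrogen-inclusive
molecular formula against the published elemental-analysis formulas, which
is the strongest structure check available since no machine-readable
structures were deposited.  Activity tables ship as plain CSV.  IC50
entries reported only as ">200 µM" are kept as censored observations
(`NA` + flag) and are never converted to numbers or imputed; censored
cells are simply absent from all pIC50 arithmetic.

Three printed-data quirks are worth knowing about (all verified by
`reproduce_report()` and documented where they bite):

* the external-validation Caco-2 row labelled "13a" carries the
  experimental activity of compound 11a (−1.0052 = −log10(10.12 µM));
  `training_split("Caco-2")` therefore excludes {6, 9, 11a}, matching the
  populated rows of the training table;
* compounds 9 (Caco-2), 11a and 11d (HepG2) are censored ">200" in the
  IC50 table yet appear with finite experimental activities (≈ 205–220
  µM) in the training/external tables; the censored flag is kept and
  those cells are excluded from the IC50→pIC50 sweep (31 cells remain);
* one cell (11d, Caco-2) prints −1.2058 where −log10(16.06) = −1.20575
  rounds to −1.2057, i.e. the printed activity was rounded from an
  unrounded IC50; the sweep therefore checks agreement within one unit
  in the fourth decimal.

## Conformers and reproducibility

All surface, shadow and dipole descriptors depend on the conformer, so
the package fixes one documented convention: a single conformer per
molecule from seeded ETKDG distance-geometry embedding (run through the
system python's RDKit) followed by MMFF94 relaxation (UFF where MMFF94
lacks parameters).  The generator is an exact function of (structure,
seed); identical inputs give bitwise-identical coordinates, which makes
every downstream descriptor — and therefore every table the package
writes — reproducible from a seed.  No conformer ensemble is attempted:
the reference descriptor software also used single conformers, its
protocol is unreported, and a documented deterministic convention is
worth more here than an undocumented search.

## Descriptor conventions

**Connectivity (chi) indices** use the hydrogen-suppressed graph with
simple vertex degrees: chi of order k sums (Π degree)^(−1/2) over
connected k-edge subgraphs; `CHI_3_C` is the 3-edge star (cluster) form.
Both simple and valence-corrected variants are computed (the descriptor
pool carries both), but the published model term `CHI_3_C` binds to the
simple form, which is the canonical choice here since the original
software does not document which it used.  All chi values are tested
exactly (1e-12) against a brute-force subgraph enumeration oracle.

**Information of atomic composition** is the Shannon entropy of the
element counts: IAC_total = n·log2 n − Σ ni·log2 ni bits, IAC_mean =
IAC_total/n.  Hydrogens are counted by default (a flag disables this):
without hydrogens the composition of typical CHNOS organics collapses to
near-uniform and the descriptor loses most of its variance.

**Gasteiger (PEOE) charges** are computed by iterative partial
equalization of orbital electronegativity, with χ = a + bq + cq², damping
(1/2)^k, and transfer normalized by the cation electronegativity of the
donor atom (20.02 for H).  The parameter table and the perception rules
(sp3/sp2/sp by bond orders; lone-pair N/O demoted to sp2 next to a
π-bearing neighbour of degree ≤ 3; sulfur sp2 only for thiocarbonyl and
aromatic-ring patterns; resonance-delocalized terminal formal charges
shared equally within their group) were chosen to reproduce RDKit's
independent implementation, and the test suite verifies per-atom
agreement within 1e-3 e on all 17 compounds — in practice agreement is at
machine precision.  Default 8 damped sweeps; charge is conserved exactly
by construction.

**Inertial alignment.**  Shadow and dipole-component descriptors depend
on the molecular frame, which the original software does not document, so
the package pins one: mass-weighted centroid at the origin; principal
axes of the mass-weighted inertia tensor on x/y/z with the smallest
moment (longest extent) on x and the largest on z; x- and y-axis signs
chosen so the third moment of coordinates along each axis is ≥ 0 (ties
broken toward the first atom); z completes a right-handed frame.
Exactly degenerate moments keep the symmetric-eigensolver order.  The
magnitude-type descriptors (dipole magnitude, SASA, Jurs, shadow areas)
are invariant to the input pose to 1e-6 relative; the signed components
are invariant up to this documented convention.

**SASA** uses Shrake–Rupley sampling with a deterministic Fibonacci
sphere: 960 points per atom, probe radius 1.4 Å (the water-probe
literature default; both configurable).  Accuracy anchors: isolated-atom
spheres within 1 % of 4πr², two-sphere systems against the closed-form
lens formula, and < 2 % drift between 960 and 10 000 points on the
largest fixtures.  Fewer than 32 points is rejected as below the
accuracy floor.

**Jurs (CPSA) descriptors** follow the Stanton–Jurs definitions from
per-atom SASA and partial charges; atoms with exactly zero charge count
to the positive set so that PPSA_1 + PNSA_1 equals total SASA
identically.  The polar/hydrophobic split for TASA/TPSA uses the
conventional |q| ≥ 0.2 cutoff.  `Jurs_PNSA_3` (Σ area·charge over
negative atoms) is ≤ 0 by construction.

**Shadow descriptors** rasterize the union of atomic van der Waals discs
projected on the xy/yz/xz planes of the aligned frame (grid step 0.1 Å,
< 0.5 % change on halving), with extents = coordinate range ± radius and
fractions relative to the enclosing rectangle.  No probe inflation is
applied: shadow indices historically use the bare van der Waals surface.
The published HepG2 model binds to the area `Shadow_YZ`; the discussion
prose around the original model mentions `Shadow_YZfrac`, but the printed
equation names the area, so the area is what the packaged model file
uses (both columns are emitted).

## Model fitting and validation

`fit_mlr()` is ordinary least squares with intercept via `stats::lm`,
rejecting rank-deficient and constant inputs by name.  The statistics
mirror the published validation surface: r², adjusted r² = 1 −
(1−r²)(n−1)/(n−p−1), SSE, LSE = SSE/n (the "least-squared error"
convention that exactly reproduces the printed 0.0168/0.0173 from the
printed residual columns), PRESS from hat-matrix leverages (tested to
1e-9 against literal n-fold refitting), and LOO q² = 1 − PRESS/SST.
PRESS ≥ SSE and q² ≤ r² hold for every OLS fit and are property-tested
across seeded problems.

The two published equations ship as JSON model files and are applied by
`predict()`; `external_validate()` refuses any overlap between training
and test labels.  Refitting the four HepG2-model descriptors on this
package's own descriptor values runs end-to-end and reports its r²
(≈ 0.45 at seed 1) — deliberately *not* asserted against the published
0.940, because the original descriptor values came from a proprietary
pipeline whose conformer, charge and frame conventions are unreported;
reproducing the printed model statistics from the printed activity
tables, and the descriptor engines from first-principles oracles, are
the two honest checks available.

## Descriptor selection (GFA)

`gfa_evolve()` is a seeded genetic algorithm over descriptor subsets:
tournament selection (size 2), single-point crossover over term lists
with duplicate collapse, add/drop/swap mutation, elitism of one (so the
best lack-of-fit is non-increasing — tested), and OLS refit of every
individual.  Scoring is Friedman's lack-of-fit, LOF =
(SSE/m)/(1 − (c + d·p)/m)², with smoothing d = 1 and the intercept
counted as a basis function (c = p = terms + 1) — a stated convention,
configurable, since the original protocol names GFA but fixes none of
its hyperparameters.  Defaults: population 100, 500 generations,
mutation probability 0.1, linear terms only (the published equations are
linear).  On exhaustively enumerable pools the GA's top model matches
brute-force LOF enumeration in ≥ 95 % of seeded trials.

## Synthetic data

The simulator is first-class and defines the study conditions for every
statistical test: descriptor matrices default to 17 samples (the
compound count) × 50 standard-normal columns with optional
equicorrelation ρ; activities are sparse linear signals (3 informative
terms by default) plus Gaussian noise with σ = 0.13 pIC50 units, chosen
once so that the residual mean square of a correctly specified fit,
σ²(n−p−1)/n ≈ 0.010–0.017 at the study's n and p, sits at the scale of
the published least-squared errors.  The molecule generator emits
coumarin-sulfonamide-like SMILES from a seeded grammar (4 scaffolds × 17
substituents, C/N/O/S/Cl only, 5–30 heavy atoms) to exercise the
descriptor pipeline end-to-end.  What passing these tests shows is that
the machinery is correct and calibrated at the study's scale; it does
not show that real descriptor matrices are Gaussian or uncorrelated —
real chi/surface columns are strongly collinear, which is precisely why
the GFA layer and not a fixed subset does the selection on real input.

Problem sizes used by the test suite and acceptance script — 17-compound
descriptor tables, 25-molecule generator smoke runs, 100-fit OLS property
loops, 25-seed GFA recovery at 100×100 GA scale — were chosen as the
smallest sizes that exercise each claim at the study's own dimensions.

## Known limitations

* Descriptor *values* are convention-dependent (conformer, radii, probe,
  frame, charge model); they match their own documented definitions and
  first-principles oracles, not the numeric output of the proprietary
  software used originally — hence the published coefficients should be
  applied to descriptors from that software's conventions, and the
  packaged fixed models are reproduced at the printed-table level.
* Single conformer, no tautomer/protonation enumeration, no
  stereochemistry-dependent descriptors.
* The MCF-7 endpoint has no published model and none is fitted here.
* The embedding backend requires a python with RDKit on the PATH (a
  documented system requirement); everything else is pure R plus
  Open Babel via ChemmineOB.
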