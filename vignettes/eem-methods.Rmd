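---
title: "Electronegativity equalization charges: model, calibration and charge-transfer profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electronegativity equalization charges: model, calibration and charge-transfer profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemr)
```

## The model

The electronegativity equalization method (EEM) assigns partial atomic
charges to a molecule from its 3D structure alone. Its physical premise is
Sanderson's equalization principle: when atoms combine, electron density
flows until every atom's electronegativity reaches a common molecular value
$\bar\chi$. Each atom's electronegativity is modelled as a linear function
of its own charge and of the electrostatic potential of all other atoms:

$$\chi_i \;=\; A_i + B_i q_i + k \sum_{j \neq i} \frac{q_j}{R_{ij}},$$

where $q_i$ is the charge of atom $i$ (in elementary charge units e),
$R_{ij}$ the interatomic distance in ångström, $A_i$ the effective
electronegativity of the neutral typed atom in a molecular environment,
$B_i$ twice its effective hardness (the resistance of the atom's
electronegativity to a change in charge), and $k$ a dimensionless factor
scaling the interatomic electrostatic term (the Yang–Wang modification),
which makes the $(A,B)$ parameter space cheap to sample during calibration.

Setting $\chi_i = \bar\chi$ for every atom and adding charge conservation
$\sum_i q_i = Q$ yields an $(n{+}1)\times(n{+}1)$ linear system in
$(q_1,\dots,q_n,\bar\chi)$. `assemble_system()` builds it and
`solve_charges()` solves it by a dense LU factorization (Gaussian
elimination with partial pivoting), then verifies the solution a
posteriori: the maximum residual must stay below $10^{-8}\max(1,|Q|)$ and
$|\sum_i q_i - Q| < 10^{-8}$. The electrostatic sum runs over *all* pairs
with no distance cutoff — the $1/R$ interaction decays too slowly to
truncate, and a dense solve of protein-sized systems is cheap on modern
hardware ($O(n^2)$ assembly, $O(n^3)$ solve).

Key assumptions inherited from the formalism: charges are point monopoles
at nuclear positions; the response is linear in the charges (no
polarizability beyond the $B_i$ term); no solvent screening; conformational
dependence enters exclusively through $R_{ij}$, which is precisely what
makes EEM suitable for comparing conformers of the same protein.

## Atom typing: the `E` and `EX` schemes

$A$ and $B$ cannot be measured; they are calibrated per *atom type*. Two
classification granularities are supported:

* **`E`** — by chemical element only (`H`, `C`, `N`, `O`, `S`, `Ca`).
* **`EX`** — by element plus the maximum order over the atom's incident
  bonds: a backbone carbonyl oxygen types as `O2`, a hydroxyl or carboxylate
  single-bonded oxygen as `O1`. Species with no bonds at all (isolated
  ions such as Ca²⁺) keep the bare element symbol, since a maximum bond
  order is undefined at zero bonds.

`EX` always refines `E`: stripping the order suffix recovers the element
partition, a property the test suite asserts on generated molecules.

Bond orders come from `perceive_bonds()`: residue templates for the twenty
standard amino acids (with a fixed Kekulé assignment for aromatic rings —
immaterial for typing, which only consumes the *maximum* incident order),
peptide bonds by the inter-residue C–N distance (≤ 1.7 Å), disulfides by
the S–S distance (≤ 2.3 Å), hydrogens attached to the nearest heavy atom
within covalent range, and a distance fallback (Cordero covalent radii
+ 0.4 Å, single bonds, with a warning) for residues without a template.
Any interatomic distance below 0.5 Å is treated as a structural error.

## Calibration

Given reference charges $q_i$ (in practice quantum-chemical population
charges; here also forward-generated synthetic ones) the equalization
equation rearranges, per atom, into a line in that atom type's parameters:

$$\underbrace{\bar\chi - k \sum_{j\neq i} \frac{q_j}{R_{ij}}}_{y_i}
  \;=\; A + B \underbrace{q_i}_{x_i}.$$

`build_regression_rows()` computes $(x_i, y_i)$ from reference charges and
actual distances, grouped by atom type; `fit_parameters()` solves each
group by ordinary least squares. Because every row involves only its own
type's $(A, B)$, the global design matrix is block-diagonal and the
per-type fits jointly minimize the overall residual — fitting types
independently is exact, not an approximation.

$k$ enters $y_i$ nonlinearly, so it is grid-searched: for each candidate
$k$ the OLS fit is computed and scored by *internal validation* — EEM
charges are re-solved for the training molecules under the fitted
parameters and compared with the reference charges via the mean
per-molecule squared Pearson correlation $R_{avg}$. `eem_calibrate()`
returns the model at the best $k$ (ties resolve to the smallest $k$,
making the selection deterministic). The default grid is 0.05–1.50 in
steps of 0.05, wide enough to bracket reported EEM calibrations while
keeping the search cheap; it is a plain argument for anyone who wants a
finer or wider sweep. Types with fewer than 2 observations (or zero charge
variance) are a hard error; fewer than 30 draws a warning, since OLS
slopes from a handful of points are fragile.

The per-molecule target $\bar\chi$ is approximated by the harmonic mean of
the constituent atoms' Pauling electronegativities (hydrogens included),
$\bar\chi \approx n / \sum_i \chi_i^{-1}$, using packaged Pauling-scale
values (Allred's revision: H 2.20, C 2.55, N 3.04, O 3.44, S 2.58,
Ca 1.00). Note the deliberate unit convention: the harmonic target is on
the Pauling scale while the fitted $A, B$ absorb whatever scale the
targets impose — no conversion is attempted, matching standard EEM
calibration practice.

### Validation statistics

`eem_validate()` solves each record with $Q$ equal to the sum of its
reference charges — so the conservation constraint can never penalize the
comparison — and reports, per molecule and averaged: squared Pearson
$R^2$, RMSD, and the mean absolute difference $D$. $R^2$ is blind to
affine distortions (a uniform shift, or even a sign flip, still scores
$R^2 = 1$), which is exactly why RMSD and $D$ are always reported
alongside; the test suite pins these identities down. $D \le$ RMSD holds
for every molecule by the power-mean inequality.

## Per-residue charge-transfer profiling

To compare two conformations of the same protein, `profile_report()`
solves charges for both structures, pairs residues on (chain, residue
number, insertion code) — a residue-name mismatch at a matched position is
an error, never silently reconciled — and computes two indicators:

* $\Delta Q_{res} = \left|\sum_{b} q - \sum_{a} q\right|$, the **net**
  charge transferred to or from the residue as a unit, summed over each
  structure's full residue atom set; the sign of the underlying difference
  is kept as a separate direction column. The alternative reading — the
  sum of per-atom absolute differences — is available as
  `delta_mode = "sum_abs"`, because the two conventions answer different
  questions (net transfer vs total per-atom change) and the choice
  materially changes the table.
* $\mathrm{RMSD}_{res} = \sqrt{\tfrac{1}{n}\sum (q_b - q_a)^2}$ over
  *name-matched* atoms only (RMSD is undefined for unpaired atoms),
  capturing intra-residue redistribution that cancels in the net sum.

A residue is flagged when its statistic exceeds the mean plus one standard
deviation over all scored residues. The SD is the population SD and the
inequality strict, so an all-equal profile yields no flags; the flagging
rule is shift-invariant by construction. Both conventions are recorded in
the JSON summary so downstream readers need not guess.

Chains excluded from pairing (for instance an activator peptide present in
only one structure) are excluded from the flagging pool as well, but stay
in their structure's charge solve — the bound peptide polarizing the
protein is part of the signal being measured, not an artifact to remove.

## The synthetic generator

Real reference sets pair molecular fragments with quantum-chemical
charges; none are shipped here. Instead `fixture_spec()` /
`make_molecules()` / `forward_reference()` generate collections of random
C/H/N/O/S/Ca molecules (element frequencies mirroring protein fragments:
H and C dominant, a few percent N and O, traces of S and Ca; coordinates
uniform in a 12 Å box with a 1.0 Å minimum separation; simple bond chains
with randomized orders for `EX` coverage) and assign charges *from the EEM
model itself* under a fixed ground-truth parameter set (an `E` table with
$A \in [2,6]$, $B \in [4,10]$, $k^* = 0.4$), with total charges drawn from
$\{-1, 0, +1\}$ and optional i.i.d. Gaussian noise emulating
reference-method discrepancy. Forward generation is the only choice that
preserves a recoverable ground truth: the calibration pipeline must return
exactly $k^*$ and the true $(A,B)$ from noiseless records, and the test
suite requires recovery to $10^{-6}$.

One subtlety: the per-molecule target recorded with each forward record is
the *solved* equalized $\bar\chi$, not the harmonic-mean approximation.
With the harmonic target each molecule's regression rows would carry a
constant offset (harmonic minus solved $\bar\chi$), and exact recovery
would be impossible — the offset is precisely the approximation error that
real calibrations absorb into their fitted parameters.
`forward_reference(..., chi_bar = "harmonic")` reproduces that regime for
anyone who wants to study it.

What the generator does **not** emulate: realistic covalent geometry,
chemically sensible bond orders, charge physics beyond the EEM functional
form, or systematic (non-Gaussian) reference-method error. Passing the
recovery tests therefore demonstrates the correctness of the fitting
machinery, not the real-data accuracy of any calibrated parameter set.

### Constructing a recoverable charge-transfer ground truth

For end-to-end profiling tests a conformer pair with a *known* answer is
needed. Rigidly displacing one residue of a random cluster by 1–2 Å is not
sufficient: the moved residue's net charge change suffers internal
cancellation, and its nearest neighbour absorbs most of the compensating
charge, so the moved residue carries the largest $\Delta Q_{res}$ in only
roughly two thirds of random geometries. `make_release_pair()` instead
emulates an activation-type segment release: a homo-elemental probe
residue sits 5 Å off the surface of a mixed 25-atom core and the active
conformer displaces it 10 Å outward. The probe couples to the whole core
rather than to a single neighbour, and its electronegativity contrast
with the core drives a coherent net transfer on decoupling, so the probe
residue carries the maximal $\Delta Q_{res}$ and the flag by construction
— verified across independent seeds in the test suite.

## Numerical and interface choices

* **Solver**: base LAPACK `solve()`; the contract is the residual bound,
  not the algorithm. A condition estimate above $10^{10}$ warns; only a
  numerically singular matrix fails.
* **Multi-model (NMR) files**: the first model by default, any model by
  index — which ensemble member to use is a scientific choice the caller
  owns.
* **Hydrogens**: charge calculation on structures containing amino acids
  refuses to run without them. Reference charge sets are all-atom; a
  heavy-atom-only solve would silently produce incomparable charges. No
  hydrogen placement is attempted — that is a structure-preparation task
  for dedicated tools.
* **Alternate locations**: highest occupancy wins, ties to file order.
* **Total charge $Q$**: defaults to conventional formal charges at neutral
  pH (Asp/Glu −1, Lys/Arg +1, His 0, charged free termini, Ca²⁺ +2),
  always overridable — and logged — wherever $Q$ is consumed.
* **On-disk formats**: plain text throughout (PDB via `bio3d`; TSV charge
  tables with 0-based atom indices and ≥ 6 decimals; a key-value parameter
  format exact to 9 decimals on round-trip; a manifest-based reference-set
  directory layout).

## Problem sizes

The shipped tests and the acceptance script run, by choice, at desk scale:
reference sets of 20 molecules of 25–35 atoms for calibration recovery,
100 molecules of up to 6 atoms for the dense-solve cross-check, a 50-atom
molecule for the equalization spread, and 30-atom conformer pairs for
profiling. The machinery itself has no size-specific code paths; solving a
full protein is the same call with a larger $n$.

## Known limitations

* Parameter sets calibrated on synthetic records are *not* transferable to
  real proteins; they validate the pipeline, nothing more. Calibrating a
  usable model requires real reference charges via the documented
  reference-set layout.
* Bond perception covers standard amino acids, waters, ions, termini,
  peptide and disulfide links; other ligands fall back to distance-based
  single bonds, which degrades `EX` (not `E`) typing for them.
* The PDB reader does not parse mmCIF, and CONECT records are ignored —
  bonds are always re-perceived from residue identity and geometry.
* Formal-charge defaults assume neutral pH and ignore pKa shifts; unusual
  protonation states must be supplied as explicit $Q$ overrides.
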