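# eemr — electronegativity equalization charges for protein structures

Partial atomic charges determine how a protein's electrostatics respond to
conformational change, but quantum-chemical charges are unaffordable at
protein scale. `eemr` implements the **electronegativity equalization
method (EEM)**, an empirical scheme that recovers geometry-dependent
charges from a single linear solve, for people who want to

* compute per-atom charges for all-atom protein structures (PDB input),
* calibrate their own EEM parameter sets against reference charges
  (e.g. quantum-chemical Mulliken charges for molecular fragments), and
* quantify **per-residue charge transfer between two conformations** of
  the same protein — the inactive-vs-active comparison that exposes
  charge-based allosteric signalling.

## The model

Electronegativity equalization states that electron density flows until
every atom's electronegativity reaches the common molecular value χ̄.
With each atom's electronegativity modelled as

    χ_i = A_i + B_i q_i + k Σ_{j≠i} q_j / R_ij ,

(A_i, B_i per atom *type*, k a dimensionless electrostatic scaling
factor, R_ij in Å, q in e), setting χ_i = χ̄ for all atoms and imposing
Σ q_i = Q gives an (n+1)×(n+1) linear system in (q_1 … q_n, χ̄), solved
directly by Gaussian elimination. Calibration rearranges the same
equation, per atom, into the line y = A + B·x with x = q_i and
y = χ̄ − k Σ q_j/R_ij, fits each atom type by ordinary least squares,
grid-searches k, and selects the model with the best internal R_avg
(mean per-molecule squared Pearson correlation against the reference
charges). Atom types come in two granularities: `E` (element) and `EX`
(element + maximum incident bond order, e.g. carbonyl `O2` vs hydroxyl
`O1`).

Profiling two conformations reports, per residue, the net transfer
ΔQ_res = |Σq(active) − Σq(inactive)| and the intra-residue redistribution
RMSD_res over name-matched atoms, flagging residues more than one
standard deviation above the average. See the methods vignette
(`vignettes/eem-methods.Rmd`) for assumptions, conventions and numerical
choices.

## Worked example

Calibrate against a synthetic reference set generated from a known
forward model (ground truth k\* = 0.4, noise 0.01 e), then profile a
constructed conformational change:

```r
library(eemr)

spec <- fixture_spec(n_molecules = 12, seed = 7, noise_sigma = 0.01)
mols <- make_molecules(spec)
recs <- forward_reference(mols, spec$true_params,
                          noise_sigma = spec$noise_sigma, seed = 7)
fit  <- eem_calibrate(recs, scheme = "E")
fit
#> EEM model fit (scheme 'E')
#>   molecules: 12, atom types: 6
#>   selected k = 0.4 (internal R_avg = 0.985007)
round(coef(fit), 3)
#>        A     B
#> H  2.569 7.934
#> C  3.000 6.301
#> N  3.734 6.943
#> O  4.242 7.617
#> S  3.213 5.133
#> Ca 2.287 4.024
```

The grid search recovers the generating k exactly and the fitted (A, B)
sit close to the truth (H: 2.5/9.0, C: 3.0/6.5, …) despite the added
noise; internal R_avg ≈ 0.985 summarizes how well re-solved EEM charges
reproduce the references. Now a conformer pair in which one peripheral
residue releases from the core:

```r
pair <- make_release_pair(seed = 11)
prof <- profile_report(pair$a, pair$b, fit, Q_a = 0, Q_b = 0)
prof
#> Per-residue charge-transfer profile: 6 residues
#>   delta_q: mean 0.002502, sd 0.002326, threshold 0.004828 e
#>   rmsd_q : mean 0.000591, sd 0.000446, threshold 0.001037 e
#>   flagged residues (descending delta_q):
#>  chain resno icode resname     delta_q direction    rmsd_q n_common sig_dq sig_rmsd
#>      A     6           SYN 0.007507358         1 0.0015047        5   TRUE     TRUE
```

Residue 6 is the released probe: it gains ~0.0075 e net
(direction `+1` = more positive in the active conformer), exceeds the
mean + 1 SD flagging threshold on both statistics, and every other
residue stays below threshold — the constructed charge transfer is
recovered. For real structures, replace the synthetic molecules with
`read_pdb()` + `perceive_bonds()` and a parameter file calibrated on
quantum-chemical reference charges.

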