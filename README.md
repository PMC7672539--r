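# EnsembleModes

Comparative analysis of protein conformational ensembles across functional
states, for structural biologists studying dynamic allostery: situations
where ligand binding or truncation of an allosteric modulator redistributes
a conformational equilibrium rather than switching a single structure. The
motivating design is the four-state study free/complex × full-length/
truncated (`ff`, `fd`, `cf`, `cd`) familiar from PDZ-domain work, but every
stage is generic over multi-model ensembles.

## What it computes

Given multi-model PDB ensembles per state, the package provides:

* **S2 order-parameter validation.** Back-calculation from coordinates,
  `S² = (3/2)[⟨μx²⟩² + ⟨μy²⟩² + ⟨μz²⟩² + 2⟨μxμy⟩² + 2⟨μxμz⟩² + 2⟨μyμz⟩²] − 1/2`,
  for backbone N–H and side-chain methyl-axis vectors, with per-class
  Pearson correlation and RMSD against experimental tables.
* **Conformational entropy.** Quasi-harmonic and Schlitter estimators on
  the mass-weighted coordinate covariance,
  `S = (k_B/2) ln det[1 + (k_B T e²/ħ²) M^{1/2} σ M^{1/2}]`,
  and the binding-entropy ratio `(S_cd − S_fd)/(S_cf − S_ff)` with a
  convergence trace over growing ensemble prefixes.
* **Combined-ensemble PCA.** Pooled-state principal components on Cα
  coordinates after iterative mean superposition; threshold-0 partition of
  conformers into open/closed (mode 1) and narrow/wide (mode 2) states;
  occupancies per ensemble and per replica; co-occurrence; projection of
  external structures; subspace overlap (RMSIP) between mode sets.
* **Discriminative contacts.** Residue-pair contact areas per conformer
  (soft-sphere overlap by default, or imported tessellation output); a pair
  discriminates two states when `|mean_A − mean_B| > sd_A + sd_B`; the
  selected contacts form a network analysed for components and Brandes
  betweenness.
* **Core mapping.** Pivot-based concatenation of multiple structure
  alignments, extraction of the common ungapped core with consensus
  numbering, and rewriting of ensembles to core-only Cα for cross-domain
  PCA.
* **Synthetic reference study.** A generator planting two collective modes
  with designed state occupancies, cone-rim bond-vector wobble with
  analytic S2, covariance scalings giving a designed entropy ratio (4.0 by
  default), and a planted contact change — the ground truth for the whole
  test suite.

## Worked example

```r
library(EnsembleModes)

study <- generateStudy(syntheticSpec(seed = 1))   # 4 states x 808 conformers

fit <- fitEnsemble(study$ensembles$ff, atomSelection(atomNames = c("N", "CA")))
cc <- correlateS2(backCalculateS2(fit), study$observedS2)
ber <- bindingEntropyRatio(study$ensembles, schedule = c(0.25, 0.5, 1))
ms <- combinedPCA(unname(study$ensembles))
part <- partitionStates(ms)
areas <- lapply(study$ensembles, contactAreas, models = seq(1, 808, 4))
net <- buildContactNetwork(discriminativeContacts(contactStatistics(areas)))
```

which prints (abridged):

```
backbone r = 0.992 (n = 64), sidechain r = 0.985 (n = 21)

BindingEntropyRatio (schlitter, 300 K)
  S_ff=9113.7 S_fd=10650.3 S_cf=8415.6 S_cd=7771.8 J/mol/K
  (S_cd - S_fd)/(S_cf - S_ff) = 4.123

StatePartition (thresholds 0, 0 A)
 ensemble  frac_open frac_narrow coOccurrence
       ff 0.95049505   0.3094059    0.6757426
       fd 0.49381188   0.7029703    0.5037129
       cf 0.08292079   0.2995050    0.6670792
       cd 0.08292079   0.6856436    0.6497525

ContactNetwork: 3 residues, 2 contacts; 1 component(s) of size 3
  residues with nonzero betweenness: 1
```

Reading this: the ensembles reproduce the (synthetic) experimental order
parameters (r ≈ 0.99); the truncated construct loses ≈ 4.1 times more
conformational entropy upon binding than the full-length one (the study was
designed at 4.0); the bound states sit almost entirely on the closed side
of mode 1 (open fraction 0.08) while the free full-length state is open
(0.95) and the free truncated state is balanced (0.49), matching the
planted occupancies 0.10/0.95/0.50 within sampling error; and the planted
side-chain contact change is recovered as a discriminative contact. Mode
orientation follows the package's reference convention (bound states on the
non-positive side), so the printed `frac_narrow` column is reported along
the recovered axis — compare it with designed values after orienting along
the planted mode, as `scripts/acceptance.R` does.

`runStudy(studyConfig(seed = 1))` performs all of the above in one call and
writes a machine-readable JSON report; `inst/scripts/run_study.R` wraps it
for the shell.

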