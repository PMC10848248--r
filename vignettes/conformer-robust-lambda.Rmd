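---
title: "Conformer-robust reorganization-energy prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer-robust reorganization-energy prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The quantity and the four-point estimate

The internal reorganization energy λ of self-exchange electron transfer is
the energy cost of the geometric relaxation that accompanies adding or
removing an electron. `reorglam` works with the hole-transport case: the
neutral molecule and its radical cation. Writing `E^s_g` for the total
energy of redox state `s` at the optimized geometry of state `g`, the
four-point estimate is

λ = (E⁺_neutral − E⁺_cation) + (E⁰_cation − E⁰_neutral),

the sum of the cation's relaxation from the neutral geometry and the
neutral's relaxation from the cation geometry. Algebraically this equals
vIP − vEA, the vertical ionization potential at the neutral geometry minus
the vertical electron affinity of the cation at the cation geometry.
`four_point_lambda()` implements the sum of relaxation terms and the test
suite enforces the identity with `vertical_ip() − vertical_ea()` to 1e-12 on
10⁵ random quadruples; `gen_energy_quadruple()` provides the analytic
harmonic oracle (two displaced parabolas of equal curvature k and
displacement d give λ = k d² exactly). Negative predicted λ is physically
impossible for true surfaces but can arise from regression models; it is
reported with a warning and never clipped, because it is a useful diagnostic
of poor generalization.

## Why encoder symmetry matters

A screening pipeline can afford only distance-geometry conformers
(RDKit's ETKDG family), which differ from DFT minima mostly by rotations
about single bonds. If the target λ is treated as a per-molecule property —
one value regardless of conformer — then a good surrogate should map all
cheap conformers of a molecule to the same prediction. The package
implements three encoders that bracket the design space:

* **`bond_invariant_3d`.** Geometry enters only through quantities that a
  bond rotation cannot change: radial-basis-expanded bond lengths on the
  edges, per-atom bend-angle summaries (Σcos θ, Σsin θ, Σcos 2θ, count over
  the triples centered at the atom), and per-rotatable-bond torsion
  statistics. For the torsion group {ψ₁…ψ_m} of one rotatable bond (all 1–4
  dihedral paths through it), the statistics are
  s_k = ((Σ cos kψ)² + (Σ sin kψ)²)/m² for harmonics k = 1…K plus the group
  size m. Each s_k is the mean of cos(k(ψ_i − ψ_j)) over ordered pairs, so a
  common shift ψ → ψ + δ — which is exactly what rotating the bond does to
  its group, and only to its group — cancels identically. The statistics are
  also invariant to path enumeration order and to reversing the bond
  direction (cosine is even), which the permutation-invariance tests
  exercise. This realizes the bond-rotation-invariance *contract* of
  torsion-aware invariant architectures without committing to any particular
  learned torsion parameterization; the contract, not the parameterization,
  is what the package's comparisons exercise, and the aggregation is
  deliberately replaceable.
* **`distance_3d`.** Continuous-filter convolutions over all atom pairs
  within a cutoff: messages are weighted by a filter network applied to the
  radial-basis expansion of the interatomic distance. Distances are
  invariant to rigid motions, so the embedding is too; but rotating a bond
  changes 1-4-and-beyond distances across it, so the embedding is
  generically bond-rotation sensitive. Pairs beyond the cutoff contribute
  nothing by construction.
* **`graph_2d`.** Message passing over the attributed 2D graph only; the
  embedding is bitwise-identical for every conformer of a molecule.

All three use sum aggregation over atoms and edges, hence are invariant to
atom relabeling, and share one readout so that comparisons isolate the
encoder's symmetry class.

## Training design: fixed random encoders, trained head

The trainable component is a 2-layer perceptron head on top of
encoder embeddings whose weights are drawn once from the config's
`init_seed` and then held fixed (graph random features). This choice keeps
every symmetry statement about the encoders exact at all times — invariances
are properties of the architecture, not of a training trajectory — makes the
5-repeat protocol cheap enough to run inside a test suite, and still leaves
the quantity of scientific interest (how encoder symmetry interacts with
cheap-conformer noise) fully exposed: the head sees exactly the information
the encoder's symmetry class admits. Embeddings are standardized on the
training split before the head; targets are left in eV. The head is trained
with Adam on a mean-squared-error loss, minibatch size 32, early stopping on
validation MAE with patience 20 (defaults), returning the best-validation
checkpoint. Non-finite gradients abort with a diagnostic; the default
starting learning rate is 1e-3, lowered to 1e-4 for `distance_3d`, the
family whose loss surface on raw distance-geometry inputs is most prone to
divergence.

## Protocol

Splits are by molecule id — conformers of one molecule share a target, so
per-conformer splitting would leak — with a fixed 10% test set and repeated
8:1 train/validation re-splits of the remainder (5 repeats by default), all
deterministic in one master seed. Training uses 5 distance-geometry
conformers per molecule, every one carrying the molecule's single target;
`train_model()` rejects datasets violating that precondition. Evaluation
averages a model's predictions over a molecule's conformers (the deployment
scheme) or scores each conformer independently, selectable by a flag since
either convention is defensible; MAE, RMSE and R² = 1 − SS_res/SS_tot are
reported (the coefficient of determination, which can be negative, not
squared Pearson). `ensemble_predict()` averages members of the split
repeats. `conformer_robustness()` re-embeds molecules and reports the
population variance (divide by n) of predictions per molecule; summaries
give both meV² variance and the meV standard deviation, since variance-like
diagnostics at meV scale are quoted ambiguously in the field.

## The synthetic benchmark

The fixture generator assembles valence-correct C/N/O/F molecules of up to 9
heavy atoms (random trees with branches, one optional 5/6-ring, double/
triple-bond promotion; ring-cycle edges may only become double bonds since a
triple bond cannot sit in a small ring). Sizes are weighted toward the cap,
as enumerated chemical spaces are, which also keeps the canonical-SMILES
duplicate rate near 5% so deduplication does not shift summary statistics
with set size. Labels are a fixed, versioned function of graph invariants
(rotatable bonds, heteroatoms, rings, multiple bonds, size) squashed through
a logistic bounded at 2.94 eV — the maximum the target reaches on QM9-scale
sets — yielding a right-skewed distribution with mean ≈ 1.2 eV; vIP is
generated in the 8–10 eV regime of small organics and vEA is derived so
vIP − vEA = λ holds exactly. Labels are therefore exactly conformer-
invariant ("graph-determined"); an optional torsion-noise mode perturbs
per-conformer pseudo-labels while leaving the molecule-level target alone.

What the benchmark emulates: per-molecule λ targets shared across cheap
conformers, realistic conformational variability from true ETKDG
embeddings, and a learnable structure–property relationship. What it does
not: quantum-chemical labels have 3D signal that graph-determined labels
lack, so here the 2D encoder is the theoretical optimum and 3D encoders are
penalized exactly by their conformer sensitivity. Passing the benchmark
shows the symmetry ordering (invariant ≪ distance-sensitive in conformer
variance, invariant < distance-sensitive in test error) — the desk-scale
analogue of the full-scale finding — not absolute accuracies on real λ data,
and the full ordering among all three encoders on DFT-labeled data is
deliberately not asserted.

A note on statistical resolution: the stability check on the generator
compares summary statistics at n = 1000 versus n = 2000. The mean and
maximum are held to 2%; the standard deviation estimator itself carries
sampling error ≈ 1/√(2n) (about 2% at n = 1000), so it is checked at its
2-sigma band (4%) — a tighter assertion would test the luck of a seed, not a
property of the generator.

## Numerical choices

* Units: eV and Ångström everywhere; torsions in radians, IUPAC sign
  convention, values in (−π, π]. 1 hartree = 27.211386 eV at ingest.
* Rotatable bond: single, acyclic, both endpoints heavy with heavy-atom
  degree ≥ 2 (hydrogens never make a bond terminal). Hydrogen-terminated 1–4
  paths are included in torsion groups by default (`include_hydrogen_torsions`),
  since every such path shifts coherently under the bond rotation; a
  heavy-atom-only mode is available.
* `rotate_bond()` moves the smaller side of the bond, ties broken toward the
  side containing the lower minimum atom index, so the operator is
  deterministic.
* Collinear bend angles are clamped into (ε, π − ε) with ε = 1e-6 rad — a
  numerical guard for downstream trigonometry, not a chemical statement.
* Distance encoder defaults: 10 Å cutoff, 50 radial basis centers on
  [0, cutoff] with width 1/Δ², 3 interaction blocks — conventional published
  defaults for this architecture family. Bond-length basis: 8 centers on
  [0.8, 2.0] Å. Torsion harmonics: K = 3.
* Conformer embedding retries: 6 seeds (seed + 1000k) with small-ring
  torsion terms, then 6 without, because the small-ring torsion minimizer
  can abort on some fluorinated rings; failures after that are loud errors
  carrying the molecule id — molecules are never silently dropped.
* Conformer aggregation is an unweighted arithmetic mean; Boltzmann
  weighting is deliberately omitted because distance-geometry conformers
  carry no energies.

## Problem sizes used by the tests

The test suite runs the invariance sweep on 50 generated molecules × 10
random (bond, δ) rotations per encoder; the encoder comparison on 1000
molecules (100-molecule test set, 5 training conformers per molecule,
hidden width 48, 2 message-passing layers, ≤ 80 epochs) across 5 master
seeds; and the ensembling comparison on 300 molecules across 10 seeds with
5 split repeats each. These sizes were chosen as the smallest at which the
qualitative orderings are stable from seed to seed.

## Known limitations

* Cation conformers are embedded from the neutral connectivity — distance
  geometry has no charge awareness. This matches the cheap-geometry
  screening setting, where no radical-cation embeddings exist, and is the
  reason the direct-λ scheme exists.
* Encoder weights are not trained end to end; absolute accuracies are
  therefore not comparable to fully trained graph networks, only the
  symmetry-driven orderings are.
* Chirality is not encoded: the torsion statistics are invariant under
  mirror reflection. QM9-scale λ regression does not exercise chirality, but
  applications that need it would have to extend the torsion aggregation.
* The synthetic labels contain no 3D signal by construction (see above); the
  torsion-noise mode exists to create one when needed.
* External (outer-sphere) reorganization energy, Marcus rate constants, and
  the electron-transport (anion) case are out of scope.
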