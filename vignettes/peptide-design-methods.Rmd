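---
title: "Peptide design from per-grid docking energies: model and methods"
author: "pepdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide design from per-grid docking energies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdesign)
```

## The model

`pepdesign` treats a candidate peptide along a binding path as a
heterogeneous Markov chain. The hidden state at grid t is the amino-acid
identity of residue t; the observation at grid t is the Ramachandran
torsion state of the docked candidate. Three layers feed the decoder.

### Binding energies to chain statistics

The inputs are 20 single-residue binding energies for the first grid box
and one 20 × 20 dipeptide energy matrix per consecutive grid pair, in
kcal/mol. Each energy E becomes a rotational-isomeric-state statistical
weight u = exp(−E / k~B~T). The chain partition function is the transfer
product Z = J\* U^(1)^ ⋯ U^(n−1)^ J with J\* a row of ones — every residue
is admitted as the first — and J a column of ones. The joint probability of
residues (i, j) at grids (t, t+1) is the ratio of the same product with
U^(t)^ reduced to its (i, j) element alone; `pair_marginals()` evaluates
this with prefix/suffix transfer vectors, which is algebraically identical
but costs one sweep instead of 400 per grid. Conditional transitions
a^(t)^(j | i) are row-renormalized pair marginals. First-grid probabilities
are the Boltzmann softmax of the first-grid energies.

Two modelling choices here were genuinely open and are worth recording:

- **Where the first-grid energies enter.** The partition function and the
  pair marginals are built from the pair matrices only; first-grid energies
  enter solely through the initialization of the decoder. This keeps the
  two energy sets in the distinct roles they play in the algorithm
  (single-residue affinity seeds the first grid; dipeptide affinities drive
  every transition) and avoids double-counting residue 1. For sensitivity
  analysis, `fold_first_grid = TRUE` folds the first-grid weights into the
  transfer product as a diagonal prefactor.
- **Conditional vs. joint transitions.** The decoder scores steps with the
  conditional a(j | i) by default, which is the standard hidden-Markov
  transition and makes the per-step breakdown interpretable as
  log-probabilities. `transition_mode = "joint"` scores with the pair
  marginal itself; on a fixed instance both modes decode an optimum of a
  well-defined objective (the enumeration tests cover both), they simply
  weight the path ends differently.

### Torsion states and emissions

Backbone dihedral pairs are classified into eleven states of the
Ramachandran map — ε′, ε, α_R, γ, δ_R, δ_L, ζ, γ′, α_L, β_s, β_p, numbered
1–11 in that order. Published maps of these basins are graphical, not
numeric, so the region geometry is data: an editable set of axis-aligned
rectangles (`read_regions()` / `write_regions()`, default shipped in
`inst/extdata/regions_default.yaml`). The default rectangles reproduce the
standard taxonomy; each contains its canonical anchor (α_R at (−63, −43),
α_L at (57, 47), and so on), they are pairwise disjoint, and the ε basin is
two rectangles so that it is contiguous across the ψ = ±180° seam. Angles
are canonically wrapped to (−180, 180], but membership is evaluated on the
torus, so classification is exactly invariant under ±360° shifts of either
angle. Points between basins — strained conformations — classify to `NA`.

Emission tables come from a coil library, the appropriate prior for the
unfolded state of a short peptide: a 20 × 11 singlet table of
P(state m | residue i) from (φ_t, ψ_t) observations, and a 20 × 20 × 11
pair table of P(state m | residues i, j) from (ψ_t, φ_t+1) observations,
classified with the same region set. The emission probability of a docked
dipeptide candidate is the product of its singlet and pair factors. The
singlet factor is indexed by the residue at grid t by default
(`singlet_index = "i"`); indexing by the following residue is a switch,
since either reading is defensible — on state-uniform emission tables the
two coincide.

### Viterbi decoding

All decoding arithmetic is in the log domain: with emission floors of
10^−4^ and chains of realistic length, linear-domain products underflow
quickly, and with pair energies near −13 kcal/mol the linear transfer
product itself approaches double-precision overflow (which is why the
weight chain is stored as logs and reduced by log-sum-exp). The forward
pass stores backpointers, so memory is O(n·20) and time O(n·20²). Ties in
the induction maximum are broken toward the lowest index in the canonical
20-letter alphabet (alphabetical by one-letter code, the same frozen order
used by every table in the package), and the tie rule is echoed in the
result so runs are reproducible.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `temperature_K` | 298.15 | K | Boltzmann scale of the weights |
| `kB` | 0.0019872 | kcal/(mol·K) | molar gas constant, matching kcal/mol energies |
| `pseudocount` | 0.5 | counts/state | additive smoothing when building emission tables |
| `floor` | 10^−4^ | probability | substituted for unclassified torsion observations |
| `transition_mode` | "conditional" | — | a(j\|i) vs. joint pair marginal |
| `singlet_index` | "i" | — | which residue indexes the singlet emission factor |

The temperature and k~B~ defaults are the physiological-scale convention
for docking scores reported per mole; neither is printed with the energies,
so both are explicit arguments. The pseudocount default keeps sparse
libraries away from hard-zero emissions; set it to 0 to reproduce raw
frequencies (residues present in the library but with only unclassified
records then raise an error, and residues absent from the library get
`NaN` rows rather than invented probabilities). The floor implements the
view that a single strained docked pose should attenuate, not veto, a
candidate; `floor = 0` restores the veto.

## The synthetic-data generator

`synthkit` functions are pure functions of a spec and a single integer
seed; each generator draws from its own named stream (a fixed per-generator
offset), so adding a generator never perturbs existing fixtures.

- `synth_energy_tables()` plants a chosen sequence `margin` kcal/mol below
  a flat background (default base −5 kcal/mol, the scale of the docking
  scores the model consumes; margin 1; Gaussian cell noise of SD 0.1
  truncated at ±margin/2 so the planted path stays strictly dominant
  cell-by-cell). `margin > 4·noise_sd` is a documented sufficient condition
  for recovery under neutral emissions, verified over 50 seeds.
- `synth_torsion_library()` draws torsion-state labels from a target
  categorical distribution per residue (and per pair), then places each
  record uniformly inside the chosen region rectangle, so built tables
  converge to the target as records grow.
- `synth_observations()` assigns candidate states directly (`uniform`
  neutralizes emissions for energy-only tests; `adversarial` penalizes the
  planted path); `synth_observation_angles()` generates actual angles,
  respecting the geometric coupling that ψ_t is shared between the two
  observation planes — a constraint with a visible consequence: a ψ_t that
  no region's φ-arc covers makes the pair-plane observation unclassified,
  exactly as strained docked poses do.

What the generator does **not** emulate: real docking-score landscapes
(correlated energies, multi-modal run ensembles), residue-specific region
shapes, sequence-dependent coil propensities of real proteins, or
structural noise in docked coordinates. Passing tests therefore certify
the statistics and the decoding — that the implementation computes the
model exactly — not that the model's designs bind real proteins; that
validation requires docking the decoded peptides, which is outside the
package.

## Numerical choices and degenerate inputs

- Transfer products, partition function and Viterbi scores: log domain
  with log-sum-exp reduction; left-to-right and right-to-left evaluations
  agree to relative 10^−12^ in the tests.
- Probabilities are invariant (≤ 10^−12^) under adding any constant to a
  grid's energies, as the Boltzmann construction requires.
- Emission/transition zeros become −∞ scores; a grid into which no path
  has finite score raises a degenerate-model error naming the grid.
- Dihedrals follow the standard signed convention (checked against an
  independent structural-biology implementation); three collinear points
  raise an undefined-dihedral error instead of returning an arbitrary
  angle. Alternate-location Cα records are resolved by highest occupancy,
  ties to the first record.
- Grid boxes use the 2.5 × (N-to-terminal-C span) edge rule, with a
  `"max"` policy that sizes every box to the largest candidate when one
  box must fit all candidates during screening. Whether grid centers come
  from a docked probe peptide or from a partner protein's interface Cα
  atoms is case-dependent, so `extract_ca_path()` serves both.

## Problem sizes used in the tests

Exhaustive-enumeration oracles run over all 20³ = 8,000 tripeptide and
20⁴ = 160,000 tetrapeptide sequences on seeded random instances, and over
alphabet sizes 2–3 up to n = 5 for the chain marginals; planted-recovery
runs use n = 4 at margin 1 kcal/mol over 50 seeds; table-recovery uses
1,000 records per cell on a 4-residue sub-alphabet; geometry properties use
50 random rigid motions and torsion targets. These sizes make the whole
suite run in well under a minute while keeping every check exact or
Monte-Carlo-tight.

## Known limitations

- The package consumes docking energies; it never runs a docking program
  (a directory of result logs or a TSV is the interface).
- One region set is used irrespective of residue type, and regions are
  axis-aligned rectangles; published basin outlines are curved.
- The decoder returns the single best sequence; k-best and posterior
  decoding are deliberately out of scope, as is a D-amino-acid alphabet.
- The coil-library prior assumes the bound peptide samples unfolded-state
  torsion statistics; strongly structured binders violate that prior.
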