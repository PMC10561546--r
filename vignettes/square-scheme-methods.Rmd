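---
title: "Square-scheme thermodynamics and surrogate models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Square-scheme thermodynamics and surrogate models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squarescheme)
```

## The model

A quinone-type molecule QH~2~ exchanging two protons and two electrons,

$$\mathrm{QH_2 \rightleftharpoons Q + 2H^+ + 2e^-},$$

visits nine protonation/charge states on a 3×3 lattice: columns count
electrons removed, rows protons removed, and `index = 3 p + e` runs from
0 (QH~2~) to 8 (Q). The sixteen reaction edges of this lattice are six
pure electron transfers (ET, horizontal), six pure proton transfers
(PT, vertical) and four concerted proton–electron transfers (PET,
diagonal). Given an aqueous Gibbs free energy per state, every edge
observable follows from three relations:

1. **PET (computational SHE).** For `red -> ox + H+ + e-`,
   $\Delta G_\mathrm{PET} = G(\mathrm{ox}) + \tfrac12 G(\mathrm{H_2,gas})
   - G(\mathrm{red})$. Referencing each released H^+^/e^−^ pair to half
   a gas-phase H~2~ *is* the standard-hydrogen-electrode reference; no
   absolute-potential constant (such as 4.44 V) is added. The standard
   potential is $E^0 = \Delta G_\mathrm{PET} / F$. The free energies are
   written for the oxidation direction; by the IUPAC convention the
   reported values are reduction potentials of the same couples.
2. **PT (isodesmic pKa).** $\Delta G_\mathrm{PT} = G(\mathrm{base}) +
   G(\mathrm{H^+,aq}) - G(\mathrm{acid})$ and
   $\mathrm{p}K_a = \Delta G_\mathrm{PT} / (RT\ln 10)$. The aqueous
   proton energy is never computed directly: it is calibrated so that a
   reference acid (formic acid, experimental pKa 3.77) is reproduced
   exactly, cancelling systematic solvation errors. Raw pKa values are
   then mapped to the reporting scale by the empirical correction
   $\mathrm{p}K_a^\mathrm{scaled} = 0.49\,\mathrm{p}K_a + 3.2$, which
   compensates the implicit-solvation bias of the underlying
   electronic-structure protocol.
3. **ET (cycle closure).** $\Delta G_\mathrm{ET} = \Delta G_\mathrm{PET}
   - RT\ln 10 \cdot \mathrm{p}K_a^\mathrm{scaled}$, and
   $E_\mathrm{red} = \Delta G_\mathrm{ET}/F$.

All energies are converted from Hartree to kJ/mol once, at ingestion
(factor 2625.4996); observables are carried at full precision and
rounded to three decimals only when serialized, matching the database
convention.

### Which PET edge defines which ET edge

The empirical pKa scaling is a *per-edge* correction, so no single set
of nine corrected free energies reproduces every scaled PT edge at
once; consequently the ET decomposition must name its legs. Each ET
edge in the top two proton rows uses the PET edge leaving its own
reactant (ET01 from PET04/PT14, ET12 from PET15/PT25, ET34 from
PET37/PT47, ET45 from PET48/PT58). The fully deprotonated row has no
outgoing PET, so ET67 and ET78 use the PET arriving at their product
(PET37/PT36 and PET48/PT47). With this pairing the Hess closure
$|\Delta G_\mathrm{PET} - \Delta G_\mathrm{ET} -
\Delta G^\mathrm{scaled}_\mathrm{PT}| < 10^{-9}$ holds for every
decomposition the construction defines — PET37 and PET48 close through
both an ET-first and a PT-first path — and partial schemes degrade
gracefully: an ET edge whose completing legs are absent is omitted
with a warning, never an error.

## pH–potential speciation

`nernst_potential()` shifts a standard potential by
$-(RT\ln 10/F)(n_p/n_e)$ per pH unit (0.0592 V at 298.15 K, the
default temperature; "room temperature" reproduces the printed
−0.059 V/pH). `overall_two_electron_potential()` combines the two
main-diagonal PET steps. Its default is the free-energy-consistent
mean $(E^0_{04} + E^0_{48})/2$, for which $2F\,E$ equals the summed
reaction free energy and whose Nernst slope for $n_p=n_e=2$ is
−0.0592 V/pH; a literal-sum mode is kept behind `mode = "sum"` because
the source relation is printed as a sum. The two modes differ by a
factor of two on a symmetric couple; the worked example below behaves
like a potential on the single-couple scale, which is why the mean is
the default.

Predominance diagrams are built by grand-potential minimization over
all nine states rather than by pairwise couples: state *i* is charged
$\mu_H = G(\mathrm{H^+}) - RT\ln10\cdot\mathrm{pH}$ per attached
proton and $\mu_e = \tfrac12 G(\mathrm{H_2}) - G(\mathrm{H^+}) - F E$
per attached electron. This reproduces the pairwise picture whenever
one couple dominates and resolves multi-state competition
automatically. The minimization runs on *effective* state energies
reconstructed from the scaled observables — the six scaled PT edges
plus PET04 and PET48 form a spanning tree of the lattice — so that PT
boundaries sit exactly at pH = pKa^scaled^; raw free energies would
misplace them at the unscaled pKa. Boundary lines are analytic:
vertical at pKa^scaled^ for pure proton couples, slope
$-0.0592\,(n_p/n_e)$ V/pH otherwise; their visible extents are traced
numerically. Exact ties (a grid point on a boundary) resolve toward
the deprotonated, then the more oxidized state, consistent with
"deprotonation occurs when pH exceeds pKa".

`classify_reduction_pathway()` walks the two electron additions of the
reduction Q → QH~2~: an electron arrives with a proton (PET) when the
pH lies below the scaled pKa of the protonated product, alone (ET)
otherwise, and a PET product may pick up a further proton (trailing
PT) when its conjugate acid is stable at that pH. A trailing PT can
never directly follow an ET step: the deciding pKa is the same edge
for both choices. Band edges across a pH window are therefore exactly
the scheme's scaled pKa values.

### The anthraquinone worked example

The five potentials printed for the 2,2-propionate ether anthraquinone
example (first/second ET at −0.464/−0.762 V, PET steps at −0.159 and
−0.352 V, overall −0.048 V at pH 0) do not determine all nine free
energies, and are not even mutually consistent under either combination
mode. `example_peaq_scheme()` is therefore an explicitly *synthetic*
reconstruction: it plants the published band-edge acidities
(pKa^scaled^ = 5, 8, 13 for PT47, PT03, PT36), closes the remaining PT
edges below pH 0 (−1, −3, −8, respecting the systematic acidity
ordering), and uses the printed PET potentials. That fixture
reproduces the published band sequence 2PET → ET-PET-PT → ET-PET → 2ET
with edges at pH 5, 8, 13:

```{r}
pathway_bands(example_peaq_scheme())
```

## Synthetic data: the stated world

The generator inverts the relations above instead of sampling free
energies directly: it draws the six scaled pKa values and the PET04 and
PET48 potentials — together a spanning tree of the lattice — and
assigns the nine free energies that reproduce them exactly. PET15,
PET37 and all six ET potentials are then derived, which is what makes
recovery testing meaningful (forward build must return the plants to
<10^−6^). Defaults encode the ranges observed across the full quinone
library: pKa in [−22, 30], E~red~ in [−1.629, 2.426] V, E^0^ in
[−1.222, 2.722] V. With `enforce_trends` the generator honors the two
systematic trends of this chemistry (the second electron donation in a
proton row occurs at lower E~red~; protonation makes reduction more
favorable) and with `order_acidity` the systematic ordering
pKa(PT25) < PT58 < PT14 < PT47 < PT03 < PT36. Under that ordering the
protonation trends hold identically, so the sampler only needs to
condition the two free potentials on linear inequalities; draws are
taken uniformly on the feasible intervals and infeasible pKa draws are
rejected up to a bound. The generator emulates thermodynamic
consistency and range/trend structure — it does *not* emulate DFT
noise, tautomer ambiguity, or the real library's core-by-core
distributions, so a green recovery test establishes correctness of the
algebra, not chemical realism.

The molecule library decorates six quinone-like core templates
(benzo-, naphtho-, anthra-, phenanthrenequinone-like) with one or two
of the nine standard functional groups at marked ring positions,
canonicalizing and deduplicating via RDKit (~4100 distinct molecules).
It is deliberately *not* a reproduction of the published 15-core set,
whose exact substitution sites are graphical; it exists so every
fingerprint and ML test runs without the deposited data.

## Descriptors and surrogate models

Five feature spaces: Descriptor I (net charge, atom count including
hydrogens, molecular weight, cavity volume, plus eight frontier-orbital
energies), II (the eight orbitals), III (the spin-up HOMO alone — the
spin-up channel lies above spin-down for the open-shell oxidation
reactants), IV (the eight product orbitals), and FP (radius-3,
1024-bit, chirality-aware Morgan/ECFP fingerprints with the net charge
appended, 1025 dimensions). Bits are binary; nothing is normalized —
forests are scale-invariant and closed-shell species simply carry
duplicated spin channels. Feature order is frozen between calls as a
training/serving-skew guard.

The forest implements the published regimen: 200 trees, data shuffled
then split 80/20, hyperparameters grid-searched by 10-fold
cross-validated MSE on the training portion, out-of-bag R² always
reported, and the whole assessment repeated five times with the worst
held-out result reported (ties toward higher RMSE). Each repeat
re-searches the grid by default (`share_search` reuses the first
search). The forest itself is the package's own compiled
implementation — no R random-forest package exists in the target
environment — using bagged CART with variance-reduction splits,
per-node feature subsampling (default `sqrt(p)`, the ranger
convention; `"third"` and `"all"` are available and the search grid
spans them), and `min_leaf = 1`. Binary columns are bit-packed so that
fingerprint split search stays cache-resident. Seeds propagate from
one master seed to every shuffle, fold assignment and bootstrap, so
reports are bit-identical across runs.

Feature attributions use TreeSHAP — exact Shapley values of the
per-tree cover-weighted conditional expectation — ported to the
package's tree arrays and validated in the tests against brute-force
subset enumeration; local accuracy (base value plus attributions
equals the prediction) holds to machine precision.

## Numerical choices and edge cases

* Conversion factor 2625.4996 kJ/mol per Hartree; gas constant
  8.314462618 J/mol/K; Faraday constant 96485.33212 C/mol.
* The reference calibration round trip is exact to ~10^−10^ pKa units,
  the cancellation limit of ~500-Hartree totals in doubles; tests
  assert 10^−9^.
* Tree growth stops on `min_leaf`, zero node variance (SSE ≤ 10^−12^),
  or an optional depth cap; splits between tied feature values are
  skipped; thresholds sit at midpoints.
* Boundary-tie tolerance in predominance is 10^−9^ kJ/mol.
* Reaction-table serialization writes three decimals; loaders collect
  invalid rows (missing target, non-integer charge, empty SMILES) into
  an error report instead of failing or silently dropping them.
  Unparsable SMILES quarantine during deduplication so one bad row
  cannot block a large load.
* The loader reports, never enforces, expected record counts (the
  deposit's own printed counts are not perfectly self-consistent).

## Known limitations

* Electronic-structure computation, tautomer ranking, solvation
  modeling and geometry handling beyond XYZ metadata are out of scope;
  free energies are inputs.
* The published Table-1 error metrics require the deposited dataset
  (a Zenodo download) and are therefore documented as optional
  post-download checks — `validate_compbatpet()` implements the count
  and extrema validations — not as desk tests.
* Fingerprint bit positions are hash-dependent; tests freeze a
  bit-count for one reference molecule under the environment's RDKit
  version rather than asserting positions.
* Activities other than H^+^ are taken as unity throughout; no
  activity-coefficient or kinetic corrections.
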