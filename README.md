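# squarescheme

Thermodynamics and machine-learned surrogates for two-proton
two-electron redox chemistry in water.

Aqueous organic redox couples — quinones above all, the workhorses of
redox-flow batteries — interconvert along the square scheme

```
QH2 <-> Q + 2H+ + 2e-
```

whose nine protonation/charge states (indexed `3*protons_removed +
electrons_removed`, 0 = QH2 … 8 = Q) are connected by six electron
transfers (ET), six proton transfers (PT) and four concerted
proton–electron transfers (PET). Given one aqueous Gibbs free energy
per state, the package derives every edge observable:

* **PET:** `dG = G(ox) + G(H2,gas)/2 - G(red)`; the half-H2 reference
  *is* the computational standard hydrogen electrode, and
  `E0 = dG/F` (V vs SHE).
* **PT:** the isodesmic pKa `dG_PT/(RT ln10)`, with `G(H+, aq)`
  calibrated so a reference acid (formic acid, pKa 3.77) is reproduced
  exactly, then corrected to the reporting scale by
  `pKa_scaled = 0.49 pKa + 3.2`.
* **ET:** `dG_ET = dG_PET - RT ln10 * pKa_scaled`, `E_red = dG_ET/F`.

On top of the schemes it builds Pourbaix (pH–potential) predominance
maps with analytic boundaries (slope `-0.0592 (n_p/n_e)` V/pH at
298.15 K), classifies reduction pathways (2PET vs ET-PET-PT vs 2ET …)
per pH band, and trains random-forest surrogates of `E_red`, `pKa`,
and `E0` from either frontier-orbital descriptors or 1025-dimensional
ECFP fingerprint descriptors, following a fixed protocol: 200 trees,
10-fold cross-validated grid search, 80/20 split, worst of five
repeats, with out-of-bag scoring and TreeSHAP attributions. A
synthetic-data module generates thermodynamically consistent schemes,
a quinone-like molecule library, and planted-signal ML datasets so
everything is testable without any external download.

The forest (bagged CART + TreeSHAP) is implemented in the package
(Rcpp); SMILES canonicalization and Morgan fingerprints are delegated
to RDKit through the system `python` (a batched helper is bundled at
`inst/python/rdkit_tools.py`).

## Worked example

The bundled synthetic reconstruction of an anthraquinone couple
(band-edge acidities 5, 8, 13; PET potentials −0.352 and −0.159 V):

```r
library(squarescheme)

s <- example_peaq_scheme()
tidy(s)[, c("name", "kind", "dg_kj_mol", "observable", "unit")]
#> # A tibble: 16 x 5
#>    name  kind  dg_kj_mol observable unit
#>    <chr> <chr>     <dbl>      <dbl> <chr>
#>  1 ET01  ET       -28.3     -0.293  V vs SHE
#>  2 ET12  ET        53.6      0.556  V vs SHE
#>  3 ET34  ET       -97.4     -1.01   V vs SHE
#>  ...
#>  7 PT03  PT        45.7      8.00   pKa
#>  ...
#> 13 PET04 PET      -34.0     -0.352  V vs SHE
#> 16 PET48 PET      -15.3     -0.159  V vs SHE

overall_two_electron_potential(s)      # (E0_PET04 + E0_PET48)/2
#> [1] -0.2555
nernst_potential(-0.048, n_p = 2, n_e = 2, ph = 8)
#> [1] -0.5212748

classify_reduction_pathway(s, ph = 6.5)
#> [1] "ET"  "PET" "PT"
pathway_bands(s)
#> # A tibble: 4 x 4
#>   ph_min ph_max pathway   steps
#>    <dbl>  <dbl> <chr>     <list>
#> 1      0      5 PET-PET   <chr [2]>
#> 2      5      8 ET-PET-PT <chr [3]>
#> 3      8     13 ET-PET    <chr [2]>
#> 4     13     14 ET-ET     <chr [2]>

pm <- pourbaix_boundaries(s)    # grid + analytic boundaries + bands
autoplot(pm)                    # ggplot Pourbaix diagram
```

The pathway bands read: below pH 5 the reduction takes two concerted
PET steps; between 5 and 8 an electron arrives first, then a PET, then
a final protonation; between 8 and 13 the trailing protonation stops;
above 13 both electrons arrive bare.

Surrogate training on synthetic planted data:

```r
d <- generate_ml_dataset(seed = 2024, n = 2000, noise_sd = 0.01,
                         signal_kind = "fingerprint_bits")
rep <- worst_of_repeats(d$features, d$targets,
                        train_config(seed = 99,
                                     grid = tibble::tibble(mtry = "sqrt",
                                                           min_leaf = 1L)))
glance(rep)     # worst-of-5 held-out metrics
#> # A tibble: 1 x 7
#>   r2_train r2_test r2_oob  rmse   mae n_train n_test
#> 1    0.988   0.924  0.935 0.204 0.142    1600    400
shap_importance(rep, d$features[1:50, ])
```

A command-line interface wraps the same functions
(`scheme`, `pourbaix`, `featurize`, `train`, `predict`, `explain`,
`simulate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","squarescheme",package="squarescheme"))')" \
  scheme --input inst/extdata/peaq_states_synthetic.csv \
  --refs inst/extdata/references.json --out-dir out/
```

## Acceptance script

`scripts/acceptance.R` re-derives the package's acceptance quantity
from scratch at run time: it assigns random free energies to a
reference acid, calibrates the aqueous proton free energy against the
experimental pKa by inverting the isodesmic relations, recomputes the
acid's pKa with the calibrated value, and writes the recovered number
as JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Electronic-structure computation (geometry optimization, single
points, solvation, frequencies, tautomer ranking) is out of scope:
free energies are inputs, read from CSV tables. The published
dataset's own error metrics require its Zenodo deposit; the loader
ships count/extrema validations (`validate_compbatpet()`) for use
after an optional download, and the test suite runs entirely on
synthetic data.
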