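# metallomer

Infer a cell's relative **metallome** — the per-metal complement of its
protein-bound trace elements — from its expressed proteome, and compare it
with metal quotas measured directly by ICP-MS.

## The problem

Phytoplankton run photosynthesis, carbon fixation and nitrogen metabolism
on metalloenzymes, but measuring which metals a cell actually *uses* is
hard: ICP-MS gives total cellular metal content (quotas, mmol metal per
mol C) without saying what the metal does, while genome-based
metalloprotein prediction ignores which genes are expressed and how
highly. A middle route is to take the *expressed* proteome from label-free
LC-MS/MS, assign each protein a metal-cofactor stoichiometry by structural
homology, and weight the stoichiometries by protein abundance.

`metallomer` implements that route as a pipeline of small, tidy steps:

1. **Template annotation** (`parse_structure()`, `detect_metal_sites()`,
   `stoichiometry_from_sites()`, `annotate_templates()`): each metal ion
   in a template structure is characterised by its first coordination
   sphere — donor atoms (N, O, S) within a 3.0 Å cutoff. Ions with no
   polymer donor in reach are flagged *adventitious* (buffer/surface ions)
   and excluded, and each retained site is attributed to the chain that
   contributes most of its polymer donors.
2. **Homology transfer** (`filter_matches()`, `transfer_annotations()`):
   fold-recognition matches are kept only at confidence strictly above
   95%, and each query protein inherits the per-chain stoichiometry of
   its best-confidence template.
3. **Quantification** (`read_quant_table()`, `normalize_median()`,
   `normalize_total()`): protein intensities are median-normalised within
   samples for cross-sample tests, and converted to relative abundances
   (fractions of total intensity) for metallome reconstruction. Zeros in
   proteinGroups-style tables are treated as censored, not as measured.
4. **Reconstruction** (`compute_metallome()`): the abundance of metal
   *m* is

   &nbsp;&nbsp;&nbsp;&nbsp;A(m) = Σᵢ pᵢ · sᵢₘ

   over proteins *i*, where pᵢ is relative abundance and sᵢₘ the number
   of ions of metal *m* in protein *i*. Units are arbitrary; only ratios
   and within-profile comparisons are meaningful.
5. **Comparison** (`correlate_metallome()`, `strain_ratio()`,
   `differential_expression()`, `metal_rollup_test()`): Pearson r² between
   log₁₀ quotas and log₁₀ reconstructed abundances; between-strain ratios
   with delta-method SDs; per-protein pooled-variance t-tests (volcano
   plots via `autoplot()`); per-metal replicate-level t-tests.

A coupled synthetic-data generator (`simulate_metallome_study()` and the
`generate_*()` functions) produces structures, match tables, intensity
matrices and quota tables with known ground truth, including free-ion
pools (Ca/Mg/K excess invisible to the proteome) and luxury-uptake
factors (quota excess without a proteome excess).

## Worked example

```r
library(metallomer)
library(dplyr)

# a two-strain study: 300 proteins, triplicates, Fe quota doubled in
# strain OA16 without any proteome change (luxury uptake)
sim <- simulate_metallome_study(n_proteins = 300, seed = 42,
                                luxury = list(OA16 = c(Fe = 2)))

store <- annotate_templates(sim$paths$structures)
ann   <- transfer_annotations(filter_matches(sim$matches), store)

summarize_counts(ann, total_proteins = 300)
#>    category                  n percent fraction
#>  1 total_proteins          300   100     1
#>  2 total_metalloproteins   111    37     0.37
#>  3 Mo                       19     6.3   0.0633
#>  4 Mg                       18     6     0.06
#>  ...

rel     <- normalize_total(sim$quant, by = "sample")
profile <- compute_metallome(rel, ann)

correlate_metallome(filter(sim$quotas, strain == "OA1"),
                    filter(profile, group == "OA1"))
#> Metallome vs quota correlation (log10 space)
#>   r-squared: 0.993 on 10 metals
```

The reconstructed metallome tracks the simulated quotas (r² = 0.99 here);
on real data the correlation is degraded by free-ion pools and
annotation error, and metals absent from either side are reported in the
result's `excluded` table rather than dropped.

The luxury-uptake diagnostic compares the two ratio kinds for Fe:

```r
strain_ratio(filter(profile, group == "OA16"),
             filter(profile, group == "OA1"))   |> filter(metal == "Fe")
#>   metal ratio     sd
#> 1 Fe    0.995 0.0673     # proteome: no change
strain_ratio(filter(sim$quotas, strain == "OA16"),
             filter(sim$quotas, strain == "OA1")) |> filter(metal == "Fe")
#>   metal ratio    sd
#> 1 Fe     2.24 0.159      # quota: doubled
```

A quota ratio near 2 with a metallome ratio near 1 is the signature of a
metal accumulated beyond metabolic use.

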