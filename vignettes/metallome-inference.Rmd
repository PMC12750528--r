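---
title: "Inferring relative metallomes from expressed proteomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring relative metallomes from expressed proteomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metallomer)
library(dplyr)
```

## The model

The package estimates a cell's *relative metallome* — how much of each
metal is bound in its expressed proteins — from three ingredients: (i)
metal-cofactor stoichiometries of template protein structures, (ii)
fold-recognition matches linking expressed proteins to those templates,
and (iii) label-free protein intensities. The reconstruction is a single
weighted sum per metal $m$:

$$A(m) \;=\; \sum_i p_i \, s_{im},$$

where $p_i$ is protein $i$'s relative abundance (its share of total
intensity) and $s_{im}$ the number of ions of metal $m$ assigned to it.
The estimate is in arbitrary units: intensities from label-free LC-MS are
not molar amounts, and different instruments or studies scale them
differently, so only *within-profile* comparisons between metals and
*between-group ratios* for the same metal are interpreted. This is also
why the comparison against ICP-MS quotas is a correlation in log space
rather than a slope or intercept test.

Three assumptions do the heavy lifting:

* **Annotation transfer is valid above the confidence cut.** A protein
  confidently matched to a structure is assumed to bind the same metals
  with the same stoichiometry. Cofactor substitution (e.g. Zn/Co
  exchange in some enzyme families) and partial metallation violate this
  silently.
* **Intensity is proportional to abundance** within a sample, after
  normalisation. Ionisation efficiency differences between proteins make
  this only approximately true; the reconstruction inherits that error.
* **Protein-bound metal is the visible fraction.** Free ions (Mg²⁺,
  Ca²⁺, K⁺ pools) and non-protein ligands are invisible to the proteome
  route; the comparison module therefore keeps such metals as explicit
  unpaired/excluded rows instead of dropping them.

## Coordination-sphere annotation

Template stoichiometries are derived locally from structures rather than
looked up: every atom of a configurable metal set becomes a candidate
site, and its first coordination sphere is the set of donor-element atoms
(default N, O, S) within a distance cutoff.

Parameters, defaults and reasoning:

* **Distance cutoff, 3.0 Å.** A typical first-shell threshold: most
  protein M–N/O/S coordination distances fall between 1.9 and 2.6 Å, and
  3.0 Å leaves headroom for longer alkali/alkaline-earth contacts without
  pulling in second-shell atoms. Configurable via
  `annotation_config(cutoff = …)`.
* **Donor elements {N, O, S}**, the protein's own ligating atoms. Waters
  are excluded from donor counting by default (`include_waters = FALSE`)
  so stoichiometry reflects the protein's first sphere, not the
  crystallographic solvent.
* **Adventitious rule.** A site with *no polymer donor* within the cutoff
  is a buffer or surface ion, not a cofactor, and is excluded from
  stoichiometry (`exclude_adventitious = TRUE`). Without this rule,
  crystallisation additives (Na⁺, Mg²⁺, Zn²⁺ soaks) inflate counts.
* **Metal set.** Alkali and alkaline-earth metals, all d-block transition
  metals, lanthanides plus Th/U, post-transition metals, and the
  metalloids As/Sb/Te — deliberately broad, because expressed proteomes
  have been annotated with unusual cofactors (V, W, Sb, Hg); narrow it
  with `annotation_config(drop_metals = …)` when that breadth is noise.

Deterministic tie-breaks, chosen once:

* **Altloc collapse**: the highest-occupancy conformer is kept; an exact
  occupancy tie goes to the alphabetically first altloc. (The underlying
  reader is asked for *all* conformers; its own default of silently
  keeping conformer "A" would bypass the occupancy rule.)
* **Chain attribution**: a site belongs to the chain contributing the
  majority of its polymer donors; an exact tie goes to the
  lexicographically smallest chain id.
* **Degenerate input**: two metal atoms on identical coordinates abort
  with an error rather than producing a double-counted site.

Stoichiometries are **per chain**, not per biological assembly: match
tables reference template chains, and assembly-level counts would
multiply-count interface sites. An assembly mode was considered and left
out; `stoichiometry_from_sites(chain_id = NULL)` already returns all
chains for callers who want to aggregate differently.

## Homology transfer

* **Strict threshold.** Matches are kept when confidence is *strictly*
  greater than 95%; a match at exactly 95.0 is excluded. The boundary has
  a dedicated test.
* **Best-match policy.** When several matches pass, the
  highest-confidence one wins (ties: smallest template id, then chain).
  Taking the union of all passing templates would double-count sites
  shared by homologous templates; a `union_max` policy (per-metal maximum
  over passing matches) is available behind a flag for callers who prefer
  recall over precision.
* **Resolvability.** A match whose template/chain is absent from the
  store cannot be transferred; it triggers a warning, and a query with
  only unresolvable matches is left unannotated. The best match is chosen
  *among resolvable matches*, so one stale store entry does not erase an
  otherwise annotatable protein. Apo chains are stored explicitly (zero
  rows) so that matching an apo template yields an annotated
  *non*-metalloprotein — which still counts in percentage denominators —
  rather than an unknown.

## Normalisation

Two normalisations serve two purposes:

* `normalize_median()` divides each sample's detected intensities by that
  sample's median (detected proteins only). It aligns samples of
  different depth for *cross-sample* tests and preserves within-sample
  rank order. Fold changes and t-tests run on these values.
* `normalize_total()` converts intensities to fractions of total; these
  feed the reconstruction. Group mode averages replicates first
  (missing excluded from the mean, all-missing proteins set to 0) and
  then normalises — so each replicate's censoring pattern does not
  re-weight the others — with sample mode (`by = "sample"`) providing the
  per-replicate profiles used for SDs and roll-up tests.

Zeros in search-engine output are treated as **missing**, not as measured
zeros: label-free zeros are censoring at the detection limit, and a
median over "detected proteins" is only meaningful under that reading.

Note that median-then-total is *not* generally the same as total alone:
median scaling changes each replicate's weight in the cross-replicate
mean unless replicate columns are proportional. The pipeline therefore
uses raw (not median-normalised) intensities on the total-normalisation
branch, and the equality is asserted in tests only where it holds
structurally (proportional replicates, single samples).

## Comparison statistics

* **Correlation** is Pearson on (log₁₀ quota, log₁₀ abundance) pairs.
  Metals span several orders of magnitude, so a linear-space r² would be
  dominated by the one or two most abundant metals; the log transform
  also makes r² exactly invariant to the metallome's arbitrary unit.
  Linear space is available via `log10 = FALSE`. At least 3 usable pairs
  are required; excluded metals are reported with reasons.
* **Ratios** use first-order (delta-method) propagation:
  $\mathrm{sd}(b/a) = (b/a)\sqrt{(s_a/a)^2 + (s_b/b)^2}$. At a CV of
  0.1 this understates the exact ratio SD by roughly 3–4% (the exact
  ratio distribution has heavier tails); the tests document this by
  checking the formula against a Monte-Carlo estimate at 5% tolerance
  and confirming convergence as the CV shrinks. For the CVs arising from
  triplicate proteomics this bias is immaterial next to the replicate
  noise itself.
* **Differential expression** is a two-sided pooled-variance (Student)
  t-test per protein on median-normalised intensities, with Welch behind
  a flag. Raw p-values are reported by default — the roll-up questions
  ("is total Co different?") are asked per metal, not per protein — and
  Benjamini–Hochberg adjustment is available via `p_adjust = "BH"`.
  Proteins with fewer than two detected replicates in either group get
  `NA` p-values rather than being dropped. Degenerate inputs (both
  groups constant) return the limit values: p = 1 when the means agree,
  p = 0 otherwise.
* **Roll-up tests** apply the same t-test to per-replicate reconstructed
  metal abundances, giving one ratio and one p-value per metal.

## The synthetic study

The generators produce coupled inputs whose ground truth is known at
every layer, under one seed:

* **Structures**: single-chain templates with planted sites whose donors
  sit at 2.0–2.6 Å (the observed first-shell range), plus an adventitious
  Na⁺ decoy whose only neighbour is a water at 3.5 Å — inside no polymer
  donor's reach, so a correct pipeline must discard it. About 20% of
  templates are apo.
* **Proteome**: a configurable fraction of proteins (default 0.37, the
  share seen in expressed phytoplankton proteomes) gets a passing match
  (confidence drawn above 95) to a metal-bearing template; others get
  passing apo matches or sub-threshold decoys straddling the cut.
* **Intensities**: per-protein log-normal base abundances
  (sdlog = 1.5, the wide dynamic range of label-free LC-MS), triplicates
  per group, multiplicative noise exp(N(0, σ²)) with σ = 0.1 (typical
  replicate CV ≈ 10%), and censoring at an overall 5% rate applied
  preferentially to low-abundance proteins — the missingness pattern of
  real label-free data, where dropouts cluster at the detection limit
  and dominant proteins are always observed.
* **Quotas**: per strain and metal,
  `scale × (bound + free) × luxury × (1 + ε)` with ε ~ N(0, 0.05²)
  truncated above −1. `free` models free-ion pools (set it high for
  Ca/Mg/K to emulate the proteome-invisible excess), `luxury` models
  uptake beyond use (a quota ratio without a metallome ratio).

What the simulation does **not** emulate: ionisation-efficiency
differences between proteins, annotation error (wrong templates passing
the cut), cofactor substitution, shared peptides, or intensity-dependent
noise. Passing the recovery tests therefore shows the pipeline's
arithmetic and plumbing are right under its own assumptions — not that
those assumptions hold for any particular organism.

Problem sizes were chosen to keep the full suite fast while leaving no
stage untested: 300 proteins × 8–10 metals × 2 groups × 3 replicates for
end-to-end recovery, 100 random structures (≤ 200 atoms) for the
detection-oracle equivalence, and 2 500 null proteins for the empirical
size of the t-test.

## Count summaries and rounding

`summarize_counts()` rounds percentages **half-up** to one decimal
(`floor(10x + 0.5)/10`), not the half-even rule of base `round()`,
because published count tables conventionally use half-up; the raw
fraction is kept alongside so no information is lost. A protein binding
*k* metals appears in *k* per-metal rows but once in the metalloprotein
total; pie-chart style `association_fractions()` instead counts each
(protein, metal) pair once. Recomputed percentages can still disagree
with a transcribed table by one unit in the last decimal when the
original was rounded differently — the raw fraction is the arbiter.

## A worked run

```{r pipeline}
sim <- simulate_metallome_study(n_proteins = 150, n_templates = 16,
                                seed = 7, luxury = list(OA16 = c(Fe = 2)))
store <- annotate_templates(sim$paths$structures)
ann <- transfer_annotations(filter_matches(sim$matches), store)
rel <- normalize_total(sim$quant, by = "sample")
profile <- compute_metallome(rel, ann)

glance(correlate_metallome(filter(sim$quotas, strain == "OA1"),
                           filter(profile, group == "OA1")))

strain_ratio(filter(profile, group == "OA16"),
             filter(profile, group == "OA1")) |>
  left_join(
    strain_ratio(filter(sim$quotas, strain == "OA16"),
                 filter(sim$quotas, strain == "OA1")),
    by = "metal", suffix = c("_metallome", "_quota")
  ) |>
  select(metal, ratio_metallome, ratio_quota)
```

The Fe row shows the luxury-uptake signature this vignette has been
describing: the quota ratio carries the planted factor while the
metallome ratio stays at 1.

## Known limitations

* Stoichiometry transfer is all-or-nothing at the protein level: no
  coverage or identity weighting, no partial-metallation model.
* Per-chain attribution cannot represent genuinely bridging sites shared
  between chains; such ions are assigned to one chain by majority/tie
  rule.
* The metallome is relative; absolute (molar) quotas cannot be recovered
  from intensities, and cross-species comparisons of absolute levels are
  out of scope by construction.
* Free-ion pools and luxury uptake are identifiable only *jointly* with
  measured quotas; from the proteome alone they are invisible.
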