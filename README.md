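# hsclone

Clonal analysis of single hematopoietic stem cell (HSC) transplantation
assays.

In these assays a single phenotypic HSC (pHSC: a CD34⁻/low KSL bone-marrow
cell, sorted from fraction F1 = CD150⁺CD41⁻, F2 = CD150⁺CD41⁺ or
F3 = CD150⁻CD41⁻) is transplanted into an irradiated recipient together
with competitor marrow, and the donor clone's output is followed as
peripheral-blood chimerism in five lineages — neutrophils/monocytes (nm),
erythrocytes (E), platelets (P), B cells (B) and T cells (T) — over 24
weeks, with secondary transplantations probing self-renewal. `hsclone`
takes such longitudinal chimerism tables (optionally backed by raw
flow-cytometry gate counts) and answers three questions:

1. **What is each clone, functionally?** Every clone is classified by its
   lineage output and reconstitution duration into HSCs (LT/IT/ST), the
   nested myeloid-restricted chain — MkRP/MkSC (platelets only), MERP/MESC
   (platelets + erythrocytes), CMRP/CMSC (+ neutrophils/monocytes) — with
   the suffix RP for short-term and SC for intermediate/long-term clones,
   plus *latent-HSCs* (myeloid-restricted output in the primary recipient
   but lymphoid output after secondary transplantation), `other`, and
   `non-reconstituting`.
2. **What does the pHSC compartment contain?** Per-fraction clonal outcomes
   are combined with fraction frequencies into absolute cell-type
   frequencies per 10⁶ BM cells, `F_t = N · Σ_f s_f · p(t|f)`, where `N` is
   pHSC abundance per 10⁶ BM cells, `s_f` the share of fraction *f* within
   the compartment and `p(t|f)` the fraction-conditional cell-type
   proportion. The package adds young-vs-aged fold changes, percentile
   bootstrap confidence intervals and a composition chi-square test.
3. **Is any of it testable without the mice?** A synthetic-cohort generator
   reproduces the study design — kinetic clone archetypes with log-normal
   per-clone plateau variation, binomial sampling through realistic gate
   sizes (30,000–50,000 leukocytes, 20,000–50,000 platelets, 500,000
   erythrocytes), ~6.7% recipient death with censoring, 1–5 secondary
   recipients per engrafting primary — so every pipeline stage has ground
   truth.

A clone is scored lineage-positive at 0.005% donor chimerism (a threshold
chosen to catch weak platelet/erythroid signals; 0.1% is supported for
sensitivity analysis), guarded by a minimum of 2 donor events whenever raw
gate counts are available.

## Worked example

```r
library(hsclone)

presets <- aging_scenarios()            # young and aged study presets
cohort  <- simulate_cohort(presets$aged, n_clones = 500, seed = 42)
cohort
#> <hsclone_cohort> 500 clones ( aged ); 31 dead; 273 secondary recipients; 26125 observations

calls <- classify_cohort(cohort)        # dead recipients are excluded first
sort(table(calls$cell_type), decreasing = TRUE)
#> non-reconstituting            ST-CMRP             ST-HSC            ST-MkRP
#>                238                 56                 36                 31
#>             IT-HSC            IT-MkSC             LT-HSC            ST-MERP
#>                 29                 19                 17                 17
#>            IT-CMSC            IT-MESC              other         latent-HSC
#>                 16                  5                  4                  1

est <- estimate_per_million(composition(calls),
                            presets$aged$fraction_frequencies)
est
#> # A tibble: 15 × 3
#>    cell_type          per_million composition
#>  1 LT-HSC                   23.3      0.0361
#>  2 IT-HSC                   39.9      0.0619
#>  3 ST-HSC                   49.4      0.0766
#>  4 latent-HSC                1.33     0.00205
#>  ...
#> 15 non-reconstituting      328.       0.509
```

The 469 surviving clones are dominated by non-reconstituting cells (about
half the aged compartment) and short-term myeloid-restricted progenitors;
`per_million` columns always sum to the preset's pHSC abundance (645.1 per
10⁶ BM cells for the aged preset) — conservation is exact by construction.
Comparing against a young cohort:

```r
young_calls <- classify_cohort(simulate_cohort(presets$young, 500, seed = 43))
composition_chisq(table(factor(young_calls$cell_type, levels = cell_types())),
                  table(factor(calls$cell_type,        levels = cell_types())))
#> $statistic 83.4; $df 13; $p_value 2.5e-12
```

so the functional composition of young and aged compartments differs
sharply, driven by expanded myeloid-restricted and non-reconstituting
cells. `bootstrap_ci()` attaches percentile intervals to every `F_t`, and
`threshold_sensitivity()` re-runs the classification across thresholds and
reports label agreement.

A thin command-line wrapper (`inst/cli/hsclone`) exposes `simulate`,
`classify`, `estimate`, `report` and `all` for shell pipelines.

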