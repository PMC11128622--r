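# epifam

Gene–gene interaction (epistasis) discovery for family-based sequencing
studies of complex disease, built around the model-based multifactor
dimensionality reduction (MB-MDR) approach.

Rare variants of individually modest effect can contribute to a complex
disease when they accumulate in genes serving the same biological
function, and pairs of such genes can interact to raise or lower risk.
`epifam` implements a complete discovery-and-replication workflow for
that hypothesis on whole-exome data from multiplex families plus
unrelated controls:

1. **Variant filtering** — site QC on the upstream calls (DP ≥ 12,
   MQ ≥ 30, QD ≥ 2, FS ≤ 25, call rate ≥ 95%), rarity (MAF < 1% in every
   reference panel where the variant is observed) and non-neutrality
   (impact ∈ {HIGH, MODERATE, MODIFIER} and/or Phred CADD ≥ 15).
2. **Co-segregation** — selection of rare variants showing *complete
   penetrance* (no unaffected carrier) and *no phenocopy* (no affected
   non-carrier) in at least one multiplex family.
3. **Pathway enrichment** — one-sided hypergeometric over-representation
   of the selected genes with Benjamini–Hochberg correction, plus a
   resampled background null (random draws of equally many non-neutral
   variants) to certify that the enrichment is not an artefact of
   gene-level tolerance.
4. **MB-MDR epistasis scan** — for each QC'd variant pair (missingness
   < 5%, Hardy–Weinberg exact p > 0.01 in controls, composite LD
   r² < 0.2), the 3×3 dosage table is labelled cell-by-cell as
   high-risk (**H**), low-risk (**L**) or uninformative (**O**) by
   sex-adjusted logistic score tests; the pooled H and L categories are
   tested by sex-adjusted logistic regression, BH-FDR-controlled across
   the scan, and confirmed by a permutation test that replays the whole
   labelling under shuffled phenotypes.
5. **Model competition** — the category-interaction model
   `affection ~ sex + 1[cell ∈ category]` is competed against `VAR1`,
   `VAR2` and `VAR1+VAR2` additive-dosage logistic models with the
   small-sample Akaike criterion, AICc = AIC + 2k(k+1)/(n−k−1); an
   interaction is retained only when every ΔAICc exceeds 10
   (Burnham–Anderson decisive support).

A seeded synthetic-data module (`sim_config()`, `simulate_study()`,
`emit_fixture()`) generates pedigrees with planted fully penetrant
co-segregating variants and planted two-locus penetrance structure
(high-risk-cell odds ratio 15 by default), so the entire pipeline is
testable without access to protected genotypes.

## Worked example

Simulate a case-control cohort around one epistatic pair (background
disease probability 0.1; genotype cells (1,1) and (0,2) at probability
0.625, i.e. a within-cell odds ratio of 15), scan it, and compete the
interaction model:

```r
library(epifam)

co <- simulate_epistatic_pair(default_penetrance_table(), 120, 120, seed = 7)
fit <- mbmdr(co)
fit
#> <mbmdr> 2 categories over 1 pairs tested (0 pairs excluded by QC); 2 significant at FDR < 0.05
#>            pair category           cells statistic         p     fdr_q    or
#> 1 rsEPI1*rsEPI2        H         0/2;1/1     53.22 2.979e-13 5.959e-13 9.518
#> 2 rsEPI1*rsEPI2        L 1/2;2/0;2/1;2/2     37.96 7.236e-10 7.236e-10 0.136

top <- fit$results[1, ]
compete_models(co, "rsEPI1", "rsEPI2", strsplit(top$cells, ";")[[1]])
#> <model_comparison> rsEPI1*rsEPI2, cells {0/2;1/1}
#>   AICc: INTERACTION=271.82, VAR1=321.35, VAR2=334.23, VAR1+VAR2=322.87
#>   delta (competing - interaction): 49.53, 62.41, 51.05
#>   retained (all > 10): TRUE

permutation_p(co, "rsEPI1", "rsEPI2", "H", B = 999, seed = 1)$p
#> [1] 0.001
```

Reading: the scan pooled the two genotype combinations 0/2 and 1/1 into
a high-risk category carried by 53% of cases (sex-adjusted OR 9.5,
p ≈ 3×10⁻¹³), the complementary low-risk category mirrors it, the
permutation test (999 label shuffles within sex strata) confirms the H
category at its floor p = 0.001, and the interaction model beats each
competing dosage model by ≈ 50 AICc points — decisively retained.

The full workflow runs from files:

```r
paths <- emit_fixture(sim_config(), "fixture_dir", seed = 42)
bundle <- run_discovery(paths$vcf, paths$ped, paths$gmt,
                        out_dir = "discovery_out", seed = 42)
```

which writes per-stage TSVs (filter audit, segregation verdicts,
enrichment, pair QC, epistasis categories, model competition, and an
interaction summary listing each significant category cell with its
case/control frequencies, OR, FDR, permutation p and ΔAICc values) plus
a JSON manifest. `run_replication()` re-tests selected pairs on an
independent cohort and declares replication only for the same category
label with overlapping genotype cells. A thin command-line wrapper with
`simulate` / `discover` / `replicate` subcommands ships in
`inst/cli/epifam.R`.

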