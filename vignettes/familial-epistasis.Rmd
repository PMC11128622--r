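---
title: "Methods: familial rare-variant epistasis discovery with epifam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: familial rare-variant epistasis discovery with epifam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical procedures implemented in
`epifam`, the assumptions behind them, the choices we made where the
design was genuinely open, and what the synthetic-data generator does
and does not emulate.

## Study design and model

The package targets a two-stage design common in family-based studies
of complex autoimmune disease such as rheumatoid arthritis: a
*discovery* sample of a few multiplex families (affected and unaffected
relatives with whole-exome calls) merged with unrelated
reference-population controls, and a *replication* sample of unrelated
cases and controls genotyped at the variants selected in discovery.

The working hypothesis has two layers. First, rare variants that
co-segregate perfectly with disease inside a family — every carrier
affected, every affected a carrier — point at genes whose disruption is
sufficient within that genetic background; over-representation of those
genes in a functional gene set nominates a pathway. Second, within the
nominated pathway, pairs of variants (rare or common) may carry
*statistical epistasis*: two-locus genotype combinations whose
case/control distribution departs from what either locus explains
alone.

### MB-MDR

For a variant pair with additive dosages $g_1, g_2 \in \{0,1,2\}$, the
samples with both dosages observed are cross-classified into the 3×3
cell table. Each cell holding at least `min_cell` samples is tested for
association between cell membership and affection with a Rao score test
from the sex-adjusted logistic null model
$\operatorname{logit} P(Y=1) = \beta_0 + \beta_s \cdot \text{sex}$.
Cells with $p \le \alpha_{cell}$ are labelled **H** (score direction
positive) or **L** (negative); the rest, and all under-occupied cells,
are **O**. The cells of one label are pooled into a single exposure
indicator and tested by sex-adjusted logistic regression (Wald test);
the pooled odds ratio, its 95% CI, and an unadjusted cross-product OR
are reported side by side because the two can differ when sex is
informative. Benjamini–Hochberg FDR is computed *jointly* over all H
and L p-values of a scan — the most conservative choice of family, and
the one that treats H and L symmetrically.

Final significance of a category comes from a permutation test:
affection labels are shuffled (within sex strata by default, preserving
the sex–phenotype margin that the adjustment models), and the *entire*
labelling-plus-pooling procedure is re-run per permutation;
$p = (1 + \#\{T^{perm} \ge T^{obs}\})/(B+1)$, with an empty permuted
category contributing $T^{perm}=0$.

A point that matters for interpretation: the asymptotic pooled
p-values are *optimistically biased by construction*, because the
pooled category only exists when at least one cell already passed its
own score test. They are useful for ranking, and the scan's FDR flags
are the trigger for permutation confirmation, but they are not
calibrated null p-values; the permutation p — which replays the
selection — is the calibrated quantity. The test suite verifies both
halves of this statement: under a fully null generator the per-cell
label rate matches $\alpha_{cell}$ and the permutation rejection rate
matches its nominal level, while the raw category rejection rate does
not (and cannot) sit at the nominal level.

### Model competition

For each selected category the interaction model
$Y \sim \text{sex} + 1[\text{cell} \in \text{category}]$ is fitted
alongside `VAR1` ($Y \sim \text{sex} + g_1$), `VAR2` and `VAR1+VAR2`
(additive dosage coding), all on the identical pairwise-complete sample
set. Small samples make the plain AIC too liberal, so every model is
scored with
$\mathrm{AICc} = \mathrm{AIC} + \frac{2k(k+1)}{n-k-1}$,
where $k$ counts all estimated parameters (intercept and sex
included: the interaction model has $k=3$, the two-dosage model
$k=4$). The interaction is *retained* when
$\Delta = \mathrm{AICc}(\text{competing}) - \mathrm{AICc}(\text{interaction}) > 10$
against **all three** competitors — the conventional threshold for
decisive support; a delta of exactly 10 does not retain. Both sign
conventions of the differences are emitted, since result tables in this
literature often print the negated values.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `min_dp`, `min_mq`, `min_qd`, `max_fs`, `min_call_rate` | 12, 30, 2, 25, 0.95 | standard hard filters for exome short-variant calls; all comparisons inclusive |
| `rare_maf_ceiling` | 0.01 (strict `<`) | "rare" means below 1% in every panel where the variant is observed; a variant absent from all panels counts as rare, because study-private familial variants are absent from public panels by construction |
| `cadd_floor`, `qualifying_impacts` | 15, {HIGH, MODERATE, MODIFIER} | non-neutrality is a disjunction of annotation class and deleteriousness rank; MODIFIER is kept although it mostly tags non-coding consequences — excluding it would silently drop intronic candidates of the kind this design exists to find |
| pair QC: `max_missing`, `hwe_alpha`, `max_r2` | 0.05 (strict), 0.01, 0.2 (strict) | missingness and LD rules are strict at the boundary; HWE is an exact conditional test in controls only |
| `alpha_cell`, `min_cell` | 0.1, 10 | conventional MB-MDR cell-labelling defaults; both exposed |
| `fdr_level` | 0.05 | category significance and the permutation trigger |
| permutations `B` | 999 in code paths, up to 10⁶ supported | no adaptive early stopping, so seeds reproduce exactly |
| `delta_threshold` | 10 | decisive-support rule |

## Decisions where the design was open

* **Carrier coding.** "Carrying" a rare variant is dosage ≥ 1
  (dominant coding): fully penetrant familial variants are essentially
  always heterozygous in cases, so recessive coding would make the
  co-segregation definition vacuous.
* **Untyped families.** A family with any missing dosage, or without
  both an affected and an unaffected genotyped member, is *untyped* for
  that variant rather than imputed: a penetrance claim cannot rest on
  imputed genotypes.
* **Enrichment universe.** All genes harbouring at least one
  site-QC-passing variant in the cohort — the sequenced-exome sampling
  frame — rather than the whole genome; configurable. A variant
  annotated to several genes counts once per gene.
* **Multi-allelic sites** are split into one biallelic record per
  alternate allele with per-allele dosage counting, keeping every
  downstream stage biallelic. Indel length is the REF/ALT length
  difference, capped at 50 bases.
* **Replication criterion.** A discovery category replicates only when
  the replication scan finds the *same label* (H or L) significant
  (permutation p, BH-adjusted across the replication tests) with at
  least one genotype cell in common; a same-label hit on disjoint cells
  is flagged `category_mismatch`, not counted.
* **Relatedness** is deliberately not modelled in the epistasis scan
  (family members enter as independent samples); this mirrors how such
  discovery analyses are actually run at this scale and is recorded in
  the output manifest as a statistical caveat. The replication stage,
  built from unrelated samples, is the guard against the resulting
  optimism.

## Numerical choices

* Cell tests are *score* tests evaluated at the null fit
  (intercept + sex). Because the null model never includes the sparse
  cell indicator, separation cannot occur at the labelling step, and
  with a single binary covariate the null fitted values are exact
  (per-stratum affection rates), so labelling is fast and
  deterministic.
* Pooled tests and the competing models are maximum-likelihood logistic
  fits. Separation — inevitable when a high-risk cell holds only
  familial cases — is detected from runaway coefficients and handled by
  a Firth-type penalized refit for the reported coefficients and Wald
  CI, flagged in the output; information criteria always use the
  maximum-likelihood log-likelihood so models remain comparable.
* Tie-breaking in the category ranking is deterministic: p ascending,
  then |statistic| descending, then lexicographic pair id and category.
* Degenerate inputs have defined outcomes: constant dosage columns make
  LD r² undefined and exclude the pair with reason `r2_undefined`; a
  category covering all nine cells is a constant predictor and an
  error; AICc is undefined when $n-k-1 < 1$ and marks the comparison
  unevaluable.
* Permutation p-values floor at $1/(B+1)$; identical seeds and input
  order give bit-identical scan and permutation output.

## What the generator emulates — and what it does not

`sim_config()` encodes the default study conditions: nine nuclear
multiplex families totalling 19 affected and 11 unaffected members, 98
unrelated controls (91 plus 200 unrelated cases in the replication
layout), 17 planted co-segregating variants (complete penetrance, no
phenocopy, each private to one family branch; 12 in the planted
25-gene pathway, 5 elsewhere), one planted epistatic pair with
background disease probability 0.1 and two high-risk cells — (1,1) and
(0,2) — at probability 0.625, i.e. a within-cell odds ratio of exactly
15, matching the magnitude of the strongest interactions this kind of
scan reports; allele frequencies 0.5 at both loci put substantial mass
off the dosage diagonal, where additive models fit poorly. Female risk
is multiplied by 1.5 on the odds scale so the sex adjustment is
exercised non-trivially. Sixty common null variants (frequencies
0.1–0.45) spread over 60 genes provide the enrichment universe and
null pairs. Genotype missingness is injected uniformly at 1%, sparing
the planted co-segregating genotypes within their own family so their
selection is deterministic by construction.

Family genotypes are always Mendelian: null variants are gene-dropped
from Hardy–Weinberg founders; the epistatic pair inside a family is
drawn by rejection on the family's affection pattern (exact conditional
sampling), and retrospectively for unrelated samples. Case/control
quotas are met by rejection sampling, so cohort composition is exact;
the run time scales inversely with the rarer outcome's probability.

The generator does **not** emulate linkage-disequilibrium structure,
population stratification, the ascertainment process by which multiplex
families are recruited, genotyping error, or X-linked inheritance
(all variants are treated as autosomal). Passing tests on this
generator therefore demonstrate the statistical machinery — filter
boundaries, co-segregation logic, calibration and power of the
interaction engine — not robustness to those real-data complications.

One empirical subtlety the generator *did* expose: when a pair truly
modifies risk and sampling is strongly ascertained, the control stratum
is depleted of high-risk genotype combinations, which distorts control
genotype frequencies — so the Hardy–Weinberg-in-controls QC rule can
reject a *true* interacting variant (in roughly a quarter of simulated
replicates at the default effect size). This is a real cost of
HWE-based QC in enriched designs; the engine's power properties are
therefore assessed with the pair supplied as QC-passed, matching the
scan's contract that pair QC has already been applied.

## Problem sizes used in the checks

The test suite and the acceptance script size their simulations for a
single CPU: exhaustive oracle comparisons (hypergeometric tail for
universes up to 12, HWE for up to 8 genotypes, 1000 random BH vectors);
500 null pairs for the raw-category rejection rate and 200 null pairs
at B = 199 for permutation calibration; 100 replicates each for
recovery (detection + retention of the planted pair at 120 cases / 120
controls) and for the additive-only specificity check; and a committed
byte-for-byte regression run of the full discovery workflow on a seeded
fixture whose pathway is defined over 12 genes (276 pairs), keeping the
reference outputs compact while the enrichment universe stays at 60
genes.

## Known limitations

Beyond the generator's simplifications listed above: the scan is
pairwise only (no higher-order interactions); the familial discovery
treats relatives as independent; asymptotic category p-values are
ranking devices, not calibrated tests (see above); Firth-flagged odds
ratios from near-separated tables remain finite but their CIs are
approximate; and the AICc competition compares non-nested models, so
"retained" means decisively better-scoring, not hypothesis-tested.
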