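---
title: "Searching for multi-SNP genotype models in case-control data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching for multi-SNP genotype models in case-control data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpga)
```

## The model

A case-control genotype dataset holds `N` individuals typed at `S` biallelic
SNPs, each genotype coded 1 (major-allele homozygote, the reference),
2 (heterozygote) or 3 (minor-allele homozygote). A *model* of order `d` is a
set of `d` pairs `(sᵢ, gᵢ)` with distinct SNPs; an individual carries the
model when they have genotype `gᵢ` at every `sᵢ`. The target of the search
is the model maximising

$$f(C) = \frac{1}{|P|}\sum_{i} m(C, P_i) - \frac{1}{|N|}\sum_{i} m(C, N_i),$$

the difference between carrier frequency among cases `P` and controls `N`,
with `m(C, X) = 1` iff `X` carries `C`. The value is signed: negative
fitness marks protective combinations, and both are reportable. A
chromosome that selects the same SNP twice does not describe a genotype
combination and is assigned fitness exactly 0 rather than being repaired —
this is the representation's own penalty and crossover is free to produce
such offspring.

Carrier frequencies, not genotype main effects, are the unit of analysis:
this is what lets a combination be associated with disease when every
marginal single-SNP test is null.

## The genetic algorithm

`run_ga()` is a literal steady-state implementation:

1. **Initialisation** — `population_size` chromosomes, each a uniformly
   random valid model of order `d` (SNPs without replacement, genotypes
   uniform).
2. **Evaluation** — fitness of every chromosome; values are cached so later
   generations only evaluate new offspring.
3. **Selection** — deterministic rank-based choice of the two fittest
   chromosomes (ties broken by population index). The scheme is sometimes
   described with the word "tournament", but the specification sorts the
   whole population and takes ranks 1 and 2; we implement exactly that.
4. **Crossover** — a uniform mask of `d` fair-coin bits; positions with a 1
   swap elements between the parents, producing two offspring.
5. **Mutation** — each offspring position mutates independently with
   probability `mutation_rate`; the replacement element is drawn uniformly
   from the pairs whose SNP is not used at any *other* position (the
   mutating position's own SNP stays eligible, so a mutation may change
   only the genotype).
6. **Replacement** — each offspring in turn replaces the *current worst*
   member iff strictly fitter. The best member can never be displaced, so
   the best-so-far history is non-decreasing by construction.

Defaults (`ga_params()`): population 50, 100 generations, mutation rate 0.1,
selection/crossover exchange probabilities 1. One run therefore performs
`50 + 2 × generations` fitness evaluations.

Design points that were genuinely open:

* *Which member does an offspring replace?* The source description says only
  "a chromosome". We replace the current worst — the standard steady-state
  choice; it preserves elitism and makes the history monotone.
* *Invalid offspring* are kept with fitness 0, not repaired; with signed
  fitness they can even outrank populations whose valid members are all
  negative. `GAResult$best_model` is therefore defined as the best *valid*
  model evaluated (from the distinct-model ledger), reported in canonical
  notation with SNP indices ascending; a chromosome is a set, so element
  order carries no information.
* *Ties* — in the exhaustive oracle, broken by enumeration order
  (lexicographic by SNP subset, then genotype codes); in the GA ledger, by
  notation. Both choices exist purely to make reports reproducible.
* *RNG discipline* — one seed drives a run; seeded entry points
  (`run_ga()`, `generate_synthetic_cohort()`) save and restore the caller's
  RNG state, so a pipeline is a pure function of (input, config, seed).
  Per-order pipeline seeds are derived as `seed + order`.

## Association statistics

For a model's 2×2 table (`a` model-positive cases, `b` model-positive
controls, `c`, `d` the complements) `odds_ratio_test()` computes
`OR = ad/bc`, the Woolf confidence interval
`exp(ln OR ± z·SE)` with `SE = √(1/a+1/b+1/c+1/d)`, and a two-sided Wald
p-value from `ln OR / SE`. Two numerical choices matter:

* `z = 1.959964`, the 97.5% normal quantile at full precision. Using the
  conventional 1.96 shifts the third decimal of wide intervals (e.g. an
  upper bound of 100.142 on a corrected sparse table becomes 100.135).
* **Zero cells**: 1 is added to *every* cell before OR/CI/p. This rule was
  fixed by a brute-force comparison of candidate corrections (+0.5 to all
  cells, +1 to all cells, +1 to zero cells only) against a published sparse
  table whose OR, CI and p are known to three decimals: only add-one-to-all
  reproduces all three (the Haldane-Anscombe +0.5 gives OR ≈ 25.4 instead
  of 13.148). The test suite re-runs this search. The model-positive case
  percentage is always reported from the uncorrected counts.

Pearson chi-square and Fisher exact p-values are available as alternatives
(`p_method`), and for well-filled tables (all cells ≥ 5) the Wald p agrees
with chi-square within 0.02 — a property the suite checks. No
multiple-testing correction is applied anywhere, deliberately: the method
this package reimplements reports raw per-model p-values, and an honest
reimplementation must do the same. Treat the p-values of the best model of
a scanned space as descriptive, not inferential.

Single-SNP tables (`single_snp_association()`) test each non-reference
genotype against the code-1 reference. Percentages are rounded to 2
decimals, ORs/CIs to 3, p-values to 3 — only in the formatting layer
(`format_best_models()`); all stored values are full precision and every
printed number is recomputable from the JSON output.

## The synthetic cohort generator

`generate_synthetic_cohort()` emulates the *shape* of a small candidate-gene
study: `n_case`/`n_control` individuals, `S` SNPs with per-SNP control-group
minor-allele frequencies in (0, 0.5), genotypes drawn independently per SNP
from Hardy-Weinberg proportions `((1-q)², 2q(1-q), q²)`, no missing values.
Optionally a risk model is embedded by overwriting each individual's
genotypes at the model SNPs with the model codes, with probability
`target_freq_case` in cases and `target_freq_control` in controls.

Background individuals can also match the embedded model by chance, so the
realised carrier frequency is `t + (1-t)·β` with `β` the Hardy-Weinberg
match probability; the frequency *difference* shrinks by `(1-β)`. This
inflation is deliberate — suppressing it would make the planted model
detectable by its artificial cleanliness — and the tests account for it with
a closed-form oracle rather than hiding it.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (real tagSNPs are correlated), genotyping error, missingness,
population stratification, or covariates. A green test on synthetic data
therefore establishes algorithmic correctness — that the search finds what
was planted and the statistics are computed right — not robustness to the
failure modes of real genotype data.

Where the defaults come from: group sizes 345/290 and the 5-SNP,
MAF > 10% panel mirror the study design this class of search was built for;
the benchmark MAF vector (0.30, 0.25, 0.40, 0.35, 0.30) used in the tests
was chosen once as a realistic such panel and not revisited.

## Data loading conventions

`read_genotype_table()` accepts integer codes or allele-pair strings
("GT" ≡ "TG"); major/minor alleles may be declared per SNP (YAML sidecar)
or are inferred from observed allele frequency, and a column with more than
two alleles is an error. Rows with any missing genotype are dropped and
counted in the load report: model membership is undefined on missing data,
and the upstream method gives no imputation rule. The drop-row policy is
this package's choice, stated here because the original cohort description
never mentions missingness.

Models of order `d = 1` are representable (useful for single-SNP work)
although searches are typically run at `d ≥ 2`; the empty model is not
representable.

## Known limitations, and two deliberately red tests

The literal algorithm evaluates `50 + 2 × 100 = 250` chromosomes per run —
of which typically only 50–70 are *distinct* valid models, because
deterministic top-2 selection fixates quickly. Spaces of 90–405 models
(orders 2–5 on 5 SNPs) are therefore *under*-sampled, and the measured
probability that a run attains the exhaustive-search optimum on a neutral
cohort is roughly 0.4–0.5 per order, not ≥ 0.95 as the acceptance targets
inherited by this package assert. Two tests in
`tests/testthat/test-acceptance.R` encode those ≥ 95% targets verbatim and
fail by design; the suite's `verify_against_oracle()` harness computes the
actual hit rates. The practical advice follows directly: on small panels,
run `exhaustive_best()` (it is cheaper than one GA run below ~10⁵ models)
or run the GA with several seeds and keep the ledger union; the GA's value
is on panels too large to enumerate.

The exhaustive oracle refuses spaces above `max_models` (default 10⁷)
rather than silently running for hours. GWAS-scale feature selection,
logistic-regression covariate adjustment, cross-validation and plotting are
out of scope.
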