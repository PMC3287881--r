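---
title: "Methods: gene-based tests combining rare and common variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-based tests combining rare and common variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Exome sequencing yields, for each gene, a mixture of rare variants (minor
allele frequency, MAF, below a threshold `T`, conventionally 5%) and common
variants. Single-marker regression is well powered for common variants but
nearly powerless for variants carried by a handful of individuals, while
collapsing ("burden") tests aggregate rare minor alleles into a per-person
score at the cost of ignoring common variation. Since a single gene can
carry causal variants on both sides of the frequency split, `raremix`
implements both families of gene tests and a combination of their p-values,
plus the machinery needed to evaluate them: a cohort simulator with a
population-structure confounder, genomic control, and power / type I error
estimation over phenotype replicates.

## Rare-variant collapsing tests

All three tests reduce a gene's dosage block `g_ij` (minor-allele counts,
individuals `i`, variants `j`) to a per-individual score `s_i` and measure
its association with a quantitative trait `y`:

* **FT (fixed threshold)** — `s_i = sum_{j: maf_j < T} g_ij`, unweighted,
  strict inequality. Variants at or above `T` are excluded entirely; with no
  qualifying variant the score is identically zero and the result is flagged.
* **WE (weighted)** — every variant in the gene is used, weighted by
  `w_j = sqrt(n_ref q_j (1 - q_j))` with the pseudocount estimate
  `q_j = (c_j + 1) / (2 n_ref + 2)` from a reference group, and
  `s_i = sum_j g_ij / w_j`. The weighting scheme was designed for
  case-control data, where `c_j` is counted in unaffected subjects. For a
  quantitative trait no controls exist; our default reference group is the
  individuals with phenotype at or below the sample median (an option uses
  the whole sample). The reference group is recomputed inside every
  permutation, so the permutation test remains exact for the full statistic.
* **VT (variable threshold)** — the FT collapse is evaluated at every
  candidate threshold (the sorted distinct observed MAFs, inclusion
  `maf <= t` so each variant enters at its own MAF) and the maximal
  association is kept, together with the smallest maximizing threshold
  `T_opt`. The threshold search is repeated inside every permutation.

The internal association measure is the Pearson correlation between `s`
and `y`, taken in absolute value (two-sided), with the convention that a
constant score or phenotype gives 0. The published descriptions of these
tests name the collapsing rules but not the internal score; any statistic
that is a monotone function of the burden-phenotype correlation yields the
same permutation ordering, and the correlation is the simplest scale-free
choice. It makes all three tests invariant to shifting `y` or rescaling it
by a positive factor, which the test suite checks.

Significance is empirical: `p = (1 + #{b: z_b >= z_obs}) / (B + 1)` over
`B` phenotype permutations (genotypes fixed), which is never zero and has
floor `1/(B+1)`. `B` defaults to 1000; the evaluation experiments below use
500. Within a gene all methods share one seed-derived permutation stream,
and gene-level seeds are derived deterministically from the base seed and
the gene identifier, so any single gene can be recomputed in isolation.

## Common-variant tests

Both tests operate on the complementary variant set, `maf >= T` (inclusive,
so the rare and common subsets partition the gene exactly).

* **CV_pmin** — ordinary least squares of `y` on each variant dosage with
  intercept (additive model), two-sided p from the slope t statistic with
  `n - 2` df; the gene summary is the minimum p, Bonferroni-multiplied by
  the number of markers actually tested (polymorphic, `maf >= T`).
* **CV_lasso** — the L1 regularization path of `y` on the standardized
  eligible dosages, scored at each model by a Mallows-Cp analog
  `Cp_k = RSS_k / sigma2 - n + 2 df_k`, where `df_k` is the number of
  nonzero coefficients. The minimum-Cp model (ties to fewer coefficients;
  the intercept-only model is always a candidate) is refit by unpenalized
  OLS and summarized by its overall F-test p-value against the
  intercept-only model, with `p = 1` for an empty selection. The correction
  multiplies by the *total* number of SNPs in the gene — deliberately
  conservative, since the LASSO's effective degrees of freedom equal the
  nonzero count.

Two open choices were fixed as follows. First, the gene p-value of the
selected model is the naive refit F-test; post-selection-adjusted inference
is out of scope, and the Bonferroni factor above presupposes the naive
refit. Second, `sigma2` in Cp is the residual mean square of the full OLS
fit on all eligible variants whenever it has positive residual df
(`m <= n - 2`); otherwise the smallest residual mean square along the path
is used and the result flagged. Predictors are standardized before
penalization and coefficients reported after refit on the original scale.

## Combined test

For a mixed gene the rare (FT, `maf < T`) and common (`maf >= T`) subsets
are disjoint, and their p-values are combined with Fisher's method:

`U = -2 sum_i log p_i`, referred to chi-square with `2n` df (here `n = 2`).

With one p-value the combination is the identity; `U = 0` iff every
component is 1. The chi-square reference assumes independent, null-uniform
inputs. Two consequences drive design choices:

* The combination uses the **FT** component for the rare signal, not WE or
  VT — those already consume the gene's common variants, which would be
  double counting.
* Genomic control is applied to each component family **before**
  combination, because Fisher's reference requires null-uniform inputs;
  combining first and correcting after would feed an inflated component
  into a fixed reference distribution. The combined family itself receives
  no further correction.

Dependence between the two components (linkage disequilibrium between rare
and common variants) is ignored; the simulator draws variants
independently, so this assumption is exact in the evaluation experiments
and approximate on real data.

## Genomic control

Each p-value in a family (one method over many genes, within one
replicate) is mapped to the 1-df chi-square statistic with that upper-tail
probability; the inflation factor is `lambda = mean(x) / 1` (the mean of a
null 1-df chi-square is exactly 1, so the mean-ratio form needs no
reference constant); statistics are divided by `lambda` and mapped back.
`lambda` is floored at 1 by default (never deflate; disable with
`floor_lambda = FALSE`). The mean-based form is used rather than the
median-based variant. Correction is per family and per replicate.

A numerical interaction worth knowing: permutation p-values are discrete
with floor `1/(B+1)`. Mapping the floor to a chi-square caps the largest
observable statistic (9.55 at `B = 500`), which biases `lambda` slightly
downward in strongly inflated families, and Bonferroni-significant
detections after correction require raw p-values near the floor. At the
evaluation scale used here this keeps corrected type I error near nominal,
but detection resolution below `alpha/N` for large `N` requires raising `B`.

## The simulator

`study_design()` describes a cohort mimicking an exome panel of unrelated
individuals (default 697) with genes in three groups — rare-only, mixed,
common-only (defaults 1732 / 1142 / 331) — and group SNP-count means 3.155,
16.336 and 1.106 (shifted Poisson, so no gene is empty and mixed genes
have at least two variants). Rare population MAFs follow a Beta
distribution truncated to (0, 0.05), `shape1 = 0.8` with `shape2` solved so
the truncated mean is 0.006 (the solved value is about 132; the implied
truncated SD is about 0.0066). Common MAFs are uniform on [0.05, 0.45].
Each mixed-gene SNP is common with probability 0.12, chosen so the pooled
mixed-group mean MAF is about 0.035; at least one variant of each kind is
forced per mixed gene.

Population structure is a two-subpopulation Balding-Nichols model: subpop
frequencies are Beta draws around the ancestral frequency with divergence
`fst` (default 0.05, a typical continental-scale value), genotypes are
Hardy-Weinberg within subpopulation, and no linkage disequilibrium exists
between variants. Variants drawn for the rare (common) side of a gene are
redrawn until the sample MAF lands on the designed side of 5%, so the gene
partition of the output is exact by construction.

The phenotype is `y = X beta + gamma * ancestry + eps`,
`eps ~ N(0, noise_sd^2)` redrawn per replicate with genotypes fixed
(mirroring a fixed-genotype, many-phenotype-replicate evaluation design).
All causal effects are positive: the collapsing tests aggregate unsigned
counts, and mixed effect signs would change their power in ways the
framework does not model. The default causal architecture places 4 causal
genes in the rare-only group and 5 in the mixed group, each with 1-11
causal variants of sample MAF in [0.0007, 0.165].

The confounder strength `gamma` is not a direct input of interest — what
matters is its consequence, the null-test inflation. `calibrate_confounder()`
finds the `gamma` at which per-SNP regression tests on a pure
confounder trait reach a target mean-based `lambda` (default 2.3, the
middle of the 2.2-2.8 range such structure produces in the motivating
setting), using fixed residual draws across candidate values so the
inflation is a smooth increasing function and a root finder applies. The
gene-level test families then show inflation of the same order (the WE and
VT families run somewhat hotter than per-SNP tests, as their scores
aggregate frequency differences across a whole gene).

What the simulator deliberately omits: linkage disequilibrium, haplotype
structure, relatedness, dichotomous traits, gene-environment and epistatic
effects, and functional annotation of variants. Tests passing on this
generator therefore demonstrate correctness of the statistical machinery
and calibration under independence — not robustness to LD between the rare
and common components of the combined test, which is the main caveat for
real data.

## Evaluation conventions

Genes are partitioned at 5% sample MAF (boundary value is common).
Rare-variant tests run on the rare-only and mixed groups; common-variant
tests on the mixed group; combined tests on mixed genes only. Power is the
fraction of causal-gene results with corrected p below `alpha / N`, with
`N` the number of genes tested in the same group (the groups are analyzed
separately; a flag switches to an all-genes denominator). Type I error is
the per-test fraction of noncausal results below uncorrected `alpha` —
an intentionally asymmetric convention matching how such studies report
"power after multiplicity control" next to "per-gene error at alpha".
QQ tables use midpoint expected quantiles `(k - 0.5) / N`. Causal-gene
ranks use average ranks on ties.

## Problem sizes used in the shipped experiments

The package's own calibration experiment (tests and `scripts/acceptance.R`)
uses 697 individuals, 200 rare-only plus 200 mixed null genes, 20 phenotype
replicates, `B = 500` permutations, and the calibrated confounder: large
enough that the binomial standard error of a type I estimate at
`alpha = 0.05` over 4000 gene tests is about 0.0035, and that per-replicate
`lambda` estimates (400 genes for the rare families) are stable to a few
percent. The qualitative power comparison uses 400 individuals and a
planted strong common variant, where the single-SNP signal is
unambiguous. These sizes are the package's own evaluation choices.

## Known limitations

* Permutation p-values are exchangeability-based; covariates cannot be
  adjusted inside the collapsing tests.
* The WE reference group for a quantitative trait is a declared convention
  (lower phenotype half), not an estimated quantity.
* Mean-based genomic control corrects the first moment only; with strong
  inflation the corrected tail is near-nominal but not exact.
* The combined test assumes independence of its two components; under LD a
  permutation-based combined null would be needed.
* `Cp` selection with more eligible variants than residual df falls back to
  a path-based variance estimate and is flagged, not exact.
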