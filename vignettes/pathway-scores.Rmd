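---
title: "Pathway polygenic scores: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway polygenic scores: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathprs)
```

## The score model

A pathway polygenic risk score restricts the usual genome-wide PRS to
variants lying within (flanked) intervals of a defined gene set. For
individual $i$ and a variant set $V$ selected at discovery-GWAS threshold
$P < p$:

$$S_i \;=\; \frac{1}{2\,|V|}\sum_{j \in V} d'_{ij}\,\ln \mathrm{OR}_j$$

where $d'_{ij} \in [0,2]$ is the dosage of the GWAS effect allele after
harmonization and $\mathrm{OR}_j$ the discovery odds ratio. The modelling
assumptions are the standard ones of summary-statistic scoring: additive
allele effects on the liability scale, no interaction terms, and discovery
effect sizes treated as fixed weights.

### Normalization

Published score tables for this kind of analysis report score magnitudes
that *shrink* as the threshold loosens and the variant count grows
(roughly 0.048 at $P<10^{-5}$, 0.023 at $P<0.05$, 0.014 at $P<0.5$), which
is the signature of a per-allele average rather than a raw sum: a raw sum
grows with the number of variants. The default normalization is therefore
`per_allele_mean` (divide the weighted sum by $2|V|$); `raw_sum` is
available by argument. Both modes give identical inference for a single
threshold, since the regression slope simply rescales.

### Harmonization and thresholding

* If the allele counted by the genotype dosage equals the GWAS effect
  allele, the dosage is used as is; if it equals the other allele, the
  dosage is reflected ($2-d$). Scores are provably invariant to how any
  genotype column happens to be coded (a tested invariant).
* Palindromic variants (A/T, C/G) are excluded: their strand cannot be
  resolved from alleles alone. Allele-set mismatches are also excluded.
  Both exclusions are logged with reason codes.
* Thresholding is strict ($P <$ cutoff), following the conventional
  "$P<0.05$" notation, so a variant with $P$ exactly at the cutoff is
  excluded; threshold sets at $10^{-5} \subseteq 0.05 \subseteq 0.5$ are
  nested by construction.
* Missing hard-call dosages are mean-imputed at twice the in-sample effect
  allele frequency before summation, the standard neutral choice: an
  imputed individual contributes the population-expected dosage.
* Dosages are hard calls in $\{0,1,2\}$. Fractional imputed dosages would
  drop into the same code path (the score is linear in dosage) but are not
  generated or read at present.
* Index variants at the locus that defined the gene set (e.g. rs1702294
  for a miR-137 gene set) can be excluded from every scoring set via
  `exclude_index_variant()`, so the score measures the downstream gene set
  rather than the index locus itself.

### Windows and coordinates

Coordinates are 1-based closed intervals throughout, matching VCF `POS`;
the gene annotation TSV is declared 1-based inclusive to avoid the 0-based
BED trap. "Within 20 kb" is read as a flank on *both* sides of the gene
boundaries, boundary-inclusive; whether a canonical-transcript TSS or the
gene boundary anchors the flank is not identifiable from the analysis
definition, and gene boundaries are used. Windows are clipped at position 1
and deliberately not merged — per-gene attribution stays available in the
logs, and de-duplication at variant selection guarantees each variant is
counted once. Greedy LD pruning (`ld_prune()`) is implemented but off by
default, matching the main analysis, which scores all in-window variants
without pruning.

## Association and meta-analysis

Each phenotype is regressed on the score with age and sex as covariates of
no interest (OLS, intercept, listwise deletion). Reported per fit: the
unstandardized slope $B$ with $t$-based SE/CI/two-sided $p$; the
standardized $\beta = B \cdot \mathrm{sd}(x)/\mathrm{sd}(y)$ (simple, not
partial, standardization — the predictor/outcome SD ratio); and
$\Delta r^2 = r^2_{\text{full}} - r^2_{\text{covariates}}$, the incremental
variance explained. Outliers are screened once at $|z|>3$ before fitting;
the rule sits behind a mask interface so an IQR fence could be swapped in.

Per-platform estimates are pooled by fixed-effect inverse variance:
$w_i = 1/\mathrm{SE}_i^2$, $\hat B = \sum w_i B_i / \sum w_i$,
$\mathrm{SE}(\hat B) = 1/\sqrt{\sum w_i}$, CI and $p$ from the normal
approximation ($z$, the convention for inverse-variance pooling; the
reference distribution is not otherwise pinned down). Heterogeneity:
$Q=\sum w_i(B_i-\hat B)^2$ on $k-1$ df and
$I^2 = \max\{0, (Q-(k-1))/Q\}\cdot 100$, floored at zero per the usual
definition. Random-effects pooling is out of scope: the design this package
serves found negligible heterogeneity between platforms and used the fixed
model. Multiplicity over cognitive domains uses Bonferroni with
$n_{\text{domains}} = 5$ by default.

## Power

`posthoc_power()` computes the power of the 1-df partial $F$ test:
$f^2 = r^2/(1-r^2)$, noncentrality $\lambda = f^2 n$ (total-$n$
convention; the alternative $\lambda = f^2(n-k-1)$ differs by under 0.1%
in power at $n \approx 10^3$, so it is documented rather than
configurable), and
$\text{power} = P\{F'(1, n - k - 2; \lambda) > F_{1-\alpha}\}$. At
$n=988$, $r^2=0.01$, $\alpha=0.05$ this gives 0.884, and a Monte-Carlo
check (10 000 simulated regressions) agrees within 0.02 — both are
recomputed by `scripts/acceptance.R` and the test suite.

```{r power}
posthoc_power(n = 988, r2 = 0.01, alpha = 0.05)
```

## The synthetic cohort generator

`simulate_cohort()` emulates the data the analysis consumes:

* **Genes**: uniform placement on configured autosomes, lengths 5–50 kb.
* **Variants**: a fixed number per flanked gene window plus decoys outside
  all windows (negative controls for selection); non-palindromic allele
  pairs; MAF uniform in a configured range.
* **Summary statistics**: a fraction of in-window variants receives a
  planted log OR $\sim N(0, \sigma)$; reported ORs are exactly
  $e^{\text{planted}}$ (so a null panel has OR $=1$ exactly), and P-values
  come from a two-sided Wald $z$ with configurable SE, so larger planted
  effects tend to smaller $P$ and null variants have uniform $P$. A full
  case-control simulation is not attempted: the pipeline consumes only
  (OR, P), so their joint behaviour is what matters.
* **Genotypes**: Binomial(2, MAF) per individual — Hardy–Weinberg, no LD.
* **Phenotypes**: $y = a\cdot\text{age} + s\cdot\text{sex} + b\cdot S^\ast
  + \varepsilon$ with age uniform on [18, 65] (the study inclusion range),
  sex Bernoulli(0.5), $S^\ast$ the planted-weight score; $b$ and
  $\mathrm{Var}(\varepsilon)$ are solved against the empirical variances so
  the expected incremental $r^2$ of the score after covariates equals the
  configured target. Phenotypes are continuous Gaussian: the cognitive
  instruments the analysis serves are heterogeneous, but all are analyzed
  by linear regression, so one continuous trait family suffices. Platform
  labels split the cohort into subsamples A and B.

Seeding uses one master seed with fixed per-stage offsets, so each stage is
independently reproducible and whole-cohort simulation is bitwise
deterministic.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: linkage disequilibrium between variants
(independent draws), population stratification and relatedness, imputation
dosage uncertainty, genotyping batch effects beyond the platform label, and
non-Gaussian phenotype features (skew, ceilings/floors common in cognitive
tests). Calibration and recovery results here validate the statistical
machinery, not robustness to those structures.

## Numerical and testing choices

* Degenerate inputs: an empty scoring set yields all-zero scores with
  `n_variants_used = 0` and a warning; a constant score in the pipeline is
  recorded as an NA association row (a strict threshold can legitimately
  leave nothing to score in a small panel) rather than aborting the run;
  constant predictors error in direct calls.
* `ld_prune()` drops on $r^2 >$ threshold (strict); at threshold 1.0 exact
  duplicate columns are still pruned, the one sensible reading of that
  boundary.
* Replicate suite sizes are the package's choices: null calibration uses
  2000 independent simulate→score→associate chains at $n=500$ on a small
  panel (5 genes × 3 SNPs + 5 decoys), giving a binomial SE of ~0.005
  around 0.05; recovery uses 200 chains at $n=5000$ with a planted
  incremental $r^2$ of 0.02 (10 genes × 3 SNPs); oracle-equivalence suites
  use 100 randomized instances each. The brute-force oracles (double-loop
  scoring, all-pairs interval scan) are separate code paths from the
  matrix-algebra and `GenomicRanges` implementations they check.
* For the recovery suite the score uses all harmonized variants
  ($P<1$), so the fitted score is an affine image of the planted score and
  the estimate isolates the phenotype model rather than threshold
  attrition.

## Known limitations

Hard-call genotypes only; fixed-effect meta-analysis only; the outlier rule
is a single-pass z-screen; the ANOVA of scores by diagnosis group is
unadjusted for covariates (the follow-up published alongside such analyses
is typically descriptive); no transcript-level window resolution or
cross-build liftover.
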