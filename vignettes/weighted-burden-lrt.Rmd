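---
title: "Weighted-burden likelihood ratio tests: model, design choices, and simulation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-burden likelihood ratio tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wblrt)
```

## The testing problem

Rare-variant association studies collapse the variants of a gene into a
per-sample *burden score*

$$S_{k} = \sum_{i=1}^{n_j} s_i\, x_{ik},$$

where $x_{ik} \in \{0,1,2\}$ is the minor-allele dosage of variant $i$ in
sample $k$ and $s_i$ a per-variant weight. With $m$ cases and $l$ controls,
fix a threshold $t$ and let $T_A$ and $T_U$ be the numbers of cases and
controls whose score strictly exceeds $t$, with proportions
$\hat p_A = T_A/m$, $\hat p_U = T_U/l$ and pooled $\hat p = (T_A+T_U)/(m+l)$.
The test statistic is a Bernoulli likelihood ratio,

$$\Lambda(t) = \log \frac{\hat p_A^{\,T_A} (1-\hat p_A)^{m-T_A}\,
  \hat p_U^{\,T_U} (1-\hat p_U)^{l-T_U}}
  {\hat p^{\,T}(1-\hat p)^{\,m+l-T}},$$

maximized over the grid of unique observed score values
(`maximize_lrt()`). The grid needs no other points: any threshold between
two consecutive unique scores produces identical exceedance counts. The
statistic is invariant to strictly increasing transforms of the scores, is
non-negative, and is zero exactly when $\hat p_A = \hat p_U$.

Three weight choices give the three tests:

* **LRT** — unit weights $s_i = 1$ (the classic burden);
* **LRT-DIR** — signs $s_i = +1$ when the variant's minor-allele frequency
  in cases is at most that in controls, $-1$ otherwise
  (`direction_weights()`), so protective and deleterious variants no longer
  cancel in the sum;
* **LRT-BS** — annotation magnitudes, by default 10 for non-synonymous
  variants on predicted protein-binding sites, 5 for other non-synonymous
  variants and 1 for the rest (`annotation_weights()`, scheme
  `"bs-10-5-1"`).

P-values come from gene-specific label permutation only; no asymptotic
reference distribution is used anywhere.

## The swapped-estimate branch and why the default is the symmetric form

The formulation this framework adapts prescribes, for configurations with
$\hat p_A \le \hat p_U$, replacing the numerator by a *swapped* version in
which cases are evaluated at $\hat p_U$ and controls at $\hat p_A$
(`lrt_at_threshold(..., mode = "direction-adjusted")`). Both branches are
implemented exactly as written. However, the swapped numerator can never
exceed the pooled denominator — over an exhaustive grid of count
configurations its log-ratio is bounded above by zero — while the threshold
grid always contains configurations with $\Lambda = 0$ (nobody exceeds).
A maximization over thresholds therefore never selects a swapped-branch
value, and a statistic using that branch is blind to control-enriched
burdens. Direction weighting deliberately *creates* control-enriched
burdens (its sign convention points every apparent effect toward controls),
so combining it with the swapped branch would discard precisely the signal
the weights align.

For that reason the pipelines for LRT-DIR and LRT-BS default to the
label-symmetric form — the plain $\Lambda$ above at every grid point, which
already satisfies $\Lambda(T_A,m,T_U,l) = \Lambda(T_U,l,T_A,m)$ and thus
tests unevenness in both directions — and expose the adjusted branching as
`mode = "direction-adjusted"` for users who want the one-sided
(case-enrichment only) behavior. The package's power results for
direction weighting depend on this choice; with the adjusted branch as
default the direction-weighted test has essentially no power by
construction.

Numerical conventions: natural logarithms; $0 \cdot \log 0 = 0$ in every
likelihood factor; a positive count against a zero swapped estimate
evaluates to $-\infty$, which is representable and never wins the
maximization; threshold ties break toward the smallest threshold, making
results deterministic.

## Permutation: gene-specific, two-stage, refit inside each replicate

Each gene's p-value is the add-one estimator
$(1 + \#\{\Lambda^{(b)} \ge \Lambda_{\text{obs}}\})/(1 + B)$ over $B$ label
permutations, with ties counted in the numerator; both choices guarantee
validity for any statistic. Permuting labels (rather than genotypes)
preserves the within-gene variant dependence.

Two details matter:

* **Early stopping.** Permutation stops at $B_1$ replicates (default
  1,000) unless the interim p-value is below the 0.1 gate, in which case it
  continues to $B_2$ (default 10,000). The stage-1 replicates are the
  prefix of the stage-2 stream, so a gene that reaches stage 2 reports
  exactly the single-stage $B_2$ p-value — a property the test suite checks
  replicate-for-replicate.
* **Refitting fitted weights.** Direction signs are functions of the
  labels, so they are recomputed from the permuted labels inside every
  replicate. Freezing the observed signs is a subtle and tempting bug that
  makes the null distribution too light-tailed; the suite contains a
  deliberate frozen-weights implementation as a regression contrast and
  verifies it is anti-conservative while the refitted engine is calibrated.
  Annotation weights do not depend on labels and stay fixed.

Per-gene seeds derive from a master seed and the gene symbol
(`derive_seed()`), so results are independent of processing order and all
methods — including the CMC and C-alpha comparators — consume identical
permutation streams, making p-values comparable replicate-for-replicate.
For cohorts small enough to enumerate, `exact = TRUE` replaces sampling
with all $\binom{n}{m}$ label assignments.

## Comparators

**CMC** collapses variants with MAF below 1% (flag-controlled; the original
method is cited without a threshold) into a carrier indicator, keeps common
variants as dosage columns, and compares group mean vectors by Hotelling's
$T^2$ with a pooled covariance. When the mean difference leaves the
covariance column space (perfect separation), the statistic is $+\infty$,
which the permutation ranking handles naturally. **C-alpha** tests
overdispersion of per-variant case allele counts around the binomial
expectation; its primary p-value is also permutation-based, with the normal
approximation $Z = T/\sqrt{c}$ reported for reference only, never for
ranking.

## What the simulator emulates — and what it does not

`simulate_cohort()` emulates an exome-sequenced case-control cohort of the
kind used to evaluate weighting schemes: order $10^2$–$10^3$ cases against
a larger control group, genes carrying a handful to dozens of rare
variants, and incomplete functional annotation.

* **MAF spectrum**: Beta(0.5, 8) truncated to (0.001, 0.05). The source
  cohort inherited its spectrum from real exomes and never states one; this
  choice concentrates mass on rare variants while keeping enough carriers
  at $n \le 2000$ for thresholds to be informative. Chosen once, stated
  here, not revisited.
* **Genotypes**: Binomial(2, MAF) per sample — Hardy–Weinberg equilibrium
  and linkage *equilibrium*. Real exomes have LD; the permutation test
  accommodates it (labels are permuted, genotypes kept intact), but the
  simulator does not generate it. Passing simulation tests therefore says
  nothing about power under strong LD.
* **Phenotype**: logistic, $\text{logit}\,P(\text{case}) = c + \sum_i
  \beta_i x_i$ over causal variants, with $c$ calibrated on the realized
  genetic scores so the expected case fraction is 0.17 (echoing a cohort of
  roughly one case to five controls).
* **Effect sizes**: $|\beta| = \ln 3$ ("strong") and $\ln 1.3$ ("weak") per
  minor allele; the evaluated gene archetypes are strong-protective,
  weak, strong-deleterious, null, and a "cancellation" gene with balanced
  $\pm\ln 3$ effects — the configuration that defeats the unweighted
  burden and motivates direction weighting. The source work names real
  genes of these types but no numeric effect sizes; the magnitudes are this
  package's choice.
* **Annotation**: the first 10 causal variants by position are marked
  `functional`, later causal variants are left indistinguishable from the
  `rest` — reproducing the incomplete-annotation design under which the
  weight-scheme grid $\{2,5,10\} \times \{1,-1\}$ is evaluated
  (`weight_scheme_grid()`).

Degenerate inputs are results, not errors: a gene whose dosage columns are
all constant reports $\Lambda = 0$, $p = 1$ and a `degenerate` flag.
Missing genotypes default to the "as-ref" policy (missing = 0 minor
alleles), which is conservative for burden scores and keeps unit-weight
scores integer; per-variant mean imputation is available. Alleles are
re-oriented so dosages always count the minor allele, with flips logged.

## Problem sizes used by the checks

The package's own studies run at desk scale, chosen as the smallest sizes
at which the binomial acceptance bands are meaningful: type-I error uses
400 null gene-tests on cohorts of 500 samples with $B_1 = 200$,
$B_2 = 999$; the power studies use 100 replicates on cohorts of 1,000
samples with $B_1 = 99$, $B_2 = 999$. At these sizes the full study suite
completes in a few minutes. Empirical rates, inflation factors and power
contrasts are always computed at run time by `power_study()`,
`run_all_genes()` and `genomic_inflation()`; none are hard-coded.

```{r example, eval = FALSE}
cfg <- sim_config(list(gene_spec("CAN", "cancellation", n_variants = 20,
                                 n_causal = 10)),
                  n_samples = 1000, seed = 2)
power_study(cfg, methods = c("lrt", "lrt-dir"), alpha = 0.05,
            R = 100, B1 = 99, B2 = 999, seed = 7)
```

## Known limitations

* No covariates, no quantitative traits, no stratified permutation: the
  likelihood is a two-group Bernoulli comparison by construction.
* The genomic inflation factor is the median-$\chi^2_1$ definition;
  published inflation factors computed under other conventions (e.g.
  regression-based) are not directly comparable.
* Permutation p-values are discrete: with $B$ replicates no p-value can
  fall below $1/(1+B)$, and the add-one estimator is mildly conservative —
  visible as inflation factors slightly below 1 on null data.
* The simulator's independence assumptions (variants, samples) make its
  type-I and power estimates cleanest-case; real-data behavior under LD,
  relatedness or population structure is out of its scope.
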