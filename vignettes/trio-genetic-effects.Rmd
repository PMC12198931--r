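---
title: "Partitioning direct and indirect genetic effects in parent-offspring trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning direct and indirect genetic effects in parent-offspring trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triogen)
```

## The scientific problem

Heritability estimates from unrelated individuals conflate two distinct
pathways. A *direct genetic effect* is the effect of a child's own
genotype on their own phenotype. An *indirect genetic effect* (often
called genetic nurture) arises when a parent's genotype shapes the
environment the child experiences — parental behavior, home environment,
or even how a parent reports on the child's behavior. Because children
share half their genome with each parent, a naive genome-wide association
or SNP-heritability analysis cannot tell these apart.

With genotyped parent-offspring trios both pathways become identifiable.
`triogen` implements the two complementary within-family approaches used
for this problem:

1. **Trio variance components (GREML on trio relatedness blocks).** A
   linear mixed model partitions the phenotypic variance of the child's
   outcome into a direct component ($\sigma^2_c$), maternal and paternal
   indirect components ($\sigma^2_m$, $\sigma^2_p$), covariances between
   direct and indirect effects ($\sigma_{om}$, $\sigma_{op}$, and between
   the parents $\sigma_{mp}$), and residual variance ($\sigma^2_e$):
   $$\mathrm{Var}(Y) = \sigma^2_c + \sigma^2_m + \sigma^2_p +
     \sigma_{om} + \sigma_{op} + \sigma^2_e.$$
   The mother-father covariance is excluded from the total under random
   mating (expected mother-father relatedness 0), though the full model
   estimates it.
2. **Trio polygenic-score regression.** For a measured polygenic score
   (PGS), the child outcome is regressed jointly on the child's, mother's
   and father's scores plus covariates:
   $$Y = \beta_0 + \beta_1 \mathrm{PGS}_c + \beta_2 \mathrm{PGS}_m +
     \beta_3 \mathrm{PGS}_p + \beta_4 \mathrm{sex} +
     \beta_5 \mathrm{age} + \varepsilon,$$
   with $\beta_1$ read as the direct association and $\beta_2,\beta_3$ as
   indirect ones, cluster-robust standard errors over maternal IDs, and
   partial $r^2$ summaries for the direct versus indirect predictor
   groups.

Because individual-level cohort data of this kind are access-restricted,
the package ships a synthetic-data generator with the exact statistical
structure the estimators assume, and every claim the package makes about
its estimators is demonstrated on that generator by the test suite and
the acceptance script.

## The covariance model and its REML estimator

For $n$ trios indexed by the child, the phenotypic covariance implied by
the components is

$$V = \sigma^2_c A_{cc} + \sigma^2_m A_{mm} + \sigma^2_p A_{pp}
  + \sigma_{om}(A_{cm} + A_{cm}^\top) + \sigma_{op}(A_{cp} + A_{cp}^\top)
  + \sigma_{mp}(A_{mp} + A_{mp}^\top) + \sigma^2_e I,$$

where the $A$ blocks are slices of one genomic relatedness matrix (GRM)
computed over all individuals: `compute_grm()` standardizes dosages as
$z = (g - 2p)/\sqrt{2p(1-p)}$ and forms $A = ZZ^\top/m$;
`extract_trio_blocks()` slices the child-child, mother-mother,
father-father, child-mother, child-father and mother-father blocks in
trio order. Within-trio child-parent relatedness is $\approx 0.5$, so the
diagonal of $V$ carries $2 \sigma_{om} \cdot 0.5 = \sigma_{om}$ — which is
why each covariance parameter appears exactly once in the variance
decomposition above.

Four nested models are fitted (`fit_variance_components()`,
`fit_vc_ladder()`):

| model | free components |
|---|---|
| full | $\sigma^2_c, \sigma^2_m, \sigma^2_p, \sigma_{om}, \sigma_{op}, \sigma_{mp}, \sigma^2_e$ |
| no_covariance | $\sigma^2_c, \sigma^2_m, \sigma^2_p, \sigma^2_e$ |
| direct_only | $\sigma^2_c, \sigma^2_e$ |
| null | $\sigma^2_e$ |

Estimation maximizes the restricted likelihood,
$-2\ell_R = \log|V| + \log|X^\top V^{-1} X| + y^\top P y +
(n - p)\log 2\pi$ with
$P = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1}$. The additive
constant convention is fixed; only differences in $-2\ell_R$ are
comparable across software, and all model comparisons in the package use
differences.

Numerical choices:

* **Optimizer.** Average-information (AI) REML: the score uses exact
  traces $\mathrm{tr}(P\,\partial V/\partial\theta_i)$, the curvature
  uses the average-information approximation
  $\tfrac12 u_i^\top P u_j$ with $u_i = (\partial V/\partial\theta_i)Py$.
  Updates are step-halved whenever they would leave the positive-definite
  region or increase $-2\ell_R$. If AI iteration stalls, a Nelder-Mead
  pass on $-2\ell_R$ takes over. Convergence is declared when the change
  in $-2\ell_R$ falls below `tol` (default `1e-8`).
* **Starting values.** The phenotypic variance is split equally over the
  model's free *variance* components; covariances start at 0. This makes
  the initial $V$ positive definite by construction.
* **Constraints.** Estimation is unconstrained by default: negative
  variance estimates are allowed and flagged (`negative_variance`),
  avoiding boundary bias in downstream model comparison; `constrain =
  TRUE` clamps variances at zero for users who want classical
  non-negative estimates.
* **Standard errors** come from the inverse AI matrix at the optimum; a
  singular information matrix yields `NA` SEs rather than an error.
* **Degenerate inputs.** Fewer than 30 trios, rank-deficient fixed-effect
  designs and non-positive-definite covariance parameters are rejected
  with distinct conditions (`triogen_not_pd` separates indefinite
  parameters from optimizer failure).

Parameter counts follow the convention that `k` is the number of
fixed-effect columns plus free components, so `AIC = -2ll + 2k` and
`BIC = -2ll + k log(n)` reproduce published information criteria when the
published parameter counts are used. Likelihood-ratio tests between
adjacent models use the naive chi-square reference with df equal to the
difference in free-component counts — deliberately no boundary
half-mixture correction, matching how these nested trio comparisons are
reported in practice. P-values for each comparison level are adjusted
across outcomes by Benjamini-Hochberg (`bh_adjust()`, delegated to
`stats::p.adjust`).

`reanalyze_fit_stats()` applies exactly this chain to a table of reported
$-2\ell$ and parameter counts. The package bundles such a table
(`inst/extdata/neurodev_fit_stats.tsv`) for four nested models of six
mother-reported neurodevelopmental outcomes (inattention, hyperactivity,
language, motor, restricted/repetitive behaviors, social communication)
at age 3 in a Norwegian birth cohort; the test suite verifies that the
recomputed AIC values match the published ones exactly and the adjusted
p-value columns match at printed precision. Because the per-outcome
sample sizes behind the published BIC column are only known as a range
(16,518-16,565), BIC is verified to be recoverable to within 0.1 for some
sample size in that range rather than exactly.

## What the simulator emulates — and what it does not

`simulate_trio_genotypes()` draws parental genotypes at unlinked biallelic
SNPs in Hardy-Weinberg proportions (allele frequencies uniform on a MAF
range, default 0.05-0.5) and derives child genotypes by Mendelian
transmission (`mendelian_transmit()`): homozygous parents transmit their
allele with certainty, heterozygotes transmit either allele with
probability one half. A configurable fraction of mothers receive a second
child, producing sibling trios that share both parents and a maternal
cluster label.

`simulate_effect_sizes()` draws per-SNP effect triples
$(\beta_c, \beta_m, \beta_p)$ i.i.d. trivariate normal with covariance
$\Sigma_\beta / m_\mathrm{causal}$, so the genetic values built from
standardized genotypes have covariance structure $\Sigma_\beta$ in
expectation and the entries of $\Sigma_\beta$ *are* the variance-component
targets. One subtlety is deliberate: an off-diagonal entry such as
$\sigma_{om}$ is the decomposition parameter, which enters the phenotypic
variance once; the realized sample covariance between child and mother
genetic values is $\approx \sigma_{om} \times 0.5$ because it is scaled
by child-parent relatedness. The REML estimator recovers the parameter
$\sigma_{om}$, not the raw sample covariance, so simulator targets and
estimates live on the same scale.

`simulate_phenotypes()` assembles
$y = G_c + G_m + G_p + \text{fixed} + e$, standardizing dosages with the
same pooled allele frequencies as `compute_grm()` so that the simulation
bookkeeping and the estimator share one scale, records the realized
components exactly (their sum reconstructs `y` to machine precision), and
generates covariates (sex, age at questionnaire return on 3-4 years,
round-robin genotyping batch). `simulate_item_responses()` adds an
item-level questionnaire layer — latent value plus item noise,
discretized at ordinal thresholds, missing completely at random,
reverse-keyed items inverted — as a fixture for the scale-scoring rules.

Design choices, made once:

* No linkage disequilibrium: the estimators under test do not require LD
  and unlinked SNPs keep the variance bookkeeping analytic.
* No assortative mating: parents are drawn independently, matching the
  model's assumption of zero expected mother-father relatedness.
* $\sigma_{mp}$ defaults to zero in the generator, mirroring its
  exclusion from the variance total, but can be set.
* Genotype missingness is off by default; when enabled it is missing
  completely at random, and GRM construction mean-imputes.
* No population stratification, genotyping error, imputation dosage
  uncertainty, or rater-bias generative model.

Consequently, passing tests demonstrate estimator correctness under the
model's own assumptions. They do not show robustness to LD, assortative
mating, stratification, or differential parental reporting — on real
data those forces load partly on the indirect components, which is a
known interpretive caveat of this design, not of the implementation.

`simulate_trio_scores()` is a second, score-level generator used for
inference calibration: it draws parental PGS directly, builds the child
score as the mid-parent mean plus segregation noise, and optionally adds
sibling pairs sharing a cluster-level maternal environmental effect. For
checking cluster-robust coverage over hundreds of replicates, the
genotype layer would add runtime but no information.

## Scale scoring and transformation

`score_scale()` implements missingness-tolerant sum scoring: reverse-keyed
items are inverted first, then a child's score is the mean of available
items times the scale length. Children missing half or more of the items
receive a missing score: the inclusion rule is *strictly less than* 50%
missingness, so exactly 50% is excluded (the stricter of the two possible
readings; the threshold is configurable via `max_missing_fraction`).
`transform_scores()` optionally applies a square root for right-skewed
scales and z-standardizes over the analysis sample (children with
non-missing scores), so the fitted measures have mean 0 and SD 1 in
exactly the sample the models see. Constant scores and negative inputs
under the square root are rejected explicitly.

## Relatedness pruning

Cryptic relatedness between trios inflates variance-component estimates.
`prune_related()` builds the graph of individual pairs with relatedness
*strictly above* the threshold (default 0.1), excluding each trio's own
child-mother, child-father and mother-father pairs, and greedily removes
whole trios — at each step the trio covering the most remaining edges,
ties broken by smallest child ID — until no edges remain. This is a
greedy vertex-cover analogue chosen because it is deterministic,
reproducible and near-minimal in practice; published analyses of this
kind use external pruning tools whose internals vary. Note the
interaction with GRM noise: relatedness estimates have sampling standard
deviation $\approx 1/\sqrt{m}$ over $m$ SNPs, so thresholds near 0.1 are
only meaningful with several thousand SNPs; desk-scale examples with
hundreds of SNPs should use higher thresholds.

## Polygenic scoring and trio regression

`compute_pgs()` is the scoring step only (weight derivation from GWAS
summary statistics is out of scope): a weighted sum of effect-allele
dosages over SNPs matched by identifier, flipping dosage when the weight
table's alleles are swapped, skipping irreconcilable pairs with a
warning, and never attempting strand flips (the intended inputs are
strand-consistent). `genotype_pca()` supplies the top principal
components of the standardized dosage matrix, and
`residualize_standardize()` takes OLS residuals of the raw scores on PCs
and batch covariates, then z-standardizes — run separately within each
family role, since each role's score enters the regression as a distinct
predictor.

`fit_trio_pgs()` estimates the six-coefficient trio regression by OLS and
replaces the classical covariance with the clustered sandwich
$(X^\top X)^{-1}\left[\sum_g (X_g^\top e_g)(X_g^\top e_g)^\top\right]
(X^\top X)^{-1}$ scaled by $\frac{G}{G-1}\cdot\frac{n-1}{n-k}$. That
small-sample factor is the common default of standard cluster-robust
implementations; the estimator family is what matters, the exact
correction is configurable (`small_sample = FALSE`). Inference uses the
normal reference for z statistics and 95% intervals — appropriate for the
hundreds-to-thousands of clusters these models target, and switchable in
principle by users who need t-with-few-clusters corrections. With
singleton clusters the estimator collapses exactly to the HC1-type
heteroskedasticity-robust covariance, which the tests verify against the
`sandwich` package.

Partial $r^2$ uses the Wald form: $t^2/(t^2 + \mathrm{df}_{res})$ for one
coefficient and $qF/(qF + \mathrm{df}_{res})$ for a group of $q$, with
$F$ the cluster-robust Wald statistic divided by $q$ and
$\mathrm{df}_{res} = n - k$. This reduces to the squared partial
correlation in the classical homoskedastic case and is invariant to
invertible reparameterizations of the group. `fit_multi_trait()` puts all
traits' trio scores in one regression and evaluates the direct group (all
child scores) against the indirect group (all parental scores).
`fdr_grid()` applies BH within one family per coefficient role, of size
outcomes × traits — e.g. a 10-outcome × 5-trait grid is corrected as 50
tests per role.

## Problem sizes used by the tests and acceptance script

These are the package's documented study conditions:

* Parameter recovery: 2,000 trios × 1,000 causal SNPs × 20 seeds,
  no-covariance truth $(\sigma^2_c, \sigma^2_m, \sigma^2_p, \sigma^2_e) =
  (0.10, 0.10, 0.05, 0.75)$; mean estimates within ±0.02 of truth and
  truth inside ±2 SE in ≥ 90% of fits.
* Model selection: the same scenario for the
  no-covariance-vs-direct-only AIC contest (20 seeds); pure noise at 500
  trios × 500 SNPs for the null-model contest, a size at which the full
  ladder fits in about a second while leaving the AIC ranking unambiguous.
* Cluster-robust calibration: 500 maternal clusters, 30% with sibling
  pairs, maternal environmental SD 0.7, 500 replicates; coverage of all
  three PGS coefficients must fall in [0.93, 0.97].
* Oracle equivalence: 30-50-trio instances against a dense-formula
  likelihood oracle (1e-6) and a coarse grid search (1e-4).
* Simulator physics: 300 trios × 1,200 SNPs; zero Mendel violations,
  mean within-trio child-parent relatedness in [0.45, 0.55], mother-father
  relatedness within ±0.02 of zero.

## Known limitations

* Univariate outcomes only: no bivariate trio models, no sibling indirect
  components, no gene-environment interaction terms.
* Proportion SEs in `variance_proportions()` treat the total variance as
  fixed (component SE divided by the total) — a first-order
  approximation, not the delta method over the full covariance of
  components.
* The published-statistics reanalysis can reproduce AIC exactly but BIC
  only to within ~0.1, because the per-outcome sample sizes behind the
  published BIC values are reported as a range.
* Binary and ordinal outcome models for questionnaire subdomains are out
  of scope; the one-child-per-family sensitivity analysis is a row
  filter, not a distinct estimator.
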