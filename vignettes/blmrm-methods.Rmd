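---
title: "Testing allele-specific expression at the gene and SNP levels with blmrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing allele-specific expression at the gene and SNP levels with blmrm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blmrm)
```

## The problem

In a diploid cell the maternal and paternal copies of most genes are
expressed at similar levels.  Genes that deviate — imprinted genes,
X-inactivated genes, genes with cis-regulatory variants on one allele —
show allele-specific expression (ASE).  Allele-resolved RNA-seq quantifies
this: at every heterozygous SNP of a gene, reads can be assigned to an
allele, giving for gene $g$, SNP $j = 1, \dots, J_g$ and biological
replicate $k = 1, \dots, K$ a maternal count $y_{gjk}$ out of a total
$n_{gjk}$ (counts are assumed mapping-bias-corrected upstream; this package
starts from the count table).

Two questions matter, and they are distinct: does the gene as a whole
favour one allele, and does the allelic ratio *vary along the gene* (as it
does when only some transcript isoforms are imbalanced)?  Methods that pool
a gene's counts into one binomial test answer a blurred version of the
first question only, and ignore both SNP-level and replicate-level
variation — with typical designs of $K = 3$–$4$ replicates, that ignored
variation turns into false discoveries.

## The model

Each gene is modelled by a binomial logistic mixed regression:

$$y_{gjk} \sim \mathrm{Binomial}(n_{gjk},\, p_{gjk}), \qquad
\log \frac{p_{gjk}}{1 - p_{gjk}} = \beta_g + S_{gj} + R_{gk},$$

with fixed gene effect $\beta_g$ (log-odds of maternal expression), random
SNP effects $S_{gj} \sim N(0, \sigma^2_{sg})$ and random replicate effects
$R_{gk} \sim N(0, \sigma^2_{rg})$.  The two scientific hypotheses are
$\beta_g \ne 0$ (gene-level ASE) and $\sigma^2_{sg} \ne 0$ (SNP-level
variation of ASE).  Crossing them gives four candidate models
$m \in \{1,2,3,4\}$: neither, gene effect only, SNP variation only, both;
$\sigma^2_{rg}$ is free in all four.

Because $J_g$ and $K$ are small, per-gene estimates are unstable.  The
package therefore shares information across the genome through hyperpriors
$\beta_g \sim N(\mu, \sigma^2)$, $\sigma^2_{sg} \sim IG(a_s, b_s)$,
$\sigma^2_{rg} \sim IG(a_r, b_r)$, whose parameters are estimated once from
all genes (empirical Bayes).  Per gene, the four models are compared by
approximate marginal likelihoods and a uniform model prior; the posterior
probabilities of interest are $P(g \in \{2,4\})$ (gene ASE),
$P(g \in \{3,4\})$ (SNP variation) and $P(g \in \{4\})$ (both).

## Likelihood machinery

The random-effect integral of a gene is evaluated by a single Laplace
approximation: the complete-data log-density is strictly concave in
$(S, R)$, so its mode is found by damped Newton iteration (gradient
tolerance `1e-8`, cap 100 iterations; implemented in C++) and the
$(J_g + K)$-dimensional Gaussian correction is applied at the mode.
Components with zero variance are removed from the integral; with both
variances zero the expression is the exact binomial log-likelihood.  On
small genes ($J + K \le 6$, moderate counts and variances) the test suite
holds this approximation to within 0.05 log-units of adaptive Gauss–Hermite
quadrature.

Maximum-likelihood fits (`fit_ml()`) maximize this approximated likelihood
over the free parameters of each model by quasi-Newton search, with
variances on the log scale, multi-start over $\beta_0 \in \{0,
\text{pooled logit}\}$, and a zero-boundary rule: a variance whose optimum
falls below `var_floor` ($10^{-8}$) is set to zero and the reduced model
refit.  $\widehat{\mathrm{Var}}(\hat\beta_g)$ is the $(\beta, \beta)$
element of the inverse observed information over the free parameters
(equivalently the profile curvature); the choice of observed rather than
expected information is a design decision — the two agree to the accuracy
that matters here and the observed version is available directly from the
optimizer.

## Empirical-Bayes estimation

Hyperparameters are estimated from pseudo-adjusted counts
($y^* = y + 1$, $n^* = n + 2$, pulling boundary ratios off 0 and 1), full-model
fits and likelihood-ratio tests:

* $\mu, \sigma^2$: method of moments over the $\hat\beta_g$ of genes whose
  gene-level LRT is significant at Storey q-value $\le$ 0.05 (a degenerate
  spread is floored at $10^{-4}$).
* $(a_s, b_s)$: from the $\hat\sigma^2_{sg}$ of genes significant in the
  SNP-variance LRT; $(a_r, b_r)$: from the $\hat\sigma^2_{rg}$ of all genes.

For the inverse-gamma components the package does **not** fit the prior
directly to the variance MLEs.  A per-gene variance MLE with $d$ degrees of
freedom is noisy ($d \hat\sigma^2 / \sigma^2 \approx \chi^2_d$, with
$d_{sg} = J_g - 1$, $d_{rg} = K - 1$ as small as 1–3), and an inverse gamma
fit to the raw MLEs recovers the convolution of prior and noise — far too
dispersed.  Instead the default maximizes the compound marginal likelihood
of the MLEs (a scaled beta-prime distribution), which is exactly the
sampling model under which the shrinkage estimators below are posterior
summaries.  MLEs sitting on the zero boundary (the optimizer's atom at
zero, which the smooth compound model cannot represent) are excluded; this
is the profile maximum likelihood of a zero-inflated mixture whose atom
probability is free, and on simulated genomes it clearly beats both
replacing zeros by an arbitrary floor (the inverse-gamma likelihood depends
on $1/x$, so a point mass at a tiny floor dominates the fit) and treating
them as left-censored draws of the smooth model (which assigns the
censoring region essentially no mass and contorts the fit to explain a
~30% atom).  The direct fit remains available (`ig_method = "direct"`), as
does the floor rule (`zero_rule = "floor"`), for comparison.

Given hyperparameters, each gene's full-model fit (raw counts) is shrunk:

$$\tilde\beta_g = \frac{\widehat{\mathrm{Var}}(\hat\beta_g)\,\hat\mu +
\hat\sigma^2 \hat\beta_g}{\widehat{\mathrm{Var}}(\hat\beta_g) +
\hat\sigma^2}, \quad
\tilde\sigma^2_{sg} = \frac{d_{sg}\hat\sigma^2_{sg} + 2\hat b_s}
{d_{sg} + 2\hat a_s}, \quad
\tilde\sigma^2_{rg} = \frac{d_{rg}\hat\sigma^2_{rg} + 2\hat b_r}
{d_{rg} + 2\hat a_r}.$$

## Model selection and the prior factors

Model $m$'s marginal likelihood is approximated by entering the shrunken
estimates into the full model-averaging integrand and Laplace-integrating
only the random effects:

$$P(\mathbf{y}^g \mid m) \approx
\Big[\int P(\mathbf{y}^g \mid \tilde\beta_g, \mathbf{b})
P(\mathbf{b} \mid \tilde\sigma^2_{sg}, \tilde\sigma^2_{rg})\,
d\mathbf{b}\Big] \times \pi(\tilde\theta_m),$$

where $\pi(\tilde\theta_m)$ is the prior density of the parameters model
$m$ includes: $N(\tilde\beta_g; \hat\mu, \hat\sigma^2)$ when the gene
effect is present, $IG(\tilde\sigma^2_{sg}; \hat a_s, \hat b_s)$ when SNP
variation is present, and $IG(\tilde\sigma^2_{rg}; \hat a_r, \hat b_r)$
always (the last is common to all four models and cancels).  These factors
matter: they are the Occam penalty of the richer models.  Dropping them
(`include_prior = FALSE`) makes the plug-in marginal of a model that
contains a fitted parameter at least as large as that of the model without
it, which destroys the calibration of the posterior probabilities and
inflates the true FDR well past its nominal level.  With the factors
included, the empirical-Bayes route closely tracks the full nested-Laplace
integration (below) at a fraction of its cost.

Posteriors are normalized by log-sum-exp under a uniform (configurable)
model prior.  Significance is declared by the Bayesian FDR rule: order
genes by decreasing posterior probability of the tested hypothesis and take
the largest prefix whose mean posterior error probability is at most
$\alpha$; ties keep input order, and the rule is monotone in $\alpha$.

A comparator (`laplace_only = TRUE`) instead integrates the model
parameters against their priors by nested Laplace approximation (inner:
random effects; outer: $(\beta_g, \sigma^2_{sg}, \sigma^2_{rg})$ on their
original scale, where the inverse-gamma densities vanish at zero so the
mode is interior).  The order of nesting — parameters outermost — was an
open design choice; it is a comparator, not the method of record, and is
noticeably slower.

## Baselines

* Pooled exact binomial test of $p = 0.5$ on $\sum y$ out of $\sum n$ —
  ignores all variance components.
* Empirical-logit location test: one-sample $t$/F test that the mean of
  $\log\{(y + 0.5)/(n - y + 0.5)\}$ across cells is zero — the gene-effect
  analogue of ANOVA-style pipelines; its exact design matrix in those
  pipelines is not public, so this is a documented analogue and a
  comparator only.
* Plain GLMM likelihood-ratio tests: model 4 vs 3 ($\chi^2_1$) for the gene
  effect; model 4 vs 2 for SNP variance and 4 vs 1 for the joint test, with
  50:50 boundary mixtures ($\chi^2_0{:}\chi^2_1$ and
  $\chi^2_1{:}\chi^2_2$) because the null variance sits on the boundary.
* Storey q-values ($\pi_0$ by the df-3 spline smoother on
  $\lambda = 0.05, \dots, 0.95$) for all frequentist baselines.

## The synthetic-genome generator

`simulate_genome()` emulates an allele-resolved bovine-liver-like count
table with known truth: equal blocks of genes from the four models; gene
effects drawn uniformly from $\{\pm 0.41, \pm 1.20, \pm 4.39\}$ (the
10th/50th/90th percentiles of significant gene effects in the motivating
tissue); $\sigma^2_{sg} \sim IG(2.35, 1.37)$ and $\sigma^2_{rg} \sim
IG(2.03, 0.09)$ (estimates from that tissue); $K = 4$ replicates.

Counts follow a two-level log-normal hierarchy tied to the fitted
log-linear relations between mean and SD of counts (intercept/slope
$-0.36/0.97$ across SNPs within a gene, $-0.53/0.77$ across replicates
within a SNP).  Two readings of those relations are implemented.  The
default (`snp_sd_mode = "count-sd"`) treats $\exp(\alpha_1 + \alpha_2 \log
\bar n)$ as the count-scale SD — which is what a regression of $\log
S(\bar n)$ on $\log \bar n$ predicts — and converts it to the matching
log-normal `sdlog`; with the stated coefficients this gives a
coefficient of variation of roughly 0.65 across SNPs and 0.25 across
replicates, resembling real tables.  The literal reading
(`snp_sd_mode = "literal"`), which uses $\alpha_1 + \alpha_2 \log \bar n$
directly as the log-scale SD, yields log-SDs above 3 at typical depths and
produces astronomically large counts (beyond $10^{15}$), so it is not the
default and caps counts at `count_cap` for representability.

Where the original study resampled per-gene depths and SNP counts from
real data, the generator uses stand-ins chosen once: $\bar n_g$ log-normal
with median 50 and a heavy right tail (`sdlog = 1.2`), and $J_g$ from a
negative-binomial-shaped frequency table with mode 2–5 and a tail to ~50
SNPs.  Simulated values are exponentiated, rounded half away from zero and
floored at one read; derived SDs are floored at 0.01.  Each simulation
replicate uses a deterministic sub-stream of the base seed, so a
configuration and replicate index reproduce a genome byte for byte.

What the generator does *not* emulate: mapping bias and its correction,
correlated SNPs within haplotype blocks, missing cells (all cells are
observed), library-size differences between replicates beyond the
log-normal spread, and the empirical joint distribution of depth and SNP
count of any particular tissue.  Passing operating-characteristic tests on
these genomes therefore shows the statistical machinery behaves as designed
under the stated generative conditions, not that identical error rates
will be observed on a particular real dataset; with a heavier-tailed depth
distribution than the real tissue, all methods (the baselines most
visibly) run somewhat more liberal than the reference study reports.

## Desk-scale study sizes

The packaged operating-characteristic checks run the study at 1000 genes
(250 per model) with 3 simulation replicates, and verify: near-nominal FDR
of the posterior-probability rule for all three hypotheses; gross FDR
inflation of the pooled binomial test (gene level) and of the plain GLMM
(joint test); power and partial-AUC ordering over the binomial test; and
hyperparameter recovery.  `scripts/acceptance.R` recomputes the headline
quantities at the same scale.  A full-size run (4000 genes, 10 replicates)
uses the same code path with a larger `sim_config()`.

## Numerical choices and degenerate inputs

* Inner Newton: tolerance $10^{-8}$, 100 iterations, step halving;
  non-convergence is flagged and the best iterate used.
* Outer optimization: `L-BFGS-B` with box bounds ($|\beta| \le 25$,
  $\sigma^2 \in [10^{-12}, 50]$); boundary refits as above.
* Posterior probabilities are clamped to $[0, 1]$ after log-sum-exp;
  all-$-\infty$ marginals are an error (pathological gene).
* Genes whose full-model fit fails fall back to the richest reduced model
  with a free gene effect; a gene with no usable fit yields an `NA` row and
  is excluded from FDR ordering.
* Ratio constancy in filtering uses exact cross-multiplication of integer
  counts, never floating-point division.
* `storey_qvalues()` falls back to $\pi_0 = 1$ (pure Benjamini–Hochberg
  scaling) when fewer than 20 p-values are available.

## Known limitations

* Inference is per-gene conditional on genome-wide hyperparameters; the
  uncertainty of the hyperparameter estimates themselves is not propagated.
* The SNP-variance test loses calibration when most genes have only 2–3
  SNPs *and* sequencing depth is very high, because a point estimate of
  $\sigma^2_{sg}$ then carries 1–2 degrees of freedom against thousands of
  reads.
* Per-SNP effect estimates (BLUPs) are exposed only as diagnostics and are
  untested.
* The real-data hyperparameter values quoted above depend on upstream read
  processing; reproducing them requires the original alignments and is out
  of scope for the packaged tests.
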