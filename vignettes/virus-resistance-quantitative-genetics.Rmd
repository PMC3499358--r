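---
title: "Quantitative genetics of virus resistance in inbred line panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of virus resistance in inbred line panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Panels of near-fully homozygous inbred lines — the Drosophila Genetic
Reference Panel (DGRP) being the canonical example — are a workhorse for
dissecting the genetic architecture of disease susceptibility. Flies from
each line are infected (here, injected with a virus) in small groups
("vials"), and either their survival is followed day by day or the infected
fraction per vial is scored. Because every line is genotyped once and
phenotyped many times, between-line variance estimates genetic variance, and
a genome-wide association scan can be run on line means.

`viroquant` implements this analysis chain end to end: a synthetic-data
generator with exactly the statistical structure the models assume, Bayesian
variance-component estimation, permutation-thresholded association scans,
multi-SNP models for loci in linkage disequilibrium, and the calculus that
converts an estimated locus effect into variance explained, including
projections to outbred populations under dominance.

# Models

## Gaussian nested model (survival traits)

For per-fly survival time $y_{ijk}$ of fly $k$ in vial $j$ of line $i$:

$$y_{ijk} = \beta + b_i + c_j + \varepsilon_{ijk},$$

with $b_i \sim N(0, V_{line})$, $c_j \sim N(0, V_{vial})$ and
$\varepsilon \sim N(0, V_r)$. All full conditionals are conjugate, so
`fit_gaussian_nested()` uses a plain Gibbs sampler. Because the model is
nested, each sweep needs only per-vial sufficient statistics; a panel of 200
lines with 4 vials of 10 flies runs a default two-chain fit in seconds.

## Binomial logit model (infection traits)

For vials scored as infected/uninfected counts, the per-vial count is
binomial with

$$\mathrm{logit}(p_{ik}) = \beta + b_i + \varepsilon_{ik},$$

where the vial-level residual $\varepsilon_{ik} \sim N(0, V_{od})$ captures
overdispersion — extra-binomial heterogeneity between vials.
`fit_binomial_logit()` updates the latent effects and $\beta$ with adaptive
random-walk Metropolis steps (tuned to roughly 44% acceptance during
burn-in) and the variances with conjugate inverse-gamma updates. The
sampler's stationary law is checked in the test suite by parameter-recovery
simulations and by agreement with maximum-likelihood fits from `glmmTMB` on
the same data.

## Multivariate binary model (genetic correlations)

To estimate genetic correlations across viruses measured on different
scales, all traits are reduced to vial-level binomial responses: survival
traits are binarized at a single observation day (dead/alive by day $d$),
and line effects become a per-line vector $\mathbf{b}_i \sim
N(0, \Sigma_G)$ with an unstructured covariance matrix, updated by a
conjugate inverse-Wishart step. The day is not dictated by the model; by
default `binarize_survival()` picks the day at which pooled mortality is
nearest 50%, which maximizes binomial information, and the choice is
overridable.

The genetic correlation between traits is computed per posterior draw,
$r = \Sigma_{ij}/\sqrt{\Sigma_{ii}\Sigma_{jj}}$, and its "MCMC p-value" is
$2\min(\Pr(r>0), \Pr(r<0))$ over the draws, floored at $2/n_{draws}$
(a sign-concentration measure, not a frequentist tail probability).

## Heritability and evolvability

Inbred lines are homozygous, so for additive loci the between-line variance
is twice the additive genetic variance of a random-mating base population:
$V_g = V_{line}/2$, applied per draw. Heritability is

$$h^2 = \frac{V_g}{V_g + V_{vial} + V_r} \quad \text{(observed scale)},
\qquad
h^2 = \frac{V_g}{V_g + V_r + \pi^2/3} \quad \text{(logit scale)},$$

where $\pi^2/3$ is the variance of the standard logistic distribution
implicit in the link. The coefficient of genetic variation,
$CV_g = 100\sqrt{V_g}/\beta$, is only computed for observed-scale traits
with a positive mean; for proportions analysed on a logit scale the trait
mean is not a meaningful standardizer and `cvg()` refuses.

All nonlinear summaries ($h^2$, $r$, $CV_g$) are computed per draw and then
averaged — a posterior mean of a ratio, not a ratio of posterior means. The
two differ slightly; this is why plugging point summaries of the components
into the $h^2$ formula reproduces published heritabilities only to about
0.01.

## Priors

Variance components get inverse-gamma priors parameterised by
$(\nu, V)$ (shape $\nu/2$, rate $\nu V/2$), default $\nu = 1, V = 1$ — a
weakly informative proper prior. Improper flat priors are retained behind
`mcmc_config(improper = TRUE)`, but with few levels (few vials per line, or
a small panel) they can produce improper or prior-dominated posteriors, so
the proper prior is the default. The line-effect covariance matrix gets an
inverse-Wishart prior with $\nu_0 = \nu + T$ and scale $V I_T$.

Convergence is reported per parameter: effective sample size (Geyer initial
positive sequence estimator) and a split-chain potential scale reduction
factor. Default chains are 20,000 iterations, 5,000 burn-in, thinning 10,
two chains — sized for panels of one to a few hundred lines. Final analyses
on large panels should scale these up (everything is configurable through
`mcmc_config()`).

# The association scan

`collapse_to_line_values()` reduces vial data to one susceptibility value
per line: the fly-count-weighted mean survival, or the pooled infected
proportion with an optional arcsine-square-root transform (which removes
the dependence of a proportion's variance on its mean; it is per-trait
configurable). The weighting enters the line mean; the regression on line
values is unweighted, mirroring how line-mean GWAS are usually run.

`filter_sites()` first sets within-line segregating calls to missing (a
residually heterozygous site in an inbred line is not a usable genotype),
then keeps sites that remain biallelic with the minor allele in at least 4
lines. `scan_assoc()` codes homozygotes $-1/+1$ so the regression slope
estimates $a$, half the difference between homozygote classes. Missing
genotypes are dropped per site (casewise); only the joint multi-SNP models
use listwise deletion, where a common line set is required.

Genome-wide significance comes from permutation: the line values are
shuffled across lines, the full scan is rerun, and the genome-wide minimum
p-value recorded; 400 permutations and the empirical $\alpha$-quantile
(type-7 interpolation) give the threshold. Covariate genotypes in
conditional scans stay attached to their lines — only the phenotype vector
is permuted — so the threshold is conditional on the covariate structure.
The same permutation scans provide the QQ null expectation: the $k$-th
observed order statistic of $-\log_{10} p$ is paired with the mean $k$-th
order statistic across permutations.

`joint_fit()` fits all listed sites simultaneously and reports each site's
marginal (drop-one) F-test; `sequential_fit()` reports ANOVA-table tests in
a stated order. Perfectly correlated sites cannot be separated by any
model; they are reported as aliased rather than given p-values, and the
marginal tests are computed in the reduced full-rank model.

No kinship or population-structure correction is implemented: line-mean
GWAS in inbred panels are commonly run without one, and an inflation of
small p-values that such structure can cause is visible in the QQ output
rather than silently absorbed.

# Variance explained and dominance projections

A scan or joint-model effect $\hat a$ overstates $a^2$ by its sampling
variance, so the bias-corrected squared effect is
$\hat a^2 - \mathrm{SE}(\hat a)^2$, floored at zero (`unbiased_a2()`).
Under random mating and additivity a biallelic locus with allele
frequencies $p, q$ contributes $2pqa^2$ to additive variance
(`locus_additive_variance()`), and its share of heritability is
$2pqa^2 / V_g$ — the denominators of $h^2$ cancel, so adjusting the
numerator is equivalent (`proportion_heritability()`). Summing loci assumes
linkage equilibrium; a pairwise genotype correlation above 0.2 triggers a
warning. Allele frequencies are computed over genotyped lines only, and the
resistant orientation is set by the sign of $\hat a$ together with the
trait direction (higher survival, or lower infection, is resistant); a zero
effect is flagged as an orientation tie.

Inbred panels cannot estimate dominance, but its possible effect on
outbred populations can be bracketed. With dominance deviation
$d = d_{ratio} \cdot a$, the average effect of an allele substitution is
$\alpha = a(1 + d_{ratio}(q - p))$ and the locus contributes
$2pq\alpha^2$ of outbred additive variance. `outbred_va_projection()`
combines this with an assumed fraction of the remaining genetic variance
that is additive and returns the locus share of outbred $V_a$. Dominance
variance $(2pqd)^2$ is deliberately excluded: the projection concerns
additive variance only.

The scenario is specified numerically as $d_{ratio} \in [-1, 1]$ rather
than verbally ("resistant allele dominant/recessive"), because verbal
dominance statements are easy to invert — the same biological scenario can
be phrased from either allele's perspective. The implementation is pinned
instead to a brute-force oracle: enumerating Hardy–Weinberg genotype
frequencies $(p^2, 2pq, q^2)$ with values $(a, d, -a)$ and regressing value
on allele count reproduces $2pq(a + d(q-p))^2$ to $10^{-10}$
(`hwe_additive_variance()`), and the test suite requires the closed-form
projection to match it across a grid of $(p, a, d)$.

# The synthetic-data generator

`generate_panel()` emulates a DGRP-like panel: fully homozygous lines
(codes 0/2), minor-allele frequencies drawn from a beta law folded onto
$(0, 0.5]$ (default shapes $(1, 3)$, skewed toward rare variants, as site
frequency spectra are), missing calls and within-line segregating calls at
configurable rates (defaults 3% and 1%), and linkage disequilibrium from a
first-order Markov process: each site copies the previous site's
line-assignment pattern with probability `ld_copy_prob` (default 0.8),
giving monotone LD decay with distance. This is the simplest process with
tunable LD; it produces blocks of perfectly correlated sites rather than
the gradual $r^2$ decay of real recombination, so analyses must tolerate
perfect proxies — which is precisely what the aliasing handling and the
"top hit or a perfect-LD copy" acceptance check exercise.

Trait simulators mirror the fitted models exactly: per-fly survival
$\beta + \text{causal} + b_i + c_j + \varepsilon$, or per-vial infected
counts with a logit-linear probability. Causal loci act through the true
(pre-masking) genotypes; homozygote classes sit at $\pm a$, so a locus at
frequency $p$ contributes $4pqa^2$ to the between-line variance of line
genetic values — twice its outbred additive contribution, the inbred-line
doubling that motivates $V_g = V_{line}/2$. The default design is 4 vials
per line and 15 flies per vial; flies per vial in real experiments vary
and the value is configurable. Survival is continuous by default, with
optional rounding to whole nonnegative days to mimic daily observation.

What the generator does *not* emulate: recombination maps, selection,
demography, population structure, batch/day effects, or the empirical LD of
any real panel. A passing recovery test therefore demonstrates correctness
of the estimators under the models' own assumptions, not robustness to the
ways real panels violate them (notably structure-driven p-value inflation).

Every simulation writes a truth manifest (model, seeds, realized line
genetic values) that round-trips through a flat text representation, so
recovery tests always score against the realized truth.

# Numerical conventions and edge cases

* Credible intervals are 95% highest-posterior-density intervals
  (shortest window containing 95% of draws).
* Moment (expected-mean-squares) estimates of the nested ANOVA use
  Searle's unbalanced-design coefficients; negative solutions are truncated
  at zero and flagged. They serve as a fast deterministic cross-check: on
  balanced designs of 200 lines the MCMC posterior means agree with them
  within 10%.
* Designs with one vial per line everywhere make $V_{vial}$ inestimable;
  it is fixed at zero with a warning rather than silently estimated.
* A single genotyped line, traits sharing no lines, negative variances, and
  positions below 1 are rejected with informative errors.
* Permutation thresholds warn below 20 permutations (unstable quantiles).
* Genotype codes: 0 = homozygous reference, 2 = homozygous alternate,
  1 = within-line segregating, −1 = missing; 1-based `chrom:pos` site ids
  throughout.
* Every pipeline artifact is stamped with the master seed and the MD5 of
  the configuration that produced it, and rerunning an identical
  configuration reproduces every output byte for byte.

# Problem sizes used in the test suite

The shipped tests run the full chain at reduced but structurally faithful
sizes, chosen to keep a complete run in a couple of minutes: variance-
component recovery at 185–200 lines × 4 vials (the published panel scale)
with shortened chains, family-wise-error calibration on a 150-line ×
2,000-site panel with 400 permutations and 200 fresh null traits, joint-
model LD disentangling at $r^2 = 0.8$ over 100 simulations, and an
end-to-end positive control on a 200-line × 500-site panel with a planted
major-effect locus of $1.5\sigma$. Larger replications simply scale the
same code.

# Known limitations

* The binomial and multivariate samplers are random-walk Metropolis within
  Gibbs; for very sparse designs (few vials, tiny counts) mixing for
  $\beta$ is slow and the effective sample size reported should be heeded.
* No REML path for unbalanced multivariate designs; the multivariate model
  is binary-only by construction.
* Extrapolation from inbred panels to outbred populations is exact only
  under additivity; the dominance projections bracket, but cannot estimate,
  the bias.
* No imputation, no indels, no structure correction, logit link only.
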