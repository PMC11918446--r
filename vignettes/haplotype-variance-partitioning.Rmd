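---
title: "Partitioning maternal and fetal genetic variance with haplotype-based GRMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning maternal and fetal genetic variance with haplotype-based GRMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pregnancy-related outcomes - gestational duration, birth weight, birth
length, head circumference - are shaped by two genomes at once: the
mother's, acting through the intrauterine environment, and the child's,
acting directly. Because a mother transmits half of her alleles to her
child, an ordinary SNP-heritability analysis of either genome is
confounded: a purely maternal trait shows a spurious "fetal" heritability
of roughly one quarter of the maternal estimate (allele sharing 0.5,
squared), and vice versa.

This package resolves the confounding by treating the mother-child duo as
the analytical unit with three haplotypes:

* **m1** - maternal transmitted alleles, present in both mother and child;
* **m2** - maternal non-transmitted alleles, present only in the mother;
* **p1** - paternal transmitted alleles, present only in the child.

One genetic relatedness matrix (GRM) is built from each haplotype and all
three are fitted simultaneously in a linear mixed model, partitioning the
phenotypic variance into components attributable to each haplotype
(`h2_m1`, `h2_m2`, `h2_p1`). m2 captures exclusively maternal effects, p1
exclusively fetal effects, and m1 both - including their covariance. Two
comparator designs are provided: the conventional single-GRM analysis of
mothers' or children's genotypes, and the quadrant design that splits a
joint mother+child genotype GRM into a mothers' block (M'), a children's
block (G) and a symmetrized cross block (D) whose component estimates the
maternal-fetal effect covariance.

## The model

For genotype dosages `x_ij` (0/1/2) with reference-allele frequency `p_i`,
relatedness between individuals `j` and `k` is the average over SNPs of
`(x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`. For a haplotype the
allele count `c_ij` is 0/1 and the cell is
`(c_ij - p_i)(c_ik - p_i) / (p_i (1 - p_i))`. In matrix form each GRM is
`Z Z' / c` for a standardized panel `Z`, with `c` chosen so the expected
diagonal is 1 under Hardy-Weinberg equilibrium (`c = S` for unweighted
panels).

The phenotype model is `y = X b + sum_k u_k + e` with
`u_k ~ N(0, A_k sigma2_k)` and `e ~ N(0, I sigma2_e)`; for the haplotype
design the `A_k` are the M1, M2 and P1 GRMs. Variance components are
estimated by restricted maximum likelihood,

```
logL = -1/2 * ( log|V| + log|X' V^-1 X| + y' P y ),
V = sum_k sigma2_k A_k + sigma2_e I,
P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1
```

(additive constants dropped), maximized by average-information (AI)
updates after one EM warm-up step, with step-halving whenever a step would
leave the positive-definite region or decrease the likelihood. This is the
standard AI-REML scheme used throughout the GREML literature; the AI
matrix doubles as the sampling covariance of the estimates, and standard
errors of variance *fractions* follow by the delta method from the full
component covariance. Each iteration costs one `n x n` Cholesky inversion;
all traces and AI entries are assembled from `O(n^2)` products. Designs
with a single GRM are rotated into the GRM eigenbasis once, after which
every likelihood evaluation is `O(n p^2)` - this is what makes
replicate-level simulation studies cheap.

### Restricted vs unrestricted fits

In unrestricted mode (`bounded = FALSE`) genetic variance components may go
negative. That is deliberate for simulation work: it keeps null components
unbiased around zero and is essential for interpreting architectures with
negatively correlated maternal-fetal effects, where the m1 component truly
collapses to zero and noise must be allowed on both sides. Restricted mode
(`bounded = TRUE`) clamps negative genetic variances to `1e-8 * var(y)`,
holds them at the bound while the score points outward, and re-releases
them otherwise - except the quadrant cross component D, which estimates a
covariance and may legitimately stay negative in either mode. The residual
variance is always kept positive. Convergence is declared when the
log-likelihood moves by less than `1e-6` (a likelihood criterion, not a
parameter one, so components wandering on a flat ridge do not stall the
fit); non-convergence within `max_iter` is reported on the fit object, not
thrown.

## Tunable parameters

* `alpha` (default -1 for GREML): exponent tying per-SNP effect variance to
  allele frequency, `var(u_i) ~ w_i [p_i(1-p_i)]^(1+alpha)`. `alpha = -1`
  is the standardized-genotype convention; -0.25 is the usual choice for
  LD-adjusted models. Weights are applied as the square root of that factor
  on centered columns, so the stated variance model holds on the variance
  scale, and the GRM normalizer is adjusted to keep a unit expected
  diagonal.
* LD pruning threshold `r2_max` (default 0.98) and window (100 kb): only
  near-duplicate markers are removed for the equal-weight pruned model.
* LD weights: `w_i = 1 / (1 + local LD score)` within a 100-kb window - a
  simple inverse-LD-score scheme that down-weights redundant markers; this
  package does not solve the quadratic program used by solver-based
  weighting tools. All recovery results in this package use GREML
  (`alpha = -1`), where neither pruning nor weights play any role.
* Kinship cutoff (default 0.05): greedy removal of the most-connected
  individual until no pair exceeds the cutoff. Note the cutoff is only
  meaningful when it sits above the GRM noise floor (off-diagonal SD is
  roughly `1/sqrt(S)`); with small simulated panels a 0.05 cutoff is inside
  the noise and would decimate the sample.
* Principal components: 20 from the genotype GRM for the genotype-based
  designs, 10 per haplotype GRM (30 total) for the haplotype design. PCs
  default to off in simulation pipelines - the simulated population is a
  single homogeneous random-mating cohort, and including them changes
  replicate means by well under one replicate-SE (asserted in the tests) -
  and should be on for real cohorts.
* Allele frequencies default to mothers-as-founders (`(m1 + m2) / 2`
  averaged over duos); pooling all three haplotypes is available. At
  realistic panel sizes the two conventions give indistinguishable fits.

## The simulator

`simulate_duo_genotypes()` draws per-SNP reference frequencies uniform on
[0.01, 0.5], four founder haplotypes per duo as independent Bernoulli
draws (linkage equilibrium, random mating), and transmits one maternal and
one paternal haplotype per SNP with equal probability, so the m1/m2/p1
labels are known ground truth. Phenotypes are built as
`g = Z_m1 (u_m + u_f1) + Z_m2 u_m + Z_p1 u_f2` over the causal variants -
the maternal transmitted haplotype carries both the maternal and the fetal
effect, which is precisely the confounding the design untangles - with
standard-normal effects on standardized columns, optionally bivariate
normal across mother and fetus with correlation `rho`, and an imprinting
transform `u_f1 = (1 - I) u_f2` on a chosen fraction of causal variants.
The residual variance is set from the realized genetic variance as
`sigma2_e = var(g) (1/h2 - 1)` with `h2 = 0.5` by default, and replicates
add fresh residuals to fixed genetic values.

Closed-form expected fractions (`expected_fractions()`) follow from the
per-variant decomposition: a causal variant contributes
`E[(u_m + u_f1)^2] : E[u_m^2] : E[u_f2^2]` through m1 : m2 : p1. This
yields the canonical patterns - equal halves for purely maternal or purely
fetal traits, 2:1:1 for independent joint effects, 4:1:1 for fully
positively correlated effects, 0:1:1 for fully negatively correlated ones,
and 1:1:1 for fully correlated effects under complete maternal imprinting.

What the simulator does **not** emulate: linkage disequilibrium (an
optional block-copy mode exists solely to exercise the pruning and
weighting code), population structure or admixture, assortative mating,
genotyping or phasing error, imputation uncertainty, binary traits, and
X-chromosome inheritance. Passing recovery tests therefore demonstrate
correctness of the estimator under its own assumptions, not robustness to
the messiness of real cohort data.

## Monte-Carlo design of the recovery studies

Replicate fits that share one simulated genotype panel share its realized
relatedness structure, so their estimates are correlated and the replicate
mean retains a panel-level noise term that does not shrink with more
replicates (empirically, an SD of roughly 0.03-0.04 on a variance fraction
at 1,000 duos x 10,000 SNPs, and larger at smaller scale). A
200-replicate, 40-panel experiment during development confirmed the
estimator is unbiased (fetal-architecture means m1 0.258 +/- 0.010,
m2 -0.005 +/- 0.008, p1 0.246 +/- 0.009 against the 0.25/0/0.25
expectation). `recovery_study(n_panels = )` therefore spreads replicates
across independently simulated panels; the shipped recovery runs use 10
panels x 5 replicates at 1,000 duos x 10,000 SNPs x 1,000 causal variants
(`scripts/acceptance.R`) and 6 panels x 6 replicates at 500 x 2,500 x 500
(the test suite), sizes chosen so the Monte-Carlo error of each reported
mean is about 2-3 percentage points.

## Numerical choices and degenerate inputs

* Mendelian-inconsistent sites are masked per duo (not dropped panel-wide)
  and mean-imputed after centering, mirroring common GRM practice; per-pair
  SNP counts are still tracked for the GCTA `.grm.N.bin` output.
* Monomorphic SNPs cannot be standardized and are excluded with a warning.
* Multi-allelic VCF records are skipped with a warning; the model is
  biallelic.
* Unphased child genotypes are a hard error - transmission cannot be
  resolved - whereas phase is otherwise trusted as given (duo-aware phasing
  tools emit the maternal allele first; residual phasing error is out of
  scope).
* Identical GRMs in one design leave only their sum identifiable; the fit
  warns and the sum matches the single-GRM fit (asserted in the tests).
* Eigenvector covariates use a deterministic sign convention (largest
  absolute entry positive); degenerate eigenvalue ties at the cutoff warn
  that the returned basis is arbitrary within the tied subspace.
* GRM binary output is float32 by convention, so round trips are exact only
  to ~1e-7 relative.

## A worked example

```{r example}
library(hgcta)

cfg <- sim_config(n_duos = 500, n_snps = 2500, architecture = "joint",
                  n_causal = 500, rho = 1, h2_total = 0.5, seed = 1)
duos <- simulate_duo_genotypes(cfg)
sim <- simulate_phenotypes(duos, draw_effects(cfg), cfg)

fit <- run_design("HGCTA", duos, sim$phenotypes[, 1])
tidy(fit)
autoplot(fit)

# replicate-level recovery against the closed-form 4:1:1 expectation
rs <- recovery_study(cfg, designs = "HGCTA", n_panels = 2)
summary(rs)
autoplot(rs)
```

## Known limitations

* The haplotype design cannot by itself distinguish positively correlated
  maternal-fetal effects from parent-of-origin effects: both inflate m1
  relative to m2 + p1. Distinguishing them requires external information
  (e.g. trio designs).
* Interpretation assumes maternal-fetal additivity and a random-mating
  population; epistasis and gene-environment interaction are unmodeled.
* Trio extensions (paternal non-transmitted alleles), binary-trait
  liability transformations and X-chromosome handling are out of scope.
* The LD-weighting scheme is an inverse-LD-score heuristic, not an
  optimized weight solver; use it for relative, not absolute, comparisons
  across weighting models.
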