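---
title: "Maternal-effect Mendelian randomisation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal-effect Mendelian randomisation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maternalmr)
```

## The scientific problem

Does a maternal exposure during pregnancy — here, maternal adiposity —
causally change an offspring outcome such as birthweight? Observational
associations are confounded, and a naive Mendelian randomisation (MR)
using maternal genotypes is contaminated by a second pathway: the mother
transmits half her alleles to the child, so any *fetal* genetic effect of
the same variants on birthweight masquerades as a maternal effect.
`maternalmr` implements the summary-statistic machinery for maternal-effect
MR: harmonisation of GWAS summary statistics, decomposition of maternal
from fetal genetic effects, the ratio-based causal estimators with their
sensitivity suite, the individual-level mother–child conditional analysis,
and a synthetic mother–child population generator that makes every step
testable with known ground truth.

## Models

### Maternal/fetal decomposition (WLM)

Two marginal GWAS of birthweight exist for the same variants: on the
subject's *own* birthweight (fetal side) and on the subject's *offspring's*
birthweight (maternal side). Writing $\beta_M$ and $\beta_F$ for the
maternal and fetal genetic effects, allelic transmission with correlation
$1/2$ between maternal and fetal dosage gives the marginal expectations

$$E[\beta_{own}] = \beta_F + \tfrac12\beta_M,\qquad
  E[\beta_{off}] = \tfrac12\beta_F + \beta_M,$$

which `wlm_decompose()` inverts per SNP:

$$\hat\beta_M = \tfrac{4\hat\beta_{off} - 2\hat\beta_{own}}{3},\qquad
  \hat\beta_F = \tfrac{4\hat\beta_{own} - 2\hat\beta_{off}}{3},$$

with variances by the same linear combination, including an optional
sampling covariance between the two marginal estimates (non-zero when the
two GWAS share individuals; for a fully shared sample it equals
$\tfrac12\,se_{own}\,se_{off}$, the analytic value under genotype
correlation $1/2$). This weighted linear model is the linear approximation
of the full structural equation model; on mother–child pairs it is
equivalent to regressing the outcome jointly on maternal and child dosage
(`conditional_maternal_effect()`), and the package tests assert that the
two routes agree (correlation $> 0.95$ at 20,000 pairs).

### Causal estimators

For harmonised records with exposure beta $\beta_{x,j} \ge 0$ and
(WLM-adjusted) outcome beta $\beta_{y,j}$:

* **Wald ratio** $\theta_j = \beta_{y,j}/\beta_{x,j}$ with first-order
  standard error $se_{y,j}/|\beta_{x,j}|$. Exposure-side uncertainty is
  deliberately ignored, the standard first-order convention for strong
  instruments; the resulting undercoverage is negligible at the instrument
  strengths simulated here (checked by the coverage test).
* **Fixed-effect IVW**: inverse-variance-weighted mean of the ratios,
  algebraically the slope of a weighted regression of $\beta_y$ on
  $\beta_x$ through the origin with weights $1/se_y^2$ (asserted to 1e-10
  against that oracle). A multiplicative random-effects variant inflates
  the SE by $\sqrt{\max(1, Q/df)}$; point estimates are identical.
* **Cochran's Q / $I^2$**: $Q = \sum w_j(\theta_j - \hat\theta)^2$,
  $I^2 = \max(0, (Q - df)/Q)\times 100$.
* **MR-Egger**: weighted regression *with* intercept; the intercept is the
  directional-pleiotropy probe. SEs use multiplicative overdispersion
  floored at one, $\max(1, Q_{resid}/(n-2))$ — the common convention. A
  t-distribution option exists for small instrument counts (default off;
  p-values are two-sided normal throughout the package).
* **Weighted median**: orders ratios, forms standardised mid-point
  cumulative weights $p_j = (\sum_{i\le j} w_i - w_j/2)/\sum w$, and
  interpolates at $p = 0.5$; consistent while valid instruments hold
  $\ge 50\%$ of the weight. Its SE is a parametric bootstrap (default 1000
  seeded draws resampling both betas from their reported normals).
* **Radial MR**: response $\beta_y/se_y$ against $\beta_x/se_y$
  (first-order weights), origin regression for the IVW variant (its slope
  *is* the IVW estimate and its squared residuals sum exactly to Cochran's
  Q — asserted as an identity), intercept for the Egger variant. Each
  squared residual is referred to $\chi^2_1$; SNPs below `alpha` are
  flagged. The default `alpha = 0.05` is a per-SNP screen;
  `0.05/n_snps` is the Bonferroni family-wise choice used in the type-I
  error test.
* **Multivariable MR**: weighted regression of $\beta_y$ on $K$ exposure
  beta columns without intercept; each coefficient is a direct effect.
  $K = 1$ reduces exactly to IVW (multiplicative-random-effects SE). Rank
  deficiency is reported naming the offending columns.

### Harmonisation

Records are aligned per SNP: identical alleles kept; swapped alleles
negate the outcome beta and reflect its allele frequency; alleles matching
only after strand complementation are complemented first; anything else is
an allele mismatch. After matching, every record is oriented so the
exposure beta is non-negative (the exposure-increasing allele convention).
Palindromic SNPs (A/T, G/C) cannot be strand-resolved from labels; they
are excluded when either allele frequency is missing or within
`palindromic_eaf_window` (default 0.08) of 0.5, and otherwise resolved by
frequency agreement. The source analyses state the orientation convention
but not the palindromic rule, so the window is exposed as configuration.
Indels and multi-allelic rows are rejected at read time; column mapping is
explicit (`default_column_map()`), with no header guessing.

## The synthetic-data generator

`sim_config()` + `simulate_duos()` emulate the statistical structure the
analysis assumes, not any particular cohort:

* Maternal genotypes are Binomial(2, f) per SNP (Hardy–Weinberg); the
  child receives one allele drawn uniformly from the mother plus one
  paternal allele at population frequency (random mating). This yields the
  mother–child dosage correlation of 0.5 that the decomposition exploits
  (checked empirically to ±0.01 at n = 100,000).
* The exposure has unit variance ("SD units"). By default the supplied
  per-SNP effects are rescaled so the genetic score explains exactly
  `exposure_h2_target` of it; with `rescale_betas = FALSE` the betas are
  taken literally and the configuration errors out if the score variance
  reaches the unit target. The default target, 2.7%, is the variance the
  76 BMI instruments explain in their source GWAS; the corresponding
  figure for the 14 favourable-adiposity instruments is unmeasurable
  because the composite phenotype is not a single trait, so the same
  default is used for both shapes. The default effect-size ladder is the
  power law $\beta_j \propto j^{-1/2}$ — a few strong and many weak
  instruments, as GWAS instrument sets typically show.
* A single scalar mediator plays the fasting-glucose role:
  `mediator = exposure + G\,\delta + noise` with `mediator_noise_sd`
  (default 0.5) and optional per-SNP direct genetic effects $\delta$
  (`mediator_snp_effects`, default 0). The outcome routes
  `mediation_fraction` of the maternal causal effect through the mediator:
  $y = \theta\,[mf\cdot M + (1-mf)\,X] + G_c\beta_F + G\alpha + e$. With
  $mf = 1$, residualising the mediator removes the exposure–outcome
  association entirely (tested). The published mediation evidence (the BMI
  effect attenuating from 35 g to 14 g on glucose adjustment) motivates
  the default `mediation_fraction = 0.6`; it is illustrative, not a
  calibrated quantity. Non-zero $\delta$ is what makes multivariable-MR
  mediation identifiable — with $\delta = 0$ the SNP–mediator betas are
  exactly proportional to the SNP–exposure betas and the two-column design
  is collinear.
* Horizontal pleiotropy adds per-allele outcome effects $\alpha$ on the
  maternal dosage channel by default (a fetal channel is available to
  stress the decomposition), either balanced (alternating sign) or
  directional (one sign). Pleiotropic SNPs are spread evenly across the
  effect-size ladder so pleiotropy status is unrelated to instrument
  strength — the InSIDE condition holds by design.
* Outcome noise is scaled so the outcome variance is approximately one
  (floored at residual variance 0.1 for extreme configurations).
* All draws come from the config's mandatory seed in a fixed order;
  `make_two_sample_dataset()` derives distinct sub-streams for the two
  populations, so exposure- and outcome-side noise are independent and a
  fixed seed reproduces byte-identical datasets.

### The two-sample outcome design

`make_two_sample_dataset()` splits the outcome population into two
disjoint halves: children of the first half provide the own-birthweight
GWAS, mothers of the second the offspring-birthweight GWAS. This mirrors
the own-birthweight-only and offspring-birthweight-only sample classes the
WLM was designed to combine and makes the default `cov_own_off = 0`
exactly true. When both marginal GWAS are instead run on one shared
population, the analytic covariance $\tfrac12\,se_{own}\,se_{off}$ should
be supplied (as the cross-validation tests do).

### What the generator does not emulate

No linkage disequilibrium between instruments, no population
stratification or assortative mating, no dynastic pathways beyond the
explicit maternal and fetal channels, no case–control ascertainment, no
missing genotypes, and a single scalar mediator. Passing tests therefore
demonstrate correctness of the estimators under the model's own
assumptions; they do not certify behaviour under LD-correlated instruments
or structured populations, which are out of scope.

## Statistical operating characteristics and their problem sizes

The test suite verifies, at sizes chosen to give each check adequate
Monte-Carlo precision while keeping a full run modest on one CPU:

* IVW ≡ WLS-through-origin on 100 random instances (1e-10 relative).
* WLM round trip on 1000 random effect pairs (1e-12).
* WLM vs conditional-duo equivalence on one population of 20,000 pairs ×
  14 SNPs (correlation > 0.95).
* 95% IVW CI coverage within [93%, 97%] over 1000 two-sample studies
  (14 SNPs, 20,000 per sample, θ = −0.2, no pleiotropy), run through the
  full generator → harmonise → WLM → IVW route.
* Directional-pleiotropy detection over 500 replicates of a stress
  scenario: 50 instruments explaining 10% of exposure variance with a
  10-fold geometric effect-size range, pleiotropy 0.25 SD per allele on
  30% of them, n = 10,000 per sample. These conditions come from a power
  analysis: the Egger intercept z-statistic is bounded by
  $\sqrt{p/(1-p)}$ (p the pleiotropic fraction) divided by the
  instrument-spread leverage factor $\sqrt{(1 + \bar x^2/S_{xx})/n_{snp}}$,
  because the conventional overdispersion-floored SE grows with the very
  contamination being tested. A narrow effect-size ladder caps the
  achievable power below 50% at *any* pleiotropy magnitude; the wide
  ladder and strong instruments give the intercept test ≈ 60% power,
  and the weighted median is required to beat IVW on absolute bias.
* Radial type-I error: over 500 null-heterogeneity replicates, at the
  Bonferroni per-SNP threshold, at most 10% of runs may flag any outlier.
* A complete hand-written enumeration of the allele-matching and
  palindromic cases.

## Numerical and design choices

* Fixed-effect IVW of Wald ratios is the main-analysis pooling;
  multiplicative random effects is offered because heterogeneity is
  expected in practice (only SEs differ).
* Degenerate inputs are errors with typed conditions: zero exposure beta
  (undefined ratio), < 2 SNPs for heterogeneity, < 3 for Egger / median /
  radial / leave-one-out, identical exposure betas (Egger rank
  deficiency), collinear exposure columns (MVMR), collinear
  maternal/child dosages, degenerate WLM covariance, empty harmonisation
  overlap.
* The weighted-median interpolation returns the extreme ratio when the
  mid-point weight already passes 0.5 at an end (the concentrated-weight
  limit), and resolves p = 0.5 ties at a ratio exactly.
* Rescaling to natural units multiplies beta, SE and CI by the outcome SD
  (484 g per birthweight SD by default) and never touches p-values.
* Reports carry a provenance block (config echo, hash, seed, package
  version); TSV column order is fixed so re-runs are byte-stable, and the
  JSON bundle round-trips every numeric value.

## Limitations

The WLM is an approximation, not the full structural equation model; the
per-SNP first-order Wald SE ignores exposure-side uncertainty and will
undercover with genuinely weak instruments; the palindromic frequency
rule can mis-orient variants whose frequencies differ strongly between
source populations; and the headline numbers of any real analysis depend
on per-SNP input tables that must be supplied by the user — the synthetic
generator validates the machinery, not any particular published estimate.
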