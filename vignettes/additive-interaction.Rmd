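---
title: "Additive interaction in weighted cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive interaction in weighted cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addinter)
```

## The model

The package analyses a binary outcome $Y$ (diagnosed diabetes) against
two binary exposures, $A$ (family history of diabetes) and $B$
(hypertension), in individual-level data with sampling weights $w_i$.
The joint exposure is coded as a 4-level factor with the doubly
unexposed as reference and three dummies $d_{01}$ ($B$ only), $d_{10}$
($A$ only), $d_{11}$ (both). The weighted logistic model

$$\operatorname{logit} P(Y=1) = \beta_0 + b_{01} d_{01} + b_{10} d_{10}
  + b_{11} d_{11} + \gamma^\top z$$

(with optional covariate dummies $z$) yields the odds ratios
$\mathrm{OR}_{jk} = e^{b_{jk}}$ and the three additive-interaction
measures

$$\mathrm{RERI} = \mathrm{OR}_{11} - \mathrm{OR}_{10} -
  \mathrm{OR}_{01} + 1, \qquad
  \mathrm{AP} = \mathrm{RERI}/\mathrm{OR}_{11}, \qquad
  S = \frac{\mathrm{OR}_{11} - 1}
           {(\mathrm{OR}_{10} - 1) + (\mathrm{OR}_{01} - 1)}.$$

Under exact additivity of excess risks RERI $=0$, AP $=0$, $S=1$;
larger values indicate synergy. Interpreting these odds-ratio versions
as risk-based measures assumes a reasonably rare outcome (so ORs
approximate risk ratios); with a ~12% outcome prevalence this is an
approximation, which is why the measures are reported with their own
uncertainty rather than as exact excess risks. The denominator of $S$
is the *sum* of the two excess odds ratios; published inline renderings
sometimes drop the outer parentheses, but the parenthesized form is the
one consistent with published worked-example values, and it is what the
package implements. When that denominator is non-positive or
$\mathrm{OR}_{11} \le 1$, $S$ is not a meaningful ratio of excess risks
and is returned flagged undefined rather than as an error or a spurious
number.

Useful identities, asserted in the test suite on random OR triples:
$\mathrm{AP}\cdot\mathrm{OR}_{11} = \mathrm{RERI}$ and
$\mathrm{RERI} = (S-1)\,((\mathrm{OR}_{10}-1)+(\mathrm{OR}_{01}-1))$,
so $\operatorname{sign}(\mathrm{RERI}) = \operatorname{sign}(\mathrm{AP})$
and, for a positive denominator, $\mathrm{RERI}>0 \iff S>1$.

## Weighted estimation

Weights are treated as sampling (probability) weights: coefficients
maximize $\sum_i w_i [y_i \log p_i + (1-y_i)\log(1-p_i)]$ via IRLS with
step-halving, so the deviance is non-increasing by construction.
Conventions that matter:

- **Normalization.** Weights are rescaled to mean 1 internally. Point
  estimates are invariant to rescaling all weights by any constant in
  any case; under this convention the sandwich covariance is invariant
  too, which is the property the tests assert.
- **Variance.** The default covariance is the sandwich estimator
  $(X^\top W X)^{-1}\left(\sum_i s_i s_i^\top\right)(X^\top W X)^{-1}$
  with score contributions $s_i = w_i (y_i - p_i) x_i$, optionally
  summed within clusters first. Model-based (inverse information)
  covariance is anti-conservative under informative weighting and is
  available but not the default. No small-sample correction is applied,
  so single-row clusters reproduce the heteroskedasticity-robust
  estimate exactly. Multistage design-based (stratum/PSU linearized)
  variance is out of scope; cluster-robust variance is the provided
  approximation.
- **Convergence.** Maximum absolute weighted score below $10^{-8}$ or
  relative deviance change below $10^{-10}$, at most 50 iterations.
- **Separation.** Any coefficient beyond $\pm 30$ on the logit scale
  aborts with an error naming the column: a diverging fit should fail
  loudly, not return a sham estimate. No penalized fallback is offered.

## Confidence intervals for the measures

**Delta method** (default). RERI and AP get Wald intervals on their
natural scales with gradients in $(b_{01}, b_{10}, b_{11})$:
$\nabla \mathrm{RERI} = (-e^{b_{01}}, -e^{b_{10}}, e^{b_{11}})$ and
$\nabla \mathrm{AP} = (-e^{b_{01}-b_{11}}, -e^{b_{10}-b_{11}},
e^{b_{10}-b_{11}} + e^{b_{01}-b_{11}} - e^{-b_{11}})$. $S$ is handled on
the log scale, $\ln S = \ln(e^{b_{11}}-1) - \ln(e^{b_{10}}+e^{b_{01}}-2)$,
and the interval exponentiated, which respects the positivity of $S$ and
is the standard approach for ratio-type interaction indices. P-values
come from the corresponding z statistics ($\ln S$ tested against 0).
Gradients are verified against central finite differences in the tests.

**Bootstrap** (switch). Nonparametric row resampling — cluster
resampling when cluster labels are supplied — refits the model per
replicate and takes percentile intervals. Point estimates always come
from the full-data fit. Replicates with failed fits or undefined $S$ are
counted and reported; more than 10% failures aborts as unreliable, as
does an outcome with zero variance. P-values use the symmetric
percentile convention $2\min(P(\hat\theta^* \le \theta_0),
P(\hat\theta^* \ge \theta_0))$.

**Classification.** RERI and AP are classified by sign against 0, $S$
against 1, with exact comparison (values within $10^{-12}$ of the null
display as "none"); a separate `significant` flag records whether the
CI excludes the null. In finite samples a point estimate is almost never
exactly null, so "no interaction" conclusions should be read from the
significance flag, and that is what the package's own null-simulation
tests assert.

## The synthetic cohort: what it emulates

Real data for the motivating analysis are access-restricted, so the
generator states a world with the same observable structure:

- **Exposures.** Marginal prevalences default to 14.33% (family
  history) and 26.98% (hypertension), the published weighted marginals.
  Co-occurrence is controlled by an odds ratio with margins held fixed
  (solved from the quadratic in the joint cell); the default 1.5
  creates realistic overlap and is overridable. An odds ratio of 0 is
  read as "never co-occur", so incompatible margins raise an
  infeasibility error.
- **Family-history detail.** Father/mother/brother/sister indicators
  are drawn conditional on any family history (conditional rates fixed
  at 0.299/0.402/0.354/0.193, derived from the published
  relative-specific marginals), with at least one relative forced for
  every family-history case; parental/sibling/any flags are derived, so
  the hierarchy invariants hold by construction.
- **Outcome and medication.** The outcome follows the logistic model
  above; default joint-exposure effects reproduce the published
  unadjusted ORs (5.93, 4.00, 17.63) with intercept −3.6. Cases are on
  medication with probability 0.825 (the published treated share);
  hypertensives with probability 0.7216. Medication flags are subsets
  of disease flags by construction.
- **Weights.** Log-normal (meanlog 0, sdlog 0.5), rescaled to mean 1;
  the real survey's weight construction is not public, so this is a
  stand-in with realistic dispersion, not an emulation.
- **Structure for the exclusion flow.** 10.2% under-45 spouse records
  and per-column missing-completely-at-random rates mirroring the
  published flow counts (0.3% outcome, 0.6% family history, 9.65% BMI,
  small rates elsewhere). Missingness is injected independently per
  column — after injection a specific relative can be observed while
  the overall flag is missing; the hierarchy holds on complete rows,
  which is all a complete-case analysis uses.
- **Clusters.** I.i.d. labels for variance testing only; no multistage
  PSU/CEB geometry.

Draws occur in a fixed documented column order with one variate per
record per column, so a config plus seed reproduces a byte-identical
table.

A green test on this world establishes that the pipeline recovers known
truths under correct specification with independent weights and MCAR
missingness. It does *not* establish robustness to informative weights,
informative missingness, measurement error in self-reports, or real
survey design effects — none of which the generator emulates.

## Exclusion flow and descriptive statistics

Rows are removed in a fixed order: age below 45, then missing outcome,
then missing any required covariate. Per-step counts depend on this
order (the order mirrors the published flow narrative) and are part of
the contract; the total removed is order-independent, and both facts
are asserted on random tables. Missing values are `NA` throughout —
never a numeric sentinel — and arithmetic paths refuse missing inputs
rather than propagating them silently.

Weighted prevalences are $\sum w y / \sum w$ with a normal interval on
the logit scale using the Kish effective sample size
$(\sum w)^2/\sum w^2$; the source studies do not state their
proportion-CI method, so this choice is the package's own, made for
boundary-respecting intervals at small effective sizes. The group
association test is the plain Pearson chi-square on unweighted counts
(a design-corrected test is out of scope); zero expected counts flag
the test invalid.

## Numerical and reporting conventions

- ORs and $S$ display to 2 decimals; AP as a fraction to 2 decimals
  (the canonical scale; percentage displays multiply by 100); measure
  cells render as `estimate; p (low high)` with stars ***/**/* at
  0.001/0.01/0.05.
- Reports render deterministically: identical input, plan and seed give
  identical bytes in all three formats (text, TSV, JSON).
- A failed model cell (e.g. separation in a degenerate stratum) renders
  as a flagged placeholder; the rest of the grid still runs.
- The published worked-example grid shipped in `inst/extdata` keeps its
  internally inconsistent unadjusted section flagged
  (`consistent = FALSE`): its printed measures do not follow from its
  printed ORs, so it is excluded from verification. One further
  section's printed RERI and $S$ reflect unrounded coefficients; with
  two-decimal printed ORs as inputs the recomputation agrees to within
  0.02 (RERI) and 0.01 ($S$), and values are reported unrounded rather
  than re-rounded.

## Simulation-based validation design

The coverage and type-I-error checks in the acceptance suite fix the
sample size (20,000) and the truth — singly-exposed ORs 4.21 and 2.82
(the published adjusted values) with the doubly-exposed OR chosen so the
true RERI is exactly 3.5, or exactly 0 for the null — and use an
exposure-only configuration with no spouse records and no missingness so
that the analytic sample equals the generated sample and 500 replicates
fit in a small compute budget. That is an experiment-design choice about
the stated world, not a relaxation: the quantities under test (interval
coverage, test size) are properties of the estimator at the stated
truth and sample size.

## Known limitations

- Odds-ratio-based RERI/AP/S inherit the rare-outcome approximation.
- Variance estimation is single-stage (robust/cluster-robust) only.
- MCAR missingness and complete-case analysis only; no imputation.
- No multiplicative-scale interaction test is headlined, and no
  Firth-type fallback exists for separated fits.
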