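---
title: "Modelling health-expectancy gains from lifestyle counterfactuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling health-expectancy gains from lifestyle counterfactuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

How many years of life — and, more importantly, of *healthy* life — could a
population gain if its lifestyle risk profile changed? `healthgains`
implements a period (Sullivan) life-table pipeline that answers this for
three lifestyle factors — smoking (never/ex/current), BMI (below 25,
25–30, above 30) and alcohol consumption (four levels in grams/day with
sex-specific boundaries) — and three outcome measures:

* **LE** — life expectancy;
* **HLY** — healthy life years, i.e. years free of long-standing activity
  limitation (the GALI survey item);
* **LEGPH** — life expectancy in good self-perceived health (years not in
  "less than good" self-perceived health).

Counterfactual scenarios replace a country's observed lifestyle
distribution with the most favourable distribution observed among the
modelled countries ("best of all"), or with everyone in the healthy
category of one or all factors ("positive" scenarios). Country outcomes
are pooled into regions with mid-year population weights.

## Model

### Life table

Single-year ages $x$ over a configurable span (default 0–100, the last
age open). From death counts $D_x$ and mid-year populations $N_x$,
$m_x = D_x / N_x$ and

$$q_x = \frac{m_x}{1 + (1 - a_x)\,m_x},$$

with separation factor $a_x = 0.5$ at all ages, including age 0: the
outcomes of interest are driven by adult mortality, and an
infant-specific $a_0$ would be invisible in every quantity the package
reports. $a_x$ is nevertheless configurable. The open age is closed with
$L_\omega = l_\omega / m_\omega$; a zero death rate at the open age is
rejected with an error rather than silently extended. The radix is
100,000 and every reported quantity is invariant to it (tested).

Health expectancy at age $a$ follows Sullivan's weighting of person-years
by the proportion healthy:

$$HE_a = \frac{1}{l_a} \sum_{x \ge a} L_x\,(1 - \pi_x),$$

where $\pi_x$ is the prevalence of the unhealthy state. The healthy
person-years are accumulated tail-first exactly as $T_x$ is, so that
$\pi \equiv 0$ reproduces $e_a$ bit-for-bit.

### The joint risk factor and the linkage

The three factors form a composite risk factor with $3 \times 3 \times 4
= 36$ categories. Reliable clustering information is typically
unavailable across countries, so the joint distribution is the product of
the marginals (independence), and composite effects are products of
marginal effects — consistent with mutually adjusted regressions on the
effect side.

Two linkage steps connect aggregate schedules to category-specific ones:

* **Mortality decomposition.** With exposure $p_c$ and relative risks
  $RR_c$, the all-reference rate is $m_0 = m / \sum_c p_c RR_c$ and
  category rates are $m_c = m_0 RR_c$. The exposure-weighted mean
  reproduces the observed aggregate identically.
* **Prevalence inversion.** With odds ratios $OR_c$, the all-reference
  odds $o_0$ solves $\sum_c p_c \frac{o_0 OR_c}{1 + o_0 OR_c} = \pi$.
  The left side is strictly increasing in $o_0$ from 0 to 1, so the root
  is unique; it is found by bisection on $\log o$ over the bracket
  $[10^{-12}, 10^{6}]$ (expanded if needed), stopping at residual
  $10^{-12}$ with a 200-iteration cap. Bisection was chosen over Newton
  steps because convergence is then guaranteed for every admissible
  input, and the solver is bit-reproducible. Aggregate prevalences of
  exactly 0 or 1 (possible at extreme ages) are clamped to
  $[10^{-9}, 1 - 10^{-9}]$ with a warning, since the odds transform is
  undefined at the boundary.

A counterfactual changes *exposure only*: category rates and the
baseline odds are held fixed, the new aggregates
$m'_x = \sum_c p'_c m_{c,x}$ and $\pi'_x = \sum_c p'_c \pi_{c,x}$ are
formed, and a fresh life table is built from $m'$. Rebuilding the table
keeps competing risks consistent and avoids overstating the benefit of
removing a single factor.

### Effects

Mortality relative risks are inputs, not estimated here (they come from
dedicated evidence syntheses in practice); they apply from age 20 by
default. Health-state odds ratios apply from age 50 (the age range the
underlying health surveys cover) and come in three specifications:
constant, stratified by age (50–65 and 65+ — the printed strata overlap
at 65, and the boundary age is assigned to the upper stratum), or
log-linear in age, $OR(x) = \exp(\beta + \gamma x)$, used for alcohol.
Reference categories resolve to 1 everywhere, as do all effects below
`apply_from_age`.

`estimate_odds_ratios()` reproduces the estimation design: per sex,
logistic regressions of the outcome on all three factors (mutually
adjusted), age and country intercepts; smoking and BMI within the two age
strata, alcohol in a single model with a continuous category-by-age
interaction. `estimate_marginal_prevalence()` fits, per sex, a
multinomial logit of the category on country and country-by-age
interaction. A multinomial model (rather than per-category binary logits)
guarantees simplex-valued predictions without post-hoc renormalisation.
Banded prevalences are brought to single ages by a linear regression plus
a generalized-cross-validated smoothing spline on the residuals
(`smooth_to_single_ages()`), then clipped to $[0,1]$ and renormalised —
clip-then-renormalise keeps every age on the simplex, and constant or
linear band patterns pass through unchanged.

### Scenarios and pooling

"Best observed" is selected *per factor, sex and single age*: the donor
country minimises the exposure-weighted mortality relative risk
$\sum_c p_c RR_c$ (ties: alphabetically first country). The criterion is
a genuine modelling choice — the notion of "most favourable" is not
canonical — so an alternative (`max_healthy_share`) is available in the
API; the weighted-RR default is documented and used everywhere else.
Selection per age allows different donors at different ages.

Reporting ages default to 0 (birth), 50 and 65 — birth and 65 being the
standard European reporting ages. Regional pooling is a
population-weighted mean of outcomes and gains; the standard four-region,
26-country European map ships as `eu_region_map()`.

## The synthetic study generator

The package includes a generator for a fully self-consistent synthetic
multi-country study with known ground truth, so every stage — estimation,
linkage, scenarios, pooling — is testable without restricted survey
microdata. It emulates:

* smooth age/sex/country-varying category prevalences from a multinomial
  logit truth (country effects enter as a shift common to a factor's
  non-healthy categories, plus a country age-slope — a structure under
  which countries are totally ordered at each age for any effect vector
  that is minimal at the healthy category, making the scenario-ordering
  property provable rather than accidental);
* an all-reference mortality schedule $m_0(x)$ = background +
  Gompertz ($5\times10^{-4} + 2\times10^{-5} e^{0.085x}$, shifted per
  country on the log scale);
* log-linear-in-age baseline odds for both unhealthy states;
* stratified smoking/BMI odds ratios and U-shaped log-linear alcohol
  odds ratios (abstainers highest, then the heaviest drinkers) — with
  "moderate" as the alcohol reference and healthy category, which is
  what a U-shape implies and what makes the ideal scenario coincide with
  the all-reference population, giving an exact analytic oracle;
* East-style countries with more smoking at older ages, fewer people at
  healthy BMI, and higher baseline mortality and unhealthy-state odds, so
  regional phenomena (lowest baseline and largest gains in the East)
  emerge from the construction;
* stationary populations (births × person-years survived) as the
  demographic envelope, and individual survey records (categories drawn
  from the marginals, binary outcomes from the implied logistic model).

In noise-free mode the observable tables are the exact expected values,
and the pipeline's decomposition/inversion recovers the generator truth
to solver precision; `ground_truth_gains()` applies the counterfactual
algebra directly to the truth, bypassing estimation, and serves as the
oracle for the full pipeline. Binomial death noise and finite-survey
noise are available for robustness checks.

What the generator does **not** emulate: real correlation (clustering)
between the three behaviours, survey weighting and non-response,
under-reporting of alcohol consumption, drinking patterns such as binge
drinking, cohort trends in behaviour, and realistic European magnitudes.
Passing tests therefore demonstrate the correctness of the machinery
under the model's own assumptions, not the accuracy of any particular
real-world estimate.

## Validation-experiment design

Two estimation-recovery experiments are part of the test suite, with
problem sizes chosen once at design time:

* **Odds ratios**: a 50,000-record two-country health survey (ages
  50–100, population-weighted); every estimated parameter is required to
  lie within 3 standard errors of its generating value, and the alcohol
  U-shape must be structurally reproduced (both arms above the moderate
  reference, abstainer above the precisely estimated high-consumption
  category, positive abstainer age-slope). The very-high-consumption
  category is deliberately rare (a few percent, as in real surveys), so
  its point estimate is covered by the 3-SE check rather than by point
  ordering.
* **Marginal prevalences**: a 50,000-record two-country adult
  cross-section (uniform ages 25–100); predictions are compared with the
  truth at ages 50–90 and must agree within 0.02 everywhere. The
  comparison grid is interior to the sampled span because predictions at
  the span's endpoints are extrapolations of the country-specific age
  lines, whose Monte Carlo error is dominated by design leverage rather
  than by anything the estimator controls.

Other sizes: the full-pipeline oracle comparison runs the default
six-country study over ages 0–100 and requires agreement with the
analytic ground truth within $10^{-6}$ years; a 200,000-individual
cohort microsimulation must agree with the deterministic life table
within 3 standard errors; linkage conservation is property-tested over a
thousand random exposure/effect draws.

## Limitations

* The Sullivan approach is cross-sectional: it assumes the risk-factor
  distribution and age-specific prevalence schedules are constant over
  time, and lets health-state prevalence respond instantly to exposure
  change. Lagged or dynamic responses are out of scope.
* Independence of the three factors is an assumption, not an estimate;
  gains for combinations of correlated behaviours will be misstated to
  the extent behaviours cluster.
* Effects of alcohol on others (violence, accidents) are not part of the
  odds ratios; only own-health effects are modelled.
* The "normal" BMI category includes underweight, slightly diluting the
  healthy reference.
* Confidence intervals on gains are not produced; outputs are point
  estimates given the input schedules and effect tables.
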