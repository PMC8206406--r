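---
title: "Control-definition sensitivity of claims-based case-control associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-definition sensitivity of claims-based case-control associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortsens)
```

## The problem

Retrospective case-control studies on administrative claims are easy to run
and easy to re-run. A rule-based phenotype definition has many defensible
variants, and each variant selects a different slice of the insured
population. `cohortsens` implements one such sensitivity analysis end to
end: a type 2 diabetes (T2D) case cohort is held fixed while the *control*
definition is permuted in four ways that differ only in how they treat
glucose/HbA1c laboratory testing, and the association between T2D status and
a depression diagnosis is measured as a bootstrap distribution of Fisher's
exact odds ratios under every definition, with and without exact age/sex
matching.

The scientific mechanism under study is **informative missingness**: a
glucose test is ordered more often for older and sicker members, so
*requiring* a (normal) glucose result selects controls that are older and
closer to the case population, while *forbidding* a glucose test selects
young, low-contact controls. The measured odds ratio moves accordingly, even
though the underlying comorbidity does not change.

## Pipeline and data model

Claims are normalized into three tables: `members` (id, sex, birth year),
`enrollment` (closed date spans) and `events` (one row per claim line:
diagnosis / procedure / pharmacy / lab result, with a code system and an
optional returned value). The stages are:

1. **Windowing.** Spans separated by at most 31 days (configurable) are
   merged; a member qualifies if one merged span covers at least 4 years,
   and phenotypes are computed over exactly the first 1461 days of the
   earliest such span. The fixed 1461-day closed window (four years
   including one leap day) makes event counts reproducible regardless of
   calendar placement. Age is the window start year minus birth year; the
   source descriptions leave both the grace period and the age reference
   date open, so both are documented configuration defaults here.
2. **Code mapping.** ICD-10 diagnoses are rewritten to ICD-9 through a
   user-supplied many-to-one map (`read_code_map()`); the packaged
   `default_code_map()` is a synthetic stand-in covering only the codes the
   bundled generator emits. Mapping is idempotent and strict by default.
3. **Phenotyping.** A rules engine over per-member windowed flags (below).
4. **Matching.** Exact 1:1 matching on (integer age, sex), at population
   level, without replacement, no caliper.
5. **Association.** Bootstrap resampling of each arm, Fisher's exact test
   per replicate, percentile summaries of the replicate odds ratios.

## Phenotyping rules

All rules are pure functions of the windowed event set, so event order can
never change a label. The case tree (an eMERGE-style adaptation for claims;
the source family fixes the structure but not the numeric thresholds, so the
thresholds here are the usual diagnostic conventions and every one is
config-overridable):

* **case** = (>= 1 T2D diagnosis) AND (T2D medication OR an abnormal
  glucose/HbA1c value) AND NOT (T1D diagnosis without any T2D diagnosis),
  with an optional family-history branch (off by default).
* Abnormal (case-side): fasting glucose >= 126 mg/dL, random glucose >= 200
  mg/dL, HbA1c >= 6.5%. Normal (control-side) bounds are stricter: < 110,
  < 140, < 6.0.

Controls share one exclusion chain -- no T2D or T1D diagnosis, no diabetes
medication, no family-history code (ICD-9 V18.0), and at least `min_visits`
(default 2) distinct claims -- and then differ only in the lab rule:

| variant | lab rule |
|---|---|
| `baseline` | >= 1 returned glucose/HbA1c value AND every returned value below its normal bound |
| `ignore_lab_value` | >= 1 returned value, values not checked |
| `ignore_lab` | no lab condition |
| `no_lab` | zero lab orders (CPT) and zero returned values (LOINC) |

By construction `baseline` is a subset of `ignore_lab_value`, which is a
subset of `ignore_lab`; `no_lab` is also inside `ignore_lab` and disjoint
from `ignore_lab_value`; the remainder of `ignore_lab` is exactly the
members with an order but no returned value. `no_lab` takes the stricter
reading of "has not had a glucose test": absence of both order codes and
result codes. Depression exposure is >= 1 windowed diagnosis in an editable
depressive-disorders rollup (default ICD-9 296.2x, 296.3x, 298.0, 300.4,
309.1, 311 -- the cited grouper distributes categories, not code lists, so
the default is an interpretation shipped as configuration).

## Statistical conventions

* The reported odds ratio is the sample OR `(a*d)/(b*c)`, the convention of
  the standard scientific stack this mirrors, not the conditional MLE. The
  Haldane-Anscombe +0.5 correction is applied to all four cells only when
  some cell is zero, and only for the OR.
* The two-sided Fisher p-value follows the point-probability rule: the sum
  of hypergeometric probabilities of all margin-fixed tables no more
  probable than the observed one, with a `1 + 1e-7` relative tolerance
  guarding floating-point ties (the same convention as `stats::fisher.test`,
  which the test suite uses as one of two independent cross-checks, the
  other being brute-force enumeration from binomial coefficients).
* Bootstrap replicates draw `n` members per arm *with* replacement; a
  without-replacement subsampling mode exists because "sampling from a
  population" is ambiguous at population sizes close to `n`.
* The 95% CI of a bootstrap distribution is the 2.5/97.5 percentile pair of
  the replicate ORs (type-7 quantiles); no analytic CI is implied. On the
  log-OR scale the CI width scales as `1/sqrt(n)`, so halving it costs four
  times the cohort.
* Matching happens once at population level and the matched populations are
  then resampled, matching how matched population tables are usually
  presented; `match_mode = "per_replicate"` re-matches inside every
  replicate for sensitivity checks.

## The synthetic generator

There is no public claims database at this scale, so `generate_claims()`
emulates the statistical structure the analysis actually consumes, and a
latent-truth table makes parameter recovery testable. Per member:

* age from a truncated normal mixture (commercially insured shape), sex
  Bernoulli;
* one enrollment span starting 2008-2013, at least 4 years long with
  probability 0.85, 10% of long spans split by a 1-31 day administrative
  gap (exercising the merge step);
* latent T2D logistic in age (`plogis(-4.8 + 0.055*age)`, ~9% overall);
  latent depression with baseline prevalence 0.12 whose odds are multiplied
  by the configured comorbidity odds ratio `theta` for T2D members -- so
  the true association is an explicit input;
* glucose/HbA1c orders at `0.08 * exp(0.045*age)` per member-year (x2.5
  for T2D), of which 53.4% return a value -- the orders-to-results ratio of
  large commercial feeds; returned values are lognormal conditional on
  latent T2D, calibrated so the tested population's HbA1c has mean ~6.28
  and median ~5.8;
* background diagnoses at an age/morbidity-graded Poisson rate calibrated
  so the case population records ~53.5 diagnosis facts per member-year,
  with 12% emitted as ICD-10 (exercising code mapping);
* condition codes at configured claims sensitivities (T2D diagnosis 0.95,
  medication 0.90; depression diagnosis 1.0, since the latent flag means
  "actively diagnosed depression" -- the exposure definition itself).

One deliberate design choice: by default depression is **independent of
age** within latent class (`dep_age_slope = 0`), which makes `theta`
exactly the marginal comorbidity odds ratio and gives the parameter-recovery
tests a sharp target. Setting `dep_age_slope > 0` (the analysis scripts use
0.06) concentrates depression in the older, more-tested population and
reproduces the mechanism by which the no-lab control group yields a much
larger odds ratio than the baseline group. Under that configuration `theta`
remains the within-age-stratum effect, and the variant-to-variant OR spread
is a *selection* artifact -- which is the point of the study design.

What the generator does **not** emulate: longitudinal disease progression
(latent flags are static), realistic billing/adjudication semantics, code
vocabularies beyond a small synthetic formulary and diagnosis pool,
geographic or plan structure, and the real joint age-testing-morbidity
distribution, which is unknowable from published summary statistics. Tests
passing on generated data therefore validate the *machinery* (rule algebra,
matching exactness, estimator calibration), not claims about any real
population.

## Problem sizes and numerical choices

Default generator size is 20,000 members, enough for every cohort to be
populated under all four variants; each analysis states its own size. The
parameter-recovery study uses 60,000 members per run (so the phenotyped
populations are large enough that population-level sampling noise is small
relative to the bootstrap CI), a reduced background-diagnosis rate (the
background codes only feed the visit-count rule, which is satisfied long
before the default volume), 200 bootstrap replicates of n = 10,000 per arm,
and 20 seeded runs per `theta` in {1.0, 1.3, 2.7}. Degenerate inputs fail
loudly: empty case or control populations, unmapped codes under the strict
policy, and zero-margin 2x2 tables are errors, not silent results.

## Known limitations

* The case tree is a faithful-convention stand-in for the published eMERGE
  logic, whose exact decision tree and thresholds are not printed in the
  source this package accompanies; everything is configurable for users who
  hold the real definitions.
* Exact matching drops cases in strata without controls; with the no-lab
  variant (young controls) this can discard much of the older case
  population, which is visible in the matched demographics and is a real
  property of the design, not an artifact.
* Fisher's exact test conditions on both margins; its discreteness makes
  the type-I rate slightly conservative at small `n`.
* The bootstrap CI reflects resampling noise around the *phenotyped
  population*, not uncertainty in the phenotyping rules themselves -- the
  spread across control definitions is precisely the quantity the pipeline
  is built to expose.
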