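# cohortsens

Sensitivity of claims-based case-control associations to the control
definition.

## The problem

Case-control studies on administrative claims start from a rule-based
phenotype: diagnoses, medications and lab values decide who is a case, who
is a control, and who is neither. Those rules have many defensible variants,
and because lab testing is not ordered at random -- a glucose test is far
more likely for an older, sicker member -- a control definition that
*requires* (or *forbids*) a glucose test silently selects a different
population. `cohortsens` implements this sensitivity analysis end to end for
the canonical example: the association between depression and type 2
diabetes (T2D).

A fixed eMERGE-style T2D case algorithm is run against four control
definitions that differ **only** in the glucose/HbA1c lab requirement:

| variant | rule |
|---|---|
| `baseline` | a returned lab value is required and must be normal |
| `ignore_lab_value` | a returned lab value is required, its value is ignored |
| `ignore_lab` | no lab condition at all |
| `no_lab` | no lab order and no returned value |

For every definition (with and without exact age/sex matching), the
depression-T2D association is measured as a bootstrap distribution of
Fisher's exact odds ratios: each of 200 replicates samples `n` members per
arm with replacement, forms the exposure-by-status 2x2 table
(`OR = ad/bc`, two-sided exact p by the point-probability rule), and the
distribution is summarized by its median and 2.5/97.5 percentiles.

Because the motivating data -- a proprietary multi-million-member claims
database -- cannot ship, the package includes a seeded synthetic claims
generator with a latent truth table: T2D and depression prevalences and
their true comorbidity odds ratio `theta` are explicit configuration, lab
testing increases with age, and only ~53% of lab orders return a value. The
full pipeline can therefore be validated by parameter recovery.

## Worked example

```r
library(cohortsens)

cfg <- run_config(
  synthetic = synthetic_config(n_members = 10000, dep_age_slope = 0.06),
  variants = c("baseline", "no_lab"), matched = c(FALSE, TRUE),
  n = 2000, reps = 100, seed = 42)
bundle <- run_pipeline(cfg)
bundle$summaries
#>    variant matched    n reps median_or ci_low ci_high ci_range n_nonsignificant
#> 1 baseline   FALSE 2000  100     2.405  2.111   2.920   0.8096                0
#> 2   no_lab   FALSE 2000  100    12.104  9.334  15.282   5.9473                0
#> 3 baseline    TRUE 2000  100     1.248  1.085   1.422   0.3368               13
#> 4   no_lab    TRUE 2000  100     1.478  1.219   1.766   0.5467                4
```

The true comorbidity odds ratio in this simulation is 1.3; depression also
rises with age (`dep_age_slope = 0.06`), which is what makes lab testing
informative. Unmatched, the same case cohort yields a median OR of 2.4
against lab-tested-and-normal controls but 12.1 against never-tested
controls -- the control definition, not the biology, moves the estimate.
The demographics table shows why:

```r
bundle$demographics
#>   population members pct_male pct_female age_mean age_sd pct_depression facts_mean facts_sd
#> 1       case     848    50.12      49.88    56.84  16.64         30.542     57.506   40.594
#> 2   baseline    3775    49.67      50.33    44.95  18.33         15.285     29.073   24.162
#> 3     no_lab    1784    49.83      50.17    18.82  12.56          3.587      7.446    5.819
```

Never-tested controls are ~26 years younger, have a fifth of the healthcare
contact (diagnosis "facts" per year), and a tenth of the depression
prevalence. Exact age/sex matching tempers the shift (1.25 vs 1.48) at the
cost of dropping cases from strata without young controls. `write_report()`
writes the demographic tables, binned age distributions, per-replicate
results and summaries as CSVs.

The association layer can also be driven directly from printed prevalences:

```r
s <- summarize_replicates(
  simulate_association(0.1751, 0.1424, n = 10000, reps = 200, seed = 1))
#>       n reps median_or ci_low ci_high ci_range n_nonsignificant
#> 1 10000  200     1.283  1.196   1.387    0.191                0
```

## Analysis workflow

The `analysis/` scripts run the whole study on a 60,000-member simulated
population, writing tables under `results/run/`:

```sh
Rscript analysis/01_simulate.R    # claims CSVs + latent truth
Rscript analysis/02_phenotype.R   # cohorts per variant + demographics
Rscript analysis/03_match.R       # exact 1:1 age/sex matching
Rscript analysis/04_associate.R   # bootstrap OR grid (4 variants x 2 x 4 sizes)
Rscript analysis/05_report.R      # age distributions, CI shrinkage, report
```

All computation lives in the package (`R/`); the scripts are thin drivers.
See `vignettes/control-definition-sensitivity.Rmd` for the model,
conventions and design choices.

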