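#!/usr/bin/env Rscript
# Stage 1: simulate the claims substrate.
#
# Draws a synthetic commercially-insured population with latent T2D and
# depression (true comorbidity OR 1.3), age-increasing glucose testing, and
# age-graded depression (dep_age_slope > 0): the informative-missingness
# condition under which requiring a lab test changes who the controls are.
# Writes members/enrollment/events CSVs plus the latent truth table.

suppressPackageStartupMessages(library(cohortsens))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 20260925L
out <- "results/run/data"

cfg <- synthetic_config(n_members = 60000, theta = 1.3,
                        dep_age_slope = 0.06, seed = seed)
message("generating ", cfg$n_members, " members (seed ", seed, ") ...")
gen <- generate_claims(cfg)
write_generated(gen, out, config = cfg)

s <- empirical_summary(gen$data, gen$truth)
message("events: ", nrow(gen$data$events),
        "; value-return fraction: ", round(s$value_return_fraction, 3))
message("tested members are ",
        round(s$mean_age_tested - s$mean_age_untested, 1),
        " years older than untested (informative missingness)")
message("glucose orders per member-year by decade:")
print(s$testing_by_decade)
message("HbA1c among returned values: mean ", round(s$hba1c[["mean"]], 2),
        ", median ", round(s$hba1c[["median"]], 2))
message("wrote ", out)
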