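# Exact 1:1 age/sex matching of controls to cases, and demographic summary
# tables in the usual cohort-characteristics layout.

#' Exact 1:1 matching on integer age and sex
#'
#' Within every (age, sex) stratum, `min(n_cases, n_controls)` pairs are
#' formed by seeded uniform sampling without replacement; members in strata
#' with no counterpart are dropped and reported. Matching is performed at
#' population level (the matched populations then feed the bootstrap), not
#' per replicate.
#'
#' @param cases,controls Cohort tibbles with `member_id`, `age`, `sex` (e.g.
#'   the `status == "case"` / `"control"` rows of a [build_cohorts()] table).
#' @param seed Optional integer seed for the within-stratum sampling.
#' @return A `matched_cohorts` object: list with `pairs` (tibble
#'   `case_id,control_id,age,sex`), `dropped_cases`, `dropped_controls`
#'   (member-id vectors).
#' @export
exact_match <- function(cases, controls, seed = NULL) {
  stopifnot(all(c("member_id", "age", "sex") %in% names(cases)),
            all(c("member_id", "age", "sex") %in% names(controls)))
  if (anyNA(cases$age) || anyNA(cases$sex) ||
      anyNA(controls$age) || anyNA(controls$sex)) {
    abort("age and sex must be present for every member",
          class = "cohortsens_schema_error")
  }
  if (!is.null(seed)) set.seed(seed)

  strata <- dplyr::inner_join(
    cases %>% count(.data$age, .data$sex, name = "n_case"),
    controls %>% count(.data$age, .data$sex, name = "n_control"),
    by = c("age", "sex"))
  if (nrow(strata) == 0) {
    abort("no (age, sex) stratum contains both a case and a control",
          class = "cohortsens_empty_cohort")
  }

  pick <- function(pool, strata) {
    pool %>%
      semi_join(strata, by = c("age", "sex")) %>%
      group_by(.data$age, .data$sex) %>%
      mutate(.ord = sample.int(n())) %>%
      left_join(strata, by = c("age", "sex")) %>%
      filter(.data$.ord <= pmin(.data$n_case, .data$n_control)) %>%
      arrange(.data$age, .data$sex, .data$.ord) %>%
      ungroup()
  }
  pc <- pick(cases, strata)
  px <- pick(controls, strata)
  pairs <- tibble(case_id = pc$member_id, control_id = px$member_id,
                  age = pc$age, sex = pc$sex)
  structure(
    list(pairs = pairs,
         dropped_cases = setdiff(cases$member_id, pairs$case_id),
         dropped_controls = setdiff(controls$member_id, pairs$control_id)),
    class = "matched_cohorts")
}

#' @export
print.matched_cohorts <- function(x, ...) {
  cat("<matched_cohorts>\n")
  cat("  pairs:           ", nrow(x$pairs), "\n")
  cat("  dropped cases:   ", length(x$dropped_cases), "\n")
  cat("  dropped controls:", length(x$dropped_controls), "\n")
  invisible(x)
}

#' Restrict cohort tables to their matched members
#'
#' @param m A [exact_match()] result.
#' @param cases,controls The cohort tibbles that were matched.
#' @return List `cases,controls` of the matched subsets (equal sizes).
#' @export
matched_populations <- function(m, cases, controls) {
  list(cases = cases %>% filter(.data$member_id %in% m$pairs$case_id),
       controls = controls %>%
         filter(.data$member_id %in% m$pairs$control_id))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Demographic summary of a cohort
#'
#' Member count, sex split, mean (population SD) age, depression percentage,
#' and mean (population SD) diagnosis facts per year -- the standard
#' cohort-characteristics rows.
#'
#' @param cohort Cohort tibble with `age`, `sex`, `exposed`,
#'   `facts_per_year`.
#' @param label Optional population label column value.
#' @return One-row tibble.
#' @export
demographic_summary <- function(cohort, label = NA_character_) {
  stopifnot(nrow(cohort) > 0)
  tibble(population = label,
         members = nrow(cohort),
         pct_male = 100 * mean(cohort$sex == "male"),
         pct_female = 100 * mean(cohort$sex == "female"),
         age_mean = mean(cohort$age),
         age_sd = pop_sd(cohort$age),
         pct_depression = 100 * mean(cohort$exposed),
         facts_mean = mean(cohort$facts_per_year),
         facts_sd = pop_sd(cohort$facts_per_year))
}

#' Standardized difference of a covariate between two arms
#'
#' `(mean1 - mean2) / sqrt((var1 + var2) / 2)` with population variances;
#' defined as 0 when both variances vanish and the means agree. After exact
#' matching this is identically 0 for age and sex.
#'
#' @param x1,x2 Numeric (or logical) covariate values in each arm.
#' @return The standardized difference.
#' @export
standardized_difference <- function(x1, x2) {
  x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  num <- mean(x1) - mean(x2)
  den <- sqrt((pop_sd(x1)^2 + pop_sd(x2)^2) / 2)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf * sign(num))
  }
  num / den
}
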