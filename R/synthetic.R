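# Seeded synthetic claims generator. Emulates the statistical structure the
# downstream analysis assumes -- age/sex-structured membership, multi-year
# enrollment spans, latent T2D and depression statuses linked by a
# configurable comorbidity odds ratio, age-increasing glucose-test ordering
# with only a subset of orders returning values, and age/morbidity gradients
# in diagnosis-code volume -- and writes the same claim tables a real extract
# would, plus a latent-truth table for parameter-recovery tests.

#' Configuration of the synthetic claims generator
#'
#' The defaults define the generator's reference population: a privately
#' insured age mixture, T2D prevalence rising logistically in age, depression
#' linked to latent T2D through a 2x2 joint distribution parameterized by the
#' baseline (non-T2D) prevalence and a true comorbidity odds ratio `theta`
#' (so the population odds ratio is an explicit input), glucose/HbA1c
#' ordering rates that increase with age, and a value-return probability
#' matching the roughly 53% of orders with a result flowing back in large
#' commercial claims feeds.
#'
#' @param n_members Number of members to generate.
#' @param age_mixture Data frame `weight,mean,sd` of normal components for the
#'   age distribution, truncated to `[age_range[1], age_range[2]]`.
#' @param age_range Integer truncation bounds for age, years.
#' @param sex_ratio Proportion male.
#' @param t2d_intercept,t2d_slope Logistic model of latent T2D prevalence:
#'   `p = plogis(t2d_intercept + t2d_slope * age)`.
#' @param p_depression_baseline Depression prevalence given no latent T2D.
#' @param theta True depression-T2D comorbidity odds ratio (> 0); depression
#'   prevalence given T2D has odds `theta` times the baseline odds.
#' @param dep_age_slope Logit-linear age term in depression prevalence
#'   (baseline prevalence is anchored at age 45). The default 0 keeps
#'   depression independent of age within latent class, so `theta` is exactly
#'   the marginal comorbidity odds ratio; positive values concentrate
#'   depression in the older (more tested) population, reproducing the
#'   informative-missingness mechanism by which lab-requiring control
#'   definitions shift the measured odds ratio.
#' @param p_enroll_long Probability a member's enrollment lasts at least the
#'   4-year qualifying span (others get a shorter, non-qualifying span).
#' @param span_gap_prob Probability a long enrollment is split into two spans
#'   separated by a short (1-31 day) administrative gap, to be re-merged by
#'   [merge_enrollment_spans()].
#' @param test_base,test_age_rate Glucose/HbA1c orders per member-year follow
#'   `min(test_cap, test_base * exp(test_age_rate * age))`.
#' @param test_t2d_mult Multiplier on the ordering rate for latent T2D
#'   members (diabetics are monitored more).
#' @param test_cap Upper bound on orders per member-year.
#' @param p_value_returned Probability a lab order has a returned value.
#' @param p_hba1c,p_fasting Of returned values, the fraction that are HbA1c
#'   and fasting glucose (the remainder are random glucose).
#' @param lab_means,lab_sdlog Log-normal location (natural units) and log-sd
#'   of returned lab values, by analyte and latent T2D status. Units: percent
#'   for HbA1c, mg/dL for glucose.
#' @param facts_base,facts_age_rate,facts_t2d_mult,facts_dep_mult,facts_cap
#'   Background diagnosis events per member-year:
#'   `min(facts_cap, facts_base * exp(facts_age_rate * (age - 40)) * mult)`.
#' @param t2d_dx_sens Probability a latent T2D member has T2D diagnosis codes
#'   in the window (claims sensitivity).
#' @param t2d_med_prob Probability a latent T2D member fills a T2D
#'   medication; `t2d_insulin_prob` likewise for insulin.
#' @param t2d_insulin_prob See `t2d_med_prob`.
#' @param p_t1d Prevalence of type 1 diabetes (drawn among non-T2D members;
#'   emits T1D diagnoses plus insulin fills).
#' @param dep_dx_sens Probability a latent depression member has depression
#'   diagnosis codes in the window. The latent flag represents actively
#'   treated (diagnosed) depression, so the default is 1.
#' @param famhx_prob Probability of a diabetes family-history (V18.0) code.
#' @param icd10_fraction Fraction of background diagnoses emitted in ICD-10,
#'   to exercise code mapping (see [default_code_map()]).
#' @param seed Integer seed making [generate_claims()] deterministic.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_members = 20000,
    age_mixture = data.frame(weight = c(0.25, 0.45, 0.30),
                             mean = c(12, 40, 62),
                             sd = c(8, 13, 10)),
    age_range = c(0L, 89L),
    sex_ratio = 0.49,
    t2d_intercept = -4.8,
    t2d_slope = 0.055,
    p_depression_baseline = 0.12,
    theta = 1.3,
    dep_age_slope = 0,
    p_enroll_long = 0.85,
    span_gap_prob = 0.10,
    test_base = 0.08,
    test_age_rate = 0.045,
    test_t2d_mult = 2.5,
    test_cap = 6,
    p_value_returned = 0.534,
    p_hba1c = 0.40,
    p_fasting = 0.30,
    lab_means = list(hba1c = c(normal = 5.55, t2d = 7.5),
                     fasting = c(normal = 92, t2d = 150),
                     random = c(normal = 100, t2d = 180)),
    lab_sdlog = list(hba1c = c(normal = 0.07, t2d = 0.15),
                     fasting = c(normal = 0.08, t2d = 0.20),
                     random = c(normal = 0.12, t2d = 0.25)),
    facts_base = 15.7,
    facts_age_rate = 0.045,
    facts_t2d_mult = 1.15,
    facts_dep_mult = 1.4,
    facts_cap = 400,
    t2d_dx_sens = 0.95,
    t2d_med_prob = 0.90,
    t2d_insulin_prob = 0.15,
    p_t1d = 0.004,
    dep_dx_sens = 1.0,
    famhx_prob = 0.03,
    icd10_fraction = 0.12,
    seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(sex_ratio, p_depression_baseline, p_enroll_long, span_gap_prob,
             p_value_returned, p_hba1c, p_fasting, t2d_dx_sens, t2d_med_prob,
             t2d_insulin_prob, p_t1d, dep_dx_sens, famhx_prob, icd10_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]",
          class = "cohortsens_config_error")
  }
  if (!is.numeric(theta) || theta <= 0) {
    abort("theta (true comorbidity odds ratio) must be > 0",
          class = "cohortsens_config_error")
  }
  if (p_hba1c + p_fasting > 1) {
    abort("p_hba1c + p_fasting must not exceed 1",
          class = "cohortsens_config_error")
  }
  if (test_base < 0 || test_cap < 0 || facts_base < 0 || facts_cap < 0) {
    abort("rates must be non-negative", class = "cohortsens_config_error")
  }
  if (n_members < 1 || abs(sum(age_mixture$weight) - 1) > 1e-8) {
    abort("n_members must be >= 1 and age mixture weights must sum to 1",
          class = "cohortsens_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

#' Built-in synthetic ICD-10 to ICD-9 code map
#'
#' Covers exactly the ICD-10 codes the generator can emit (a synthetic
#' stand-in for a real terminology crosswalk, which a production run supplies
#' as a user config; see [read_code_map()]).
#'
#' @return A [code_map()].
#' @export
default_code_map <- function() {
  code_map(c("I10" = "401.9", "E78.5" = "272.4", "J18.9" = "486",
             "J02.9" = "462", "M54.5" = "724.2", "K21.9" = "530.81",
             "J45.909" = "493.90", "R53.81" = "780.79", "M79.1" = "729.5",
             "M25.561" = "719.46", "E11.9" = "250.00", "F32.9" = "311"))
}

background_icd9 <- c("401.9", "272.4", "486", "462", "724.2", "530.81",
                     "493.90", "780.79", "729.5", "719.46")
background_icd10 <- c("I10", "E78.5", "J18.9", "J02.9", "M54.5", "K21.9",
                      "J45.909", "R53.81", "M79.1", "M25.561")
t2d_dx_codes <- c("250.00", "250.02", "250.50")
t1d_dx_codes <- c("250.01", "250.03")
dep_dx_codes <- c("311", "296.20", "296.30", "300.4", "309.1")

draw_mixture_ages <- function(n, mixture, range) {
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  age <- round(rnorm(n, mixture$mean[comp], mixture$sd[comp]))
  bad <- age < range[1] | age > range[2]
  while (any(bad)) {
    k <- which(bad)
    age[k] <- round(rnorm(length(k), mixture$mean[comp[k]],
                          mixture$sd[comp[k]]))
    bad <- age < range[1] | age > range[2]
  }
  as.integer(age)
}

# Uniformly dated events for rep(members, counts); dates land in the first
# `placement_days` days of the member's enrollment (the phenotyping window),
# so configured emission probabilities act directly on window phenotypes.
make_events <- function(member_id, counts, span_start, placement_days,
                        kind, system, codes, value = NULL) {
  total <- sum(counts)
  if (total == 0) {
    return(tibble(member_id = character(), date = as.Date(character()),
                  kind = character(), system = character(),
                  code = character(), value = numeric()))
  }
  idx <- rep.int(seq_along(member_id), counts)
  offset <- floor(runif(total) * rep.int(placement_days, counts))
  tibble(member_id = rep.int(member_id, counts),
         date = span_start[idx] + offset,
         kind = kind, system = system,
         code = if (length(codes) == 1) codes else
           sample(codes, total, replace = TRUE),
         value = if (is.null(value)) NA_real_ else value)
}

#' Generate a synthetic claims dataset with latent truth
#'
#' Deterministic for a fixed seed. Members receive enrollment spans (a share
#' long enough to qualify for the 4-year window, some split by short
#' administrative gaps), latent T2D/depression statuses with the configured
#' marginals and comorbidity odds ratio, background diagnosis events at an
#' age- and morbidity-graded Poisson rate, glucose/HbA1c orders at an
#' age-increasing rate of which only `p_value_returned` return a value (drawn
#' conditional on latent T2D), and condition-specific diagnosis/medication
#' codes at the configured claims sensitivities. Phenotype-relevant events
#' are dated inside the first four years of enrollment.
#'
#' @param config A [synthetic_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List with elements `data` (a [claims_dataset()]) and `truth`
#'   (tibble `member_id,true_t2d,true_depression,tested`).
#' @export
generate_claims <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n_members
  id <- sprintf("M%07d", seq_len(n))
  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
  age <- draw_mixture_ages(n, config$age_mixture, config$age_range)

  # enrollment: start anywhere in 2008-2013, duration long (>= 4y) or short
  start <- as.Date("2008-01-01") + floor(runif(n) * 2191)
  long <- runif(n) < config$p_enroll_long
  dur <- ifelse(long, 1461 + floor(runif(n) * 1440),
                365 + floor(runif(n) * 1095))
  birth_year <- as.integer(format(start, "%Y")) - age
  members <- tibble(member_id = id, sex = sex, birth_year = birth_year)

  gap_split <- long & runif(n) < config$span_gap_prob
  gap <- 1L + floor(runif(n) * 31)
  cut <- floor(dur * runif(n, 0.3, 0.7))
  span_end <- start + dur - 1
  cut_end <- start + cut - 1
  tail_start <- start + cut + gap
  tail_end <- span_end + gap
  enrollment <- bind_rows(
    tibble(member_id = id[!gap_split], start = start[!gap_split],
           end = span_end[!gap_split]),
    tibble(member_id = id[gap_split], start = start[gap_split],
           end = cut_end[gap_split]),
    tibble(member_id = id[gap_split], start = tail_start[gap_split],
           end = tail_end[gap_split])) %>%
    arrange(.data$member_id, .data$start)

  # latent statuses: T2D logistic in age; depression with baseline odds
  # (anchored at age 45) times theta for T2D members, optionally logit-linear
  # in age (dep_age_slope > 0 makes depression, like testing, concentrate in
  # older members -- the informative-missingness configuration)
  p_t2d <- plogis(config$t2d_intercept + config$t2d_slope * age)
  true_t2d <- runif(n) < p_t2d
  lodds0 <- log(config$p_depression_baseline /
                  (1 - config$p_depression_baseline))
  p_dep <- plogis(lodds0 + config$dep_age_slope * (age - 45) +
                    ifelse(true_t2d, log(config$theta), 0))
  true_dep <- runif(n) < p_dep
  t1d <- !true_t2d & runif(n) < config$p_t1d

  # events are placed in the phenotyping window (first 4y of enrollment)
  place_days <- pmin(dur, 1461L)
  years <- place_days / 365.25

  facts_rate <- pmin(config$facts_cap,
                     config$facts_base *
                       exp(config$facts_age_rate * (age - 40)) *
                       ifelse(true_t2d, config$facts_t2d_mult, 1) *
                       ifelse(true_dep, config$facts_dep_mult, 1))
  n_bg <- rpois(n, facts_rate * years)
  n_bg10 <- rbinom(n, n_bg, config$icd10_fraction)
  ev_bg9 <- make_events(id, n_bg - n_bg10, start, place_days,
                        "diagnosis", "ICD9", background_icd9)
  ev_bg10 <- make_events(id, n_bg10, start, place_days,
                         "diagnosis", "ICD10", background_icd10)

  test_rate <- pmin(config$test_cap,
                    config$test_base * exp(config$test_age_rate * age) *
                      ifelse(true_t2d, config$test_t2d_mult, 1))
  n_orders <- rpois(n, test_rate * years)
  ev_orders <- make_events(id, n_orders, start, place_days,
                           "procedure", "CPT",
                           code_sets()$lab_order_cpt)
  n_results <- rbinom(n, n_orders, config$p_value_returned)
  res_idx <- rep.int(seq_len(n), n_results)
  n_res_total <- length(res_idx)
  if (n_res_total > 0) {
    u <- runif(n_res_total)
    analyte <- ifelse(u < config$p_hba1c, "hba1c",
                      ifelse(u < config$p_hba1c + config$p_fasting,
                             "fasting", "random"))
    status <- ifelse(true_t2d[res_idx], "t2d", "normal")
    mu <- sdl <- numeric(n_res_total)
    for (a in c("hba1c", "fasting", "random")) {
      for (s in c("normal", "t2d")) {
        k <- analyte == a & status == s
        mu[k] <- log(config$lab_means[[a]][[s]])
        sdl[k] <- config$lab_sdlog[[a]][[s]]
      }
    }
    val <- rlnorm(n_res_total, mu, sdl)
    loinc <- character(n_res_total)
    cs <- code_sets()
    loinc[analyte == "hba1c"] <- sample(cs$hba1c_loinc,
                                        sum(analyte == "hba1c"),
                                        replace = TRUE)
    loinc[analyte == "fasting"] <- "1558-6"
    loinc[analyte == "random"] <- sample(c("2339-0", "2345-7"),
                                         sum(analyte == "random"),
                                         replace = TRUE)
    ev_results <- tibble(
      member_id = id[res_idx],
      date = start[res_idx] + floor(runif(n_res_total) *
                                      place_days[res_idx]),
      kind = "lab_result", system = "LOINC", code = loinc,
      value = round(val, 1))
  } else {
    ev_results <- make_events(character(), integer(), start, place_days,
                              "lab_result", "LOINC", "1558-6")
  }

  t2d_detected <- true_t2d & runif(n) < config$t2d_dx_sens
  n_t2d_dx <- ifelse(t2d_detected, 1L + rpois(n, 2), 0L)
  ev_t2d <- make_events(id, n_t2d_dx, start, place_days,
                        "diagnosis", "ICD9", t2d_dx_codes)
  t2d_med <- true_t2d & runif(n) < config$t2d_med_prob
  n_med <- ifelse(t2d_med, 1L + rpois(n, 3), 0L)
  ev_med <- make_events(id, n_med, start, place_days,
                        "pharmacy", "NDC", code_sets()$t2d_meds)
  ins <- (true_t2d & runif(n) < config$t2d_insulin_prob) | t1d
  n_ins <- ifelse(ins, 1L + rpois(n, 2), 0L)
  ev_ins <- make_events(id, n_ins, start, place_days,
                        "pharmacy", "NDC", code_sets()$insulin_meds)
  n_t1d_dx <- ifelse(t1d, 1L + rpois(n, 1), 0L)
  ev_t1d <- make_events(id, n_t1d_dx, start, place_days,
                        "diagnosis", "ICD9", t1d_dx_codes)

  dep_detected <- true_dep & runif(n) < config$dep_dx_sens
  n_dep_dx <- ifelse(dep_detected, 1L + rpois(n, 1.5), 0L)
  ev_dep <- make_events(id, n_dep_dx, start, place_days,
                        "diagnosis", "ICD9", dep_dx_codes)

  n_fh <- as.integer(runif(n) < config$famhx_prob)
  ev_fh <- make_events(id, n_fh, start, place_days,
                       "diagnosis", "ICD9", "V18.0")

  events <- bind_rows(ev_bg9, ev_bg10, ev_orders, ev_results, ev_t2d,
                      ev_med, ev_ins, ev_t1d, ev_dep, ev_fh) %>%
    arrange(.data$member_id, .data$date, .data$kind, .data$code)

  truth <- tibble(member_id = id, true_t2d = true_t2d,
                  true_depression = true_dep, tested = n_orders > 0)
  list(data = claims_dataset(members, enrollment, events), truth = truth)
}

#' Summarize a generated dataset against its generating assumptions
#'
#' Reports the moments the generator is supposed to control: mean
#' glucose/HbA1c orders per member-year by age decade (the testing-intensity
#' curve), latent-class prevalences and the depression prevalence within each
#' T2D class, the fraction of orders with a returned value, and the mean age
#' of tested versus untested members (the informative-missingness gap).
#'
#' @param ds A generated [claims_dataset()].
#' @param truth The matching latent-truth tibble.
#' @return List of tibbles/scalars: `testing_by_decade`, `prevalence`,
#'   `value_return_fraction`, `mean_age_tested`, `mean_age_untested`,
#'   `hba1c` (mean/median of returned HbA1c values).
#' @export
empirical_summary <- function(ds, truth) {
  enrol1 <- ds$enrollment %>%
    group_by(.data$member_id) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    mutate(years = pmin(as.numeric(.data$end - .data$start) + 1, 1461) /
             365.25)
  cs <- code_sets()
  orders <- ds$events %>%
    filter(.data$kind == "procedure", .data$code %in% cs$lab_order_cpt) %>%
    count(.data$member_id, name = "n_orders")
  n_results <- sum(ds$events$kind == "lab_result" &
                     ds$events$code %in% c(cs$glucose_loinc, cs$hba1c_loinc))
  per_member <- ds$members %>%
    left_join(enrol1, by = "member_id") %>%
    mutate(age = as.integer(format(.data$start, "%Y")) - .data$birth_year,
           decade = pmin(.data$age %/% 10L, 8L) * 10L) %>%
    left_join(orders, by = "member_id") %>%
    mutate(n_orders = dplyr::coalesce(.data$n_orders, 0L)) %>%
    left_join(truth, by = "member_id")
  testing <- per_member %>%
    group_by(.data$decade) %>%
    summarise(members = n(),
              tests_per_member_year = mean(.data$n_orders / .data$years),
              .groups = "drop") %>%
    arrange(.data$decade)
  prevalence <- per_member %>%
    group_by(.data$true_t2d) %>%
    summarise(members = n(), p_depression = mean(.data$true_depression),
              .groups = "drop")
  a1c <- ds$events$value[ds$events$kind == "lab_result" &
                           ds$events$code %in% cs$hba1c_loinc]
  total_orders <- sum(per_member$n_orders)
  list(testing_by_decade = testing,
       prevalence = prevalence,
       value_return_fraction =
         if (total_orders > 0) n_results / total_orders else NA_real_,
       mean_age_tested = mean(per_member$age[per_member$n_orders > 0]),
       mean_age_untested = mean(per_member$age[per_member$n_orders == 0]),
       hba1c = c(mean = mean(a1c), median = median(a1c)))
}

#' Write generated claims plus truth table to a run directory
#'
#' Emits the three claims CSVs, `truth.csv`, and a `manifest.json` recording
#' the seed and a hash of the configuration.
#'
#' @param gen Result of [generate_claims()].
#' @param dir Output directory.
#' @param config The [synthetic_config()] used (for the manifest hash).
#' @return `dir`, invisibly.
#' @export
write_generated <- function(gen, dir, config = NULL) {
  write_claims(gen$data, dir)
  readr::write_csv(gen$truth, file.path(dir, "truth.csv"))
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(config)) config$seed else NA,
    config_hash = if (!is.null(config)) rlang::hash(unclass(config)) else NA,
    rows = list(members = nrow(gen$data$members),
                enrollment = nrow(gen$data$enrollment),
                events = nrow(gen$data$events)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
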