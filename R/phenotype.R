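# Rule-based (eMERGE-style) phenotyping: the T2D case tree, the four control
# eligibility variants that differ only in their glucose/HbA1c lab
# requirement, and the depression exposure definition.

#' Clinical code sets driving the phenotyping rules
#'
#' Named vocabularies used by the rules engine. Diagnosis sets are prefix
#' sets: a code matches if it starts with any listed prefix (so `"296.2"`
#' covers `296.20`-`296.26`). Defaults use the standard ICD-9-CM T2D/T1D
#' fifth-digit convention, the glucose/HbA1c LOINC and lab-order CPT codes of
#' the eMERGE T2D algorithm, ICD V18.0 for family history of diabetes, and an
#' editable depressive-disorders rollup (the CCS category ships as codes here
#' because CCS distributes groupers, not code lists). Medication sets are NDC
#' package codes and are deployment-specific (an ingredient-to-NDC map is a
#' user-supplied input); defaults match the synthetic generator's formulary.
#'
#' @param t2d_dx,t1d_dx,depression_dx,family_history ICD-9-CM prefix sets.
#' @param glucose_loinc,hba1c_loinc LOINC codes of returned lab values.
#' @param lab_order_cpt CPT codes indicating a glucose/HbA1c order.
#' @param t2d_meds,insulin_meds NDC sets for oral T2D agents and insulins.
#' @return A `code_sets` list.
#' @export
code_sets <- function(
    t2d_dx = c(sprintf("250.%d0", 0:9), sprintf("250.%d2", 0:9)),
    t1d_dx = c(sprintf("250.%d1", 0:9), sprintf("250.%d3", 0:9)),
    depression_dx = c("296.2", "296.3", "298.0", "300.4", "309.1", "311"),
    family_history = "V18.0",
    glucose_loinc = c("1558-6", "2339-0", "2345-7"),
    hba1c_loinc = c("4548-4", "17856-6", "4549-2", "17855-8"),
    lab_order_cpt = c("82947", "80047", "80048", "80053", "80069", "83036"),
    t2d_meds = c("00093-1048-01", "00093-7214-01", "00378-0221-01"),
    insulin_meds = c("00002-8215-01", "00088-2219-01")) {
  cs <- list(t2d_dx = t2d_dx, t1d_dx = t1d_dx, depression_dx = depression_dx,
             family_history = family_history, glucose_loinc = glucose_loinc,
             hba1c_loinc = hba1c_loinc, lab_order_cpt = lab_order_cpt,
             t2d_meds = t2d_meds, insulin_meds = insulin_meds)
  if (length(intersect(cs$t2d_dx, cs$t1d_dx))) {
    abort("t2d_dx and t1d_dx prefix sets must be disjoint",
          class = "cohortsens_config_error")
  }
  structure(cs, class = "code_sets")
}

#' Load code sets and thresholds from a YAML config
#'
#' @param path YAML file; any subset of the [code_sets()] and
#'   [phenotype_config()] fields may be given and overrides the default.
#' @return List with elements `codes` and `config`.
#' @export
read_phenotype_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cs_fields <- names(formals(code_sets))
  pc_fields <- names(formals(phenotype_config))
  codes <- do.call(code_sets,
                   lapply(raw[intersect(names(raw), cs_fields)], as.character))
  config <- do.call(phenotype_config, raw[intersect(names(raw), pc_fields)])
  list(codes = codes, config = config)
}

#' Phenotyping thresholds and rule options
#'
#' Case-side "abnormal" thresholds and control-side "normal" bounds for the
#' three lab families, the distinct-claim (visit) minimum for controls, and
#' the observation-window length. The source algorithm family fixes the
#' rule structure but implementations choose clinical thresholds; defaults
#' follow the usual diagnostic conventions (fasting glucose >= 126 mg/dL,
#' random glucose >= 200 mg/dL, HbA1c >= 6.5%) with stricter normal bounds on
#' the control side (< 110, < 140, < 6.0). All are overridable.
#'
#' @param window_years Observation window length in years.
#' @param min_visits Minimum distinct claims (any kind) a control must have.
#' @param abnormal_fasting_glucose,abnormal_random_glucose,abnormal_hba1c
#'   Case-side thresholds (value `>=` threshold is abnormal). Units: mg/dL,
#'   mg/dL, percent.
#' @param normal_fasting_glucose,normal_random_glucose,normal_hba1c
#'   Control-side bounds (every returned value must be strictly below its
#'   bound for the baseline control definition).
#' @param require_family_history_branch If `TRUE`, a family-history code plus
#'   an abnormal lab can substitute for a T2D diagnosis in the case tree
#'   (optional branch; off by default).
#' @return A `phenotype_config` list.
#' @export
phenotype_config <- function(window_years = 4,
                             min_visits = 2,
                             abnormal_fasting_glucose = 126,
                             abnormal_random_glucose = 200,
                             abnormal_hba1c = 6.5,
                             normal_fasting_glucose = 110,
                             normal_random_glucose = 140,
                             normal_hba1c = 6.0,
                             require_family_history_branch = FALSE) {
  cfg <- list(window_years = window_years, min_visits = min_visits,
              abnormal_fasting_glucose = abnormal_fasting_glucose,
              abnormal_random_glucose = abnormal_random_glucose,
              abnormal_hba1c = abnormal_hba1c,
              normal_fasting_glucose = normal_fasting_glucose,
              normal_random_glucose = normal_random_glucose,
              normal_hba1c = normal_hba1c,
              require_family_history_branch = require_family_history_branch)
  if (cfg$normal_fasting_glucose > cfg$abnormal_fasting_glucose ||
      cfg$normal_random_glucose > cfg$abnormal_random_glucose ||
      cfg$normal_hba1c > cfg$abnormal_hba1c) {
    abort("control-side normal bounds must not exceed case-side thresholds",
          class = "cohortsens_config_error")
  }
  structure(cfg, class = "phenotype_config")
}

#' The four control-definition variants
#' @return Character vector of variant names in presentation order.
#' @export
control_variants <- function() {
  c("baseline", "ignore_lab_value", "ignore_lab", "no_lab")
}

matches_prefix <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

# Per-member phenotyping flags, computed once from the windowed events.
# Everything downstream (case rule, all four control variants, exposure) is a
# pure function of these flags, so event order can never matter.
member_flags <- function(ds, codes, config) {
  win <- qualifying_windows(ds$enrollment, config$window_years)
  ev <- window_events(ds$events, win)

  dx <- ev$kind == "diagnosis" & ev$system == "ICD9"
  is_result <- ev$kind == "lab_result" & ev$system == "LOINC" &
    !is.na(ev$value) &
    ev$code %in% c(codes$glucose_loinc, codes$hba1c_loinc)
  fg <- is_result & ev$code == "1558-6"
  rg <- is_result & ev$code %in% setdiff(codes$glucose_loinc, "1558-6")
  a1c <- is_result & ev$code %in% codes$hba1c_loinc
  abnormal <- (fg & ev$value >= config$abnormal_fasting_glucose) |
    (rg & ev$value >= config$abnormal_random_glucose) |
    (a1c & ev$value >= config$abnormal_hba1c)
  above_normal <- (fg & ev$value >= config$normal_fasting_glucose) |
    (rg & ev$value >= config$normal_random_glucose) |
    (a1c & ev$value >= config$normal_hba1c)

  # one C-level aggregation pass per member (rowsum) instead of grouped
  # summaries: claims extracts run to millions of event rows
  mat <- cbind(
    t2d_dx = dx & matches_prefix(ev$code, codes$t2d_dx),
    t1d_dx = dx & matches_prefix(ev$code, codes$t1d_dx),
    dep_dx = dx & matches_prefix(ev$code, codes$depression_dx),
    famhx = dx & matches_prefix(ev$code, codes$family_history),
    t2d_med = ev$kind == "pharmacy" & ev$system == "NDC" &
      ev$code %in% codes$t2d_meds,
    insulin = ev$kind == "pharmacy" & ev$system == "NDC" &
      ev$code %in% codes$insulin_meds,
    abnormal = abnormal,
    above_normal = above_normal,
    n_orders = ev$kind == "procedure" & ev$system == "CPT" &
      ev$code %in% codes$lab_order_cpt,
    n_results = is_result,
    n_claims = rep(TRUE, nrow(ev)))
  agg <- rowsum(mat + 0L, ev$member_id)
  if (nrow(ev) == 0) {
    agg <- matrix(0L, 0, ncol(mat), dimnames = list(NULL, colnames(mat)))
  }
  flags <- tibble(
    member_id = rownames(agg) %||% character(0),
    t2d_dx = agg[, "t2d_dx"] > 0, t1d_dx = agg[, "t1d_dx"] > 0,
    dep_dx = agg[, "dep_dx"] > 0, famhx = agg[, "famhx"] > 0,
    t2d_med = agg[, "t2d_med"] > 0, insulin = agg[, "insulin"] > 0,
    abnormal = agg[, "abnormal"] > 0,
    above_normal = agg[, "above_normal"] > 0,
    n_orders = as.integer(agg[, "n_orders"]),
    n_results = as.integer(agg[, "n_results"]),
    n_claims = as.integer(agg[, "n_claims"]))

  win %>%
    left_join(ds$members, by = "member_id") %>%
    mutate(age = as.integer(format(.data$start, "%Y")) - .data$birth_year) %>%
    select("member_id", "age", "sex") %>%
    left_join(flags, by = "member_id") %>%
    mutate(dplyr::across(c("t2d_dx", "t1d_dx", "dep_dx", "famhx", "t2d_med",
                           "insulin", "abnormal", "above_normal"),
                         ~ dplyr::coalesce(.x, FALSE)),
           dplyr::across(c("n_orders", "n_results", "n_claims"),
                         ~ dplyr::coalesce(.x, 0L))) %>%
    left_join(facts_per_year(ds, win), by = "member_id")
}

# Case rule tree: (>=1 T2D dx) AND (T2D med OR abnormal glucose/HbA1c value)
# AND NOT (T1D dx without any T2D dx). With the optional family-history
# branch, famhx + abnormal lab substitutes for the T2D diagnosis.
case_flag <- function(fl, config) {
  dx_branch <- fl$t2d_dx
  if (isTRUE(config$require_family_history_branch)) {
    dx_branch <- dx_branch | (fl$famhx & fl$abnormal)
  }
  dx_branch & (fl$t2d_med | fl$abnormal) & !(fl$t1d_dx & !fl$t2d_dx)
}

# Exclusions shared by every control variant, in audit order.
control_exclusion <- function(fl, config) {
  dplyr::case_when(
    fl$t2d_dx ~ "t2d_dx",
    fl$t1d_dx ~ "t1d_dx",
    fl$t2d_med | fl$insulin ~ "diabetes_med",
    fl$famhx ~ "family_history",
    fl$n_claims < config$min_visits ~ "min_visits",
    .default = NA_character_)
}

variant_lab_rule <- function(fl, variant) {
  switch(variant,
    baseline = fl$n_results >= 1 & !fl$above_normal,
    ignore_lab_value = fl$n_results >= 1,
    ignore_lab = rep(TRUE, nrow(fl)),
    no_lab = fl$n_orders == 0 & fl$n_results == 0,
    abort(paste0("unknown control variant: ", variant),
          class = "cohortsens_config_error"))
}

#' Build case/control cohort tables for each control variant
#'
#' Applies, in order: enrollment windowing, the T2D case rule tree, the shared
#' control exclusions (no T2D/T1D diagnosis, no diabetes medication, no
#' family-history code, a minimum distinct-claim count), the variant-specific
#' glucose/HbA1c lab rule, and the depression exposure definition. Members
#' failing a rule are labeled `excluded` with the first failing rule for
#' audit.
#'
#' @param ds A [claims_dataset()] (code-mapped: no ICD-10 events).
#' @param codes [code_sets()].
#' @param config [phenotype_config()].
#' @param variants Subset of [control_variants()] to build.
#' @param on_empty `"error"` (default) aborts when a variant has an empty case
#'   or control population; `"keep"` returns the table anyway.
#' @return Named list (one per variant) of cohort tibbles with columns
#'   `member_id`, `status` (`case`/`control`/`excluded`), `exclusion_reason`,
#'   `exposed` (depression diagnosis in window), `age`, `sex`,
#'   `facts_per_year`.
#' @export
build_cohorts <- function(ds, codes = code_sets(),
                          config = phenotype_config(),
                          variants = control_variants(),
                          on_empty = c("error", "keep")) {
  on_empty <- arg_match(on_empty)
  stopifnot(all(variants %in% control_variants()))
  if (any(ds$events$system == "ICD10")) {
    abort("dataset contains ICD-10 events; apply_code_map() first",
          class = "cohortsens_config_error")
  }
  fl <- member_flags(ds, codes, config)
  is_case <- case_flag(fl, config)
  shared_excl <- control_exclusion(fl, config)

  out <- lapply(variants, function(v) {
    lab_ok <- variant_lab_rule(fl, v)
    status <- dplyr::case_when(is_case ~ "case",
                               is.na(shared_excl) & lab_ok ~ "control",
                               .default = "excluded")
    reason <- dplyr::case_when(
      status != "excluded" ~ NA_character_,
      !is.na(shared_excl) ~ shared_excl,
      .default = "lab_rule")
    tab <- tibble(member_id = fl$member_id, status = status,
                  exclusion_reason = reason, exposed = fl$dep_dx,
                  age = fl$age, sex = fl$sex,
                  facts_per_year = fl$facts_per_year)
    if (on_empty == "error") {
      if (!any(tab$status == "case")) {
        abort(paste0("empty case population (variant '", v, "')"),
              class = "cohortsens_empty_cohort")
      }
      if (!any(tab$status == "control")) {
        abort(paste0("empty control population for variant '", v, "'"),
              class = "cohortsens_empty_cohort")
      }
    }
    tab
  })
  setNames(out, variants)
}

#' Classify members as T2D cases
#'
#' @inheritParams build_cohorts
#' @return Tibble `member_id,case` over windowed members.
#' @export
classify_case <- function(ds, codes = code_sets(),
                          config = phenotype_config()) {
  fl <- member_flags(ds, codes, config)
  tibble(member_id = fl$member_id, case = case_flag(fl, config))
}

#' Classify members as eligible controls under one variant
#'
#' Cases are never controls; the shared exclusions and the variant's lab rule
#' are applied to everyone else.
#'
#' @inheritParams build_cohorts
#' @param variant One of [control_variants()].
#' @return Tibble `member_id,control` over windowed members.
#' @export
classify_control <- function(ds, variant, codes = code_sets(),
                             config = phenotype_config()) {
  fl <- member_flags(ds, codes, config)
  ok <- !case_flag(fl, config) & is.na(control_exclusion(fl, config)) &
    variant_lab_rule(fl, variant)
  tibble(member_id = fl$member_id, control = ok)
}

#' Classify depression exposure
#'
#' Exposed means at least one diagnosis event in the observation window whose
#' code falls in the depressive-disorders rollup.
#'
#' @inheritParams build_cohorts
#' @return Tibble `member_id,exposed` over windowed members.
#' @export
classify_exposure <- function(ds, codes = code_sets(),
                              config = phenotype_config()) {
  fl <- member_flags(ds, codes, config)
  tibble(member_id = fl$member_id, exposed = fl$dep_dx)
}
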