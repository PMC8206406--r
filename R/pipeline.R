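# Orchestration: generate -> code-map -> phenotype -> match -> associate ->
# report, driven by one serializable configuration with per-stage seeds.

#' Full run configuration
#'
#' @param synthetic A [synthetic_config()] (the data source for a simulated
#'   run). Set to `NULL` and supply `data_dir` to run on claims read from
#'   disk instead.
#' @param data_dir Directory of claims CSVs when `synthetic` is `NULL`.
#' @param codes,phenotype [code_sets()] and [phenotype_config()].
#' @param code_map A [code_map()] for ICD-10 translation.
#' @param max_gap_days Enrollment-span merge tolerance, days.
#' @param variants Control-definition variants to run.
#' @param matched Logical vector: run unmatched and/or age/sex-matched arms.
#' @param n Per-arm bootstrap sample sizes.
#' @param reps Bootstrap replicates per cell.
#' @param alpha Two-sided significance level.
#' @param match_mode `"population"` (match once, then bootstrap the matched
#'   populations; default) or `"per_replicate"` (draw stratum-matched
#'   controls afresh inside every replicate).
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       data_dir = NULL,
                       codes = code_sets(),
                       phenotype = phenotype_config(),
                       code_map = default_code_map(),
                       max_gap_days = 31,
                       variants = control_variants(),
                       matched = c(FALSE, TRUE),
                       n = c(1000, 2000, 5000, 10000),
                       reps = 200,
                       alpha = 0.05,
                       match_mode = c("population", "per_replicate"),
                       seed = 1L) {
  match_mode <- arg_match(match_mode)
  structure(list(synthetic = synthetic, data_dir = data_dir, codes = codes,
                 phenotype = phenotype, code_map = code_map,
                 max_gap_days = max_gap_days, variants = variants,
                 matched = matched, n = n, reps = reps, alpha = alpha,
                 match_mode = match_mode, seed = as.integer(seed)),
            class = "run_config")
}

stage_seed <- function(cfg, stage) {
  offsets <- c(generate = 11L, match = 23L, associate = 37L)
  (cfg$seed * 1000L + offsets[[stage]]) %% 2000000011L
}

cohort_arm <- function(tab, which) tab[tab$status == which, , drop = FALSE]

# Per-replicate stratum matching: each replicate draws n cases (with
# replacement) from the strata that have controls, then a same-stratum
# control per sampled case.
bootstrap_matched <- function(cases, controls, n, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  key <- function(df) paste(df$age, df$sex)
  ctrl_by_stratum <- split(controls$exposed, key(controls))
  cases <- cases[key(cases) %in% names(ctrl_by_stratum), , drop = FALSE]
  if (nrow(cases) == 0) {
    abort("no (age, sex) stratum contains both a case and a control",
          class = "cohortsens_empty_cohort")
  }
  ck <- key(cases)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(nrow(cases), n, replace = TRUE)
    ce <- cases$exposed[idx]
    strat_n <- table(ck[idx])
    xe <- unlist(lapply(names(strat_n), function(s) {
      pool <- ctrl_by_stratum[[s]]
      pool[sample.int(length(pool), strat_n[[s]], replace = TRUE)]
    }), use.names = FALSE)
    ft <- fisher_exact(contingency(ce, xe))
    out[[r]] <- tibble(replicate = r, n = n,
                       a = sum(ce), b = n - sum(ce),
                       c = sum(xe), d = n - sum(xe),
                       odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  }
  bind_rows(out)
}

age_histogram <- function(cohort, bin_width = 5) {
  cohort %>%
    mutate(age_bin = (.data$age %/% bin_width) * bin_width) %>%
    count(.data$age_bin, name = "members") %>%
    arrange(.data$age_bin)
}

#' Run the whole sensitivity-analysis pipeline
#'
#' Generates (or reads) claims, maps ICD-10 codes, merges enrollment spans,
#' builds the case cohort and all configured control-definition cohorts,
#' summarizes their demographics, matches controls to cases exactly on age
#' and sex, and computes the bootstrap Fisher odds-ratio grid over
#' (variant x matched x sample size). Fully deterministic for a fixed
#' configuration.
#'
#' @param cfg A [run_config()].
#' @return A `report_bundle`: list with `config_hash`, `seed`, `cohorts`
#'   (per-variant tables), `truth` (when simulated), `demographics` (case +
#'   per-variant control rows), `matched_demographics`, `match_drops`,
#'   `age_distributions`, `summaries` (one row per grid cell), `replicates`
#'   (per-replicate results), and `log` (stage row counts).
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  truth <- NULL
  if (!is.null(cfg$synthetic)) {
    gen <- generate_claims(cfg$synthetic, seed = stage_seed(cfg, "generate"))
    ds <- gen$data
    truth <- gen$truth
  } else {
    ds <- read_claims(cfg$data_dir)
  }
  log <- list(members = nrow(ds$members), events = nrow(ds$events))

  ds <- apply_code_map(ds, cfg$code_map, unmapped = "error")
  ds$enrollment <- merge_enrollment_spans(ds$enrollment, cfg$max_gap_days)

  cohorts <- tryCatch(
    build_cohorts(ds, cfg$codes, cfg$phenotype, cfg$variants),
    cohortsens_empty_cohort = function(e) {
      abort(paste0("stage 'phenotype' failed: ", conditionMessage(e),
                   "; rerun with run_pipeline(<same config>)"),
            class = "cohortsens_stage_error", parent = e)
    })
  cases <- cohort_arm(cohorts[[1]], "case")
  log$cases <- nrow(cases)

  demographics <- bind_rows(
    demographic_summary(cases, "case"),
    bind_rows(lapply(cfg$variants, function(v) {
      demographic_summary(cohort_arm(cohorts[[v]], "control"), v)
    })))

  age_distributions <- bind_rows(
    age_histogram(cases) %>% mutate(population = "case"),
    bind_rows(lapply(cfg$variants, function(v) {
      age_histogram(cohort_arm(cohorts[[v]], "control")) %>%
        mutate(population = v)
    }))) %>%
    select("population", "age_bin", "members")

  matches <- list()
  matched_demographics <- list()
  match_drops <- list()
  if (any(cfg$matched)) {
    for (i in seq_along(cfg$variants)) {
      v <- cfg$variants[i]
      controls <- cohort_arm(cohorts[[v]], "control")
      m <- exact_match(cases, controls,
                       seed = stage_seed(cfg, "match") + i)
      pops <- matched_populations(m, cases, controls)
      matches[[v]] <- pops
      matched_demographics[[v]] <- bind_rows(
        demographic_summary(pops$cases, paste0("case_matched_", v)),
        demographic_summary(pops$controls, paste0(v, "_matched")))
      match_drops[[v]] <- tibble(
        variant = v, pairs = nrow(m$pairs),
        dropped_cases = length(m$dropped_cases),
        dropped_controls = length(m$dropped_controls))
    }
  }

  empty_summary <- tibble(variant = character(), matched = logical(),
                          n = numeric(), reps = integer(),
                          median_or = numeric(), ci_low = numeric(),
                          ci_high = numeric(), ci_range = numeric(),
                          n_nonsignificant = integer())
  empty_replicates <- tibble(replicate = integer(), n = numeric(),
                             a = integer(), b = integer(), c = integer(),
                             d = integer(), odds_ratio = numeric(),
                             p_value = numeric(), variant = character(),
                             matched = logical())
  grid <- expand.grid(variant = cfg$variants, matched = cfg$matched,
                      n = cfg$n, stringsAsFactors = FALSE)
  summaries <- vector("list", nrow(grid))
  replicates <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    v <- grid$variant[g]
    m <- grid$matched[g]
    nn <- grid$n[g]
    aseed <- stage_seed(cfg, "associate") + g
    if (m && cfg$match_mode == "per_replicate") {
      controls <- cohort_arm(cohorts[[v]], "control")
      res <- bootstrap_matched(cases, controls, nn, cfg$reps, seed = aseed)
    } else {
      if (m) {
        arm_case <- matches[[v]]$cases$exposed
        arm_ctrl <- matches[[v]]$controls$exposed
      } else {
        arm_case <- cases$exposed
        arm_ctrl <- cohort_arm(cohorts[[v]], "control")$exposed
      }
      res <- bootstrap_association(arm_case, arm_ctrl, nn, cfg$reps,
                                   seed = aseed)
    }
    s <- summarize_replicates(res, cfg$alpha)
    summaries[[g]] <- tibble(variant = v, matched = m) %>%
      dplyr::bind_cols(s)
    replicates[[g]] <- res %>% mutate(variant = v, matched = m)
  }

  structure(
    list(config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
         cohorts = cohorts, truth = truth,
         demographics = demographics,
         matched_demographics = bind_rows(matched_demographics),
         match_drops = bind_rows(match_drops),
         age_distributions = age_distributions,
         summaries = bind_rows(c(list(empty_summary), summaries)),
         replicates = bind_rows(c(list(empty_replicates), replicates)),
         log = log),
    class = "report_bundle")
}

fmt2 <- function(x) formatC(x, format = "f", digits = 2)

format_demographics <- function(demo) {
  tibble(population = demo$population,
         members = demo$members,
         pct_male = fmt2(demo$pct_male),
         pct_female = fmt2(demo$pct_female),
         age = paste0(fmt2(demo$age_mean), " (", fmt2(demo$age_sd), ")"),
         pct_depression = fmt2(demo$pct_depression),
         facts_per_year = paste0(fmt2(demo$facts_mean), " (",
                                 fmt2(demo$facts_sd), ")"))
}

#' Write a report bundle to a run directory
#'
#' Emits the demographic tables (cohort-characteristics layout, percentages
#' rounded to 2 decimals), binned age distributions, the bootstrap summary
#' grid and per-replicate results as CSVs with stable column order, a
#' human-readable `summary.txt`, and a `manifest.json` recording the seed and
#' config hash.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) {
    abort(paste0("cannot create output directory: ", dir),
          class = "cohortsens_io_error")
  }
  readr::write_csv(format_demographics(bundle$demographics),
                   file.path(dir, "demographics.csv"))
  if (nrow(bundle$matched_demographics) > 0) {
    readr::write_csv(format_demographics(bundle$matched_demographics),
                     file.path(dir, "matched_demographics.csv"))
  }
  readr::write_csv(bundle$age_distributions,
                   file.path(dir, "age_distributions.csv"))
  readr::write_csv(bundle$summaries,
                   file.path(dir, "bootstrap_summaries.csv"))
  readr::write_csv(bundle$replicates, file.path(dir, "replicates.csv"))
  jsonlite::write_json(
    list(seed = bundle$seed, config_hash = bundle$config_hash,
         log = bundle$log,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  s <- bundle$summaries
  lines <- c("Bootstrap Fisher odds-ratio summaries",
             "(median [2.5%, 97.5%] over replicates; n per arm)", "")
  if (nrow(s) > 0) {
    lines <- c(lines, sprintf(
      "%-18s %-9s n=%-6d OR %s [%s, %s]  nonsig %d/%d",
      s$variant, ifelse(s$matched, "matched", "unmatched"), s$n,
      fmt2(s$median_or), fmt2(s$ci_low), fmt2(s$ci_high),
      s$n_nonsignificant, s$reps))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
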