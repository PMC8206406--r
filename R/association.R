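# Exposure-by-status 2x2 tables, Fisher's exact test, bootstrap odds-ratio
# distributions and their summaries.

#' Construct a 2x2 exposure-by-arm table
#'
#' @param a Exposed cases. @param b Unexposed cases.
#' @param c Exposed controls. @param d Unexposed controls.
#' @return A `table2x2` object.
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("2x2 cells must be non-negative integers",
          class = "cohortsens_config_error")
  }
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Tabulate exposure counts for two arms
#'
#' @param case_exposed,control_exposed Logical exposure flags of the sampled
#'   case and control members.
#' @return A [table2x2()].
#' @export
contingency <- function(case_exposed, control_exposed) {
  if (length(case_exposed) == 0 || length(control_exposed) == 0) {
    abort("both arms must be non-empty", class = "cohortsens_empty_cohort")
  }
  table2x2(sum(case_exposed), sum(!case_exposed),
           sum(control_exposed), sum(!control_exposed))
}

# Sample odds ratio with the Haldane-Anscombe +0.5 continuity correction
# applied to every cell iff any cell is zero.
sample_or <- function(a, b, c, d) {
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

# Two-sided Fisher p by the point-probability rule: sum the hypergeometric
# probabilities of all margin-fixed tables no more probable than the observed
# one (relative tolerance guards floating-point ties).
fisher_p <- function(a, b, c, d) {
  n_case <- a + b
  n_ctrl <- c + d
  k <- a + c
  support <- max(0L, k - n_ctrl):min(k, n_case)
  probs <- dhyper(support, n_case, n_ctrl, k)
  p_obs <- dhyper(a, n_case, n_ctrl, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher's exact test on a 2x2 table
#'
#' Reports the sample odds ratio `(a*d)/(b*c)` (with the Haldane-Anscombe
#' +0.5 correction to all cells iff any cell is zero) and the two-sided exact
#' p-value: the sum of probabilities of all tables with the observed margins
#' whose point hypergeometric probability does not exceed that of the
#' observed table.
#'
#' @param t A [table2x2()].
#' @return Named list with elements `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(t) {
  if (!inherits(t, "table2x2")) {
    abort("fisher_exact expects a table2x2", class = "cohortsens_config_error")
  }
  if (t$a + t$b == 0L || t$c + t$d == 0L ||
      t$a + t$c == 0L || t$b + t$d == 0L) {
    abort("fisher_exact requires all margins positive",
          class = "cohortsens_degenerate_table")
  }
  list(odds_ratio = sample_or(t$a, t$b, t$c, t$d),
       p_value = fisher_p(t$a, t$b, t$c, t$d))
}

#' Population odds ratio implied by two exposure prevalences
#'
#' The analytic oracle for simulation checks:
#' `(p1/(1-p1)) / (p0/(1-p0))`.
#'
#' @param p1,p0 Exposure prevalence in the case and control population,
#'   strictly inside (0, 1).
#' @return The odds ratio.
#' @export
odds_ratio_from_prevalence <- function(p1, p0) {
  if (any(c(p1, p0) <= 0) || any(c(p1, p0) >= 1)) {
    abort("prevalences must lie strictly in (0, 1)",
          class = "cohortsens_config_error")
  }
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' Control prevalence that yields a target odds ratio
#'
#' Inverse of [odds_ratio_from_prevalence()] in its second argument.
#'
#' @param p1 Case-arm exposure prevalence.
#' @param or Target odds ratio.
#' @return The control-arm prevalence.
#' @export
prevalence_for_odds_ratio <- function(p1, or) {
  q <- (p1 / (1 - p1)) / or
  q / (1 + q)
}

#' Bootstrap the Fisher odds ratio over resampled cohorts
#'
#' Per replicate, draws `n` members from each arm's population (with
#' replacement by default, the bootstrap; optionally without, as subsampling),
#' forms the 2x2 exposure table, and runs [fisher_exact()].
#'
#' @param case_exposed,control_exposed Logical exposure flags of the case and
#'   control populations.
#' @param n Per-arm sample size of each replicate.
#' @param reps Number of replicates (default 200).
#' @param seed Optional integer seed.
#' @param replace Sample with replacement (default `TRUE`). Without
#'   replacement, `n` must not exceed either population.
#' @return Tibble `replicate,n,a,b,c,d,odds_ratio,p_value` with `reps` rows.
#' @export
bootstrap_association <- function(case_exposed, control_exposed, n,
                                  reps = 200, seed = NULL, replace = TRUE) {
  if (length(case_exposed) == 0 || length(control_exposed) == 0) {
    abort("both populations must be non-empty",
          class = "cohortsens_empty_cohort")
  }
  stopifnot(n >= 1, reps >= 1)
  if (!replace && n > min(length(case_exposed), length(control_exposed))) {
    abort("n exceeds a population size and replace = FALSE",
          class = "cohortsens_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    ce <- case_exposed[sample.int(length(case_exposed), n,
                                  replace = replace)]
    xe <- control_exposed[sample.int(length(control_exposed), n,
                                     replace = replace)]
    ft <- fisher_exact(contingency(ce, xe))
    out[[r]] <- tibble(replicate = r, n = n,
                       a = sum(ce), b = n - sum(ce),
                       c = sum(xe), d = n - sum(xe),
                       odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  }
  bind_rows(out)
}

#' Bootstrap the odds ratio for Bernoulli arms with known prevalences
#'
#' The simulation used to check the method against printed prevalences: each
#' replicate draws `n` Bernoulli exposures per arm at the given prevalences
#' (equivalent to bootstrap resampling from an infinite population) and runs
#' [fisher_exact()].
#'
#' @param p_case,p_control True exposure prevalence of each arm.
#' @inheritParams bootstrap_association
#' @return Tibble as in [bootstrap_association()].
#' @export
simulate_association <- function(p_case, p_control, n, reps = 200,
                                 seed = NULL) {
  stopifnot(p_case >= 0, p_case <= 1, p_control >= 0, p_control <= 1,
            n >= 1, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- rbinom(reps, n, p_case)
  c <- rbinom(reps, n, p_control)
  res <- lapply(seq_len(reps), function(r) {
    fisher_exact(table2x2(a[r], n - a[r], c[r], n - c[r]))
  })
  tibble(replicate = seq_len(reps), n = n,
         a = a, b = n - a, c = c, d = n - c,
         odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
         p_value = vapply(res, `[[`, numeric(1), "p_value"))
}

#' Summarize a bootstrap odds-ratio distribution
#'
#' Median and 2.5/97.5 percentile of the replicate odds ratios, the CI range,
#' and the count of non-significant replicates (two-sided `p >= alpha`).
#'
#' @param results Replicate tibble from [bootstrap_association()] or
#'   [simulate_association()].
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble `n,reps,median_or,ci_low,ci_high,ci_range,
#'   n_nonsignificant`.
#' @export
summarize_replicates <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) >= 2)
  q <- quantile(results$odds_ratio, c(0.025, 0.975), names = FALSE)
  tibble(n = results$n[1], reps = nrow(results),
         median_or = median(results$odds_ratio),
         ci_low = q[1], ci_high = q[2], ci_range = q[2] - q[1],
         n_nonsignificant = sum(results$p_value >= alpha))
}

#' Ratio of bootstrap CI widths between two sample sizes
#'
#' How much wider the 95% percentile CI of the odds-ratio distribution is at
#' the smaller sample size (expected to scale as `1/sqrt(n)` on the log-OR
#' scale).
#'
#' @param s_small_n,s_large_n [summarize_replicates()] rows at the smaller
#'   and larger `n`.
#' @return `s_small_n$ci_range / s_large_n$ci_range`.
#' @export
ci_width_ratio <- function(s_small_n, s_large_n) {
  if (s_large_n$ci_range == 0) {
    abort("denominator CI range is zero",
          class = "cohortsens_degenerate_table")
  }
  s_small_n$ci_range / s_large_n$ci_range
}
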