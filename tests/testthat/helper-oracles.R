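# Independent brute-force oracle for Fisher's exact test: enumerate every
# table with the observed margins, compute point probabilities from binomial
# coefficients (not dhyper), and sum those no more probable than observed.
oracle_fisher <- function(a, b, c, d) {
  n1 <- a + b
  n2 <- c + d
  k <- a + c
  N <- n1 + n2
  xs <- max(0, k - n2):min(k, n1)
  probs <- choose(n1, xs) * choose(n2, k - xs) / choose(N, k)
  p_obs <- choose(n1, a) * choose(n2, c) / choose(N, k)
  or <- if (a == 0 || b == 0 || c == 0 || d == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
}

# Toy claims builders: members enrolled 2010-01-01..2013-12-31, which is
# exactly the 1461-day (4-year) qualifying window.
toy_members <- function(n, age = 50, sex = "male") {
  tibble::tibble(member_id = sprintf("T%02d", seq_len(n)),
                 sex = rep_len(sex, n),
                 birth_year = 2010L - rep_len(age, n))
}

toy_enrollment <- function(members, start = "2010-01-01",
                           end = "2013-12-31") {
  tibble::tibble(member_id = members$member_id,
                 start = as.Date(start), end = as.Date(end))
}

toy_event <- function(member_id, code, kind = "diagnosis", system = "ICD9",
                      date = "2011-06-01", value = NA_real_) {
  tibble::tibble(member_id = member_id, date = as.Date(date), kind = kind,
                 system = system, code = code, value = value)
}

no_events <- function() toy_event(character(), character())[0, ]

toy_dataset <- function(members, events = no_events(),
                        enrollment = toy_enrollment(members)) {
  claims_dataset(members, enrollment, events)
}

# A member's minimal claim history for a given archetype, appended to events.
visits <- function(id, n = 3, code = "401.9") {
  toy_event(rep(id, n), rep(code, n),
            date = as.Date("2011-01-01") + seq_len(n))
}
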