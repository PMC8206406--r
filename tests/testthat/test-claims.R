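test_that("packaged demo fixture reads with expected rows and mapping flag", {
  dir <- system.file("extdata", "demo", package = "cohortsens")
  ds <- read_claims(dir)
  expect_s3_class(ds, "claims_dataset")
  expect_identical(nrow(ds$members), 3L)
  expect_identical(nrow(ds$events), 3L)
  expect_identical(sum(ds$events$system == "ICD10"), 1L)
})

test_that("empty member file yields an empty dataset and no cohorts", {
  dir <- withr::local_tempdir()
  ds0 <- claims_dataset(toy_members(0), toy_enrollment(toy_members(0)),
                        no_events())
  write_claims(ds0, dir)
  ds <- read_claims(dir)
  expect_identical(nrow(ds$members), 0L)
  expect_identical(nrow(qualifying_windows(ds$enrollment)), 0L)
  expect_error(build_cohorts(ds), class = "cohortsens_empty_cohort")
})

test_that("schema violations are reported by column name", {
  dir <- withr::local_tempdir()
  write_claims(toy_dataset(toy_members(2)), dir)
  bad <- readr::read_csv(file.path(dir, "members.csv"),
                         show_col_types = FALSE)
  names(bad)[1] <- "memberid"
  readr::write_csv(bad, file.path(dir, "members.csv"))
  expect_error(read_claims(dir), class = "cohortsens_schema_error",
               regexp = "member_id")
})

test_that("unknown columns are dropped with a warning", {
  dir <- withr::local_tempdir()
  write_claims(toy_dataset(toy_members(2)), dir)
  m <- readr::read_csv(file.path(dir, "members.csv"), show_col_types = FALSE)
  m$plan_code <- "X"
  readr::write_csv(m, file.path(dir, "members.csv"))
  expect_warning(ds <- read_claims(dir), regexp = "plan_code")
  expect_false("plan_code" %in% names(ds$members))
})

test_that("unparseable dates are an error naming the line", {
  dir <- withr::local_tempdir()
  mem <- toy_members(1)
  write_claims(toy_dataset(mem), dir)
  writeLines(c("member_id,start,end", "T01,2010-01-01,notadate"),
             file.path(dir, "enrollment.csv"))
  expect_error(read_claims(dir), class = "cohortsens_parse_error",
               regexp = "line")
})

test_that("read -> write -> read round-trips bit-identically", {
  src <- system.file("extdata", "demo", package = "cohortsens")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_claims(read_claims(src), d1)
  write_claims(read_claims(d1), d2)
  for (f in c("members.csv", "enrollment.csv", "events.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_equal(read_claims(d1), read_claims(d2))
})

test_that("code mapping rewrites ICD-10 events and is idempotent", {
  mem <- toy_members(1)
  ds <- toy_dataset(mem, toy_event("T01", "E11.9", system = "ICD10"))
  m <- code_map(c("E11.9" = "250.00"))
  out <- apply_code_map(ds, m)
  expect_identical(out$events$code, "250.00")
  expect_identical(out$events$system, "ICD9")
  expect_equal(apply_code_map(out, m), out)

  icd9_only <- toy_dataset(mem, toy_event("T01", "401.9"))
  expect_equal(apply_code_map(icd9_only, m), icd9_only)
})

test_that("unmapped codes error under strict policy and drop under drop", {
  ds <- toy_dataset(toy_members(1),
                    toy_event("T01", "Z99.9", system = "ICD10"))
  m <- code_map(c("E11.9" = "250.00"))
  expect_error(apply_code_map(ds, m), class = "cohortsens_unmapped_code",
               regexp = "Z99.9")
  expect_warning(out <- apply_code_map(ds, m, unmapped = "drop"),
                 regexp = "Z99.9")
  expect_identical(nrow(out$events), 0L)
})

test_that("code maps load from two-column CSV", {
  path <- system.file("extdata", "icd10_to_icd9_synthetic.csv",
                      package = "cohortsens")
  m <- read_code_map(path)
  expect_s3_class(m, "code_map")
  expect_identical(unname(m$entries[["I10"]]), "401.9")
  ds <- toy_dataset(toy_members(1),
                    toy_event("T01", "I10", system = "ICD10"))
  expect_identical(apply_code_map(ds, m)$events$code, "401.9")
})

test_that("qualifying windows follow the 4-year first-span contract", {
  # 6-year span: window is its first 1461 days
  e1 <- tibble::tibble(member_id = "A", start = as.Date("2010-01-01"),
                       end = as.Date("2015-12-31"))
  w <- qualifying_windows(e1)
  expect_identical(w$start, as.Date("2010-01-01"))
  expect_identical(w$end, as.Date("2013-12-31"))

  # two 3-year spans with a wide gap: ineligible
  e2 <- tibble::tibble(member_id = "B",
                       start = as.Date(c("2008-01-01", "2012-01-01")),
                       end = as.Date(c("2010-12-31", "2014-12-31")))
  expect_identical(nrow(qualifying_windows(e2)), 0L)

  # but the same member qualifies once short gaps are merged
  e3 <- tibble::tibble(member_id = "C",
                       start = as.Date(c("2010-01-01", "2012-01-20")),
                       end = as.Date(c("2012-01-01", "2014-12-31")))
  expect_identical(nrow(qualifying_windows(e3)), 0L)
  merged <- merge_enrollment_spans(e3, max_gap_days = 31)
  expect_identical(nrow(merged), 1L)
  wm <- qualifying_windows(merged)
  expect_identical(wm$end - wm$start, as.difftime(1460, units = "days"))

  # span of exactly 4 years: window equals the span
  e4 <- tibble::tibble(member_id = "D", start = as.Date("2010-01-01"),
                       end = as.Date("2013-12-31"))
  w4 <- qualifying_windows(e4)
  expect_identical(w4$end, e4$end)

  # a window never exceeds its enrollment span
  expect_true(all(w$end <= e1$end))
})

test_that("span merging respects the gap tolerance", {
  e <- tibble::tibble(member_id = c("A", "A", "A"),
                      start = as.Date(c("2010-01-01", "2011-02-01",
                                        "2013-06-01")),
                      end = as.Date(c("2011-01-15", "2012-01-01",
                                      "2014-01-01")))
  m <- merge_enrollment_spans(e, max_gap_days = 31)
  expect_identical(nrow(m), 2L)  # 16-day gap merged, 1.4-year gap kept
  m0 <- merge_enrollment_spans(e, max_gap_days = 0)
  expect_identical(nrow(m0), 3L)
})

test_that("facts per year divides windowed diagnosis counts by window years", {
  mem <- toy_members(2)
  ev <- dplyr::bind_rows(
    toy_event(rep("T01", 8), rep("401.9", 8),
              date = as.Date("2011-01-01") + 1:8),
    toy_event("T01", "82947", kind = "procedure", system = "CPT"),
    toy_event("T01", "401.9", date = "2019-06-01"))  # outside window
  ds <- toy_dataset(mem, ev,
                    enrollment = toy_enrollment(mem, end = "2019-12-31"))
  f <- facts_per_year(ds, qualifying_windows(ds$enrollment))
  expect_equal(f$facts_per_year[f$member_id == "T01"], 2.0)
  expect_equal(f$facts_per_year[f$member_id == "T02"], 0.0)
})
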