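# One toy family of members exercises every branch of the case tree and the
# four control-definition lab rules.
toy_cohort_dataset <- function() {
  mem <- toy_members(8)
  ev <- dplyr::bind_rows(
    # T01: T2D dx + metformin-like NDC -> case
    toy_event("T01", "250.00"),
    toy_event("T01", "00093-1048-01", kind = "pharmacy", system = "NDC"),
    visits("T01"),
    # T02: T1D dx only + insulin -> excluded everywhere, never a case
    toy_event("T02", "250.01"),
    toy_event("T02", "00002-8215-01", kind = "pharmacy", system = "NDC"),
    visits("T02"),
    # T03: one normal glucose value (order + result) -> A, B, C; not D
    toy_event("T03", "82947", kind = "procedure", system = "CPT"),
    toy_event("T03", "1558-6", kind = "lab_result", system = "LOINC",
              value = 95),
    visits("T03"),
    # T04: zero lab orders/results -> C and D; not A or B
    visits("T04"),
    # T05: family-history code -> excluded under every variant
    toy_event("T05", "V18.0"),
    visits("T05"),
    # T06: abnormal HbA1c value but no T2D dx -> control only where values
    # are ignored (B) or labs not required (C)
    toy_event("T06", "4548-4", kind = "lab_result", system = "LOINC",
              value = 7.1),
    visits("T06"),
    # T07: lab order without a returned value -> C only among lab variants
    # (not A/B: no value; not D: an order exists)
    toy_event("T07", "80053", kind = "procedure", system = "CPT"),
    visits("T07"),
    # T08: depression dx + normal value -> exposed control
    toy_event("T08", "311"),
    toy_event("T08", "2339-0", kind = "lab_result", system = "LOINC",
              value = 105),
    visits("T08"))
  toy_dataset(mem, ev)
}

test_that("case rule tree fires on dx+med and respects the T1D exclusion", {
  ds <- toy_cohort_dataset()
  cc <- classify_case(ds)
  expect_true(cc$case[cc$member_id == "T01"])
  expect_false(cc$case[cc$member_id == "T02"])  # T1D only + insulin
  expect_false(cc$case[cc$member_id == "T04"])  # no relevant events
  # abnormal lab alone (no T2D dx) is not a case under the default tree
  expect_false(cc$case[cc$member_id == "T06"])
})

test_that("members with no events are not cases", {
  mem <- toy_members(2)
  cc <- classify_case(toy_dataset(mem))
  expect_false(any(cc$case))
})

test_that("control variants implement the four lab rules", {
  ds <- toy_cohort_dataset()
  ctrl <- function(v) {
    cl <- classify_control(ds, v)
    setNames(cl$control, cl$member_id)
  }
  A <- ctrl("baseline"); B <- ctrl("ignore_lab_value")
  C <- ctrl("ignore_lab"); D <- ctrl("no_lab")

  # normal-value member: control under A, B, C; not D
  expect_true(A[["T03"]] && B[["T03"]] && C[["T03"]])
  expect_false(D[["T03"]])
  # no-lab member: control under C and D only
  expect_false(A[["T04"]] || B[["T04"]])
  expect_true(C[["T04"]] && D[["T04"]])
  # family history excludes under every variant
  expect_false(A[["T05"]] || B[["T05"]] || C[["T05"]] || D[["T05"]])
  # abnormal value: fails A's value check, passes B and C
  expect_false(A[["T06"]])
  expect_true(B[["T06"]] && C[["T06"]])
  expect_false(D[["T06"]])
  # order without value: fails A/B (no result) and D (an order exists)
  expect_false(A[["T07"]] || B[["T07"]] || D[["T07"]])
  expect_true(C[["T07"]])
  # cases and T1D members are never controls
  for (v in control_variants()) {
    expect_false(ctrl(v)[["T01"]])
    expect_false(ctrl(v)[["T02"]])
  }
  expect_error(classify_control(ds, "nope"),
               class = "cohortsens_config_error")
})

test_that("min_visits excludes low-contact members from controls", {
  mem <- toy_members(1)
  ds <- toy_dataset(mem, toy_event("T01", "401.9"))  # a single claim
  co <- build_cohorts(ds, config = phenotype_config(min_visits = 2),
                      variants = "ignore_lab", on_empty = "keep")
  expect_identical(co$ignore_lab$exclusion_reason, "min_visits")
  co1 <- build_cohorts(ds, config = phenotype_config(min_visits = 1),
                       variants = "ignore_lab", on_empty = "keep")
  expect_identical(co1$ignore_lab$status, "control")
})

test_that("depression exposure is a windowed set-membership test", {
  mem <- toy_members(3)
  ev <- dplyr::bind_rows(
    toy_event("T01", "311"),
    toy_event("T02", "296.25", date = "2019-06-01"))  # outside the window
  ds <- toy_dataset(mem, ev,
                    enrollment = toy_enrollment(mem, end = "2019-12-31"))
  ex <- classify_exposure(ds)
  expect_true(ex$exposed[ex$member_id == "T01"])
  expect_false(ex$exposed[ex$member_id == "T02"])
  expect_false(ex$exposed[ex$member_id == "T03"])
})

test_that("classification is invariant to event order", {
  ds <- toy_cohort_dataset()
  co1 <- build_cohorts(ds, on_empty = "keep")
  withr::with_seed(4, {
    ds2 <- ds
    ds2$events <- ds2$events[sample.int(nrow(ds2$events)), ]
  })
  co2 <- build_cohorts(ds2, on_empty = "keep")
  for (v in control_variants()) {
    expect_equal(dplyr::arrange(co1[[v]], member_id),
                 dplyr::arrange(co2[[v]], member_id))
  }
})

test_that("control variants nest and exclude as sets on generated data", {
  for (s in c(21, 22, 23)) {
    g <- generate_claims(synthetic_config(n_members = 3000), seed = s)
    ds <- apply_code_map(g$data, default_code_map())
    ds$enrollment <- merge_enrollment_spans(ds$enrollment)
    co <- build_cohorts(ds)
    ids <- function(v) co[[v]]$member_id[co[[v]]$status == "control"]
    A <- ids("baseline"); B <- ids("ignore_lab_value")
    C <- ids("ignore_lab"); D <- ids("no_lab")
    expect_true(all(A %in% B))
    expect_true(all(B %in% C))
    expect_true(all(D %in% C))
    expect_length(intersect(B, D), 0)
    # C \ (B u D) is exactly the members with an order but no returned value
    expect_gt(length(C), length(B) + length(D))
    # Table-1 direction: ignore_lab > ignore_lab_value > baseline counts
    expect_gt(length(C), length(B))
    expect_gt(length(B), length(A))
    # the same member set is classified in every variant
    for (v in control_variants()) {
      expect_identical(sort(co[[v]]$member_id), sort(co$baseline$member_id))
    }
  }
})

test_that("datasets with no lab events leave lab-requiring variants empty", {
  cfg <- synthetic_config(n_members = 1500, test_base = 0)
  g <- generate_claims(cfg, seed = 6)
  ds <- apply_code_map(g$data, default_code_map())
  ds$enrollment <- merge_enrollment_spans(ds$enrollment)
  expect_error(build_cohorts(ds, variants = "baseline"),
               class = "cohortsens_empty_cohort", regexp = "baseline")
  co <- build_cohorts(ds, on_empty = "keep")
  expect_identical(sum(co$baseline$status == "control"), 0L)
  expect_identical(sum(co$ignore_lab_value$status == "control"), 0L)
  ids <- function(v) sort(co[[v]]$member_id[co[[v]]$status == "control"])
  expect_identical(ids("no_lab"), ids("ignore_lab"))
})

test_that("phenotype YAML config round-trips code sets and thresholds", {
  path <- system.file("extdata", "phenotype_default.yaml",
                      package = "cohortsens")
  pc <- read_phenotype_config(path)
  expect_identical(pc$codes$glucose_loinc, c("1558-6", "2339-0", "2345-7"))
  expect_identical(pc$config$min_visits, 2L)
  expect_error(phenotype_config(normal_hba1c = 7),
               class = "cohortsens_config_error")
})
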