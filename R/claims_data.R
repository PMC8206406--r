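#' @import rlang
#' @importFrom dplyr %>% arrange bind_rows count filter group_by
#'   left_join mutate n select semi_join summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median plogis quantile rbinom rlnorm rnorm rpois runif
#'   setNames dhyper
NULL

# -- claims dataset container ------------------------------------------------

#' Construct a normalized claims dataset
#'
#' Bundles the three entity tables of an administrative claims extract --
#' members, enrollment spans, and coded events -- after validating their
#' schemas and invariants (sorted, non-overlapping spans; lab values only on
#' lab-result events).
#'
#' @param members Data frame with columns `member_id`, `sex`
#'   (`"male"`/`"female"`), `birth_year` (integer year).
#' @param enrollment Data frame with columns `member_id`, `start`, `end`
#'   (closed `Date` intervals).
#' @param events Data frame with columns `member_id`, `date`, `kind`
#'   (`diagnosis`, `procedure`, `pharmacy`, `lab_result`), `system` (`ICD9`,
#'   `ICD10`, `CPT`, `NDC`, `LOINC`), `code`, `value` (numeric; `NA` except on
#'   lab results).
#' @return An object of class `claims_dataset`: a list of the three tibbles.
#' @export
claims_dataset <- function(members, enrollment, events) {
  members <- as_tibble(members)
  enrollment <- as_tibble(enrollment)
  events <- as_tibble(events)

  check_columns(members, c("member_id", "sex", "birth_year"), "members")
  check_columns(enrollment, c("member_id", "start", "end"), "enrollment")
  check_columns(events, c("member_id", "date", "kind", "system", "code"),
                "events")
  if (!"value" %in% names(events)) events$value <- NA_real_

  members$member_id <- as.character(members$member_id)
  members$birth_year <- as.integer(members$birth_year)
  bad_sex <- setdiff(unique(members$sex), c("male", "female"))
  if (length(bad_sex)) {
    abort(paste0("members$sex must be 'male' or 'female'; found: ",
                 paste(bad_sex, collapse = ", ")),
          class = "cohortsens_schema_error")
  }

  enrollment$member_id <- as.character(enrollment$member_id)
  enrollment$start <- as.Date(enrollment$start)
  enrollment$end <- as.Date(enrollment$end)
  if (any(enrollment$end < enrollment$start)) {
    abort("enrollment spans must have end >= start",
          class = "cohortsens_schema_error")
  }
  enrollment <- arrange(enrollment, .data$member_id, .data$start)
  overlap <- enrollment %>%
    group_by(.data$member_id) %>%
    summarise(bad = any(.data$start[-1] <= .data$end[-n()]), .groups = "drop")
  if (any(overlap$bad, na.rm = TRUE)) {
    abort("enrollment spans overlap within a member; merge them first",
          class = "cohortsens_schema_error")
  }

  events$member_id <- as.character(events$member_id)
  events$date <- as.Date(events$date)
  events$code <- as.character(events$code)
  bad_kind <- setdiff(unique(events$kind),
                      c("diagnosis", "procedure", "pharmacy", "lab_result"))
  if (length(bad_kind)) {
    abort(paste0("unknown event kind: ", paste(bad_kind, collapse = ", ")),
          class = "cohortsens_schema_error")
  }
  bad_system <- setdiff(unique(events$system),
                        c("ICD9", "ICD10", "CPT", "NDC", "LOINC"))
  if (length(bad_system)) {
    abort(paste0("unknown code system: ", paste(bad_system, collapse = ", ")),
          class = "cohortsens_schema_error")
  }
  if (any(!is.na(events$value) & events$kind != "lab_result")) {
    abort("only lab_result events may carry a value",
          class = "cohortsens_schema_error")
  }
  if (any(!nzchar(events$code))) {
    abort("event codes must be non-empty", class = "cohortsens_schema_error")
  }

  structure(list(members = members, enrollment = enrollment, events = events),
            class = "claims_dataset")
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat("  members:   ", nrow(x$members), "\n")
  cat("  enrollment:", nrow(x$enrollment), "spans\n")
  cat("  events:    ", nrow(x$events), "\n")
  n10 <- sum(x$events$system == "ICD10")
  if (n10 > 0) cat("  (", n10, "ICD-10 events awaiting code mapping )\n")
  invisible(x)
}

check_columns <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("table '", table, "' is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cohortsens_schema_error")
  }
  invisible(df)
}

# -- delimited readers / writers ---------------------------------------------

table_specs <- function() {
  list(
    members = list(
      file = "members.csv",
      cols = readr::cols(member_id = readr::col_character(),
                         sex = readr::col_character(),
                         birth_year = readr::col_integer())),
    enrollment = list(
      file = "enrollment.csv",
      cols = readr::cols(member_id = readr::col_character(),
                         start = readr::col_date(format = "%Y-%m-%d"),
                         end = readr::col_date(format = "%Y-%m-%d"))),
    events = list(
      file = "events.csv",
      cols = readr::cols(member_id = readr::col_character(),
                         date = readr::col_date(format = "%Y-%m-%d"),
                         kind = readr::col_character(),
                         system = readr::col_character(),
                         code = readr::col_character(),
                         value = readr::col_double()))
  )
}

read_claims_table <- function(path, spec, table) {
  if (!file.exists(path)) {
    abort(paste0("claims file not found: ", path),
          class = "cohortsens_io_error")
  }
  required <- names(spec$cols$cols)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(required, header)
  # 'value' is optional on disk: datasets without lab results may omit it
  if (table == "events") missing <- setdiff(missing, "value")
  if (length(missing)) {
    abort(paste0("file '", basename(path), "' is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cohortsens_schema_error")
  }
  extra <- setdiff(header, required)
  if (length(extra)) {
    warn(paste0("file '", basename(path), "': ignoring unknown column(s): ",
                paste(extra, collapse = ", ")))
  }
  # parse problems are re-raised below as row-level errors
  df <- suppressWarnings(
    readr::read_csv(path, col_types = spec$cols, show_col_types = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(paste0("file '", basename(path), "': failed to parse ",
                 nrow(probs), " field(s); first at line ", probs$row[1],
                 " column '", required[probs$col[1]], "' (", probs$expected[1],
                 ")"),
          class = "cohortsens_parse_error")
  }
  df[required[required %in% names(df)]]
}

#' Read a claims dataset from delimited files
#'
#' Expects UTF-8, comma-delimited files with a header row and ISO-8601 dates:
#' `members.csv` (`member_id,sex,birth_year`), `enrollment.csv`
#' (`member_id,start,end`) and `events.csv`
#' (`member_id,date,kind,system,code,value`). Unknown columns are dropped with
#' a warning; a missing required column or an unparseable field is an error
#' naming the column / line.
#'
#' @param dir Directory containing the three files, or a named character
#'   vector/list with elements `members`, `enrollment`, `events` giving paths.
#' @return A [claims_dataset()].
#' @export
read_claims <- function(dir) {
  specs <- table_specs()
  if (is.character(dir) && length(dir) == 1 && is.null(names(dir))) {
    paths <- lapply(specs, function(s) file.path(dir, s$file))
  } else {
    paths <- as.list(dir)
    check_columns(as.data.frame(setNames(rep(list(1), length(paths)),
                                         names(paths))),
                  names(specs), "paths")
  }
  tabs <- Map(function(nm) read_claims_table(paths[[nm]], specs[[nm]], nm),
              names(specs))
  if (!"value" %in% names(tabs$events)) tabs$events$value <- NA_real_
  claims_dataset(tabs$members, tabs$enrollment, tabs$events)
}

#' Write a claims dataset to delimited files
#'
#' Inverse of [read_claims()]; writes `members.csv`, `enrollment.csv`,
#' `events.csv` into `dir` (created if needed). Writing then re-reading
#' round-trips the dataset exactly.
#'
#' @param ds A [claims_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_claims <- function(ds, dir) {
  stopifnot(inherits(ds, "claims_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(ds$members, file.path(dir, "members.csv"))
  readr::write_csv(ds$enrollment, file.path(dir, "enrollment.csv"))
  readr::write_csv(ds$events, file.path(dir, "events.csv"))
  invisible(dir)
}

# -- code-system mapping -----------------------------------------------------

#' Read a two-column code map
#'
#' @param path CSV with columns `source_code,target_code` (a many-to-one map,
#'   e.g. ICD-10-CM to ICD-9-CM).
#' @param source_system,target_system Code systems the map translates between.
#' @return A `code_map` object.
#' @export
read_code_map <- function(path, source_system = "ICD10",
                          target_system = "ICD9") {
  df <- readr::read_csv(path, col_types = readr::cols(
    source_code = readr::col_character(),
    target_code = readr::col_character()), show_col_types = FALSE)
  check_columns(df, c("source_code", "target_code"), basename(path))
  code_map(setNames(df$target_code, df$source_code),
           source_system, target_system)
}

#' @rdname read_code_map
#' @param entries Named character vector: `names()` are source codes, values
#'   are target codes.
#' @export
code_map <- function(entries, source_system = "ICD10",
                     target_system = "ICD9") {
  stopifnot(is.character(entries), !is.null(names(entries)),
            all(nzchar(names(entries))), all(nzchar(entries)))
  structure(list(entries = entries, source_system = source_system,
                 target_system = target_system),
            class = "code_map")
}

#' Translate coded events between code systems
#'
#' Rewrites every event in the map's source system (by default ICD-10-CM
#' diagnoses) to its target system so that downstream phenotyping rules only
#' see one vocabulary. Events already in other systems are untouched; the
#' operation is idempotent.
#'
#' @param ds A [claims_dataset()].
#' @param map A [code_map()].
#' @param unmapped `"error"` (default): any source-system code absent from the
#'   map aborts, listing the offending codes; `"drop"`: such events are removed
#'   with a warning.
#' @return The mapped [claims_dataset()], with no source-system events left.
#' @export
apply_code_map <- function(ds, map, unmapped = c("error", "drop")) {
  stopifnot(inherits(ds, "claims_dataset"), inherits(map, "code_map"))
  unmapped <- arg_match(unmapped)
  ev <- ds$events
  idx <- ev$system == map$source_system
  if (!any(idx)) return(ds)
  src <- ev$code[idx]
  tgt <- unname(map$entries[src])
  if (anyNA(tgt)) {
    bad <- sort(unique(src[is.na(tgt)]))
    if (unmapped == "error") {
      abort(paste0("no ", map$target_system, " mapping for ",
                   map$source_system, " code(s): ",
                   paste(bad, collapse = ", ")),
            class = "cohortsens_unmapped_code")
    }
    warn(paste0("dropping ", sum(is.na(tgt)), " event(s) with unmapped ",
                map$source_system, " code(s): ", paste(bad, collapse = ", ")))
  }
  ev$code[idx] <- tgt
  ev$system[idx] <- map$target_system
  ev <- ev[!(idx & is.na(ev$code)), ]
  ds$events <- ev
  ds
}

# -- enrollment windowing ----------------------------------------------------

#' Merge administratively fragmented enrollment spans
#'
#' Claims extracts often split one continuous coverage period into several
#' spans separated by short administrative gaps. Spans of the same member
#' separated by at most `max_gap_days` days are merged into one.
#'
#' @param enrollment Enrollment tibble (`member_id,start,end`).
#' @param max_gap_days Largest gap (days strictly between one span's end and
#'   the next span's start) still treated as continuous coverage. Default 31.
#' @return Merged, sorted enrollment tibble.
#' @export
merge_enrollment_spans <- function(enrollment, max_gap_days = 31) {
  e <- arrange(enrollment, .data$member_id, .data$start)
  n <- nrow(e)
  if (n == 0) return(select(e, "member_id", "start", "end"))
  # a sorted span opens a new run unless it follows the same member's
  # previous span within the gap tolerance
  same <- c(FALSE, e$member_id[-1] == e$member_id[-n])
  gap <- c(NA_integer_, as.integer(e$start[-1] - e$end[-n]) - 1L)
  grp <- cumsum(!(same & !is.na(gap) & gap <= max_gap_days))
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(member_id = e$member_id[first], start = e$start[first],
         end = e$end[last])
}

#' Phenotyping observation windows
#'
#' A member qualifies for the study if some continuous enrollment span covers
#' at least `years` years; phenotypes are then defined over exactly the first
#' `years` years of the earliest such span. The window is a closed interval of
#' exactly `365 * years + 1` days (1461 days for the default 4 years,
#' including one leap day) so event counts are reproducible across calendar
#' placements.
#'
#' @param enrollment Enrollment tibble, already merged
#'   (see [merge_enrollment_spans()]).
#' @param years Required continuous coverage, in years. Default 4.
#' @return Tibble `member_id,start,end` with one row per qualifying member;
#'   members with no qualifying span are absent.
#' @export
qualifying_windows <- function(enrollment, years = 4) {
  len <- window_days(years)
  e <- enrollment %>%
    arrange(.data$member_id, .data$start) %>%
    filter(as.integer(.data$end - .data$start) + 1L >= len)
  e <- e[!duplicated(e$member_id), , drop = FALSE]
  mutate(select(e, "member_id", "start"), end = .data$start + (len - 1L))
}

window_days <- function(years) as.integer(365L * years + 1L)

#' Restrict events to each member's observation window
#'
#' @param events Events tibble.
#' @param windows Window tibble from [qualifying_windows()].
#' @return Events of windowed members falling inside their window (closed
#'   interval), with the window bounds joined on.
#' @export
window_events <- function(events, windows) {
  events %>%
    dplyr::inner_join(windows, by = "member_id") %>%
    filter(.data$date >= .data$start, .data$date <= .data$end)
}

#' Diagnosis facts per member-year
#'
#' The "fact count" healthcare-intensity proxy: diagnosis-kind events recorded
#' in a member's observation window divided by the window length in years.
#' Members with a window but no diagnoses get rate 0.
#'
#' @param ds A [claims_dataset()].
#' @param windows Window tibble from [qualifying_windows()].
#' @return Tibble `member_id,facts_per_year`.
#' @export
facts_per_year <- function(ds, windows) {
  yrs <- as.numeric(windows$end[1] - windows$start[1] + 1) / 365.25
  if (nrow(windows) == 0) yrs <- 1
  counts <- window_events(ds$events, windows) %>%
    filter(.data$kind == "diagnosis") %>%
    count(.data$member_id, name = "n_dx")
  windows %>%
    left_join(counts, by = "member_id") %>%
    mutate(n_dx = dplyr::coalesce(.data$n_dx, 0L),
           facts_per_year = .data$n_dx / yrs) %>%
    select("member_id", "facts_per_year")
}
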