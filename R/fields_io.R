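#' Read and write longitudinal visual-field tables
#'
#' The on-disk format is a plain CSV with one row per test and the header
#' `patient_id, gender, eye, test_date, age_years, s01...s54`, where the
#' s-columns are the 54 sensitivities (dB, two decimals) in row-major
#' valid-cell order for the recorded eye, and `test_date` is ISO-8601.
#'
#' `read_fields()` validates every row (sensitivity range, parseable date,
#' positive age), groups records by patient and eye, sorts them by date and
#' assigns a 1-based `test_number` within each eye. Malformed rows abort
#' with their line numbers. `write_fields()` writes the same schema back;
#' the pair round-trips exactly up to float formatting.
#'
#' @param path File path of the field CSV.
#' @param fields A field tibble as produced by `read_fields()` or
#'   [generate_cohort()].
#' @return `read_fields()`: a tibble with columns `patient_id`, `gender`,
#'   `eye`, `test_date` (`Date`), `age_years`, `test_number` and
#'   `s01`...`s54`, sorted by patient, eye and date.
#' @export
read_fields <- function(path) {
  spec <- readr::cols(
    patient_id = readr::col_character(),
    gender = readr::col_character(),
    eye = readr::col_character(),
    test_date = readr::col_date(format = "%Y-%m-%d"),
    age_years = readr::col_double(),
    .default = readr::col_double()
  )
  tbl <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE))
  missing <- setdiff(field_csv_header(), names(tbl))
  if (length(missing) > 0L) {
    abort(paste0("field CSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  validate_fields(tbl)
}

#' @rdname read_fields
#' @export
write_fields <- function(fields, path) {
  stopifnot(all(field_csv_header() %in% names(fields)))
  out <- fields %>%
    select(all_of(field_csv_header())) %>%
    mutate(across(all_of(s_cols()), ~ round(.x, 2)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

s_cols <- function() sprintf("s%02d", 1:54)

field_csv_header <- function() {
  c("patient_id", "gender", "eye", "test_date", "age_years", s_cols())
}

# Validate a raw field tibble, then sort and assign test_number.
validate_fields <- function(tbl) {
  sv <- as.matrix(tbl[s_cols()])
  bad_s <- which(!is.finite(sv) | sv < 0 | sv > 50, arr.ind = TRUE)
  bad_date <- which(is.na(tbl$test_date))
  bad_age <- which(!is.finite(tbl$age_years) | tbl$age_years <= 0)
  bad_eye <- which(!tbl$eye %in% c("right", "left"))
  problems <- c(
    if (nrow(bad_s) > 0L) sprintf(
      "row %d: %s out of [0, 50] dB", bad_s[, 1L], s_cols()[bad_s[, 2L]]),
    if (length(bad_date) > 0L) sprintf("row %d: unparseable test_date", bad_date),
    if (length(bad_age) > 0L) sprintf("row %d: non-positive age_years", bad_age),
    if (length(bad_eye) > 0L) sprintf("row %d: eye must be right/left", bad_eye)
  )
  if (length(problems) > 0L) {
    abort(c("malformed field rows:", utils::head(problems, 20L)))
  }
  dup <- tbl %>%
    group_by(.data$patient_id, .data$eye, .data$test_date) %>%
    filter(dplyr::n() > 1L)
  if (nrow(dup) > 0L) {
    abort("duplicate test dates within a patient eye.")
  }
  tbl %>%
    arrange(.data$patient_id, .data$eye, .data$test_date) %>%
    group_by(.data$patient_id, .data$eye) %>%
    mutate(test_number = row_number()) %>%
    ungroup() %>%
    select(all_of(c("patient_id", "gender", "eye", "test_date",
                    "age_years", "test_number")), all_of(s_cols()))
}

# n x 54 sensitivity matrix from a field tibble
field_matrix <- function(fields) {
  as.matrix(fields[s_cols()])
}

#' Mean deviation for every field in a table
#'
#' Convenience wrapper computing the 52-point mean deviation of each row of
#' a field tibble against a normative surface.
#'
#' @inheritParams read_fields
#' @param normative An `hvf_normative` surface.
#' @return The input tibble with an `md` column (dB) appended.
#' @export
add_mean_deviation <- function(fields, normative = normative_surface()) {
  fields$md <- md_matrix(field_matrix(fields), fields$eye,
                         fields$age_years, normative)
  fields
}
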