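#' Temporal interval bins
#'
#' Prediction intervals from 0.75 to 5.5 years are tiled by ten 0.5-year
#' bins centred at 1.0, 1.5, ..., 5.5 years. Each bin covers
#' \[centre - 0.25, centre + 0.25), half-open on the right so no interval
#' falls in two bins; the final bin is closed at 5.5 so the stated upper
#' limit itself is kept. Intervals outside \[0.75, 5.5\] years are
#' excluded.
#'
#' @param interval_years Positive numeric vector of intervals in years.
#' @return `assign_bin()`: the bin centre for each interval, `NA` where the
#'   interval is excluded. `interval_bins()`: a tibble of the ten bins with
#'   `center`, `lower` (inclusive) and `upper` (exclusive except the last).
#' @examples
#' assign_bin(c(0.74, 0.75, 1.0, 1.25, 5.5, 5.51))
#' @export
assign_bin <- function(interval_years) {
  if (any(interval_years <= 0, na.rm = TRUE)) {
    abort("intervals must be positive.")
  }
  centers <- 1 + 0.5 * pmin(floor((interval_years - 0.75) / 0.5), 9)
  centers[interval_years < 0.75 | interval_years > 5.5] <- NA_real_
  centers
}

#' @rdname assign_bin
#' @export
interval_bins <- function() {
  center <- seq(1, 5.5, by = 0.5)
  tibble(center = center, lower = center - 0.25, upper = center + 0.25)
}

#' Build all admissible temporal test pairs
#'
#' Every ordered (earlier, later) combination of two tests of the same eye
#' of the same patient forms a candidate pair; pairs with an interval below
#' 0.75 or above 5.5 years are excluded, and the rest are binned into
#' 0.5-year intervals. Eyes with fewer than two tests contribute no pairs.
#' Intervals are computed from calendar dates using a 365.25-day year.
#'
#' @param fields A field tibble ([read_fields()], [generate_cohort()]).
#' @return A tibble with one row per pair: `pair_id`, `patient_id`, `eye`,
#'   `input_date`, `target_date`, `input_test_number`,
#'   `target_test_number`, `interval_years`, `bin_center`.
#' @export
make_pairs <- function(fields) {
  keys <- fields %>%
    select(all_of(c("patient_id", "eye", "test_date", "test_number")))
  pairs <- keys %>%
    inner_join(keys, by = c("patient_id", "eye"),
               suffix = c("_in", "_tg"), relationship = "many-to-many") %>%
    filter(.data$test_date_tg > .data$test_date_in) %>%
    mutate(interval_years =
             as.numeric(.data$test_date_tg - .data$test_date_in) / 365.25,
           bin_center = assign_bin(.data$interval_years)) %>%
    filter(!is.na(.data$bin_center))
  pairs %>%
    arrange(.data$patient_id, .data$eye, .data$test_date_in,
            .data$test_date_tg) %>%
    mutate(pair_id = row_number()) %>%
    select("pair_id", "patient_id", "eye",
           input_date = "test_date_in", target_date = "test_date_tg",
           input_test_number = "test_number_in",
           target_test_number = "test_number_tg",
           "interval_years", "bin_center")
}

#' Patient-level train/test and cross-validation split
#'
#' Splits patients (never individual eyes or tests) into a held-out test
#' set and `k` disjoint cross-validation folds over the remainder, so both
#' eyes and all tests of a patient always land in the same part. The
#' assignment is a seeded permutation: deterministic under the same seed,
#' fold sizes differing by at most one patient.
#'
#' @param patient_ids Character vector of patient ids (duplicates allowed;
#'   they are collapsed).
#' @param test_fraction Fraction of patients held out for testing.
#' @param k Number of cross-validation folds.
#' @param seed Integer seed.
#' @return A tibble with columns `patient_id` and `part` (`"test"` or
#'   `"fold_0"`...`"fold_<k-1>"`), of class `split_plan`.
#' @export
split_patients <- function(patient_ids, test_fraction = 0.2, k = 10,
                           seed = 1L) {
  ids <- sort(unique(patient_ids))
  n <- length(ids)
  if (n < k + 1L) {
    abort(sprintf("need at least %d patients for %d folds plus a test set.",
                  k + 1L, k))
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  n_test <- round(n * test_fraction)
  part <- character(n)
  part[seq_len(n_test)] <- "test"
  rest <- seq(n_test + 1L, n)
  part[rest] <- sprintf("fold_%d", (seq_along(rest) - 1L) %% k)
  out <- tibble(patient_id = shuffled, part = part) %>%
    arrange(.data$patient_id)
  class(out) <- c("split_plan", class(out))
  out
}

# Join the split part onto a pair or field tibble.
add_split <- function(tbl, plan) {
  left_join(tbl, plan, by = "patient_id")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d patients, %d test, %d folds>\n",
              nrow(x), sum(x$part == "test"),
              dplyr::n_distinct(x$part[x$part != "test"])))
  NextMethod()
}

# n x 54 input and target sensitivity matrices (plus metadata vectors) for
# a pair tibble; used by baselines, training and evaluation.
pair_matrices <- function(pairs, fields) {
  key_in <- paste(pairs$patient_id, pairs$eye, pairs$input_date)
  key_tg <- paste(pairs$patient_id, pairs$eye, pairs$target_date)
  key_f <- paste(fields$patient_id, fields$eye, fields$test_date)
  i_in <- match(key_in, key_f)
  i_tg <- match(key_tg, key_f)
  if (anyNA(i_in) || anyNA(i_tg)) {
    abort("pairs reference tests missing from `fields`.")
  }
  m <- field_matrix(fields)
  list(
    input = m[i_in, , drop = FALSE],
    target = m[i_tg, , drop = FALSE],
    t = pairs$interval_years,
    eye = pairs$eye,
    patient_id = pairs$patient_id,
    bin_center = pairs$bin_center,
    input_row = i_in, target_row = i_tg
  )
}
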