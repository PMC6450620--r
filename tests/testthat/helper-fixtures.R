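# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Small default-calibration cohort reused across tests.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_cohort(sim_config(n_patients = 60, seed = 7))
  }
  .fixtures$small
}

# Mid-size cohort for training and model-comparison tests.
train_cohort <- function() {
  if (is.null(.fixtures$train)) {
    .fixtures$train <- generate_cohort(sim_config(n_patients = 100, seed = 21))
  }
  .fixtures$train
}

# Deterministic regular-visit field table: every patient tested every
# half-year from 0 to 6 years, so every interval bin is populated for every
# patient. Sensitivities decay linearly from a per-patient start value.
regular_fields <- function(n_patients = 12, eye = "right") {
  t_rel <- seq(0, 6, by = 0.5)
  rows <- list()
  for (i in seq_len(n_patients)) {
    start <- 20 + (i %% 10)
    for (j in seq_along(t_rel)) {
      v <- pmin(pmax(start - 0.5 * t_rel[j] + seq(0, 5.3, by = 0.1), 0), 50)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = sprintf("R%03d", i), gender = "female", eye = eye,
        test_date = as.Date("2010-01-01") + floor(t_rel[j] * 365.25),
        age_years = 60 + t_rel[j],
        !!!stats::setNames(as.list(v), sprintf("s%02d", 1:54)))
    }
  }
  hvfcast:::validate_fields(dplyr::bind_rows(rows))
}

# Independent two-test patients whose target field is a deterministic
# function of the input field and the interval: target = rule(input, t).
# Gives exactly one pair per patient with no test reused.
two_test_fields <- function(n_patients, rule,
                            t_range = c(1, 4), eye = "right") {
  rows <- list()
  for (i in seq_len(n_patients)) {
    input <- round(runif(54, 5, 35), 2)
    days <- sample(ceiling(t_range[1] * 365.25):floor(t_range[2] * 365.25), 1)
    t <- days / 365.25   # interval reconstructed exactly from the dates
    target <- pmin(pmax(rule(input, t), 0), 50)
    for (k in 1:2) {
      v <- if (k == 1) input else target
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = sprintf("T%03d", i), gender = "male", eye = eye,
        test_date = as.Date("2012-01-01") + c(0L, days)[k],
        age_years = 55 + c(0, t)[k],
        !!!stats::setNames(as.list(v), sprintf("s%02d", 1:54)))
    }
  }
  hvfcast:::validate_fields(dplyr::bind_rows(rows))
}

# Random valid 54-vector of sensitivities.
random_values <- function(n = 54) round(stats::runif(n, 0, 50), 2)
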