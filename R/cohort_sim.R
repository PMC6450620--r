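#' Heteroscedastic test-retest noise model
#'
#' Perimetric threshold variability grows as sensitivity falls: roughly
#' 2-3 dB of test-retest spread at normal sensitivities and considerably
#' more in damaged regions. The model is a retest SD that is linear in the
#' true sensitivity between two anchors and clamped outside them, so it is
#' non-increasing in sensitivity everywhere.
#'
#' @param sd_at_30dB Retest SD at 30 dB true sensitivity (healthy range).
#' @param sd_at_10dB Retest SD at 10 dB (damaged range).
#' @return An object of class `hvf_noise` with a `$sd(s)` function.
#' @examples
#' nm <- noise_model()
#' nm$sd(c(35, 30, 20, 10, 0))
#' @export
noise_model <- function(sd_at_30dB = 2.5, sd_at_10dB = 5) {
  stopifnot(sd_at_30dB >= 0, sd_at_10dB >= sd_at_30dB)
  sd_fun <- function(s) {
    f <- pmin(pmax((30 - s) / 20, 0), 1)
    sd_at_30dB + (sd_at_10dB - sd_at_30dB) * f
  }
  structure(list(sd = sd_fun, sd_at_30dB = sd_at_30dB,
                 sd_at_10dB = sd_at_10dB), class = "hvf_noise")
}

#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Defaults are calibrated to the demographic structure of a large
#' unfiltered clinical 24-2 perimetry population: about 3.6 tests per eye
#' (SD 1.9), first-test age 61.9 (SD 14.8) years, roughly 3.5 years between
#' first and last test, and an average mean deviation near -6.73 dB with a
#' wide (about 6 dB) spread produced by a mixture of disease archetypes.
#' Point-wise decay slopes follow a Gaussian rate-of-progression model with
#' mean -0.36 and SD 0.60 dB/year, decomposed into global, sector and
#' cell-level components so that progression is spatially correlated.
#'
#' @param n_patients Number of patients to simulate.
#' @param both_eyes_prob Probability a patient contributes both eyes.
#' @param visits_mean,visits_sd Moments of the per-eye test-count
#'   distribution (1 + negative binomial).
#' @param gap_mean_years,gap_shape Inter-visit gap Gamma distribution.
#' @param followup_cap_years Visits beyond this follow-up are dropped.
#' @param age_mean,age_sd,age_range First-visit age (truncated normal).
#' @param male_prob Probability of male gender.
#' @param archetype_weights Named mixture weights over the disease
#'   archetypes `normal`, `early_arcuate`, `moderate`, `severe`,
#'   `hemifield`; must sum to 1.
#' @param rop Gaussian rate-of-progression parameters ([rop_params()]).
#' @param var_split Fractions of slope variance assigned to the global,
#'   sector and cell components; must sum to 1.
#' @param noise An [noise_model()] for measurement error.
#' @param depth_scale Global multiplier on archetype depression depths;
#'   the default was calibrated once by bisection so a large default cohort
#'   reaches the target mean deviation.
#' @param severity_sdlog Log-SD of the per-eye lognormal severity factor.
#' @param target_md Cohort mean deviation the calibration targets (dB).
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       both_eyes_prob = 0.7,
                       visits_mean = 3.6, visits_sd = 1.9,
                       gap_mean_years = 1.35, gap_shape = 4,
                       followup_cap_years = 12,
                       age_mean = 61.9, age_sd = 14.8,
                       age_range = c(18, 100),
                       male_prob = 0.458,
                       archetype_weights = c(normal = 0.30,
                                             early_arcuate = 0.25,
                                             moderate = 0.20,
                                             severe = 0.15,
                                             hemifield = 0.10),
                       rop = rop_params(),
                       var_split = c(global = 0.25, sector = 0.50,
                                     cell = 0.25),
                       noise = noise_model(),
                       depth_scale = 0.92,
                       severity_sdlog = 0.35,
                       target_md = -6.73,
                       seed = 1L) {
  stopifnot(
    n_patients >= 1,
    both_eyes_prob >= 0, both_eyes_prob <= 1,
    abs(sum(archetype_weights) - 1) < 1e-8,
    all(names(archetype_weights) %in% names(archetype_depths())),
    abs(sum(var_split) - 1) < 1e-8, all(var_split >= 0),
    rop$sigma >= 0, inherits(noise, "hvf_noise"),
    visits_sd^2 > visits_mean - 1  # needed by the negative-binomial form
  )
  structure(
    list(n_patients = n_patients, both_eyes_prob = both_eyes_prob,
         visits_mean = visits_mean, visits_sd = visits_sd,
         gap_mean_years = gap_mean_years, gap_shape = gap_shape,
         followup_cap_years = followup_cap_years,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         male_prob = male_prob, archetype_weights = archetype_weights,
         rop = rop, var_split = var_split, noise = noise,
         depth_scale = depth_scale, severity_sdlog = severity_sdlog,
         target_md = target_md, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# ---- spatial structure ------------------------------------------------------

# Six-sector map per eye (simplified arcuate/quadrant layout), as an integer
# 54-vector in row-major valid-cell order. Sectors: 1 central, 2 nasal step,
# 3 superior temporal wedge, 4 inferior temporal wedge, 5 superior arcuate,
# 6 inferior arcuate. nx is the nasal-positive horizontal coordinate.
hvf_sectors <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  co <- hvf_coords(eye)
  nx <- if (eye == "right") -co$x else co$x
  ecc <- sqrt(co$x^2 + co$y^2)
  sector <- integer(54L)
  sector[ecc <= 11] <- 1L
  sector[sector == 0L & nx >= 21] <- 2L
  sector[sector == 0L & nx <= -15 & co$y > 0] <- 3L
  sector[sector == 0L & nx <= -15 & co$y < 0] <- 4L
  sector[sector == 0L & co$y > 0] <- 5L
  sector[sector == 0L & co$y < 0] <- 6L
  sector
}

archetype_depths <- function() {
  c(normal = 0, early_arcuate = 8, moderate = 13, severe = 22,
    hemifield = 18)
}

# Smooth per-cell depression weights (0..1) for an archetype, row-major
# 54-vector. Hemifield confines all depression strictly to one half of the
# field (superior or inferior) and is not smoothed across the midline.
archetype_weights_cells <- function(archetype, eye,
                                    hemi = c("superior", "inferior")) {
  co <- hvf_coords(eye)
  nx <- if (eye == "right") -co$x else co$x
  sec <- hvf_sectors(eye)
  w <- switch(archetype,
    normal = rep(0, 54L),
    early_arcuate = ifelse(sec == 5L, 1, ifelse(sec == 2L & co$y > 0, 0.6, 0)),
    moderate = ifelse(sec %in% c(5L, 6L), 1,
                      ifelse(sec == 2L, 0.8, 0.3)),
    severe = ifelse(sec %in% c(5L, 6L), 1, 0.85),
    hemifield = {
      hemi <- match.arg(hemi)
      s <- if (hemi == "superior") co$y > 0 else co$y < 0
      as.numeric(s)
    },
    abort(sprintf("unknown archetype '%s'.", archetype))
  )
  if (archetype %in% c("early_arcuate", "moderate", "severe")) {
    w <- smooth_cells(w, eye)
  }
  w
}

# One pass of 3x3 neighbour averaging over the valid cells of the grid.
smooth_cells <- function(w, eye) {
  co <- hvf_coords(eye)
  out <- numeric(54L)
  for (i in seq_len(54L)) {
    nb <- abs(co$row - co$row[i]) <= 1 & abs(co$col - co$col[i]) <= 1
    out[i] <- mean(w[nb])
  }
  out
}

# ---- sampling primitives ----------------------------------------------------

#' Sample a baseline (first-visit) true field
#'
#' Draws the noiseless sensitivity field of an eye at its first test:
#' the age-adjusted normative surface minus an archetype-specific,
#' spatially smooth depression scaled by a per-eye lognormal severity
#' factor, clamped to \[0, 50\] dB. Uses the current RNG state; cohort-level
#' determinism comes from the seed in [generate_cohort()].
#'
#' @param archetype One of `normal`, `early_arcuate`, `moderate`, `severe`,
#'   `hemifield`.
#' @param age Age in years at the test.
#' @param eye `"right"` or `"left"`.
#' @param config A [sim_config()].
#' @param normative An [normative_surface()].
#' @return An `hvf_grid` of true (noiseless) sensitivities.
#' @export
sample_baseline_field <- function(archetype, age, eye = "right",
                                  config = sim_config(),
                                  normative = normative_surface()) {
  if (!archetype %in% names(archetype_depths())) {
    abort(sprintf("unknown archetype '%s'.", archetype))
  }
  hemi <- if (runif(1) < 0.5) "superior" else "inferior"
  w <- archetype_weights_cells(archetype, eye, hemi)
  severity <- exp(rnorm(1, 0, config$severity_sdlog))
  depth <- config$depth_scale * archetype_depths()[[archetype]] * severity
  v <- normative_values(normative, eye, age) - depth * w
  to_grid(pmin(pmax(v, 0), 50), eye)
}

#' Sample a per-cell progression slope field
#'
#' Point-wise decay slopes (dB/year) with marginal distribution
#' Normal(mu, sigma^2) from the rate-of-progression parameters, decomposed
#' as slope = mu + sigma * (sqrt(f_g) Z_global + sqrt(f_s) Z_sector +
#' sqrt(f_c) Z_cell) so that cells within an anatomical sector progress
#' together. The variance fractions must sum to one, which preserves the
#' marginal moments exactly. Slopes are archetype-independent so the
#' configured Gaussian calibration holds marginally over the whole cohort.
#'
#' @param rop [rop_params()] with mean and SD in dB/year.
#' @param eye `"right"` or `"left"`.
#' @param var_split Named fractions `global`, `sector`, `cell` summing to 1.
#' @return Numeric 54-vector of slopes in row-major valid-cell order.
#' @export
sample_slope_field <- function(rop = rop_params(), eye = "right",
                               var_split = c(global = 0.25, sector = 0.50,
                                             cell = 0.25)) {
  if (abs(sum(var_split) - 1) > 1e-8 || any(var_split < 0)) {
    abort("`var_split` fractions must be non-negative and sum to 1.")
  }
  stopifnot(rop$sigma >= 0)
  sec <- hvf_sectors(eye)
  zg <- rnorm(1)
  zs <- rnorm(max(sec))[sec]
  zc <- rnorm(54L)
  rop$mu + rop$sigma * (sqrt(var_split[["global"]]) * zg +
                          sqrt(var_split[["sector"]]) * zs +
                          sqrt(var_split[["cell"]]) * zc)
}

# Simulate one eye of one patient; returns measured rows plus the true
# sensitivity matrix as an attribute.
sim_eye <- function(config, normative, patient_id, gender, eye, age0) {
  n_visits <- sample_visit_count(1L, config)
  gaps <- rgamma(max(n_visits - 1L, 0L), shape = config$gap_shape,
                 scale = config$gap_mean_years / config$gap_shape)
  t_rel <- c(0, cumsum(gaps))
  t_rel <- t_rel[t_rel <= config$followup_cap_years]
  n_visits <- length(t_rel)

  archetype <- sample_archetypes(1L, config)
  baseline <- from_grid(sample_baseline_field(archetype, age0, eye,
                                              config, normative))
  slope <- sample_slope_field(config$rop, eye, config$var_split)

  true_m <- pmin(pmax(
    matrix(baseline, n_visits, 54L, byrow = TRUE) + outer(t_rel, slope),
    0), 50)
  sd_m <- matrix(config$noise$sd(true_m), n_visits, 54L)
  meas <- pmin(pmax(true_m + rnorm(length(true_m)) * sd_m, 0), 50)

  start <- as.Date("2005-01-01") + round(runif(1, 0, 3650))
  rows <- tibble(
    patient_id = patient_id, gender = gender, eye = eye,
    test_date = start + round(t_rel * 365.25),
    age_years = age0 + t_rel
  )
  meas <- round(meas, 2)
  colnames(meas) <- s_cols()
  rows <- dplyr::bind_cols(rows, as_tibble(meas))
  attr(rows, "true") <- true_m
  attr(rows, "archetype") <- archetype
  rows
}

# Mixture draw over disease archetypes.
sample_archetypes <- function(n, config) {
  sample(names(config$archetype_weights), n, replace = TRUE,
         prob = config$archetype_weights)
}

sample_visit_count <- function(n, config) {
  mu <- config$visits_mean - 1
  size <- mu^2 / (config$visits_sd^2 - mu)
  1L + rnbinom(n, mu = mu, size = size)
}

#' Simulate one patient
#'
#' Draws gender, first-visit age, one or both eyes, and a full longitudinal
#' series per eye: visits at Gamma-distributed gaps, true fields following
#' baseline + slope * time (clamped to \[0, 50\] dB), and measured fields
#' with heteroscedastic Gaussian noise added before clamping (floor
#' censoring, as on the device). Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @param normative An [normative_surface()].
#' @param patient_id Identifier for the simulated patient.
#' @return A field tibble (one row per test); the noiseless sensitivities
#'   are attached as attribute `"true"` (one matrix per eye, row-bound in
#'   the same order as the rows).
#' @export
sample_patient <- function(config, normative = normative_surface(),
                           patient_id = "P00001") {
  gender <- if (runif(1) < config$male_prob) "male" else "female"
  age0 <- truncnorm1(config$age_mean, config$age_sd, config$age_range)
  eyes <- if (runif(1) < config$both_eyes_prob) c("right", "left")
          else sample(c("right", "left"), 1L)
  parts <- lapply(eyes, function(e)
    sim_eye(config, normative, patient_id, gender, e, age0))
  out <- dplyr::bind_rows(parts)
  attr(out, "true") <- do.call(rbind, lapply(parts, attr, "true"))
  out
}

truncnorm1 <- function(mean, sd, range) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates `config$n_patients` patients under the configured seed and
#' returns a validated field tibble (sorted, with `test_number` assigned).
#' When `path` is given the cohort is also written as a field CSV, with a
#' demographic summary table alongside (`<path>` and
#' `<stem>_summary.csv`).
#'
#' @param config A [sim_config()].
#' @param normative An [normative_surface()] used both to build the fields
#'   and later to score mean deviation.
#' @param path Optional output CSV path.
#' @return The field tibble; the summary tibble is attached as attribute
#'   `"summary"` and can be recomputed with [cohort_summary()].
#' @examples
#' fields <- generate_cohort(sim_config(n_patients = 5, seed = 42))
#' cohort_summary(fields)
#' @export
generate_cohort <- function(config = sim_config(),
                            normative = normative_surface(),
                            path = NULL) {
  fields <- withr::with_seed(config$seed, {
    ids <- sprintf("P%05d", seq_len(config$n_patients))
    dplyr::bind_rows(lapply(ids, function(id)
      sample_patient(config, normative, id)))
  })
  fields <- validate_fields(fields)
  summary <- cohort_summary(fields, normative)
  if (!is.null(path)) {
    write_fields(fields, path)
    readr::write_csv(summary,
                     sub("\\.csv$", "_summary.csv", path), progress = FALSE)
  }
  attr(fields, "summary") <- summary
  fields
}

#' Demographic summary of a field table
#'
#' One-row-per-statistic table in the layout of a study's baseline
#' demographics: patient/eye/test counts, first-test age, gender and eye
#' fractions, tests per eye, follow-up, and average mean deviation.
#'
#' @inheritParams add_mean_deviation
#' @return A tibble with columns `statistic` and `value`.
#' @export
cohort_summary <- function(fields, normative = normative_surface()) {
  md <- md_matrix(field_matrix(fields), fields$eye, fields$age_years,
                  normative)
  per_eye <- fields %>%
    group_by(.data$patient_id, .data$eye) %>%
    summarise(n_tests = dplyr::n(),
              first_age = .data$age_years[1L],
              followup = max(.data$age_years) - min(.data$age_years),
              .groups = "drop")
  tibble(
    statistic = c("patients_n", "eyes_n", "fields_n",
                  "age_first_mean", "age_first_sd",
                  "male_frac", "right_eye_frac",
                  "tests_per_eye_mean", "tests_per_eye_sd",
                  "followup_years_mean", "followup_years_sd",
                  "md_mean", "md_sd"),
    value = c(dplyr::n_distinct(fields$patient_id), nrow(per_eye),
              nrow(fields),
              mean(per_eye$first_age), sd(per_eye$first_age),
              mean(fields$gender == "male"), mean(fields$eye == "right"),
              mean(per_eye$n_tests), sd(per_eye$n_tests),
              mean(per_eye$followup), sd(per_eye$followup),
              mean(md), sd(md))
  )
}
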