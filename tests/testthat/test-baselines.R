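test_that("simulated ROP with sigma 0 is the deterministic EMGT drift", {
  v <- rep(30, 54)
  out <- predict_rop(v, t = 2, params = rop_params(-0.36, 0))
  expect_equal(out, rep(30 - 0.72, 54), tolerance = 1e-12)

  # linear in t before clamping
  out4 <- predict_rop(v, t = 4, params = rop_params(-0.36, 0))
  expect_equal(v - out4, 2 * (v - out), tolerance = 1e-12)

  # floor clamp: an all-zero field stays at zero under negative drift
  expect_equal(predict_rop(rep(0, 54), 1, rop_params(-0.36, 0)), rep(0, 54))
  expect_error(predict_rop(v, t = 0), "positive")
})

test_that("simulated ROP changes have the EMGT moments at one year", {
  n <- 1e6 / 54  # about one million per-point draws
  input <- matrix(25, ceiling(n), 54)
  out <- predict_rop(input, t = 1, params = rop_params(), seed = 51)
  change <- as.vector(out - input)   # far from the clamps at 25 dB
  expect_lt(abs(mean(change) - (-0.36)), 0.01)
  expect_lt(abs(sd(change) - 0.60), 0.01)
})

test_that("empirical ROP recovers exact and simulated slopes", {
  # exact: pairs built with slope -0.5 everywhere and no noise
  withr::with_seed(52, {
    f <- two_test_fields(6, function(input, t) input - 0.5 * t)
    fit <- fit_empirical_rop(make_pairs(f), f)
    expect_equal(fit$mu, -0.5, tolerance = 1e-9)
    expect_equal(fit$sigma, 0, tolerance = 1e-7)
  })

  # noiseless heterogeneous cohort: recover (-0.36, 0.60) within MC error
  # follow-up capped so the 0 dB floor is never reached (no censoring bias);
  # slopes are cluster-correlated within an eye, so the SD estimate needs a
  # fairly large cohort to settle
  cfg <- sim_config(n_patients = 800, noise = noise_model(0, 0), seed = 53,
                    followup_cap_years = 6,
                    archetype_weights = c(normal = 1, early_arcuate = 0,
                                          moderate = 0, severe = 0,
                                          hemifield = 0))
  f <- generate_cohort(cfg)
  p <- make_pairs(f)
  fit <- fit_empirical_rop(p, f)
  expect_lt(abs(fit$mu - (-0.36)), 0.02)
  expect_lt(abs(fit$sigma - 0.60), 0.02)
})

test_that("empirical ROP equals a flat-loop mean/SD oracle", {
  fields <- small_cohort()
  pairs <- head(make_pairs(fields), 40)
  fit <- fit_empirical_rop(pairs, fields)
  pm <- hvfcast:::pair_matrices(pairs, fields)
  acc <- c()
  for (i in seq_len(nrow(pairs))) for (j in 1:54) {
    acc <- c(acc, (pm$target[i, j] - pm$input[i, j]) / pm$t[i])
  }
  expect_equal(fit$mu, mean(acc), tolerance = 1e-12)
  expect_equal(fit$sigma, sd(acc), tolerance = 1e-12)
})

test_that("pointwise regression recovers a noiseless linear rule exactly", {
  withr::with_seed(54, {
    f <- two_test_fields(40, function(input, t) 0.9 * input - 0.4 * t)
    fit <- fit_pointwise(make_pairs(f), f)
    expect_equal(unname(fit$coefficients[, "intercept"]), rep(0, 54),
                 tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[, "b_input"]), rep(0.9, 54),
                 tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[, "b_t"]), rep(-0.4, 54),
                 tolerance = 1e-8)
  })
})

test_that("pointwise regression satisfies the identity law", {
  withr::with_seed(55, {
    f <- two_test_fields(40, function(input, t) input)
    fit <- fit_pointwise(make_pairs(f), f)
    expect_equal(unname(fit$coefficients[, "b_input"]), rep(1, 54),
                 tolerance = 1e-7)
    expect_equal(unname(fit$coefficients[, "intercept"]), rep(0, 54),
                 tolerance = 1e-7)
    expect_equal(unname(fit$coefficients[, "b_t"]), rep(0, 54),
                 tolerance = 1e-7)
    # prediction then reproduces any input
    v <- random_values()
    expect_equal(predict(fit, v, t = 2), pmin(pmax(v, 0), 50),
                 tolerance = 1e-6)
  })
})

test_that("pointwise OLS matches the closed-form normal equations", {
  fields <- small_cohort()
  pairs <- head(make_pairs(fields), 30)
  fit <- fit_pointwise(pairs, fields)
  pm <- hvfcast:::pair_matrices(pairs, fields)
  for (j in c(1, 17, 54)) {
    X <- cbind(1, pm$input[, j], pm$t)
    beta <- solve(t(X) %*% X, t(X) %*% pm$target[, j])
    expect_equal(unname(fit$coefficients[j, ]), as.vector(beta),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient cells fall back to the empirical ROP", {
  withr::with_seed(56, {
    f <- regular_fields(n_patients = 4)
    # make cell 1 constant across all tests: constant input column
    f$s01 <- 10
    p <- make_pairs(f)
    expect_warning(fit <- fit_pointwise(p, f), "fallback")
    expect_true(fit$fallback[1])
    expect_false(any(fit$fallback[-1]))
    pred <- predict(fit, rep(10, 54), t = 2)
    expect_equal(pred[1], 10 + fit$fallback_rop$mu * 2, tolerance = 1e-9)
  })
})

test_that("the PMAE floor has the Gaussian closed form", {
  expect_equal(theoretical_pmae_floor(0), 0)
  expect_equal(theoretical_pmae_floor(1), sqrt(2 / pi))
  expect_equal(theoretical_pmae_floor(2.91), 2.91 * sqrt(2 / pi),
               tolerance = 1e-12)
  expect_lt(abs(theoretical_pmae_floor(2.91) - 2.32), 0.01)
  expect_error(theoretical_pmae_floor(-1), "non-negative")

  # Monte-Carlo verification of E|N(0,1)|
  z <- withr::with_seed(57, abs(rnorm(1e6)))
  expect_lt(abs(mean(z) - theoretical_pmae_floor(1)), 0.005)
})

test_that("no predictor beats the noise floor on noisy targets", {
  withr::with_seed(58, {
    sigma <- 2.5
    n <- 400
    truth <- matrix(runif(n * 54, 10, 30), n, 54)
    target <- truth + rnorm(n * 54) * sigma  # unclamped noisy measurements
    # the oracle predictor: the truth itself
    pmae <- rowMeans(abs(truth - target))
    floor <- theoretical_pmae_floor(sigma)
    mc_se <- sd(pmae) / sqrt(n)
    expect_gte(mean(pmae), floor - 3 * mc_se)
  })
})

test_that("retest-SD estimator recovers a known noise SD", {
  withr::with_seed(59, {
    # pairs of same-eye tests two weeks apart with pure N(0, 2^2) noise
    rows <- list()
    for (i in 1:150) {
      base <- runif(54, 12, 28)
      for (d in c(0, 14)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patient_id = sprintf("N%03d", i), gender = "female",
          eye = "right", test_date = as.Date("2015-01-01") + d,
          age_years = 60,
          !!!stats::setNames(as.list(pmin(pmax(base + rnorm(54, 0, 2), 0), 50)),
                             sprintf("s%02d", 1:54)))
      }
    }
    f <- hvfcast:::validate_fields(dplyr::bind_rows(rows))
    est <- estimate_retest_sd(f, max_years = 0.25)
    expect_lt(abs(as.numeric(est) - 2), 0.1)
    expect_equal(attr(est, "n_pairs"), 150L)
  })
})
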