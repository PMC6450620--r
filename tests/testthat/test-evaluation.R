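test_that("grid metrics match loop oracles and obey PMAE <= RMSE", {
  withr::with_seed(71, {
    a <- to_grid(random_values(), "right")
    expect_equal(unname(pairwise_metrics(a, a)), c(0, 0))

    # constant 2.47 dB error: PMAE = RMSE = 2.47
    v <- rep(20, 54)
    b <- to_grid(v, "right")
    c247 <- to_grid(v + 2.47, "right")
    m <- pairwise_metrics(c247, b)
    expect_equal(unname(m["pmae"]), 2.47, tolerance = 1e-12)
    expect_equal(unname(m["rmse"]), 2.47, tolerance = 1e-12)

    for (i in 1:10) {
      x <- random_values(); y <- random_values()
      m <- pairwise_metrics(to_grid(x, "left"), to_grid(y, "left"))
      acc1 <- 0; acc2 <- 0
      for (j in 1:54) {
        acc1 <- acc1 + abs(x[j] - y[j]); acc2 <- acc2 + (x[j] - y[j])^2
      }
      expect_equal(unname(m["pmae"]), acc1 / 54, tolerance = 1e-9)
      expect_equal(unname(m["rmse"]), sqrt(acc2 / 54), tolerance = 1e-9)
      expect_lte(m["pmae"], m["rmse"] + 1e-12)
    }
    expect_error(pairwise_metrics(to_grid(x, "left"), to_grid(y, "right")),
                 "mask")
  })
})

test_that("Bland-Altman agreement matches the textbook formulas", {
  withr::with_seed(72, {
    actual <- rnorm(40, -6, 4)

    # constructed offset: +0.41 dB everywhere
    ba <- bland_altman_md(actual + 0.41, actual)
    expect_equal(ba$mean_diff, 0.41, tolerance = 1e-12)
    expect_equal(ba$loa_upper - ba$loa_lower, 0, tolerance = 1e-12)
    expect_equal(ba$pearson_r, 1, tolerance = 1e-12)

    ba0 <- bland_altman_md(actual, actual)
    expect_equal(ba0$mean_diff, 0)

    # loop oracle on noisy predictions
    pred <- actual + rnorm(40, 0.3, 1.2)
    ba <- bland_altman_md(pred, actual)
    d <- pred - actual
    n <- 40
    md <- sum(d) / n
    sdd <- sqrt(sum((d - md)^2) / (n - 1))
    r <- sum((pred - mean(pred)) * (actual - mean(actual))) /
      sqrt(sum((pred - mean(pred))^2) * sum((actual - mean(actual))^2))
    expect_equal(ba$mean_diff, md, tolerance = 1e-9)
    expect_equal(ba$loa_lower, md - 1.96 * sdd, tolerance = 1e-9)
    expect_equal(ba$loa_upper, md + 1.96 * sdd, tolerance = 1e-9)
    expect_equal(ba$pearson_r, r, tolerance = 1e-9)
    expect_equal(ba$adj_r_squared, 1 - (1 - r^2) * (n - 1) / (n - 2),
                 tolerance = 1e-9)

    expect_warning(ba_deg <- bland_altman_md(rep(1, 5), 1:5), "undefined")
    expect_true(is.na(ba_deg$pearson_r))
    expect_error(bland_altman_md(1:2, 1:2), "at least 3")
  })
})

test_that("cluster-bootstrap CI is degenerate-safe and brackets the mean", {
  pm <- rep(2.47, 30)
  eyes <- rep(sprintf("e%d", 1:6), each = 5)
  ci <- pmae_confidence_interval(pm, eyes, B = 200, seed = 1)
  expect_equal(unname(ci), c(2.47, 2.47))

  withr::with_seed(73, {
    pm <- rnorm(200, 3, 0.5)
    eyes <- rep(sprintf("e%d", 1:40), each = 5)
    ci <- pmae_confidence_interval(pm, eyes, B = 500, seed = 2)
    expect_lte(ci[["lower"]], mean(pm))
    expect_gte(ci[["upper"]], mean(pm))
  })
  expect_error(pmae_confidence_interval(1:5, rep("e1", 5)), "two eyes")
})

test_that("bootstrap CI width agrees with normal theory for iid eyes", {
  withr::with_seed(74, {
    n_eyes <- 400
    mu <- 3; sigma <- 0.6
    pm <- rnorm(n_eyes, mu, sigma)       # one pair per eye
    eyes <- sprintf("e%d", 1:n_eyes)
    ci <- pmae_confidence_interval(pm, eyes, B = 2000, seed = 3)
    width <- ci[["upper"]] - ci[["lower"]]
    expected <- 2 * 1.96 * sd(pm) / sqrt(n_eyes)
    expect_lt(abs(width - expected) / expected, 0.15)
  })
})

test_that("evaluate_models scores predictors and guards against leakage", {
  fields <- small_cohort()
  pairs <- make_pairs(fields)
  plan <- split_patients(unique(fields$patient_id), k = 5, seed = 3)
  test_pairs <- hvfcast:::add_split(pairs, plan) %>%
    dplyr::filter(part == "test") %>%
    dplyr::select(-part)

  perfect <- function(p, f) hvfcast:::pair_matrices(p, f)$target
  ev <- evaluate_models(list(perfect = perfect), test_pairs, fields,
                        plan = plan, B = 100, seed = 1)
  expect_equal(ev$overall$pmae, 0)
  expect_equal(ev$overall$rmse, 0)
  expect_true(all(ev$by_bin$pmae_mean == 0))
  expect_equal(ev$agreement$mean_diff, 0)

  # leakage: training-fold pairs must be rejected outright
  expect_error(
    evaluate_models(list(perfect = perfect), pairs, fields, plan = plan),
    "leakage")

  # tidiers return the metric tables
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1L)
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("deterministic under fixed seeds", {
  fields <- small_cohort()
  pairs <- make_pairs(fields)
  plan <- split_patients(unique(fields$patient_id), k = 5, seed = 3)
  test_pairs <- hvfcast:::add_split(pairs, plan) %>%
    dplyr::filter(part == "test") %>%
    dplyr::select(-part)
  rop <- predictor_rop(rop_params(), seed = 11)
  e1 <- evaluate_models(list(rop = rop), test_pairs, fields, B = 100,
                        seed = 4)
  e2 <- evaluate_models(list(rop = rop), test_pairs, fields, B = 100,
                        seed = 4)
  expect_identical(e1$overall, e2$overall)
  expect_identical(e1$by_bin, e2$by_bin)
})
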