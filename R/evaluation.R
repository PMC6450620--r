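#' Per-pair pointwise error metrics
#'
#' For each pair, the pointwise mean absolute error (PMAE) and root mean
#' squared error (RMSE) between the predicted and actual target field over
#' the 54 valid cells. By Jensen's inequality PMAE <= RMSE for every pair,
#' with equality only under constant absolute error.
#'
#' @param predictions Prediction tibble (`pair_id` + `s01`...`s54`), e.g.
#'   from [predict_ensemble()], or an n x 54 matrix aligned with `pairs`.
#' @param pairs,fields Pair and field tibbles.
#' @return The pair tibble with `pmae` and `rmse` columns (dB) appended.
#' @export
pair_metrics <- function(predictions, pairs, fields) {
  pred <- prediction_matrix(predictions, pairs)
  pm <- pair_matrices(pairs, fields)
  d <- pred - pm$target
  pairs %>%
    mutate(pmae = rowMeans(abs(d)), rmse = sqrt(rowMeans(d^2)))
}

# Accept either a pair_id-keyed tibble or a bare aligned matrix.
prediction_matrix <- function(predictions, pairs) {
  if (is.matrix(predictions)) {
    stopifnot(nrow(predictions) == nrow(pairs), ncol(predictions) == 54L)
    return(predictions)
  }
  stopifnot(all(c("pair_id", s_cols()) %in% names(predictions)))
  i <- match(pairs$pair_id, predictions$pair_id)
  if (anyNA(i)) abort("predictions missing for some pairs.")
  as.matrix(predictions[i, s_cols()])
}

#' Grid-level PMAE and RMSE
#'
#' Scalar metrics between two single fields given as `hvf_grid`s with
#' identical masks.
#'
#' @param predicted,actual `hvf_grid` objects for the same eye.
#' @return A named numeric vector `c(pmae = , rmse = )` in dB.
#' @export
pairwise_metrics <- function(predicted, actual) {
  stopifnot(inherits(predicted, "hvf_grid"), inherits(actual, "hvf_grid"))
  if (!identical(predicted$mask, actual$mask)) {
    abort("grids have different masks.")
  }
  d <- from_grid(predicted) - from_grid(actual)
  c(pmae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Cluster-bootstrap confidence interval for the mean PMAE
#'
#' Test points within an eye are strongly correlated, so the CI resamples
#' whole eyes (clusters), not pairs or points: B bootstrap replicates of
#' the eye set, each scoring the equally-weighted mean of the per-pair
#' PMAEs of the sampled eyes, summarised by percentile bounds.
#' Deterministic under `seed`.
#'
#' @param pmae Per-pair PMAE values.
#' @param eye_id Cluster identifier per pair (patient + eye).
#' @param B Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Named vector `c(lower = , upper = )`.
#' @export
pmae_confidence_interval <- function(pmae, eye_id, B = 1000L, level = 0.95,
                                     seed = 1L) {
  stopifnot(length(pmae) == length(eye_id))
  eyes <- unique(eye_id)
  if (length(eyes) < 2L) {
    abort("need at least two eyes for a cluster bootstrap.")
  }
  by_eye <- split(pmae, factor(eye_id, levels = eyes))
  stat <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(i) {
      mean(unlist(by_eye[sample.int(length(eyes), replace = TRUE)],
                  use.names = FALSE))
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

#' Bland-Altman agreement of predicted and actual mean deviation
#'
#' Differences are predicted minus actual MD. Returns the mean difference,
#' the +/-1.96 SD limits of agreement, the Pearson correlation, and the
#' adjusted R-squared of the simple linear regression of actual on
#' predicted MD. With fewer than 3 pairs or zero variance the correlation
#' is undefined and reported as `NA`.
#'
#' @param predicted_md,actual_md Numeric vectors of MD values (dB).
#' @return A one-row tibble: `n`, `mean_diff`, `loa_lower`, `loa_upper`,
#'   `pearson_r`, `adj_r_squared`.
#' @export
bland_altman_md <- function(predicted_md, actual_md) {
  stopifnot(length(predicted_md) == length(actual_md))
  n <- length(predicted_md)
  if (n < 3L) abort("need at least 3 MD pairs.")
  d <- predicted_md - actual_md
  s <- sd(d)
  degenerate <- sd(predicted_md) == 0 || sd(actual_md) == 0
  if (degenerate) {
    warn("zero variance in MD values; correlation undefined.")
    r <- NA_real_
    adj <- NA_real_
  } else {
    r <- cor(predicted_md, actual_md)
    r2 <- r^2  # simple regression of actual on predicted
    adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  }
  tibble(n = n, mean_diff = mean(d),
         loa_lower = mean(d) - 1.96 * s, loa_upper = mean(d) + 1.96 * s,
         pearson_r = r, adj_r_squared = adj)
}

# ---- predictor wrappers -----------------------------------------------------

#' Predictor constructors for model comparison
#'
#' [evaluate_models()] compares arbitrary predictors. A predictor is a
#' function `(pairs, fields) -> n x 54 prediction matrix` aligned with the
#' pair rows. These constructors wrap the package's models in that
#' interface: the simulated/empirical rate-of-progression models (seeded),
#' the pointwise regressed linear model, and the deep fold ensemble.
#'
#' @param params [rop_params()] for an ROP predictor.
#' @param seed Seed for the ROP sampling step.
#' @param model A `pointwise_model`.
#' @param bundle A `model_bundle`.
#' @return A predictor function.
#' @export
predictor_rop <- function(params = rop_params(), seed = 1L) {
  force(params); force(seed)
  function(pairs, fields) {
    pm <- pair_matrices(pairs, fields)
    withr::with_seed(as.integer(seed), {
      change <- matrix(rnorm(length(pm$input)), nrow(pm$input), 54L) *
        (params$sigma * pm$t) + params$mu * pm$t
      pmin(pmax(pm$input + change, 0), 50)
    })
  }
}

#' @rdname predictor_rop
#' @export
predictor_pointwise <- function(model) {
  force(model)
  function(pairs, fields) {
    pm <- pair_matrices(pairs, fields)
    predict(model, pm$input, pm$t)
  }
}

#' @rdname predictor_rop
#' @export
predictor_deep <- function(bundle) {
  force(bundle)
  function(pairs, fields) {
    prediction_matrix(predict_ensemble(bundle, pairs, fields), pairs)
  }
}

#' Evaluate predictors on held-out pairs
#'
#' Scores one or more predictors on test pairs: overall and per-bin masked
#' PMAE (with cluster-bootstrap CI) and RMSE, plus Bland-Altman agreement
#' between predicted and actual mean deviation. When a split plan is
#' supplied, the function asserts that no test pair belongs to a training
#' patient (leakage guard) and fails hard otherwise.
#'
#' @param predictors Named list of predictor functions
#'   (see [predictor_rop()]).
#' @param pairs Held-out pair tibble.
#' @param fields Field tibble.
#' @param plan Optional [split_patients()] plan; test pairs must all carry
#'   part `"test"`.
#' @param normative Normative surface for MD computation.
#' @param B,seed Bootstrap settings for the PMAE CI.
#' @return An object of class `hvf_eval`: `by_bin` and `overall` metric
#'   tibbles and an `agreement` tibble (one row per predictor).
#' @export
evaluate_models <- function(predictors, pairs, fields, plan = NULL,
                            normative = normative_surface(),
                            B = 1000L, seed = 1L) {
  stopifnot(is.list(predictors), length(predictors) >= 1L,
            !is.null(names(predictors)))
  if (!is.null(plan)) {
    part <- add_split(pairs, plan)$part
    if (any(part != "test", na.rm = TRUE) || anyNA(part)) {
      abort("train/test leakage: some evaluation pairs are not test-set patients.")
    }
  }
  pm <- pair_matrices(pairs, fields)
  eye_id <- paste(pairs$patient_id, pairs$eye)
  target_rows <- fields[pm$target_row, , drop = FALSE]
  actual_md <- md_matrix(pm$target, pairs$eye, target_rows$age_years,
                         normative)
  by_bin <- list()
  overall <- list()
  agreement <- list()
  for (nm in names(predictors)) {
    pred <- predictors[[nm]](pairs, fields)
    pred <- prediction_matrix(pred, pairs)
    d <- pred - pm$target
    pmae <- rowMeans(abs(d))
    rmse <- sqrt(rowMeans(d^2))
    ci <- pmae_confidence_interval(pmae, eye_id, B = B, seed = seed)
    overall[[nm]] <- tibble(
      predictor = nm, n_pairs = nrow(pairs), pmae = mean(pmae),
      pmae_lower = ci[["lower"]], pmae_upper = ci[["upper"]],
      rmse = mean(rmse))
    bb <- tibble(bin_center = pairs$bin_center, pmae = pmae, rmse = rmse,
                 eye_id = eye_id) %>%
      group_by(.data$bin_center) %>%
      summarise(n_pairs = dplyr::n(), pmae_mean = mean(.data$pmae),
                rmse_mean = mean(.data$rmse),
                pmae_lower = if (dplyr::n_distinct(.data$eye_id) >= 2L)
                  pmae_confidence_interval(.data$pmae, .data$eye_id,
                                           B = B, seed = seed)[["lower"]]
                else NA_real_,
                pmae_upper = if (dplyr::n_distinct(.data$eye_id) >= 2L)
                  pmae_confidence_interval(.data$pmae, .data$eye_id,
                                           B = B, seed = seed)[["upper"]]
                else NA_real_,
                .groups = "drop") %>%
      mutate(predictor = nm, .before = 1L)
    by_bin[[nm]] <- bb
    pred_md <- md_matrix(pred, pairs$eye, target_rows$age_years, normative)
    agreement[[nm]] <- bland_altman_md(pred_md, actual_md) %>%
      mutate(predictor = nm, .before = 1L)
  }
  structure(list(by_bin = dplyr::bind_rows(by_bin),
                 overall = dplyr::bind_rows(overall),
                 agreement = dplyr::bind_rows(agreement)),
            class = "hvf_eval")
}

#' @export
print.hvf_eval <- function(x, ...) {
  cat("<hvf_eval>\noverall:\n")
  print(x$overall)
  cat("MD agreement:\n")
  print(x$agreement)
  invisible(x)
}

#' @param x An `hvf_eval`.
#' @param ... Unused.
#' @rdname evaluate_models
#' @export
tidy.hvf_eval <- function(x, ...) x$by_bin

#' @rdname evaluate_models
#' @export
glance.hvf_eval <- function(x, ...) {
  left_join(x$overall,
            x$agreement %>%
              select(all_of(c("predictor", "mean_diff", "pearson_r",
                              "adj_r_squared"))),
            by = "predictor")
}

#' Plot per-bin PMAE curves
#'
#' Average PMAE for each time-interval bin with bootstrap CI error bars,
#' one line per predictor.
#'
#' @param object An `hvf_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hvf_eval <- function(object, ...) {
  ggplot2::ggplot(object$by_bin,
                  ggplot2::aes(x = .data$bin_center, y = .data$pmae_mean,
                               colour = .data$predictor)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$pmae_lower,
                                        ymax = .data$pmae_upper),
                           width = 0.1, na.rm = TRUE) +
    ggplot2::labs(x = "prediction interval (years)", y = "PMAE (dB)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of mean-deviation agreement
#'
#' @param predicted_md,actual_md MD vectors (dB).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(predicted_md, actual_md) {
  stats <- bland_altman_md(predicted_md, actual_md)
  df <- tibble(mean_md = (predicted_md + actual_md) / 2,
               diff_md = predicted_md - actual_md)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_md, y = .data$diff_md)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = stats$mean_diff, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(stats$loa_lower, stats$loa_upper),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "mean of predicted and actual MD (dB)",
                  y = "predicted - actual MD (dB)") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity grid
#'
#' Heatmap of an `hvf_grid` in chart orientation; invalid cells are blank.
#'
#' @param grid An `hvf_grid`.
#' @return A ggplot object.
#' @export
plot_field <- function(grid) {
  stopifnot(inherits(grid, "hvf_grid"))
  co <- hvf_coords(grid$eye)
  df <- co %>% mutate(value = from_grid(grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(limits = c(0, 40), low = "black",
                                 high = "white", name = "dB") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "eccentricity (deg)", y = NULL,
                  title = sprintf("%s eye", grid$eye)) +
    ggplot2::theme_minimal()
}
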