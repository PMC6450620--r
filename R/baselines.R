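#' Gaussian rate-of-progression parameters
#'
#' Point-wise visual-field decay is modelled as a Gaussian rate of
#' progression (ROP): over an interval of t years the change at a test
#' point is Normal(mu * t, (sigma * t)^2). The defaults are the Early
#' Manifest Glaucoma Trial calibration of -0.36 dB/year (mean) and
#' 0.60 dB/year (SD).
#'
#' @param mu Mean rate of progression in dB/year.
#' @param sigma SD of the rate of progression in dB/year (>= 0).
#' @return An object of class `rop_params`.
#' @export
rop_params <- function(mu = -0.36, sigma = 0.60) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  structure(list(mu = mu, sigma = sigma), class = "rop_params")
}

#' @export
print.rop_params <- function(x, ...) {
  cat(sprintf("<rop_params: mu = %.4f, sigma = %.4f dB/year>\n",
              x$mu, x$sigma))
  invisible(x)
}

#' @export
tidy.rop_params <- function(x, ...) {
  tibble(term = c("mu", "sigma"), estimate = c(x$mu, x$sigma),
         unit = "dB/year")
}

#' Simulated rate-of-progression prediction
#'
#' The simplest progression forecast: for each valid point of the input
#' field draw a change from Normal(mu * t, (sigma * t)^2), add it to the
#' input sensitivity, and clamp the result to \[0, 50\] dB (clamping after
#' sampling). With `sigma = 0` the model is deterministic and linear in t
#' before clamping.
#'
#' @param input An n x 54 matrix (or length-54 vector) of input
#'   sensitivities in dB.
#' @param t Interval in years (> 0); scalar or length n.
#' @param params [rop_params()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Predicted sensitivities, same shape as `input`.
#' @examples
#' predict_rop(rep(30, 54), t = 2, params = rop_params(-0.36, 0))[1]
#' @export
predict_rop <- function(input, t, params = rop_params(), seed = NULL) {
  if (any(t <= 0)) abort("`t` must be positive.")
  vec <- is.null(dim(input))
  m <- if (vec) matrix(input, 1L) else input
  stopifnot(ncol(m) == 54L)
  draw <- function() {
    change <- matrix(rnorm(length(m), mean = 0, sd = 1),
                     nrow(m), 54L) * (params$sigma * t) + params$mu * t
    pmin(pmax(m + change, 0), 50)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  if (vec) out[1L, ] else out
}

#' Fit the empirical rate-of-progression model
#'
#' Pools the annualised per-point changes (target - input) / t over all
#' valid cells of all training pairs into a single Gaussian and returns its
#' mean and SD as [rop_params()]. Applying the fitted parameters with
#' [predict_rop()] gives the empirical-ROP forecast. A per-cell variant
#' (`pooled = FALSE`) returns one mu/sigma pair per point, but the pooled
#' form is the default model.
#'
#' @param pairs A pair tibble from [make_pairs()] (training pairs only).
#' @param fields The field tibble the pairs refer to.
#' @param pooled Pool all 54 cells into one Gaussian (default) or fit one
#'   per cell.
#' @return [rop_params()] when pooled, else a tibble with `cell`, `mu`,
#'   `sigma`.
#' @export
fit_empirical_rop <- function(pairs, fields, pooled = TRUE) {
  if (nrow(pairs) < 2L) abort("need at least 2 training pairs.")
  pm <- pair_matrices(pairs, fields)
  rate <- (pm$target - pm$input) / pm$t
  if (pooled) {
    rop_params(mu = mean(rate), sigma = sd(as.vector(rate)))
  } else {
    tibble(cell = seq_len(54L),
           mu = colMeans(rate),
           sigma = apply(rate, 2L, sd))
  }
}

#' Fit the pointwise regressed linear model
#'
#' Fits 54 independent ordinary-least-squares models, one per perimetry
#' point: target sensitivity regressed on an intercept, the same point's
#' input sensitivity, and the interval in years. Cells whose design matrix
#' is rank-deficient on the training data (for example constant inputs)
#' are flagged and fall back to the empirical-ROP forecast at prediction
#' time.
#'
#' @inheritParams fit_empirical_rop
#' @return An object of class `pointwise_model` with per-cell coefficients
#'   `(intercept, b_input, b_t)`, residual SDs, fallback flags and the
#'   fallback [rop_params()].
#' @export
fit_pointwise <- function(pairs, fields) {
  if (nrow(pairs) < 3L) abort("need at least 3 training pairs per cell.")
  pm <- pair_matrices(pairs, fields)
  coef_m <- matrix(NA_real_, 54L, 3L,
                   dimnames = list(NULL, c("intercept", "b_input", "b_t")))
  resid_sd <- rep(NA_real_, 54L)
  fallback <- logical(54L)
  for (j in seq_len(54L)) {
    X <- cbind(1, pm$input[, j], pm$t)
    if (qr(X)$rank < 3L) {
      fallback[j] <- TRUE
      next
    }
    fit <- lm.fit(X, pm$target[, j])
    coef_m[j, ] <- fit$coefficients
    df <- nrow(X) - 3L
    resid_sd[j] <- if (df > 0L) sqrt(sum(fit$residuals^2) / df) else NA_real_
  }
  if (any(fallback)) {
    warn(sprintf("%d cell(s) rank-deficient; using empirical-ROP fallback.",
                 sum(fallback)))
  }
  structure(
    list(coefficients = coef_m, resid_sd = resid_sd, fallback = fallback,
         fallback_rop = fit_empirical_rop(pairs, fields),
         n_pairs = nrow(pairs)),
    class = "pointwise_model"
  )
}

#' @param object,x A `pointwise_model`.
#' @param input,t,... See [predict_rop()]; further arguments ignored.
#' @rdname fit_pointwise
#' @export
predict.pointwise_model <- function(object, input, t, ...) {
  vec <- is.null(dim(input))
  m <- if (vec) matrix(input, 1L) else input
  stopifnot(ncol(m) == 54L)
  if (any(t <= 0)) abort("`t` must be positive.")
  co <- object$coefficients
  out <- matrix(co[, "intercept"], nrow(m), 54L, byrow = TRUE) +
    m * matrix(co[, "b_input"], nrow(m), 54L, byrow = TRUE) +
    outer(rep(t, length.out = nrow(m)), co[, "b_t"])
  if (any(object$fallback)) {
    fb <- object$fallback_rop
    j <- which(object$fallback)
    out[, j] <- m[, j] + fb$mu * t  # deterministic fallback (mean change)
  }
  out <- pmin(pmax(out, 0), 50)
  if (vec) out[1L, ] else out
}

#' @export
print.pointwise_model <- function(x, ...) {
  cat(sprintf(
    "<pointwise_model: 54 per-point OLS fits on %d pairs (%d fallback)>\n",
    x$n_pairs, sum(x$fallback)))
  invisible(x)
}

#' @rdname fit_pointwise
#' @export
tidy.pointwise_model <- function(x, ...) {
  tibble(cell = seq_len(54L),
         intercept = x$coefficients[, "intercept"],
         b_input = x$coefficients[, "b_input"],
         b_t = x$coefficients[, "b_t"],
         resid_sd = x$resid_sd,
         fallback = x$fallback)
}

#' @rdname fit_pointwise
#' @export
glance.pointwise_model <- function(x, ...) {
  tibble(n_pairs = x$n_pairs,
         n_fallback = sum(x$fallback),
         mean_resid_sd = mean(x$resid_sd, na.rm = TRUE))
}

#' Theoretical lower bound on the pointwise MAE
#'
#' Under Gaussian test-retest noise no predictor can beat the noise itself:
#' even the true underlying sensitivity mispredicts a noisy measurement by
#' |N(0, sigma_i^2)| at point i, whose expectation is sigma_i * sqrt(2/pi).
#' The bound is the mean of that quantity over the valid points. Supply
#' either a single pooled noise SD or one SD per point.
#'
#' @param sigma Noise SD in dB: scalar or length-54 vector, all >= 0.
#' @return The floor on the expected pointwise MAE, in dB.
#' @examples
#' theoretical_pmae_floor(1)        # sqrt(2/pi)
#' theoretical_pmae_floor(2.91)     # about 2.32 dB
#' @export
theoretical_pmae_floor <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma < 0)) {
    abort("`sigma` must be non-negative and finite.")
  }
  stopifnot(length(sigma) %in% c(1L, 54L))
  mean(sigma) * sqrt(2 / pi)
}

#' Estimate test-retest noise SD from short-interval replicates
#'
#' Pairs of tests of the same eye taken within `max_years` of each other
#' are treated as replicates of the same underlying field; the per-point
#' differences then have SD sqrt(2) times the single-test noise SD, so the
#' pooled SD of differences divided by sqrt(2) estimates the retest SD.
#' This is the estimator feeding [theoretical_pmae_floor()].
#'
#' @param fields A field tibble.
#' @param max_years Maximum interval for two tests to count as replicates.
#' @return Pooled retest SD in dB (scalar), with the number of replicate
#'   pairs as attribute `"n_pairs"`.
#' @export
estimate_retest_sd <- function(fields, max_years = 0.5) {
  keys <- fields %>%
    select(all_of(c("patient_id", "eye", "test_date")))
  reps <- keys %>%
    inner_join(keys, by = c("patient_id", "eye"),
               suffix = c("_a", "_b"), relationship = "many-to-many") %>%
    filter(.data$test_date_b > .data$test_date_a,
           as.numeric(.data$test_date_b - .data$test_date_a) / 365.25 <=
             max_years)
  if (nrow(reps) == 0L) abort("no replicate pairs within `max_years`.")
  key_f <- paste(fields$patient_id, fields$eye, fields$test_date)
  m <- field_matrix(fields)
  d <- m[match(paste(reps$patient_id, reps$eye, reps$test_date_b), key_f), ,
         drop = FALSE] -
    m[match(paste(reps$patient_id, reps$eye, reps$test_date_a), key_f), ,
      drop = FALSE]
  out <- sd(as.vector(d)) / sqrt(2)
  attr(out, "n_pairs") <- nrow(reps)
  out
}
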