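#' The 24-2 test-point grid
#'
#' A Humphrey 24-2 field measures 54 sensitivity thresholds on an 8 x 9
#' lattice of 6-degree spacing. Rows run from +21 to -21 degrees of vertical
#' eccentricity; columns are the eye's nine horizontal chart positions in
#' printout order (left to right). The lattice is ragged: row-wise point
#' counts are 4, 6, 8, 9, 9, 8, 6, 4, and the two 9-point rows carry the
#' extra nasal-step point at 27 degrees. Two points sit on the physiologic
#' blind spot (15 degrees temporal, +/-3 degrees) and are excluded from the
#' mean deviation but are ordinary test points otherwise.
#'
#' `hvf_mask()` returns the 8 x 9 logical validity mask for an eye;
#' `hvf_blind_spot()` the mask of the two blind-spot cells;
#' `hvf_coords()` the per-cell chart coordinates in degrees.
#' The left-eye mask is the column mirror of the right-eye mask.
#'
#' @param eye `"right"` or `"left"`.
#' @return An 8 x 9 logical matrix (`hvf_mask`, `hvf_blind_spot`) or a
#'   tibble with columns `row`, `col`, `x`, `y` for the 54 valid cells
#'   (`hvf_coords`).
#' @examples
#' rowSums(hvf_mask("right"))
#' @export
hvf_mask <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  m <- matrix(FALSE, 8L, 9L)
  span <- list(4:7, 3:8, 2:9, 1:9, 1:9, 2:9, 3:8, 4:7)
  for (r in 1:8) m[r, span[[r]]] <- TRUE
  if (eye == "left") m <- m[, 9:1]
  m
}

#' @rdname hvf_mask
#' @export
hvf_blind_spot <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  b <- matrix(FALSE, 8L, 9L)
  col <- if (eye == "right") 8L else 2L  # 15 degrees temporal
  b[4:5, col] <- TRUE
  b
}

#' @rdname hvf_mask
#' @export
hvf_coords <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  # chart x positions, printout order; nasal extreme is -27 (right) / +27 (left)
  x <- if (eye == "right") seq(-27, 21, by = 6) else seq(-21, 27, by = 6)
  y <- seq(21, -21, by = -6)
  m <- hvf_mask(eye)
  idx <- which(t(m))  # row-major
  tibble(
    row = (idx - 1L) %/% 9L + 1L,
    col = (idx - 1L) %% 9L + 1L
  ) %>%
    mutate(x = x[.data$col], y = y[.data$row])
}

# 54-vector positions (row-major order) of the two blind-spot cells
blind_spot_index <- function(eye) {
  as.vector(t(hvf_blind_spot(eye)))[as.vector(t(hvf_mask(eye)))]
}

#' Embed 54 sensitivities into the 8 x 9 grid
#'
#' `to_grid()` places an ordered 54-vector of sensitivities (row-major
#' valid-cell order for the given eye) into an 8 x 9 matrix; invalid cells
#' are filled with the sentinel value 0, matching the masked-loss
#' convention. `from_grid()` inverts it exactly.
#'
#' @param values Numeric vector of length 54, each value in \[0, 50\] dB.
#' @param eye `"right"` or `"left"`.
#' @return `to_grid()`: an object of class `hvf_grid` — a list with
#'   `values` (8 x 9 matrix), `mask` (8 x 9 logical) and `eye`.
#'   `from_grid()`: the numeric 54-vector.
#' @examples
#' g <- to_grid(seq(0.5, 27, by = 0.5), "right")
#' all.equal(from_grid(g), seq(0.5, 27, by = 0.5))
#' @export
to_grid <- function(values, eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (length(values) != 54L) {
    abort(sprintf("`values` must have length 54, not %d.", length(values)))
  }
  bad <- which(!is.finite(values) | values < 0 | values > 50)
  if (length(bad) > 0L) {
    abort(sprintf(
      "sensitivities out of [0, 50] dB at position(s) %s.",
      paste(bad, collapse = ", ")
    ))
  }
  mask <- hvf_mask(eye)
  vt <- matrix(0, 9L, 8L)       # transposed so filling is row-major
  vt[t(mask)] <- values
  structure(list(values = t(vt), mask = mask, eye = eye), class = "hvf_grid")
}

#' @param grid An `hvf_grid`.
#' @rdname to_grid
#' @export
from_grid <- function(grid) {
  stopifnot(inherits(grid, "hvf_grid"))
  as.vector(t(grid$values))[as.vector(t(grid$mask))]
}

#' @export
print.hvf_grid <- function(x, ...) {
  cat(sprintf("<hvf_grid: %s eye>\n", x$eye))
  v <- round(x$values)
  v[!x$mask] <- NA
  print(v, na.print = ".")
  invisible(x)
}

#' Synthetic normative sensitivity surface
#'
#' Mean deviation requires an age-matched normal reference per test point.
#' The device's normative database is proprietary, so the package carries a
#' simple synthetic surface: sensitivity declines linearly with
#' eccentricity from a foveal peak, and with age at a uniform rate. It is
#' used consistently for both simulation and evaluation, so mean-deviation
#' values are internally coherent even though they are not the printout MD.
#'
#' @param peak_db Sensitivity at fixation for a reference-age normal (dB).
#' @param ecc_slope Decline per degree of eccentricity (dB/degree).
#' @param age_slope Normal ageing decline (dB/year, negative).
#' @param ref_age Age (years) at which `peak_db` applies.
#' @return An object of class `hvf_normative`: per-eye 8 x 9 reference
#'   matrices at `ref_age` plus the ageing slope.
#' @examples
#' norm <- normative_surface()
#' range(norm$right[hvf_mask("right")])
#' @export
normative_surface <- function(peak_db = 34, ecc_slope = 0.1,
                              age_slope = -0.07, ref_age = 45) {
  stopifnot(peak_db > 0, age_slope <= 0)
  surf <- function(eye) {
    co <- hvf_coords(eye)
    v <- matrix(0, 8L, 9L)
    v[cbind(co$row, co$col)] <- peak_db - ecc_slope * sqrt(co$x^2 + co$y^2)
    v
  }
  structure(
    list(right = surf("right"), left = surf("left"),
         age_slope = age_slope, ref_age = ref_age),
    class = "hvf_normative"
  )
}

# 54-vector of age-adjusted normative sensitivities for one eye
normative_values <- function(normative, eye, age) {
  base <- as.vector(t(normative[[eye]]))[as.vector(t(hvf_mask(eye)))]
  base + normative$age_slope * (age - normative$ref_age)
}

#' Mean deviation of a field
#'
#' The unweighted mean of (measured - age-adjusted normative) sensitivity
#' over the 52 valid cells that are not on the blind spot. Equal weighting
#' keeps the index linear (adding c dB everywhere adds c to the MD); the
#' device's variance-weighted MD requires its proprietary normative
#' database and is out of scope.
#'
#' @param grid An `hvf_grid`, or a numeric 54-vector (then pass `eye`).
#' @param normative An `hvf_normative` surface.
#' @param age Age in years at the test (> 0).
#' @param eye Eye, only needed when `grid` is a bare vector.
#' @return Mean deviation in dB (scalar).
#' @examples
#' norm <- normative_surface()
#' v <- normative_values_at(norm, "right", 60)
#' mean_deviation(to_grid(v, "right"), norm, 60)  # 0
#' @export
mean_deviation <- function(grid, normative, age, eye = NULL) {
  stopifnot(inherits(normative, "hvf_normative"), age > 0)
  if (inherits(grid, "hvf_grid")) {
    eye <- grid$eye
    values <- from_grid(grid)
  } else {
    stopifnot(!is.null(eye), length(grid) == 54L)
    values <- grid
  }
  keep <- !blind_spot_index(eye)
  mean(values[keep] - normative_values(normative, eye, age)[keep])
}

#' @rdname mean_deviation
#' @export
normative_values_at <- function(normative, eye, age) {
  stopifnot(inherits(normative, "hvf_normative"))
  normative_values(normative, eye, age)
}

# Vectorised MD for an n x 54 matrix of sensitivities (rows = fields).
# eye and age are length-n vectors.
md_matrix <- function(values, eye, age, normative) {
  out <- numeric(nrow(values))
  for (e in c("right", "left")) {
    i <- which(eye == e)
    if (length(i) == 0L) next
    keep <- !blind_spot_index(e)
    base <- normative_values(normative, e, normative$ref_age)[keep]
    dev <- values[i, keep, drop = FALSE] -
      matrix(base, length(i), sum(keep), byrow = TRUE) -
      normative$age_slope * (age[i] - normative$ref_age)
    out[i] <- rowMeans(dev)
  }
  out
}
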