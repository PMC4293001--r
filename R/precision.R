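#' Height resolution of a raster figure
#'
#' A raster image resolves the unit (0, 1) probability axis into
#' `dpi * axis_length_inches` pixels, so the smallest distinguishable height
#' difference is the reciprocal of that pixel count.
#'
#' @param dpi Dots per inch of the image.
#' @param axis_length_inches Physical length of the probability axis.
#' @return Height resolution (probability units per pixel).
#' @examples
#' raster_resolution(300, 1.6)  # ~0.002
#' @export
raster_resolution <- function(dpi, axis_length_inches) {
  stopifnot(dpi > 0, axis_length_inches > 0)
  1 / (dpi * axis_length_inches)
}

#' Height resolution of a vector (PostScript) figure
#'
#' Vector coordinates are printed to a fixed number of decimal places of a
#' printer point, so an axis of `axis_length_points` resolves the unit
#' probability axis into `axis_length_points * 10^decimals` distinguishable
#' heights.
#'
#' @param axis_length_points Axis length in printer points (72 per inch).
#' @param decimals Decimal places of the stored coordinates.
#' @return Height resolution on a unit axis.
#' @examples
#' vector_resolution(115.2, 3)  # ~1e-5, two hundred times finer than raster
#' @export
vector_resolution <- function(axis_length_points, decimals) {
  stopifnot(axis_length_points > 0, decimals >= 0)
  1 / (axis_length_points * 10^decimals)
}

#' Delta-method error model for the inverted number at risk
#'
#' The number at risk recovered from two adjacent curve heights is a ratio
#' `R = N/D` whose numerator and denominator are linear combinations of
#' rounded device coordinates.  With the probability axis running 0-5% and
#' heights `a`, `b` on the curve and `c`, `d` the 5% and 0% landmarks, the
#' estimate is `[20(c-d) - (b-d)] / (a - b)`: numerator error coefficients
#' (20, -19, -1) on `(c, d, b)` and denominator error `e_a - e_b`.  Each
#' coordinate's rounding error is uniform over the full rounding width, so
#' its standard deviation is `rounding_range / sqrt(12)`.
#'
#' @param mu1 Error-free numerator magnitude in points (e.g. `20 * 100 =
#'   2000` for a 100-point 0-5% axis).
#' @param mu2 Error-free denominator (jump) magnitude in points (e.g. 0.5).
#' @param rounding_range Full width of the per-coordinate uniform rounding
#'   error in points: 0.001 for three-decimal coordinates, 0.01 for two.
#' @param coef_num Error coefficients of the numerator's coordinates.
#' @param var_den Denominator error variance in units of `sigma_e^2`
#'   (default 2: the difference of two heights).
#' @param cov_nd Numerator-denominator error covariance in units of
#'   `sigma_e^2` (default 1: the shared height `b` appears in both with
#'   product of coefficients `(-1)(-1) = 1`).
#' @return An object of class `error_model`: a list with the inputs plus
#'   `sigma_e`, `sigma1_sq`, `sigma2_sq`, `sigma12` (absolute variances /
#'   covariance) and `cv` (coefficient of variation of the ratio).
#' @examples
#' error_model(mu1 = 2000, mu2 = 0.5, rounding_range = 0.01)$cv  # ~0.0082
#' @export
error_model <- function(mu1, mu2, rounding_range,
                        coef_num = c(20, -19, -1), var_den = 2, cov_nd = 1) {
  stopifnot(mu1 > 0, rounding_range >= 0)
  if (mu2 <= 0) abort("mu2 (the jump magnitude) must be positive")
  sigma_e <- rounding_range / sqrt(12)
  s2 <- sigma_e^2
  sigma1_sq <- sum(coef_num^2) * s2
  sigma2_sq <- var_den * s2
  sigma12 <- cov_nd * s2
  cv <- sqrt(max(0, sigma1_sq / mu1^2 + sigma2_sq / mu2^2 -
                   2 * sigma12 / (mu1 * mu2)))
  structure(list(mu1 = mu1, mu2 = mu2, rounding_range = rounding_range,
                 coef_num = coef_num, var_den = var_den, cov_nd = cov_nd,
                 sigma_e = sigma_e, sigma1_sq = sigma1_sq,
                 sigma2_sq = sigma2_sq, sigma12 = sigma12, cv = cv),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "<error_model: mu1 = %g, mu2 = %g pts, rounding %g pts -> sigma_e = %.3g, CV = %.4g%%>\n",
    x$mu1, x$mu2, x$rounding_range, x$sigma_e, 100 * x$cv))
  invisible(x)
}

#' Coefficient of variation of the inverted ratio
#'
#' First-order (delta-method) CV of `R = N/D`:
#' `CV^2 = sigma1^2/mu1^2 + sigma2^2/mu2^2 - 2*sigma12/(mu1*mu2)`.
#' Exactly linear in the rounding range.  Validate against
#' [ratio_cv_montecarlo()], which simulates the actual uniform rounding
#' errors.
#'
#' @param model An [error_model()], or `mu1` if the components are given
#'   directly.
#' @param mu2,rounding_range Passed to [error_model()] when `model` is
#'   numeric.
#' @param ... Further arguments to [error_model()].
#' @return The CV (dimensionless; multiply by 100 for percent).
#' @examples
#' ratio_cv(2000, 0.5, 0.01)    # two-decimal rounding
#' ratio_cv(2000, 0.5, 0.001)   # three-decimal rounding, 10x smaller
#' @export
ratio_cv <- function(model, mu2 = NULL, rounding_range = NULL, ...) {
  if (is.numeric(model)) {
    model <- error_model(model, mu2, rounding_range, ...)
  }
  stopifnot(inherits(model, "error_model"))
  model$cv
}

#' Monte-Carlo check of the delta-method CV
#'
#' Draws independent uniform rounding errors for the four coordinates
#' (`a`, `b` on the curve; `c`, `d` the axis landmarks), forms the ratio
#' exactly as the recovery does, and returns its empirical CV.  The
#' independent oracle for [ratio_cv()].
#'
#' @param model An [error_model()].
#' @param n_draws Number of simulated rounding realisations.
#' @param seed Optional RNG seed for reproducibility.
#' @return Empirical `sd(R)/mean(R)`.
#' @export
ratio_cv_montecarlo <- function(model, n_draws = 1e6, seed = NULL) {
  stopifnot(inherits(model, "error_model"))
  if (!is.null(seed)) set.seed(seed)
  half <- model$rounding_range / 2
  if (half == 0) return(0)
  e_a <- runif(n_draws, -half, half)
  e_b <- runif(n_draws, -half, half)
  e_c <- runif(n_draws, -half, half)
  e_d <- runif(n_draws, -half, half)
  k <- model$coef_num
  N <- if (length(k) == 2L) {
    model$mu1 + k[1] * e_a + k[2] * e_d     # per-jump model: numerator a - d
  } else {
    model$mu1 + k[1] * e_c + k[2] * e_d + k[3] * e_b
  }
  D <- model$mu2 + e_a - e_b
  R <- N / D
  stats::sd(R) / mean(R)
}

#' Per-row precision of recovered numbers at risk
#'
#' Applies the delta-method CV row by row to a recovered risk-set table:
#' the denominator magnitude is that row's jump expressed in device points
#' (`J(t_j) * axis_scale`) and the numerator is the pre-jump height in
#' device points.  For this per-jump ratio `n = d * a/(a - b)` (heights
#' `a`, `b` above the zero landmark) the numerator error is a difference of
#' two coordinates and shares the `a` term with the denominator.
#'
#' @param table A `risk_set_table` (needs columns `n`, `d`).
#' @param curve The `step_curve` the table came from (for the heights).
#' @param axis_scale Device points per height unit (e.g. 108 for a
#'   1.5-inch unit axis); see [axis_scale()].
#' @param rounding_range Per-coordinate rounding width in points.
#' @return The table with added columns `cv` and `sd_n` (expected standard
#'   deviation of the recovered `n`).
#' @export
n_precision_report <- function(table, curve, axis_scale,
                               rounding_range = 0.001) {
  jr <- jumps_and_ratios(curve)
  stopifnot(nrow(jr) == nrow(table))
  cv <- vapply(seq_len(nrow(jr)), function(j) {
    if (rounding_range == 0) return(0)
    ratio_cv(error_model(
      mu1 = jr$S_prev[j] * axis_scale,
      mu2 = jr$jump[j] * axis_scale,
      rounding_range = rounding_range,
      coef_num = c(1, -1),   # numerator a - d: two rounded coordinates
      var_den = 2, cov_nd = 1))
  }, double(1))
  out <- tibble::as_tibble(as.data.frame(table))
  out$cv <- cv
  out$sd_n <- cv * out$n
  out
}
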