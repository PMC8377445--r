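#' Arrhenius coordinates
#'
#' Transforms measured temperature and rate into Arrhenius-plot
#' coordinates: x = 1/T with T in Kelvin, y = ln(rate). A process obeying
#' k = A exp(-Ea/RT) is a straight line in these coordinates with slope
#' -Ea/R and intercept ln A.
#'
#' @param temperature_C temperature in degrees Celsius (> -273.15).
#' @param rate rate in min^-1 (> 0).
#' @return A tibble with columns `inv_T` (K^-1) and `ln_rate`.
#' @examples
#' to_arrhenius_coords(25, 1) # x = 1/298.15, y = 0
#' @export
to_arrhenius_coords <- function(temperature_C, rate) {
  stopifnot(is.numeric(temperature_C), is.numeric(rate))
  if (any(temperature_C <= -273.15)) stop("temperature at or below absolute zero")
  if (any(rate <= 0)) stop("rates must be positive")
  tibble::tibble(
    inv_T = 1 / celsius_to_kelvin(temperature_C),
    ln_rate = log(rate)
  )
}

#' Inverse of [to_arrhenius_coords()]
#'
#' @param inv_T reciprocal absolute temperature, K^-1.
#' @param ln_rate natural log of the rate.
#' @return A tibble with `temperature_C` and `rate`.
#' @export
from_arrhenius_coords <- function(inv_T, ln_rate) {
  stopifnot(all(inv_T > 0))
  tibble::tibble(
    temperature_C = 1 / inv_T - 273.15,
    rate = exp(ln_rate)
  )
}

#' Add Arrhenius coordinates to an interval table
#'
#' @param data tibble with `temperature_C` and `rate_per_min` columns
#'   (as produced by [compute_intervals()]).
#' @return `data` with `inv_T` and `ln_rate` columns appended.
#' @export
add_arrhenius_coords <- function(data) {
  stopifnot(is.data.frame(data))
  dplyr::bind_cols(
    data,
    to_arrhenius_coords(data$temperature_C, data$rate_per_min)
  )
}

arrhenius_points <- function(data) {
  # accept either raw interval tables or pre-transformed coordinates
  if (all(c("inv_T", "ln_rate") %in% names(data))) {
    tibble::tibble(
      inv_T = data$inv_T, ln_rate = data$ln_rate,
      temperature_C = if ("temperature_C" %in% names(data)) {
        data$temperature_C
      } else {
        1 / data$inv_T - 273.15
      }
    )
  } else if (all(c("temperature_C", "rate_per_min") %in% names(data))) {
    dplyr::bind_cols(
      to_arrhenius_coords(data$temperature_C, data$rate_per_min),
      tibble::tibble(temperature_C = data$temperature_C)
    )
  } else {
    stop(
      "data must contain either (inv_T, ln_rate) or ",
      "(temperature_C, rate_per_min) columns"
    )
  }
}

restrict_range <- function(points, range_C) {
  if (is.null(range_C)) return(points)
  stopifnot(length(range_C) == 2, range_C[1] <= range_C[2])
  dplyr::filter(
    points,
    .data$temperature_C >= range_C[1],
    .data$temperature_C <= range_C[2]
  )
}

#' Fit a linear Arrhenius model and estimate the apparent activation energy
#'
#' Ordinary least squares of ln(rate) on 1/T, restricted to a core
#' temperature range over which the plot is treated as linear. The
#' apparent activation energy is Ea = -slope * R (reported in kJ/mol)
#' with a 68% confidence half-width from the Student-t quantile at the
#' fit's residual degrees of freedom. Each row of `data` is one
#' independent biological measurement (one embryo-interval observation);
#' per-temperature means are for display only.
#'
#' @param data tibble of observations with `temperature_C` and
#'   `rate_per_min` (or pre-computed `inv_T`, `ln_rate`).
#' @param core_range numeric length-2, degrees Celsius; observations
#'   outside the closed range are excluded. `NULL` uses all points.
#' @param start_code,end_code optional labels carried into the result.
#' @return An object of class `arrhenius_fit` with elements `slope_K`,
#'   `intercept`, `Ea_kJ`, `se_Ea_kJ`, `ci68_Ea_kJ`, `core_range`, `n`,
#'   `rss`, `dof`, and the underlying `lm` fit.
#' @examples
#' d <- tibble::tibble(
#'   temperature_C = c(15, 20, 25, 30),
#'   rate_per_min = exp(5 - 64 * 1000 / 8.314 / (273.15 + c(15, 20, 25, 30)))
#' )
#' fit <- fit_arrhenius(d)
#' fit$Ea_kJ
#' @export
fit_arrhenius <- function(data, core_range = NULL,
                          start_code = NA_character_, end_code = NA_character_) {
  pts <- restrict_range(arrhenius_points(data), core_range)
  if (nrow(pts) < 3) stop("need at least 3 points inside the core range")
  if (stats::sd(pts$inv_T) == 0) stop("no variance in 1/T; cannot fit a slope")
  fit <- stats::lm(ln_rate ~ inv_T, data = pts)
  # summary.lm warns on numerically perfect fits; exact synthetic data is legitimate here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  se_slope <- sm$coefficients["inv_T", "Std. Error"]
  dof <- fit$df.residual
  # 68% CI half-width: t quantile at 0.84 (two-sided 68%)
  tq <- if (dof >= 1) stats::qt(0.84, dof) else NA_real_
  structure(
    list(
      start_code = start_code, end_code = end_code,
      slope_K = slope,
      intercept = unname(stats::coef(fit)[1]),
      Ea_kJ = slope_K_to_ea(-slope),
      se_Ea_kJ = slope_K_to_ea(se_slope),
      ci68_Ea_kJ = slope_K_to_ea(se_slope) * tq,
      core_range = core_range,
      n = nrow(pts),
      rss = sum(stats::residuals(fit)^2),
      dof = dof,
      lm = fit,
      points = pts
    ),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  lab <- if (!is.na(x$start_code)) paste0(" [", x$start_code, "-", x$end_code, "]") else ""
  cat(sprintf(
    "Arrhenius linear fit%s: Ea = %.2f +/- %.2f kJ/mol (68%% CI), n = %d\n",
    lab, x$Ea_kJ, x$ci68_Ea_kJ, x$n
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy arrhenius_fit
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope_K", "Ea_kJ"),
    estimate = c(x$intercept, x$slope_K, x$Ea_kJ),
    std.error = {
      cf <- suppressWarnings(summary(x$lm))$coefficients
      c(cf["(Intercept)", "Std. Error"], cf["inv_T", "Std. Error"], x$se_Ea_kJ)
    }
  )
}

#' @export
#' @method glance arrhenius_fit
glance.arrhenius_fit <- function(x, ...) {
  tibble::tibble(
    start_code = x$start_code, end_code = x$end_code,
    Ea_kJ = x$Ea_kJ, ci68_Ea_kJ = x$ci68_Ea_kJ,
    n = x$n, rss = x$rss, dof = x$dof,
    r.squared = suppressWarnings(summary(x$lm))$r.squared
  )
}

#' Fit a quadratic model in Arrhenius coordinates
#'
#' Least squares of ln(rate) on a quadratic in x = 1/T, by default over
#' all available temperatures (the departure from linearity lives at the
#' extremes). The sign of the leading coefficient reports concavity:
#' negative means concave downward, i.e. rates at both temperature
#' extremes fall below the straight-line extrapolation.
#'
#' @inheritParams fit_arrhenius
#' @param range_C optional temperature restriction in Celsius, e.g. a
#'   viable-regime window; default `NULL` fits all data.
#' @return An object of class `arrhenius_quad` with coefficients `c2`,
#'   `c1`, `c0` of ln k = c2 x^2 + c1 x + c0, `concavity` ("downward",
#'   "upward" or "none"), `n`, `rss`, and the `lm` fit.
#' @export
fit_arrhenius_quadratic <- function(data, range_C = NULL,
                                    start_code = NA_character_,
                                    end_code = NA_character_) {
  pts <- restrict_range(arrhenius_points(data), range_C)
  if (nrow(pts) < 4) stop("need at least 4 points for a quadratic fit")
  fit <- stats::lm(ln_rate ~ inv_T + I(inv_T^2), data = pts)
  if (anyNA(stats::coef(fit))) stop("rank-deficient quadratic design")
  cf <- stats::coef(fit)
  c2 <- unname(cf[3])
  structure(
    list(
      start_code = start_code, end_code = end_code,
      c2 = c2, c1 = unname(cf[2]), c0 = unname(cf[1]),
      concavity = if (c2 < 0) "downward" else if (c2 > 0) "upward" else "none",
      range_C = range_C,
      n = nrow(pts),
      rss = sum(stats::residuals(fit)^2),
      lm = fit,
      points = pts
    ),
    class = "arrhenius_quad"
  )
}

#' @export
print.arrhenius_quad <- function(x, ...) {
  cat(sprintf(
    "Quadratic Arrhenius fit: c2 = %.4g (%s), n = %d\n",
    x$c2, x$concavity, x$n
  ))
  invisible(x)
}

#' @export
#' @method tidy arrhenius_quad
tidy.arrhenius_quad <- function(x, ...) {
  tibble::tibble(
    term = c("c0", "c1", "c2"),
    estimate = c(x$c0, x$c1, x$c2)
  )
}

#' BIC comparison of linear vs quadratic Arrhenius models
#'
#' Fits both models to the same points and compares them with the
#' Gaussian concentrated-likelihood BIC, `n log(RSS/n) + k log(n)`, with
#' k = 2 parameters for the line and 3 for the parabola (the residual
#' variance is profiled out and contributes equally). The reported
#' statistic is the half log-ratio `lambda = (BIC_linear - BIC_quad)/2`;
#' positive values prefer the quadratic. On exactly linear data the two
#' RSS coincide and `lambda = -log(n)/2`: the penalty decides. A
#' perfectly quadratic signal drives `lambda` to +Inf, capped at
#' `lambda_cap`; if both models interpolate exactly the line is
#' preferred.
#'
#' @inheritParams fit_arrhenius
#' @param range_C optional temperature restriction in Celsius.
#' @param lambda_cap sentinel magnitude used when an RSS is exactly zero.
#' @return An object of class `bic_comparison`: `bic_linear`,
#'   `bic_quadratic`, `log_ratio`, `preferred`, `n`.
#' @export
bic_compare <- function(data, range_C = NULL, lambda_cap = 1e6) {
  pts <- restrict_range(arrhenius_points(data), range_C)
  n <- nrow(pts)
  if (n < 5) stop("need at least 5 points for the BIC comparison")
  lin <- stats::lm(ln_rate ~ inv_T, data = pts)
  quad <- stats::lm(ln_rate ~ inv_T + I(inv_T^2), data = pts)
  rss_l <- sum(stats::residuals(lin)^2)
  rss_q <- sum(stats::residuals(quad)^2)
  eps <- .Machine$double.eps * sum(pts$ln_rate^2)
  bic <- function(rss, k) n * log(rss / n) + k * log(n)
  if (rss_l <= eps && rss_q <= eps) {
    # both interpolate: the penalty decides for the line
    lambda <- -log(n) / 2
    bic_l <- bic_q <- NA_real_
  } else if (rss_q <= eps) {
    lambda <- lambda_cap
    bic_l <- bic(rss_l, 2)
    bic_q <- NA_real_
  } else {
    bic_l <- bic(rss_l, 2)
    bic_q <- bic(rss_q, 3)
    lambda <- (bic_l - bic_q) / 2
  }
  structure(
    list(
      bic_linear = bic_l, bic_quadratic = bic_q,
      log_ratio = lambda,
      preferred = if (lambda > 0) "quadratic" else "linear",
      n = n
    ),
    class = "bic_comparison"
  )
}

#' @export
print.bic_comparison <- function(x, ...) {
  cat(sprintf(
    "BIC model comparison: lambda = %.3f, %s preferred (n = %d)\n",
    x$log_ratio, x$preferred, x$n
  ))
  invisible(x)
}

#' @export
#' @method tidy bic_comparison
tidy.bic_comparison <- function(x, ...) {
  tibble::tibble(
    bic_linear = x$bic_linear, bic_quadratic = x$bic_quadratic,
    log_ratio = x$log_ratio, preferred = x$preferred, n = x$n
  )
}

#' Compare the slopes of two Arrhenius regressions (ANCOVA F-test)
#'
#' Tests whether two intervals share a common slope (equal apparent
#' activation energies) by comparing the full model with separate slopes
#' and intercepts against the reduced model with a common slope, via the
#' extra-sum-of-squares F-test on the group-by-1/T interaction. Post-hoc
#' power at the given alpha is computed from the noncentral F
#' distribution with noncentrality estimated from the observed statistic
#' (lambda = F * df1).
#'
#' @param data_a,data_b observation tibbles for the two intervals
#'   (columns as in [fit_arrhenius()]).
#' @param core_range shared core temperature range in Celsius, or `NULL`.
#' @param alpha significance level for the power computation.
#' @return An object of class `slope_comparison`: `F`, `p`, `df1`, `df2`,
#'   `power`, `delta_Ea_kJ` (slope difference as activation energy),
#'   group sizes.
#' @export
compare_slopes <- function(data_a, data_b, core_range = NULL, alpha = 0.05) {
  a <- restrict_range(arrhenius_points(data_a), core_range)
  b <- restrict_range(arrhenius_points(data_b), core_range)
  if (nrow(a) < 3 || nrow(b) < 3) stop("each group needs at least 3 points")
  both <- dplyr::bind_rows(
    dplyr::mutate(a, group = "A"),
    dplyr::mutate(b, group = "B")
  )
  full <- stats::lm(ln_rate ~ inv_T * group, data = both)
  reduced <- stats::lm(ln_rate ~ inv_T + group, data = both)
  if (anyNA(stats::coef(full))) stop("singular design in slope comparison")
  an <- stats::anova(reduced, full)
  Fobs <- an$F[2]
  df1 <- an$Df[2]
  df2 <- full$df.residual
  p <- an$`Pr(>F)`[2]
  ncp <- Fobs * df1
  power <- 1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = ncp)
  slope_diff <- unname(stats::coef(full)["inv_T:groupB"])
  structure(
    list(
      F = Fobs, p = p, df1 = df1, df2 = df2, power = power,
      delta_Ea_kJ = slope_K_to_ea(-slope_diff),
      n_a = nrow(a), n_b = nrow(b), alpha = alpha
    ),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf(
    "Slope comparison: F(%d, %d) = %.3f, p = %.3g, post-hoc power = %.3f\n",
    x$df1, x$df2, x$F, x$p, x$power
  ))
  invisible(x)
}

#' @export
#' @method tidy slope_comparison
tidy.slope_comparison <- function(x, ...) {
  tibble::tibble(
    F = x$F, p = x$p, df1 = x$df1, df2 = x$df2,
    power = x$power, delta_Ea_kJ = x$delta_Ea_kJ
  )
}

#' Initial rate from an absorbance time course
#'
#' Least-squares slope of absorbance against time within a closed
#' analysis window, the standard estimate of an initial enzymatic rate
#' from a spectrophotometric trace (e.g. NADH production followed at
#' 340 nm).
#'
#' @param trace tibble with columns `time_min` and `absorbance`.
#' @param window numeric length-2, minutes; samples with
#'   `window[1] <= time <= window[2]` are used.
#' @return Slope in absorbance units per minute.
#' @export
rate_from_absorbance <- function(trace, window = c(1.5, 4.5)) {
  stopifnot(is.data.frame(trace), all(c("time_min", "absorbance") %in% names(trace)))
  stopifnot(length(window) == 2, window[1] <= window[2])
  inside <- trace |>
    dplyr::filter(.data$time_min >= window[1], .data$time_min <= window[2])
  if (nrow(inside) < 3) stop("fewer than 3 samples inside the analysis window")
  unname(stats::coef(stats::lm(absorbance ~ time_min, data = inside))[2])
}

#' Quarter-power allometric time ratio
#'
#' Predicted fold-difference in developmental time between two embryos
#' from the quarter-power mass-scaling rule: rates scale as mass^(-1/4),
#' so times scale as (mass_1/mass_2)^(1/4).
#'
#' @param mass_1,mass_2 embryonic (non-yolk) masses, micrograms.
#' @return Predicted fold slow-down of organism 1 relative to organism 2.
#' @examples
#' allometric_time_ratio(25, 0.67) # ~2.5-fold
#' @export
allometric_time_ratio <- function(mass_1, mass_2) {
  if (any(c(mass_1, mass_2) <= 0)) stop("masses must be positive")
  (mass_1 / mass_2)^(1 / 4)
}

#' Duration ratio
#'
#' One-line convenience for comparing homologous interval durations
#' between organisms.
#'
#' @param t1,t2 durations in any common unit.
#' @return `t1 / t2`.
#' @export
duration_ratio <- function(t1, t2) t1 / t2
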