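#' Sequential reaction network
#'
#' A chain of first-order transitions, each obeying Arrhenius kinetics
#' with its own activation energy `Ea_kJ_per_mol` and pre-exponential
#' factor `A_per_min`. The chain's relaxation time is the sum of
#' per-reaction times, tau(T) = sum_i exp(Ea_i/(R T))/A_i, and its
#' composite rate in Arrhenius coordinates is ln k = -ln tau.
#'
#' @param Ea_kJ_per_mol numeric vector of activation energies, kJ/mol.
#' @param A_per_min numeric vector of pre-exponential factors, min^-1
#'   (recycled to the length of `Ea_kJ_per_mol`).
#' @return A tibble of class `reaction_network` with one row per
#'   reaction.
#' @examples
#' net <- reaction_network(c(60, 80), c(1e9, 1e12))
#' network_tau(net, 25)
#' @export
reaction_network <- function(Ea_kJ_per_mol, A_per_min) {
  stopifnot(is.numeric(Ea_kJ_per_mol), is.numeric(A_per_min))
  if (length(Ea_kJ_per_mol) == 0) stop("a network needs at least one reaction")
  if (any(!is.finite(Ea_kJ_per_mol))) stop("activation energies must be finite")
  if (any(A_per_min <= 0)) stop("pre-exponential factors must be positive")
  out <- tibble::tibble(
    Ea_kJ_per_mol = Ea_kJ_per_mol,
    A_per_min = rep_len(A_per_min, length(Ea_kJ_per_mol))
  )
  class(out) <- c("reaction_network", class(out))
  out
}

# log per-reaction times at one inverse temperature x = 1/T_K:
# log tau_i = b_i * x - log A_i, with b_i = Ea_i/R in Kelvin
network_log_times <- function(network, x) {
  ea_to_slope_K(network$Ea_kJ_per_mol) * x - log(network$A_per_min)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# weighted moments of the slope coefficients b_i with weights
# proportional to the per-reaction times at x; everything in log space
network_moments <- function(network, x) {
  b <- ea_to_slope_K(network$Ea_kJ_per_mol)
  lt <- network_log_times(network, x)
  w <- exp(lt - max(lt))
  w <- w / sum(w)
  m <- sum(w * b)
  v <- sum(w * (b - m)^2)
  list(mean_b = m, var_b = v)
}

#' Relaxation time of a sequential network
#'
#' Total expected completion time: the sum of per-reaction times
#' 1/k_i(T). Evaluated with log-sum-exp so large activation energies do
#' not overflow.
#'
#' @param network a [reaction_network()].
#' @param temperature_C temperature(s) in degrees Celsius.
#' @return Relaxation time(s) in minutes.
#' @export
network_tau <- function(network, temperature_C) {
  stopifnot(inherits(network, "reaction_network"))
  x <- 1 / celsius_to_kelvin(temperature_C)
  vapply(x, function(xi) exp(logsumexp(network_log_times(network, xi))), numeric(1))
}

#' Composite rate of a sequential network in Arrhenius coordinates
#'
#' ln k(T) = -ln tau(T). For a single reaction this reduces exactly to
#' the Arrhenius line ln A - Ea/(R T); for longer chains the composite is
#' always concave downward in 1/T (its second derivative in x = 1/T is
#' minus the time-weighted variance of the per-reaction Ea/R, which is
#' never positive).
#'
#' @inheritParams network_tau
#' @return ln composite rate (rate in min^-1), one value per temperature.
#' @export
composite_lnk <- function(network, temperature_C) {
  stopifnot(inherits(network, "reaction_network"))
  x <- 1 / celsius_to_kelvin(temperature_C)
  vapply(x, function(xi) -logsumexp(network_log_times(network, xi)), numeric(1))
}

#' Analytic derivatives of the composite Arrhenius curve
#'
#' First and second derivatives of y = ln k with respect to x = 1/T
#' (Kelvin^-1). Writing w_i for the relative per-reaction times at x and
#' b_i = Ea_i/R, the derivatives have closed weighted-moment forms:
#' dy/dx = -E_w(b), d2y/dx2 = -Var_w(b) <= 0.
#'
#' @inheritParams network_tau
#' @return A tibble with `temperature_C`, `dy_dx`, `d2y_dx2`.
#' @export
composite_lnk_derivs <- function(network, temperature_C) {
  stopifnot(inherits(network, "reaction_network"))
  x <- 1 / celsius_to_kelvin(temperature_C)
  mom <- lapply(x, function(xi) network_moments(network, xi))
  tibble::tibble(
    temperature_C = temperature_C,
    dy_dx = -vapply(mom, `[[`, numeric(1), "mean_b"),
    d2y_dx2 = -vapply(mom, `[[`, numeric(1), "var_b")
  )
}

#' Curvature of the composite Arrhenius curve
#'
#' Standard plane-curve curvature kappa = |y''| / (1 + y'^2)^(3/2) of
#' y = ln k as a function of x = 1/T (K^-1), evaluated from the analytic
#' derivatives. A single reaction is an exact line (kappa = 0); any
#' longer chain bends downward, and kappa quantifies how visibly it
#' departs from the Arrhenius line. Curvature is not invariant under
#' axis rescaling, so this (1/T in K^-1, natural log rate) convention is
#' normative for the optimization routines.
#'
#' @inheritParams network_tau
#' @return Curvature value(s), one per temperature.
#' @export
curvature_at <- function(network, temperature_C) {
  d <- composite_lnk_derivs(network, temperature_C)
  abs(d$d2y_dx2) / (1 + d$dy_dx^2)^(3 / 2)
}

#' Predict a composite Arrhenius curve from fitted sub-intervals
#'
#' Treats each fitted sub-interval as one reaction of a sequential chain
#' (its apparent Ea and ln A become the reaction parameters) and predicts
#' the composite ln rate of the spanned interval. The tangent activation
#' energy is the least-squares slope of the prediction over a stated core
#' range, converted to kJ/mol, i.e. what a linear Arrhenius fit to the
#' prediction would report.
#'
#' @param fits list of `arrhenius_fit` objects covering contiguous
#'   sub-intervals (a warning is raised if the start/end codes do not
#'   chain; computation proceeds).
#' @param temperatures numeric vector of temperatures, Celsius.
#' @param core_range numeric length-2, Celsius, used for the tangent
#'   slope; defaults to the range of `temperatures`.
#' @return An object of class `composite_prediction`: `prediction` (a
#'   tibble with `temperature_C`, `lnk`), `tangent_Ea_kJ`, `network`.
#' @export
predict_composite <- function(fits, temperatures, core_range = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (inherits(fits, "arrhenius_fit")) fits <- list(fits)
  ok <- vapply(fits, inherits, logical(1), "arrhenius_fit")
  if (!all(ok)) stop("fits must be arrhenius_fit objects")
  starts <- vapply(fits, function(f) f$start_code, character(1))
  ends <- vapply(fits, function(f) f$end_code, character(1))
  if (!anyNA(starts) && length(fits) > 1 &&
      !all(starts[-1] == ends[-length(ends)])) {
    warning("sub-interval fits are not contiguous; proceeding anyway")
  }
  net <- reaction_network(
    Ea_kJ_per_mol = vapply(fits, function(f) f$Ea_kJ, numeric(1)),
    A_per_min = exp(vapply(fits, function(f) f$intercept, numeric(1)))
  )
  if (is.null(core_range)) core_range <- range(temperatures)
  pred <- tibble::tibble(
    temperature_C = temperatures,
    lnk = composite_lnk(net, temperatures)
  )
  core <- dplyr::filter(
    pred,
    .data$temperature_C >= core_range[1],
    .data$temperature_C <= core_range[2]
  )
  if (nrow(core) < 2) stop("core range must contain at least 2 grid temperatures")
  xs <- 1 / celsius_to_kelvin(core$temperature_C)
  tangent_fit <- stats::lm(core$lnk ~ xs)
  structure(
    list(
      prediction = pred,
      tangent_Ea_kJ = slope_K_to_ea(-unname(stats::coef(tangent_fit)[2])),
      core_range = core_range,
      network = net
    ),
    class = "composite_prediction"
  )
}

#' @export
print.composite_prediction <- function(x, ...) {
  cat(sprintf(
    "Composite prediction from %d sub-interval(s): tangent Ea = %.2f kJ/mol over %s-%s C\n",
    nrow(x$network), x$tangent_Ea_kJ, x$core_range[1], x$core_range[2]
  ))
  invisible(x)
}

#' Expand one reaction into an equivalent chain of identical reactions
#'
#' Splits a reaction into `m` identical reactions that keep the original
#' pre-exponential factor and carry the adjusted activation energy
#' Ea' = Ea - R T_ref ln(m) (in kJ/mol). Because reactions sharing one
#' Ea collapse exactly into a single Arrhenius reaction, the m-chain's
#' relaxation time equals the original reaction's exactly at T = T_ref
#' (and only there: away from T_ref the chain's shallower slope makes it
#' faster below and slower above, or vice versa).
#'
#' @param Ea_kJ_per_mol,A_per_min parameters of the reaction to expand.
#' @param m number of identical reactions in the expansion.
#' @param T_ref_K reference absolute temperature at which the relaxation
#'   time is preserved.
#' @return A [reaction_network()] of `m` identical reactions.
#' @examples
#' expand_reaction(66.74, 1e10, m = 999, T_ref_K = 295.15)
#' @export
expand_reaction <- function(Ea_kJ_per_mol, A_per_min, m, T_ref_K = 295.15) {
  stopifnot(length(Ea_kJ_per_mol) == 1, length(A_per_min) == 1, m >= 1)
  Ea_new <- Ea_kJ_per_mol - gas_constant * T_ref_K * log(m) / 1000
  reaction_network(rep(Ea_new, m), rep(A_per_min, m))
}

#' Serialize a reaction network to JSON
#'
#' @param network a [reaction_network()].
#' @param path file path; the JSON is an array of
#'   `{Ea_kJ_per_mol, A_per_min}` objects.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  jsonlite::write_json(
    as.data.frame(network), path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  reaction_network(df$Ea_kJ_per_mol, df$A_per_min)
}
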