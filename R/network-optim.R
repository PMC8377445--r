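#' Sample a random sequential network within physiological bounds
#'
#' Draws activation energies uniformly within `Ea_bounds` and
#' per-reaction times at a reference temperature log-uniformly within
#' `time_bounds_min`; each pre-exponential factor is back-solved so the
#' reaction takes exactly its sampled time at `T_ref_K`. The defaults
#' bound Ea by literature values for enzymes (20-100 kJ/mol) and the
#' per-state time 1/k between 1 s and 3 days (the span from an
#' implausibly fast embryonic transition to the length of entire fly
#' development).
#'
#' @param n number of reactions.
#' @param Ea_bounds numeric length-2, kJ/mol.
#' @param time_bounds_min numeric length-2, minutes; per-reaction 1/k at
#'   `T_ref_K`.
#' @param T_ref_K reference absolute temperature.
#' @return A [reaction_network()] with `n` reactions.
#' @export
random_network <- function(n, Ea_bounds = c(20, 100),
                           time_bounds_min = c(1 / 60, 3 * 24 * 60),
                           T_ref_K = 295.15) {
  stopifnot(n >= 1, Ea_bounds[1] <= Ea_bounds[2],
            time_bounds_min[1] <= time_bounds_min[2], time_bounds_min[1] > 0)
  Ea <- stats::runif(n, Ea_bounds[1], Ea_bounds[2])
  log_t <- stats::runif(n, log(time_bounds_min[1]), log(time_bounds_min[2]))
  # tau_i(T_ref) = exp(b_i/T_ref)/A_i = t_i  =>  log A_i = b_i/T_ref - log t_i
  log_A <- ea_to_slope_K(Ea) / T_ref_K - log_t
  reaction_network(Ea, exp(log_A))
}

# curvature at x_target of a 2-reaction network parameterized as
# (Ea1, Ea2, log t1, log t2) with t_i the per-reaction time at T_target
worst_case_objective <- function(par, x_target) {
  b <- ea_to_slope_K(par[1:2])
  lt <- par[3:4]
  w <- exp(lt - max(lt))
  w <- w / sum(w)
  m <- sum(w * b)
  v <- sum(w * (b - m)^2)
  v / (1 + m^2)^(3 / 2)
}

# analytic gradient of worst_case_objective via weighted-moment identities:
# d m / d lt_i = w_i (b_i - m);  d v / d lt_i = w_i ((b_i - m)^2 - v)
worst_case_gradient <- function(par, x_target) {
  cc <- 1000 / gas_constant
  b <- cc * par[1:2]
  w <- exp(par[3:4] - max(par[3:4]))
  w <- w / sum(w)
  m <- sum(w * b)
  v <- sum(w * (b - m)^2)
  g <- (1 + m^2)^(-3 / 2)
  dk_dv <- g
  dk_dm <- -3 * v * m * (1 + m^2)^(-5 / 2)
  dm_dEa <- w * cc
  dv_dEa <- 2 * cc * w * (b - m)
  dm_dlt <- w * (b - m)
  dv_dlt <- w * ((b - m)^2 - v)
  c(dk_dv * dv_dEa + dk_dm * dm_dEa,
    dk_dv * dv_dlt + dk_dm * dm_dlt)
}

#' Maximize composite-curve curvature over constrained 2-reaction networks
#'
#' Searches for the sequential 2-reaction network whose composite
#' Arrhenius curve bends the most at a target temperature: a worst case
#' for the near-linearity of chained Arrhenius steps. The search runs a
#' multi-start bounded quasi-Newton (L-BFGS-B) optimization over
#' (Ea_1, Ea_2, log t_1, log t_2), where t_i is the per-reaction time
#' 1/k_i at `T_target_K`, subject to box constraints on both. The best
#' feasible solution is returned together with its expansion to an
#' `expand_to`-reaction chain: the lower-Ea reaction is split via
#' [expand_reaction()] into `expand_to - 1` identical reactions, which
#' preserves the composite relaxation time exactly at the target
#' temperature.
#'
#' @param n_starts number of uniformly sampled starting points (>= 1).
#' @param Ea_bounds,time_bounds_min box constraints as in
#'   [random_network()].
#' @param T_target_K absolute temperature at which curvature is
#'   maximized.
#' @param expand_to total size of the expanded network (`NULL` skips the
#'   expansion).
#' @param seed optional integer seed; a run is fully reproducible given
#'   `(seed, n_starts)`. `NULL` leaves the RNG state alone.
#' @return An object of class `curvature_optimum`: `network` (the
#'   2-reaction optimum), `curvature`, `lower_Ea_kJ`, `expanded`
#'   (the `expand_to`-reaction equivalent), `starts` (per-start tibble),
#'   `converged`.
#' @export
optimize_worst_case <- function(n_starts = 64,
                                Ea_bounds = c(20, 100),
                                time_bounds_min = c(1 / 60, 3 * 24 * 60),
                                T_target_K = 295.15,
                                expand_to = 1000,
                                seed = NULL) {
  stopifnot(n_starts >= 1)
  if (!is.null(seed)) set.seed(seed)
  x_target <- 1 / T_target_K
  lower <- c(Ea_bounds[1], Ea_bounds[1], log(time_bounds_min[1]), log(time_bounds_min[1]))
  upper <- c(Ea_bounds[2], Ea_bounds[2], log(time_bounds_min[2]), log(time_bounds_min[2]))
  one_start <- function(i) {
    p0 <- stats::runif(4, lower, upper)
    res <- tryCatch(
      stats::optim(
        p0, function(p) -worst_case_objective(p, x_target),
        gr = function(p) -worst_case_gradient(p, x_target),
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 1e4, maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble::tibble(
        Ea1 = NA_real_, Ea2 = NA_real_, log_t1 = NA_real_, log_t2 = NA_real_,
        curvature = -Inf, converged = FALSE
      ))
    }
    tibble::tibble(
      Ea1 = res$par[1], Ea2 = res$par[2],
      log_t1 = res$par[3], log_t2 = res$par[4],
      curvature = -res$value, converged = res$convergence == 0
    )
  }
  starts <- purrr::map_dfr(seq_len(n_starts), one_start)
  feasible <- dplyr::filter(starts, is.finite(.data$curvature))
  if (nrow(feasible) == 0) stop("no feasible optimization start succeeded")
  best <- feasible[which.max(feasible$curvature), ]

  Ea <- c(best$Ea1, best$Ea2)
  t_min <- exp(c(best$log_t1, best$log_t2))
  A <- exp(ea_to_slope_K(Ea) / T_target_K - log(t_min))
  net <- reaction_network(Ea, A)

  # independent constraint check at the returned optimum
  t_check <- network_log_times(net, 1 / T_target_K)
  tol <- 1e-8
  ok <- all(Ea >= Ea_bounds[1] - tol, Ea <= Ea_bounds[2] + tol,
            exp(t_check) >= time_bounds_min[1] * (1 - 1e-6),
            exp(t_check) <= time_bounds_min[2] * (1 + 1e-6))
  if (!ok) stop("optimizer returned an infeasible solution")

  expanded <- NULL
  if (!is.null(expand_to) && expand_to > 2) {
    low <- which.min(Ea)
    high <- setdiff(1:2, low)
    expanded <- dplyr::bind_rows(
      expand_reaction(Ea[low], A[low], m = expand_to - 1, T_ref_K = T_target_K),
      reaction_network(Ea[high], A[high])
    )
    class(expanded) <- c("reaction_network", class(tibble::tibble()))
  }
  structure(
    list(
      network = net,
      curvature = best$curvature,
      lower_Ea_kJ = min(Ea),
      expanded = expanded,
      T_target_K = T_target_K,
      Ea_bounds = Ea_bounds,
      time_bounds_min = time_bounds_min,
      starts = starts,
      converged = any(feasible$converged)
    ),
    class = "curvature_optimum"
  )
}

#' @export
print.curvature_optimum <- function(x, ...) {
  cat(sprintf(
    "Worst-case curvature optimum: Ea = (%.2f, %.2f) kJ/mol, kappa = %.4g at %.2f K\n",
    x$network$Ea_kJ_per_mol[1], x$network$Ea_kJ_per_mol[2],
    x$curvature, x$T_target_K
  ))
  invisible(x)
}

#' @export
#' @method glance curvature_optimum
glance.curvature_optimum <- function(x, ...) {
  tibble::tibble(
    lower_Ea_kJ = x$lower_Ea_kJ,
    upper_Ea_kJ = max(x$network$Ea_kJ_per_mol),
    curvature = x$curvature,
    T_target_K = x$T_target_K,
    n_starts = nrow(x$starts),
    converged = x$converged
  )
}

#' Vertical offset aligning two Arrhenius-coordinate predictions
#'
#' Finds the constant to add to prediction B's ln k so that its tangent
#' line coincides with prediction A's at a reference temperature (or so
#' that least-squares lines over a core range share their fitted value at
#' the range centre). Only the offset is applied; any slope mismatch is
#' reported, never corrected. This mirrors the vertical y-axis scaling
#' used to overlay model networks on empirical data for shape
#' comparison.
#'
#' @param pred_a,pred_b tibbles with `temperature_C` and `lnk` on a
#'   shared temperature grid (or `composite_prediction` objects).
#' @param T_ref_K reference absolute temperature for tangent matching;
#'   ignored when `core_range` is given.
#' @param core_range optional Celsius range: align least-squares lines
#'   fitted over this range instead of local tangents.
#' @return A list: `offset` (add to B's lnk), `slope_mismatch_K`
#'   (tangent slope difference A - B, in Kelvin), `tangent_Ea_a_kJ`,
#'   `tangent_Ea_b_kJ`.
#' @export
tangent_align <- function(pred_a, pred_b, T_ref_K = 295.15, core_range = NULL) {
  grab <- function(p) {
    if (inherits(p, "composite_prediction")) p$prediction else p
  }
  a <- grab(pred_a)
  b <- grab(pred_b)
  stopifnot(all(c("temperature_C", "lnk") %in% names(a)),
            all(c("temperature_C", "lnk") %in% names(b)))
  if (!isTRUE(all.equal(a$temperature_C, b$temperature_C))) {
    stop("predictions must share a temperature grid")
  }
  x <- 1 / celsius_to_kelvin(a$temperature_C)
  line_at <- function(y, x0) {
    if (!is.null(core_range)) {
      keep <- a$temperature_C >= core_range[1] & a$temperature_C <= core_range[2]
      if (sum(keep) < 2) stop("core range contains fewer than 2 grid points")
      fit <- stats::lm(y[keep] ~ x[keep])
      cf <- stats::coef(fit)
      list(value = cf[1] + cf[2] * x0, slope = unname(cf[2]))
    } else {
      # local tangent from the two grid points bracketing x0
      if (x0 < min(x) || x0 > max(x)) stop("T_ref outside the temperature grid")
      idx <- order(abs(x - x0))[1:2]
      slope <- diff(y[idx]) / diff(x[idx])
      list(value = y[idx[1]] + slope * (x0 - x[idx[1]]), slope = slope)
    }
  }
  x0 <- if (is.null(core_range)) {
    1 / T_ref_K
  } else {
    mean(1 / celsius_to_kelvin(core_range))
  }
  la <- line_at(a$lnk, x0)
  lb <- line_at(b$lnk, x0)
  list(
    offset = unname(la$value - lb$value),
    slope_mismatch_K = la$slope - lb$slope,
    tangent_Ea_a_kJ = slope_K_to_ea(-la$slope),
    tangent_Ea_b_kJ = slope_K_to_ea(-lb$slope)
  )
}
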