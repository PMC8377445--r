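#' Design for a synthetic embryo-timing experiment
#'
#' Describes a ground-truth generative model for staged event-timing
#' tables: an ordered score sequence, a true Arrhenius (or concave
#' quadratic) temperature dependence for each adjacent interval,
#' a temperature panel with replicate embryos, multiplicative lognormal
#' duration noise of a given CV, optional shared-clutch offsets (frog
#' recordings share a mother per temperature; fly recordings do not), and
#' a viability window outside of which late scores are withheld.
#'
#' @param organism label, e.g. "fly" or "frog".
#' @param scores character vector of score codes in developmental order
#'   (>= 2).
#' @param Ea_kJ true per-interval activation energies, length
#'   `length(scores) - 1` (recycled).
#' @param lnA true per-interval log pre-exponential factors (rate in
#'   min^-1), recycled likewise.
#' @param c2 optional per-interval quadratic coefficients of ln k in
#'   x = 1/T (0 = pure Arrhenius; negative = concave downward),
#'   recycled.
#' @param temperatures_C nominal temperature panel, Celsius.
#' @param replicates embryos per temperature.
#' @param cv duration coefficient of variation of the multiplicative
#'   noise (0 = noise-free).
#' @param clutch_sd standard deviation of the shared per-temperature
#'   log-duration offset (0 = independent mothers).
#' @param temperature_jitter_sd sd of the measured-temperature spread
#'   around the nominal value, Celsius (emulating thermometer error).
#' @param viability_window Celsius range outside which embryos die
#'   before the late scores; their timelines are truncated after
#'   `nonviable_keep` scores.
#' @param nonviable_keep number of leading scores still observed at
#'   non-viable temperatures.
#' @param seed integer seed making the generated table reproducible.
#' @return A list of class `timing_design`.
#' @export
timing_design <- function(organism = "fly",
                          scores = LETTERS[1:8],
                          Ea_kJ = 64,
                          lnA = NULL,
                          c2 = 0,
                          temperatures_C = seq(14, 28, by = 2),
                          replicates = 5,
                          cv = 0.05,
                          clutch_sd = 0,
                          temperature_jitter_sd = 0,
                          viability_window = c(-Inf, Inf),
                          nonviable_keep = max(2, ceiling(length(scores) / 2)),
                          seed = 1L) {
  stopifnot(length(scores) >= 2, cv >= 0, clutch_sd >= 0,
            replicates >= 1, length(temperatures_C) >= 1,
            viability_window[1] <= viability_window[2])
  n_int <- length(scores) - 1
  if (is.null(lnA)) {
    # choose lnA so each interval takes 60 min at 25 C under pure Arrhenius
    lnA <- rep_len(Ea_kJ, n_int) * 1000 / gas_constant / 298.15 + log(1 / 60)
  }
  structure(
    list(
      organism = organism, scores = scores,
      Ea_kJ = rep_len(Ea_kJ, n_int),
      lnA = rep_len(lnA, n_int),
      c2 = rep_len(c2, n_int),
      temperatures_C = temperatures_C,
      replicates = replicates, cv = cv, clutch_sd = clutch_sd,
      temperature_jitter_sd = temperature_jitter_sd,
      viability_window = viability_window,
      nonviable_keep = nonviable_keep,
      seed = as.integer(seed)
    ),
    class = "timing_design"
  )
}

# true ln rate of interval i at absolute temperature T_K
design_ln_rate <- function(design, i, T_K) {
  x <- 1 / T_K
  design$lnA[i] - ea_to_slope_K(design$Ea_kJ[i]) * x + design$c2[i] * x^2
}

#' Generate a synthetic event-timing table with known ground truth
#'
#' Simulates the long-format table produced by scoring time-lapse
#' recordings. For each embryo, each interval's mean duration is 1/k(T)
#' under the design's true model at the embryo's measured temperature;
#' the realized duration multiplies in mean-one lognormal replicate noise
#' and, if enabled, a shared per-temperature clutch factor. Absolute
#' score times are cumulative sums from the first score (time zero).
#' Timelines at temperatures outside the viability window are truncated
#' after `nonviable_keep` scores, emulating death at the extremes.
#'
#' @param design a [timing_design()].
#' @return A list with `events` (tibble in the long input format:
#'   `embryo_id`, `organism`, `temperature_C`, `score_code`, `time_min`)
#'   and `truth` (the per-interval true parameters and per-embryo
#'   realized temperatures).
#' @export
generate_timelines <- function(design) {
  stopifnot(inherits(design, "timing_design"))
  if (length(design$temperatures_C) == 0) stop("empty temperature list")
  set.seed(design$seed)
  sdlog <- sqrt(log(1 + design$cv^2))
  clutch_sdlog <- design$clutch_sd
  n_int <- length(design$scores) - 1

  rows <- list()
  embryo_no <- 0
  for (ti in seq_along(design$temperatures_C)) {
    T_nom <- design$temperatures_C[ti]
    clutch <- if (clutch_sdlog > 0) {
      stats::rnorm(1, 0, clutch_sdlog) - clutch_sdlog^2 / 2
    } else {
      0
    }
    viable <- T_nom >= design$viability_window[1] &
      T_nom <= design$viability_window[2]
    keep <- if (viable) length(design$scores) else design$nonviable_keep
    for (r in seq_len(design$replicates)) {
      embryo_no <- embryo_no + 1
      T_meas <- T_nom + if (design$temperature_jitter_sd > 0) {
        stats::rnorm(1, 0, design$temperature_jitter_sd)
      } else {
        0
      }
      T_K <- celsius_to_kelvin(T_meas)
      mean_dur <- exp(-vapply(seq_len(n_int), design_ln_rate,
                              numeric(1), design = design, T_K = T_K))
      noise <- if (design$cv > 0) {
        exp(stats::rnorm(n_int, 0, sdlog) - sdlog^2 / 2)
      } else {
        rep(1, n_int)
      }
      dur <- mean_dur * noise * exp(clutch)
      times <- c(0, cumsum(dur))
      rows[[embryo_no]] <- tibble::tibble(
        embryo_id = sprintf("%s_T%02d_r%02d", design$organism, ti, r),
        organism = design$organism,
        temperature_C = T_meas,
        score_code = design$scores[seq_len(keep)],
        time_min = times[seq_len(keep)]
      )
    }
  }
  list(
    events = dplyr::bind_rows(rows),
    truth = list(
      scores = design$scores,
      Ea_kJ = design$Ea_kJ, lnA = design$lnA, c2 = design$c2,
      cv = design$cv, clutch_sd = design$clutch_sd,
      viability_window = design$viability_window,
      seed = design$seed
    )
  )
}

#' Generate a synthetic absorbance time course
#'
#' Linear absorbance growth plus i.i.d. Gaussian noise, emulating a
#' spectrophotometric enzyme-assay trace sampled at a fixed rate.
#'
#' @param rate true slope, absorbance units per minute.
#' @param intercept absorbance at time zero.
#' @param duration_min trace length, minutes.
#' @param sampling_s sampling period, seconds.
#' @param noise_sd Gaussian noise sd, absorbance units.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return A tibble with `time_min` and `absorbance`.
#' @export
generate_absorbance_trace <- function(rate, intercept = 0.1, duration_min = 5,
                                      sampling_s = 1, noise_sd = 0,
                                      seed = NULL) {
  stopifnot(duration_min > 0, sampling_s > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_min, by = sampling_s / 60)
  tibble::tibble(
    time_min = t,
    absorbance = intercept + rate * t +
      if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
  )
}
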