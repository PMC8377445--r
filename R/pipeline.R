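#' Configuration for a full timing analysis
#'
#' @param organism "fly" or "frog" (or any label).
#' @param scores retained score codes in developmental order.
#' @param origin score code defining time zero (fly: the 14th cleavage
#'   "A"; frog: the 3rd cleavage "A").
#' @param core_range Celsius range treated as linear in the Arrhenius
#'   plot (fly default 14.3-27; frog 12.2-25.7).
#' @param viable_range Celsius range over which embryos reach the last
#'   scored event (fly 14.3-30.1; frog 12.2-28.5); used by the
#'   quadratic/BIC viable-regime analyses when
#'   `quad_restrict_viable = TRUE`.
#' @param composite_span length-2 score codes delimiting the span whose
#'   composite rate is predicted from its sub-interval fits.
#' @param quad_restrict_viable restrict quadratic/BIC fits to
#'   `viable_range` instead of all temperatures.
#' @param alpha significance level for slope comparisons.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(organism = "fly",
                            scores = LETTERS[1:12],
                            origin = scores[1],
                            core_range = if (organism == "frog") c(12.2, 25.7) else c(14.3, 27),
                            viable_range = if (organism == "frog") c(12.2, 28.5) else c(14.3, 30.1),
                            composite_span = c(scores[1], scores[min(7, length(scores))]),
                            quad_restrict_viable = FALSE,
                            alpha = 0.05) {
  stopifnot(length(scores) >= 2, origin %in% scores,
            core_range[1] <= core_range[2],
            viable_range[1] <= viable_range[2],
            all(composite_span %in% scores))
  structure(
    list(
      organism = organism, scores = scores, origin = origin,
      core_range = core_range, viable_range = viable_range,
      composite_span = composite_span,
      quad_restrict_viable = quad_restrict_viable,
      alpha = alpha
    ),
    class = "analysis_config"
  )
}

#' Run the full temperature-scaling analysis on a timing table
#'
#' Orchestrates every stage: re-zeroes times at the configured origin,
#' builds per-embryo interval observations for every adjacent score
#' pair, fits linear (core-range) and quadratic (all-temperature or
#' viable-regime) Arrhenius models per interval, runs the linear vs
#' quadratic BIC comparison for every (start, end) pair with start
#' before end, compares the slopes of every pair of adjacent intervals
#' by ANCOVA (raw p-values, with a Holm-adjusted column added as a
#' labelled extension), and predicts the composite rate of the
#' configured span from its sub-interval fits. No stage mutates its
#' inputs; the returned manifest contains every computed number.
#'
#' @param events long-format tibble of scored events.
#' @param config an [analysis_config()].
#' @return A list of class `analysis_report` with tibbles
#'   `interval_fits`, `quadratic_fits`, `bic_matrix`,
#'   `slope_comparisons`, the `composite` prediction, `rate_summaries`,
#'   and a `manifest` list.
#' @export
run_full_analysis <- function(events, config) {
  stopifnot(is.data.frame(events), inherits(config, "analysis_config"))
  scores <- config$scores
  events <- relative_times(events, config$origin)

  adjacent <- tibble::tibble(
    start_code = scores[-length(scores)],
    end_code = scores[-1]
  )
  interval_obs <- purrr::map2(
    adjacent$start_code, adjacent$end_code,
    function(s, e) suppressWarnings(compute_intervals(events, s, e))
  )
  names(interval_obs) <- paste0(adjacent$start_code, "-", adjacent$end_code)

  fits <- purrr::map2(
    interval_obs, seq_len(nrow(adjacent)),
    function(obs, i) {
      tryCatch(
        fit_arrhenius(obs, core_range = config$core_range,
                      start_code = adjacent$start_code[i],
                      end_code = adjacent$end_code[i]),
        error = function(e) NULL
      )
    }
  )
  interval_fits <- purrr::map_dfr(purrr::compact(fits), glance)

  quad_range <- if (config$quad_restrict_viable) config$viable_range else NULL
  quadratic_fits <- purrr::map2_dfr(
    interval_obs, seq_len(nrow(adjacent)),
    function(obs, i) {
      q <- tryCatch(
        fit_arrhenius_quadratic(obs, range_C = quad_range,
                                start_code = adjacent$start_code[i],
                                end_code = adjacent$end_code[i]),
        error = function(e) NULL
      )
      if (is.null(q)) return(NULL)
      tibble::tibble(
        start_code = q$start_code, end_code = q$end_code,
        c2 = q$c2, c1 = q$c1, c0 = q$c0,
        concavity = q$concavity, n = q$n, rss = q$rss
      )
    }
  )

  all_pairs <- tidyr::expand_grid(
    i = seq_along(scores), j = seq_along(scores)
  ) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(start_code = scores[.data$i], end_code = scores[.data$j])
  bic_matrix <- purrr::map_dfr(seq_len(nrow(all_pairs)), function(r) {
    obs <- suppressWarnings(
      compute_intervals(events, all_pairs$start_code[r], all_pairs$end_code[r])
    )
    cmp <- tryCatch(bic_compare(obs, range_C = quad_range), error = function(e) NULL)
    if (is.null(cmp)) return(NULL)
    tibble::tibble(
      start_code = all_pairs$start_code[r], end_code = all_pairs$end_code[r],
      log_ratio = cmp$log_ratio, preferred = cmp$preferred, n = cmp$n
    )
  })

  # pairwise ANCOVA between adjacent-interval regressions
  keep_idx <- which(!vapply(fits, is.null, logical(1)))
  pair_idx <- utils::combn(keep_idx, 2)
  slope_comparisons <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(c_) {
    i <- pair_idx[1, c_]; j <- pair_idx[2, c_]
    cmp <- tryCatch(
      compare_slopes(interval_obs[[i]], interval_obs[[j]],
                     core_range = config$core_range, alpha = config$alpha),
      error = function(e) NULL
    )
    if (is.null(cmp)) return(NULL)
    tibble::tibble(
      interval_a = names(interval_obs)[i],
      interval_b = names(interval_obs)[j],
      F = cmp$F, p = cmp$p, power = cmp$power,
      delta_Ea_kJ = cmp$delta_Ea_kJ
    )
  })
  if (nrow(slope_comparisons) > 0) {
    slope_comparisons$p_holm <- stats::p.adjust(slope_comparisons$p, "holm")
  }

  span_i <- match(config$composite_span, scores)
  span_fits <- purrr::compact(fits[seq(span_i[1], span_i[2] - 1)])
  composite <- if (length(span_fits) >= 1) {
    grid <- seq(config$viable_range[1], config$viable_range[2], by = 0.5)
    predict_composite(span_fits, grid, core_range = config$core_range)
  } else {
    NULL
  }

  rate_summaries <- purrr::map_dfr(interval_obs, summarize_rates)

  manifest <- list(
    organism = config$organism,
    origin = config$origin,
    core_range_C = config$core_range,
    viable_range_C = config$viable_range,
    interval_fits = as.data.frame(interval_fits),
    quadratic_fits = as.data.frame(quadratic_fits),
    bic_matrix = as.data.frame(bic_matrix),
    slope_comparisons = as.data.frame(slope_comparisons),
    composite_tangent_Ea_kJ = if (!is.null(composite)) composite$tangent_Ea_kJ else NULL,
    skip_reports = purrr::map(interval_obs, skip_report)
  )

  structure(
    list(
      config = config,
      interval_observations = interval_obs,
      interval_fits = interval_fits,
      fits = fits,
      quadratic_fits = quadratic_fits,
      bic_matrix = bic_matrix,
      slope_comparisons = slope_comparisons,
      composite = composite,
      rate_summaries = rate_summaries,
      manifest = manifest
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf(
    "Timing analysis (%s): %d interval fits, %d BIC comparisons, %d slope comparisons\n",
    x$config$organism, nrow(x$interval_fits), nrow(x$bic_matrix),
    nrow(x$slope_comparisons)
  ))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits flat CSV tables for each stage and a JSON manifest holding
#' every computed number. Writing the same report twice produces
#' byte-identical files.
#'
#' @param report an `analysis_report` from [run_full_analysis()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(tbl, name) {
    readr::write_csv(tbl, file.path(dir, paste0(name, ".csv")))
  }
  wr(report$interval_fits, "interval_fits")
  wr(report$quadratic_fits, "quadratic_fits")
  wr(report$bic_matrix, "bic_matrix")
  wr(report$slope_comparisons, "slope_comparisons")
  wr(report$rate_summaries, "rate_summaries")
  if (!is.null(report$composite)) {
    wr(report$composite$prediction, "composite_prediction")
  }
  jsonlite::write_json(
    report$manifest, file.path(dir, "manifest.json"),
    digits = NA, auto_unbox = TRUE, null = "null", pretty = TRUE
  )
  invisible(dir)
}
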