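#' Read a long-format developmental timing table
#'
#' Reads a CSV of scored developmental events, one row per event, with
#' columns `embryo_id`, `organism`, `temperature_C`, `score_code`,
#' `time_min`. Times are absolute video times in minutes; score codes are
#' case-sensitive single characters (letters for retained scores, digits
#' for candidate scores later dropped by reproducibility screening).
#'
#' @param path path to a CSV file.
#' @return A tibble with the five columns above.
#' @export
read_timing_table <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      embryo_id = readr::col_character(),
      organism = readr::col_character(),
      temperature_C = readr::col_double(),
      score_code = readr::col_character(),
      time_min = readr::col_double()
    )
  )
  required <- c("embryo_id", "organism", "temperature_C", "score_code", "time_min")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("timing table is missing columns: ", paste(missing, collapse = ", "))
  }
  tbl
}

#' Re-zero event times at an origin score
#'
#' Subtracts each embryo's time at `origin_code` from all of its scored
#' times, so that the origin event is exactly time zero and earlier events
#' carry negative times. Embryos that lack the origin score are dropped
#' and reported in the `skipped` attribute. Pairwise time differences
#' (interval durations) are unchanged, and re-zeroing is idempotent.
#'
#' @param events tibble of scored events (see [read_timing_table()]).
#' @param origin_code score code defining time zero (e.g. the last
#'   syncytial cleavage in fly, the third cleavage in frog).
#' @return The events tibble with `time_min` re-zeroed; attribute
#'   `skipped` holds a tibble of dropped embryos with a reason.
#' @export
relative_times <- function(events, origin_code) {
  stopifnot(is.data.frame(events), is.character(origin_code), length(origin_code) == 1)
  origin <- events |>
    dplyr::filter(.data$score_code == origin_code) |>
    dplyr::distinct(.data$embryo_id, .keep_all = TRUE) |>
    dplyr::select("embryo_id", origin_time = "time_min")
  dropped <- setdiff(unique(events$embryo_id), origin$embryo_id)
  out <- events |>
    dplyr::inner_join(origin, by = "embryo_id") |>
    dplyr::mutate(time_min = .data$time_min - .data$origin_time) |>
    dplyr::select(-"origin_time")
  attr(out, "skipped") <- tibble::tibble(
    embryo_id = dropped,
    reason = rep("missing origin score", length(dropped))
  )
  out
}

#' Per-embryo interval durations between two scores
#'
#' For every embryo that has both the start and end score, computes the
#' interval duration `time[end] - time[start]` in minutes and the
#' pseudo-reaction rate `1/duration` in min^-1. Embryos missing either
#' score are skipped; embryos whose recorded times violate developmental
#' order (non-positive duration) are rejected as scoring errors. Both are
#' counted in the `skip_report` attribute, never clamped.
#'
#' @param events tibble of scored events (see [read_timing_table()]).
#' @param start_code,end_code score codes delimiting the interval; the
#'   start must precede the end developmentally.
#' @return A tibble with one row per retained embryo: `embryo_id`,
#'   `organism`, `temperature_C`, `start_code`, `end_code`,
#'   `duration_min`, `rate_per_min`. Attribute `skip_report` is a list
#'   with counts and ids of skipped/rejected embryos.
#' @examples
#' ev <- tibble::tibble(
#'   embryo_id = "e1", organism = "fly", temperature_C = 25,
#'   score_code = c("A", "B"), time_min = c(0, 30)
#' )
#' compute_intervals(ev, "A", "B")
#' @export
compute_intervals <- function(events, start_code, end_code) {
  stopifnot(is.data.frame(events))
  if (identical(start_code, end_code)) stop("start and end scores must differ")
  wide <- events |>
    dplyr::filter(.data$score_code %in% c(start_code, end_code)) |>
    dplyr::distinct(.data$embryo_id, .data$score_code, .keep_all = TRUE) |>
    tidyr::pivot_wider(
      id_cols = c("embryo_id", "organism", "temperature_C"),
      names_from = "score_code", values_from = "time_min"
    )
  for (code in c(start_code, end_code)) {
    if (!code %in% names(wide)) wide[[code]] <- NA_real_
  }
  wide <- wide |>
    dplyr::mutate(duration_min = .data[[end_code]] - .data[[start_code]])

  missing_ids <- wide$embryo_id[is.na(wide$duration_min)]
  bad_ids <- wide$embryo_id[!is.na(wide$duration_min) & wide$duration_min <= 0]
  if (length(bad_ids) > 0) {
    warning(
      "rejected ", length(bad_ids),
      " embryo(s) with non-positive ", start_code, "-", end_code,
      " duration (scoring order violation): ",
      paste(utils::head(bad_ids, 5), collapse = ", ")
    )
  }
  out <- wide |>
    dplyr::filter(!is.na(.data$duration_min), .data$duration_min > 0) |>
    dplyr::transmute(
      .data$embryo_id, .data$organism, .data$temperature_C,
      start_code = start_code, end_code = end_code,
      duration_min = .data$duration_min,
      rate_per_min = 1 / .data$duration_min
    )
  attr(out, "skip_report") <- list(
    start_code = start_code, end_code = end_code,
    n_missing = length(missing_ids), missing_ids = missing_ids,
    n_rejected = length(bad_ids), rejected_ids = bad_ids
  )
  out
}

#' Skip/diagnostic report of an interval table
#'
#' @param intervals result of [compute_intervals()].
#' @return list with skip counts and embryo ids.
#' @export
skip_report <- function(intervals) {
  attr(intervals, "skip_report")
}

#' Mean coefficient of variation for every score pair
#'
#' For each ordered score pair and each temperature with at least two
#' replicate embryos, computes the coefficient of variation of the
#' interval duration (sample standard deviation over mean, as a
#' percentage), then averages the per-temperature CVs with equal weight.
#' Temperatures with a single replicate are skipped. This reproduces the
#' reproducibility screen used to choose which scored events to keep.
#'
#' @param events tibble of scored events.
#' @param scores character vector of candidate score codes in
#'   developmental order. Defaults to the codes present, in order of
#'   mean scored time.
#' @return A tibble with one row per ordered pair: `start_code`,
#'   `end_code`, `mean_cv_pct` (NA if no temperature qualifies),
#'   `n_temperatures`.
#' @export
cv_matrix <- function(events, scores = NULL) {
  stopifnot(is.data.frame(events))
  if (is.null(scores)) {
    scores <- events |>
      dplyr::group_by(.data$score_code) |>
      dplyr::summarise(m = mean(.data$time_min), .groups = "drop") |>
      dplyr::arrange(.data$m) |>
      dplyr::pull(.data$score_code)
  }
  pairs <- tidyr::expand_grid(
    i = seq_along(scores), j = seq_along(scores)
  ) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(start_code = scores[.data$i], end_code = scores[.data$j])

  cv_one <- function(start_code, end_code) {
    ivals <- suppressWarnings(compute_intervals(events, start_code, end_code))
    per_temp <- ivals |>
      dplyr::group_by(.data$temperature_C) |>
      dplyr::summarise(
        n = dplyr::n(),
        mu = mean(.data$duration_min),
        sdv = stats::sd(.data$duration_min),
        .groups = "drop"
      ) |>
      dplyr::filter(.data$n >= 2, .data$mu != 0)
    if (nrow(per_temp) == 0) {
      return(tibble::tibble(mean_cv_pct = NA_real_, n_temperatures = 0L))
    }
    tibble::tibble(
      mean_cv_pct = mean(per_temp$sdv / per_temp$mu * 100),
      n_temperatures = nrow(per_temp)
    )
  }
  pairs |>
    dplyr::mutate(cv = purrr::map2(.data$start_code, .data$end_code, cv_one)) |>
    tidyr::unnest("cv") |>
    dplyr::select("start_code", "end_code", "mean_cv_pct", "n_temperatures")
}

#' Select the most reproducibly scored events
#'
#' Iteratively removes the score whose adjacent-interval mean CV is
#' largest until `k` scores remain. At each step, a score's figure of
#' merit is the mean of the CVs of the intervals to its current left and
#' right neighbours (endpoints use their single adjacent interval);
#' adjacency is recomputed after every removal. Ties are broken by
#' developmental order: the earlier score is kept.
#'
#' @param cv_tbl long CV table from [cv_matrix()].
#' @param scores candidate score codes in developmental order.
#' @param k number of scores to retain.
#' @return Character vector of the `k` retained score codes, in
#'   developmental order.
#' @export
select_scores <- function(cv_tbl, scores, k) {
  stopifnot(is.data.frame(cv_tbl), k >= 1)
  if (k > length(scores)) stop("k exceeds the number of candidate scores")
  lookup <- function(a, b) {
    row <- cv_tbl[cv_tbl$start_code == a & cv_tbl$end_code == b, ]
    if (nrow(row) == 0 || is.na(row$mean_cv_pct[1])) NA_real_ else row$mean_cv_pct[1]
  }
  retained <- scores
  while (length(retained) > k) {
    merit <- vapply(seq_along(retained), function(idx) {
      nb <- c(
        if (idx > 1) lookup(retained[idx - 1], retained[idx]),
        if (idx < length(retained)) lookup(retained[idx], retained[idx + 1])
      )
      nb <- nb[!is.na(nb)]
      if (length(nb) == 0) Inf else mean(nb)
    }, numeric(1))
    # drop the worst; on ties keep the earlier score (drop the later one)
    worst <- max(merit)
    drop_idx <- max(which(merit == worst))
    retained <- retained[-drop_idx]
  }
  retained
}

#' Per-temperature summaries of interval rates
#'
#' Computes the per-embryo natural-log rate first, then its mean and
#' standard error across replicate embryos at each temperature. The
#' standard error is undefined (NA) for a single replicate.
#'
#' @param intervals result of [compute_intervals()] for one score pair.
#' @return A tibble with one row per temperature: `start_code`,
#'   `end_code`, `temperature_C`, `n`, `mean_ln_rate`, `se_ln_rate`,
#'   `mean_duration_min`.
#' @export
summarize_rates <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) > 0 &&
      dplyr::n_distinct(intervals$start_code, intervals$end_code) > 1) {
    stop("summarize_rates expects observations of a single score pair")
  }
  intervals |>
    dplyr::group_by(
      .data$start_code, .data$end_code, .data$temperature_C
    ) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ln_rate = mean(log(.data$rate_per_min)),
      se_ln_rate = ifelse(
        dplyr::n() >= 2,
        stats::sd(log(.data$rate_per_min)) / sqrt(dplyr::n()),
        NA_real_
      ),
      mean_duration_min = mean(.data$duration_min),
      .groups = "drop"
    )
}
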