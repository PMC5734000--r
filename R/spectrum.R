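## Per-center pathway spectra and outcome statistics: series cost,
## revascularization rate, 365-day mortality, direct standardization.

#' Aggregate classified series into pathway spectra
#'
#' Counts the 15 pathway types per group and stores them in canonical
#' column order. Ratios (the spectrum proper) are obtained with
#' [spectrum_matrix()]; keeping raw counts makes cluster pooling exact.
#'
#' @param classified Output of [classify_series()] (optionally with a
#'   grouping column such as `center_id`).
#' @param by Name of the grouping column; `NULL` aggregates everything into
#'   a single `"all"` row.
#' @return A tibble of class `careflow_spectra`: the grouping column,
#'   `n_series`, and one count column per pathway type in canonical order.
#' @export
#' @examples
#' cl <- tibble::tibble(center_id = "A",
#'                      series_type = c("E", "E", "NI", "I"))
#' compute_spectra(cl)
compute_spectra <- function(classified, by = "center_id") {
  if (is.null(by)) {
    classified$.scope <- "all"
    by <- ".scope"
  }
  stopifnot(by %in% names(classified), "series_type" %in% names(classified))
  bad <- setdiff(unique(classified$series_type), .SERIES_TYPES)
  if (length(bad) > 0) {
    stop("unknown series type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- classified |>
    dplyr::count(.data[[by]],
                 series_type = factor(.data$series_type, levels = .SERIES_TYPES),
                 .drop = FALSE, name = "n") |>
    tidyr::pivot_wider(names_from = "series_type", values_from = "n",
                       values_fill = 0L)
  out <- dplyr::mutate(out, n_series = rowSums(out[.SERIES_TYPES]),
                       .after = dplyr::all_of(by))
  if (by == ".scope") names(out)[1] <- "scope"
  empty <- out$n_series == 0
  if (any(empty)) {
    message(sum(empty), " group(s) with no classified series excluded from spectra")
    out <- out[!empty, , drop = FALSE]
  }
  class(out) <- c("careflow_spectra", class(out))
  out
}

#' Spectrum matrix of a `careflow_spectra` table
#'
#' @param spectra Output of [compute_spectra()].
#' @param what `"ratio"` (rows sum to 1) or `"count"`.
#' @return Numeric matrix, rows = groups (named), columns = the 15 pathway
#'   types in canonical order.
#' @export
spectrum_matrix <- function(spectra, what = c("ratio", "count")) {
  what <- match.arg(what)
  m <- as.matrix(spectra[.SERIES_TYPES])
  rownames(m) <- spectra[[1]]
  if (what == "ratio") m <- m / spectra$n_series
  m
}

#' Reimbursement cost of each event series
#'
#' Sums the tariff over all (post-merge) care events of a series; death
#' markers cost nothing.
#'
#' @param series_events Output of [extract_event_series()].
#' @param tariff Tariff tibble (`procedure`, `cost_huf`), see
#'   [default_tariff()].
#' @return A tibble `patient_id`, `series_idx`, `cost_huf`.
#' @export
#' @examples
#' # a single stress ECG costs its tariff entry
series_cost <- function(series_events, tariff = default_tariff()) {
  care <- series_events[series_events$death == 0L, , drop = FALSE]
  missing <- setdiff(unique(care$procedure), tariff$procedure)
  if (length(missing) > 0) {
    stop("no tariff entry for procedure(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cost <- setNames(tariff$cost_huf, tariff$procedure)
  series_events |>
    dplyr::group_by(.data$patient_id, .data$series_idx) |>
    dplyr::summarise(
      cost_huf = sum(cost[.data$procedure[.data$death == 0L]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(cost_huf = dplyr::coalesce(.data$cost_huf, 0))
}

#' Revascularization rate
#'
#' Among series containing at least one coronary angiography (CA), the
#' share in which a CA was followed by a revascularization (PCI or CABG) of
#' the same patient within `window_days` days. The follow-up may fall in a
#' later series of the same patient; a same-day revascularization counts as
#' following (canonical intra-day order places CA first). With no CA series
#' at all the rate is undefined and `NA` is returned with a message.
#'
#' @param series_events Output of [extract_event_series()] (whole
#'   population or one group's subset).
#' @param window_days Follow-up window in days.
#' @return A single proportion, or `NA_real_` if no series contains a CA.
#' @export
revascularization_rate <- function(series_events, window_days = 180) {
  ca <- series_events[series_events$procedure == "CA", , drop = FALSE]
  if (nrow(ca) == 0) {
    message("no series with coronary angiography; revascularization rate undefined")
    return(NA_real_)
  }
  rv <- series_events[series_events$procedure %in% c("PCI", "CABG"),
                      c("patient_id", "day"), drop = FALSE]
  names(rv)[2] <- "rv_day"
  hits <- dplyr::inner_join(
    ca[c("patient_id", "series_idx", "day")], rv,
    by = "patient_id", relationship = "many-to-many"
  )
  hits <- hits[hits$rv_day - hits$day >= 0 & hits$rv_day - hits$day <= window_days, ]
  num <- nrow(dplyr::distinct(hits, .data$patient_id, .data$series_idx))
  den <- nrow(dplyr::distinct(ca, .data$patient_id, .data$series_idx))
  num / den
}

#' Death day of each patient
#'
#' @param events Registry event tibble (death markers included).
#' @return A tibble `patient_id`, `death_day`.
#' @export
patient_deaths <- function(events) {
  d <- events[events$death == 1L, c("patient_id", "day"), drop = FALSE]
  names(d)[2] <- "death_day"
  tibble::as_tibble(d)
}

#' 365-day mortality of a set of series
#'
#' Share of series whose patient died within `window_days` days of the
#' series' index event.
#'
#' @param classified Output of [classify_series()].
#' @param deaths Output of [patient_deaths()] on the full registry (deaths
#'   may fall outside any series).
#' @param window_days Window in days after the index event.
#' @return A single proportion.
#' @export
mortality_365 <- function(classified, deaths, window_days = 365) {
  x <- dplyr::left_join(classified, deaths, by = "patient_id")
  died <- !is.na(x$death_day) &
    x$death_day - x$index_day >= 0 &
    x$death_day - x$index_day <= window_days
  mean(died)
}

#' Directly standardized rate
#'
#' Recomputes a crude rate as the weighted average of stratum-specific
#' rates under a fixed reference population's stratum distribution.
#'
#' @param stratum_rates Named numeric vector of per-stratum rates.
#' @param stratum_weights Named numeric vector of reference weights
#'   (must sum to 1); every weighted stratum needs a rate.
#' @return The standardized rate.
#' @export
#' @examples
#' direct_standardize(c(young = 0.1, old = 0.3), c(young = 0.5, old = 0.5))
direct_standardize <- function(stratum_rates, stratum_weights) {
  if (abs(sum(stratum_weights) - 1) > 1e-8) {
    stop("stratum weights must sum to 1", call. = FALSE)
  }
  need <- names(stratum_weights)[stratum_weights > 0]
  missing <- setdiff(need, names(stratum_rates))
  if (length(missing) > 0) {
    stop("no rate for stratum(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(stratum_weights[need] * stratum_rates[need])
}

#' Outcome summary per group
#'
#' Computes, per group of series (for example per center or per cluster),
#' the number of series, the revascularization rate, the 365-day mortality
#' and the average reimbursement cost per series.
#'
#' @param classified Output of [classify_series()], with the grouping
#'   column already attached (e.g. `center_id` via
#'   [assign_series_centers()]).
#' @param series_events Output of [extract_event_series()].
#' @param deaths Output of [patient_deaths()].
#' @param tariff Tariff tibble.
#' @param by Grouping column name in `classified`; `NULL` for a single
#'   pooled row.
#' @return A tibble `scope`, `n_series`, `revasc_rate`, `mort365`,
#'   `avg_cost_huf`.
#' @export
summarize_outcomes <- function(classified, series_events, deaths,
                               tariff = default_tariff(), by = "center_id") {
  costs <- series_cost(series_events, tariff)
  x <- classified |>
    dplyr::left_join(costs, by = c("patient_id", "series_idx"))
  if (is.null(by)) {
    x$.scope <- "all"
    by <- ".scope"
  }
  groups <- split(seq_len(nrow(x)), x[[by]])
  se_key <- paste(series_events$patient_id, series_events$series_idx)
  purrr::map_dfr(names(groups), function(g) {
    rows <- groups[[g]]
    keys <- paste(x$patient_id[rows], x$series_idx[rows])
    se_g <- series_events[se_key %in% keys, , drop = FALSE]
    tibble::tibble(
      scope = g,
      n_series = length(rows),
      revasc_rate = suppressMessages(revascularization_rate(se_g)),
      mort365 = mortality_365(x[rows, , drop = FALSE], deaths),
      avg_cost_huf = mean(x$cost_huf[rows])
    )
  })
}
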