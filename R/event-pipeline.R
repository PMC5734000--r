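## Event-list cleaning, phantom-event merging, gap-delimited series
## extraction and 15-way pathway classification.

#' Sort an event table canonically
#'
#' Events are ordered by patient, day, care category (E < NI < I, death
#' last) and procedure code. Same-day ties are therefore resolved
#' deterministically, which fixes the classification of series with
#' same-day events.
#'
#' @param events Registry event tibble.
#' @return The sorted tibble.
#' @export
arrange_timeline <- function(events) {
  cat_rank <- c(E = 1L, NI = 2L, I = 3L)
  r <- cat_rank[.event_category(events$procedure)]
  r[is.na(r)] <- 4L  # death sorts after same-day care events
  events[order(events$patient_id, events$day, r, events$procedure), , drop = FALSE]
}

#' Merge redundant (phantom) events
#'
#' Administrative claims often record one clinical act as several rows (for
#' example a two-day SPECT protocol). Any two same-procedure events of one
#' patient separated by at most the procedure's merge window are collapsed
#' into the earlier one, applied greedily left to right: the first event of
#' a run is kept and every same-procedure event within the window of the
#' last *kept* event is dropped.
#'
#' @param events Registry event tibble.
#' @param merge_windows Named numeric vector of per-procedure windows in
#'   days; procedures not named are never merged. Default merges SPECT rows
#'   up to 2 days apart.
#' @return The merged, canonically sorted tibble.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = "P1", day = c(10L, 11L), zip = "Z1", provider_id = "C1",
#'   procedure = "SPECT", death = 0L
#' )
#' merge_phantom_events(ev)
merge_phantom_events <- function(events, merge_windows = c(SPECT = 2)) {
  if (any(merge_windows < 0)) stop("merge windows must be >= 0", call. = FALSE)
  .validate_registry_cols(events)
  events <- arrange_timeline(events)
  if (nrow(events) == 0 || length(merge_windows) == 0) return(events)

  keep <- rep(TRUE, nrow(events))
  for (proc in names(merge_windows)) {
    w <- merge_windows[[proc]]
    if (w <= 0) next
    idx <- which(events$procedure == proc)
    if (length(idx) < 2) next
    for (grp in split(idx, events$patient_id[idx])) {
      last_kept <- -Inf
      for (i in grp) {
        if (events$day[i] - last_kept > w) {
          last_kept <- events$day[i]
        } else {
          keep[i] <- FALSE
        }
      }
    }
  }
  events[keep, , drop = FALSE]
}

#' Extract gap-delimited event series
#'
#' An event qualifies as an index event iff it is a care event (not a death
#' marker), no event of the same patient occurred in the preceding
#' `gap_days` days, and it falls at least `gap_days` days after observation
#' start (day `>= gap_days`), so the event-free run-in is verifiable. A
#' series runs from its index event until the next `> gap_days` event-free
#' stretch, a death event, or the end of observation; events before the
#' first index event are discarded.
#'
#' @param events Merged, validated registry event tibble.
#' @param gap_days Event-free gap (days) that delimits series.
#' @param observation_end Last day of the observation window; must be `>=`
#'   the latest event day.
#' @return A tibble of series member events: the input columns plus
#'   `category` (`NA` for death rows), `series_idx` (per patient, from 1),
#'   `index_day` and `terminated_by` (`"gap"`, `"death"` or
#'   `"end_of_observation"`).
#' @export
extract_event_series <- function(events, gap_days = 180, observation_end) {
  .validate_registry_cols(events)
  if (nrow(events) == 0) {
    return(dplyr::mutate(events, category = character(0), index_day = integer(0),
                         terminated_by = character(0), series_idx = integer(0)))
  }
  if (observation_end < max(events$day)) {
    stop("observation_end (", observation_end, ") is earlier than the latest ",
         "event day (", max(events$day), ")", call. = FALSE)
  }
  .validate_death_rows(events)
  events <- arrange_timeline(events)
  events$category <- .event_category(events$procedure)

  out <- events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      .gap_before = .data$day - dplyr::lag(.data$day),
      .block = cumsum(is.na(.data$.gap_before) | .data$.gap_before > .env$gap_days)
    ) |>
    dplyr::group_by(.data$patient_id, .data$.block) |>
    dplyr::mutate(
      .first_day = dplyr::first(.data$day),
      .index_ok = dplyr::first(.data$death) == 0L & .data$.first_day >= .env$gap_days,
      .has_death = any(.data$death == 1L)
    ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(.last_block = .data$.block == max(.data$.block)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.index_ok)
  if (nrow(out) == 0) {
    out <- dplyr::select(out, -dplyr::starts_with("."))
    return(dplyr::mutate(out, index_day = integer(0),
                         terminated_by = character(0), series_idx = integer(0)))
  }
  out <- out |>
    dplyr::mutate(index_day = as.integer(.data$.first_day)) |>
    dplyr::group_by(.data$patient_id, .data$.block) |>
    dplyr::mutate(terminated_by = dplyr::case_when(
      .data$.has_death ~ "death",
      !dplyr::first(.data$.last_block) ~ "gap",
      .env$observation_end - max(.data$day) > .env$gap_days ~ "gap",
      TRUE ~ "end_of_observation"
    )) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(series_idx = match(.data$.block, sort(unique(.data$.block)))) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::starts_with("."))
  out
}

.validate_death_rows <- function(events) {
  d <- events[events$death == 1L, , drop = FALSE]
  if (nrow(d) == 0) return(invisible(events))
  if (anyDuplicated(d$patient_id)) {
    stop("more than one death event for patient(s): ",
         paste(unique(d$patient_id[duplicated(d$patient_id)]), collapse = ", "),
         call. = FALSE)
  }
  last_care <- tapply(events$day[events$death == 0L],
                      events$patient_id[events$death == 0L], max)
  bad <- d$patient_id[d$day < last_care[d$patient_id] & !is.na(last_care[d$patient_id])]
  if (length(bad) > 0) {
    stop("death is not the last event for patient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(events)
}

#' Pathway label of a category sequence
#'
#' Low-level classifier: the label is the hyphen-join of the distinct care
#' categories in order of first occurrence. Repeats of an already-seen
#' category never alter the label.
#'
#' @param categories Character vector of per-event categories (`"E"`,
#'   `"NI"`, `"I"`; `NA` entries, e.g. death markers, are ignored).
#' @return A single pathway-type label.
#' @export
#' @examples
#' series_type_label(c("E", "NI", "I"))   # "E-NI-I"
#' series_type_label(c("E", "E", "I", "NI", "I"))  # "E-I-NI"
series_type_label <- function(categories) {
  categories <- categories[!is.na(categories)]
  bad <- setdiff(unique(categories), .CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown care category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(categories) == 0) {
    stop("cannot classify a series with no care events", call. = FALSE)
  }
  paste(unique(categories), collapse = "-")
}

#' Classify extracted event series
#'
#' Collapses the per-event output of [extract_event_series()] into one row
#' per series, labelled with its pathway type.
#'
#' @param series_events Output of [extract_event_series()].
#' @return A tibble with one row per series: `patient_id`, `series_idx`,
#'   `zip` (ZIP of the patient's first event), `index_day`, `series_type`,
#'   `terminated_by` and `n_events` (care events only).
#' @export
classify_series <- function(series_events) {
  stopifnot(all(c("patient_id", "series_idx", "category", "index_day",
                  "terminated_by") %in% names(series_events)))
  series_events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(.zip = dplyr::first(.data$zip)) |>
    dplyr::group_by(.data$patient_id, .data$series_idx) |>
    dplyr::summarise(
      zip = dplyr::first(.data$.zip),
      index_day = dplyr::first(.data$index_day),
      series_type = series_type_label(.data$category),
      terminated_by = dplyr::first(.data$terminated_by),
      n_events = sum(!is.na(.data$category)),
      .groups = "drop"
    )
}
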