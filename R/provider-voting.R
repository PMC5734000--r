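## Majority-vote attribution of a dominant de facto care center to each ZIP
## area, per care level (primary = E, secondary = NI, tertiary = I).

.LEVEL_CATEGORY <- c(primary = "E", secondary = "NI", tertiary = "I")

#' Map provider departments onto institutions
#'
#' Large institutions appear in claims data as many departments; votes and
#' all per-center statistics should treat them as one entity. Replaces
#' `provider_id` by its institution id; providers absent from the map keep
#' their own id (identity default).
#'
#' @param events Registry event tibble.
#' @param institution_map Named character vector (`provider -> institution`)
#'   or a two-column data frame `provider_id`, `institution_id`. `NULL`
#'   leaves the table unchanged.
#' @return The event tibble with mapped `provider_id`.
#' @export
aggregate_departments <- function(events, institution_map = NULL) {
  if (is.null(institution_map)) return(events)
  if (is.data.frame(institution_map)) {
    institution_map <- setNames(institution_map$institution_id,
                                institution_map$provider_id)
  }
  hit <- events$provider_id %in% names(institution_map)
  events$provider_id[hit] <- unname(institution_map[events$provider_id[hit]])
  events
}

#' Assign dominant de facto care centers to ZIP areas
#'
#' For the chosen care level, each resident patient contributes one vote for
#' the provider of their chronologically first event of that level's
#' category; a patient's ZIP is the ZIP of their first event overall. The
#' provider with the most votes in a ZIP wins; ties go to the
#' lexicographically smallest provider id. ZIP areas without any voting
#' patient are omitted (with a message).
#'
#' @param events Registry event tibble (canonical or not; sorted internally).
#' @param level `"primary"` (E events), `"secondary"` (NI) or `"tertiary"`
#'   (I).
#' @return A tibble with columns `zip`, `level`, `center_id`,
#'   `votes_for_winner`, `total_votes`.
#' @export
assign_dominant_centers <- function(events, level = c("primary", "secondary", "tertiary")) {
  level <- match.arg(level)
  target <- .LEVEL_CATEGORY[[level]]
  .validate_registry_cols(events)
  events <- arrange_timeline(events)
  events$category <- .event_category(events$procedure)

  patient_zip <- events |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::select("patient_id", "zip")

  votes <- events |>
    dplyr::filter(.data$category == .env$target) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::select("patient_id", vote = "provider_id") |>
    dplyr::left_join(patient_zip, by = "patient_id")

  no_vote <- setdiff(unique(events$zip), unique(votes$zip))
  if (length(no_vote) > 0) {
    message(length(no_vote), " ZIP area(s) had no ", level,
            "-level voters and were omitted: ",
            paste(utils::head(sort(no_vote), 5), collapse = ", "),
            if (length(no_vote) > 5) ", ..." else "")
  }

  votes |>
    dplyr::count(.data$zip, .data$vote, name = "n_votes") |>
    dplyr::group_by(.data$zip) |>
    dplyr::arrange(dplyr::desc(.data$n_votes), .data$vote, .by_group = TRUE) |>
    dplyr::summarise(
      level = .env$level,
      center_id = dplyr::first(.data$vote),
      votes_for_winner = dplyr::first(.data$n_votes),
      total_votes = sum(.data$n_votes),
      .groups = "drop"
    )
}

#' Attach each series to its ZIP's dominant center
#'
#' Series are attributed to the dominant center of the patient's ZIP (the
#' population-served view), not to the provider who performed the events.
#' Series from ZIP areas without an assigned center are dropped with a
#' message.
#'
#' @param classified Output of [classify_series()].
#' @param assignment Output of [assign_dominant_centers()].
#' @return `classified` with a `center_id` column.
#' @export
assign_series_centers <- function(classified, assignment) {
  out <- dplyr::left_join(classified,
                          dplyr::select(assignment, "zip", "center_id"),
                          by = "zip")
  n_drop <- sum(is.na(out$center_id))
  if (n_drop > 0) {
    message(n_drop, " series from unassigned ZIP area(s) dropped")
    out <- out[!is.na(out$center_id), , drop = FALSE]
  }
  out
}
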