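## Cluster characterization tables, pairwise percent differences with
## Fisher exact tests, and the machine-readable analysis report.

#' Pool percentages across clusters
#'
#' The whole-population percentage of a feature is the series-count-
#' weighted mean of the cluster percentages. This identity lets a pooled
#' column be recomputed from per-cluster columns and their `n`.
#'
#' @param values Numeric vector (one value per cluster) or a matrix with
#'   one column per cluster.
#' @param n Series counts per cluster.
#' @return The pooled value(s).
#' @export
#' @examples
#' pool_percentages(c(10.28, 6.04, 8.18), c(130327, 217514, 158246))
pool_percentages <- function(values, n) {
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(n))
    return(as.vector(values %*% n) / sum(n))
  }
  stopifnot(length(values) == length(n))
  sum(values * n) / sum(n)
}

#' Per-cluster characterization summary
#'
#' Pools member centers' series counts into per-cluster pathway-type
#' percentages (series-count-weighted, not unweighted means of center
#' ratios), appends outcome rates and average cost when outcome inputs are
#' supplied, the average intra-cluster correlation when a correlation
#' matrix is supplied, and always appends the pooled whole-population row.
#'
#' @param spectra A `careflow_spectra` table (per center).
#' @param partition A `careflow_partition` over the spectra's centers.
#' @param outcomes Optional per-cluster outcome tibble from
#'   [summarize_outcomes()] whose `scope` equals the cluster id as
#'   character (plus an optional pooled row with scope `"all"`).
#' @param corr Optional correlation matrix for intra-cluster averages.
#' @return A tibble of class `careflow_cluster_summary`: one row per
#'   cluster plus a `"pooled"` row; columns `cluster`, `n_series`, the 15
#'   pathway types (percent), and when available `revasc_rate_pct`,
#'   `mort365_pct`, `avg_cost_huf`, `intra_corr`.
#' @export
summarize_clusters <- function(spectra, partition, outcomes = NULL, corr = NULL) {
  memb <- partition$membership[spectra[[1]]]
  if (anyNA(memb)) stop("every center needs a cluster assignment", call. = FALSE)
  counts <- spectrum_matrix(spectra, "count")
  cls <- sort(unique(memb))
  rows <- lapply(cls, function(cl) {
    cnt <- colSums(counts[memb == cl, , drop = FALSE])
    if (sum(cnt) == 0) stop("cluster ", cl, " has no series", call. = FALSE)
    c(n_series = sum(cnt), 100 * cnt / sum(cnt))
  })
  pooled <- colSums(counts)
  rows <- c(rows, list(c(n_series = sum(pooled), 100 * pooled / sum(pooled))))
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    tibble::tibble(cluster = c(as.character(cls), "pooled")), out
  )
  if (!is.null(outcomes)) {
    oc <- dplyr::mutate(outcomes,
                        cluster = ifelse(.data$scope == "all", "pooled", .data$scope))
    out <- dplyr::left_join(
      out,
      dplyr::transmute(oc, cluster = .data$cluster,
                       revasc_rate_pct = 100 * .data$revasc_rate,
                       mort365_pct = 100 * .data$mort365,
                       avg_cost_huf = .data$avg_cost_huf),
      by = "cluster"
    )
  }
  if (!is.null(corr)) {
    cs <- cluster_correlation_summary(corr, partition)
    intra <- setNames(cs$mean_correlation[cs$type == "intra"],
                      as.character(cs$cluster_a[cs$type == "intra"]))
    out$intra_corr <- intra[out$cluster]
  }
  class(out) <- c("careflow_cluster_summary", class(out))
  out
}

#' Percent difference of two rates
#'
#' `100 * (a - b) / b`, the relative difference of `a` against reference
#' `b`. Swapping the pair changes the reference:
#' `(1 + pd(a,b)/100) * (1 + pd(b,a)/100) = 1`.
#'
#' @param a,b Numeric vectors; `b` is the reference.
#' @return Percent differences; `NA` (with a warning) where `b == 0`.
#' @export
#' @examples
#' percent_difference(54182, 66953)  # -19.07...
percent_difference <- function(a, b) {
  out <- 100 * (a - b) / b
  if (any(b == 0, na.rm = TRUE)) {
    warning("percent difference undefined for zero reference", call. = FALSE)
    out[b == 0] <- NA_real_
  }
  out
}

#' Two-sided Fisher exact test on two proportions
#'
#' Exact two-sided p-value for the 2x2 table
#' `[[count_a, n_a - count_a], [count_b, n_b - count_b]]`. Vectorized over
#' its arguments.
#'
#' @param count_a,n_a Successes and total in group a.
#' @param count_b,n_b Successes and total in group b.
#' @return Numeric vector of p-values.
#' @export
#' @examples
#' exact_test(5, 10, 5, 10)  # identical proportions -> 1
exact_test <- function(count_a, n_a, count_b, n_b) {
  mapply(function(xa, na, xb, nb) {
    stopifnot(xa <= na, xb <= nb)
    fisher.test(matrix(c(xa, na - xa, xb, nb - xb), nrow = 2, byrow = TRUE))$p.value
  }, count_a, n_a, count_b, n_b)
}

#' Pairwise cluster comparisons
#'
#' For every unordered cluster pair and every feature (the 15 pathway-type
#' shares, the revascularization rate, the 365-day mortality, the average
#' cost), the percent difference of the first cluster against the second,
#' with a two-sided Fisher exact p-value on the underlying 2x2 counts
#' (each type versus all other series; revascularized versus other
#' CA series; died versus survived). Cost is a per-series average with no
#' natural 2x2 table, so its p-value is `NA`.
#'
#' @param spectra A `careflow_spectra` table.
#' @param partition A `careflow_partition`.
#' @param outcomes Optional per-cluster [summarize_outcomes()] tibble (adds
#'   the outcome rows). Needs `n_series`, `revasc_rate`, `mort365`,
#'   `avg_cost_huf` and, for the revascularization test, `n_ca` (number of
#'   CA series) if present.
#' @return A tibble `feature`, `cluster_a`, `cluster_b`, `value_a`,
#'   `value_b`, `percent_difference`, `p_value`.
#' @export
compare_clusters <- function(spectra, partition, outcomes = NULL) {
  memb <- partition$membership[spectra[[1]]]
  counts <- spectrum_matrix(spectra, "count")
  cls <- sort(unique(memb))
  ccount <- t(vapply(cls, function(cl) colSums(counts[memb == cl, , drop = FALSE]),
                     numeric(ncol(counts))))
  ntot <- rowSums(ccount)
  if (length(cls) < 2) {
    return(tibble::tibble(feature = character(0), cluster_a = character(0),
                          cluster_b = character(0), value_a = numeric(0),
                          value_b = numeric(0), percent_difference = numeric(0),
                          p_value = numeric(0)))
  }
  pairs <- utils::combn(seq_along(cls), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    ia <- pairs[1, j]; ib <- pairs[2, j]
    pct_a <- unname(100 * ccount[ia, ] / ntot[ia])
    pct_b <- unname(100 * ccount[ib, ] / ntot[ib])
    res <- tibble::tibble(
      feature = colnames(counts),
      cluster_a = as.character(cls[ia]),
      cluster_b = as.character(cls[ib]),
      value_a = pct_a,
      value_b = pct_b,
      # types absent from the reference cluster have no defined difference
      percent_difference = suppressWarnings(percent_difference(pct_a, pct_b)),
      p_value = unname(exact_test(ccount[ia, ], ntot[ia], ccount[ib, ], ntot[ib]))
    )
    if (!is.null(outcomes)) {
      oa <- outcomes[outcomes$scope == as.character(cls[ia]), ]
      ob <- outcomes[outcomes$scope == as.character(cls[ib]), ]
      if (nrow(oa) == 1 && nrow(ob) == 1) {
        mort <- tibble::tibble(
          feature = "mort365_pct",
          cluster_a = as.character(cls[ia]), cluster_b = as.character(cls[ib]),
          value_a = 100 * oa$mort365, value_b = 100 * ob$mort365,
          percent_difference = percent_difference(100 * oa$mort365, 100 * ob$mort365),
          p_value = exact_test(round(oa$mort365 * oa$n_series), oa$n_series,
                               round(ob$mort365 * ob$n_series), ob$n_series)
        )
        rv <- tibble::tibble(
          feature = "revasc_rate_pct",
          cluster_a = as.character(cls[ia]), cluster_b = as.character(cls[ib]),
          value_a = 100 * oa$revasc_rate, value_b = 100 * ob$revasc_rate,
          percent_difference = percent_difference(100 * oa$revasc_rate,
                                                  100 * ob$revasc_rate),
          p_value = if (!is.null(oa$n_ca) && !is.na(oa$revasc_rate) &&
                        !is.na(ob$revasc_rate)) {
            exact_test(round(oa$revasc_rate * oa$n_ca), oa$n_ca,
                       round(ob$revasc_rate * ob$n_ca), ob$n_ca)
          } else NA_real_
        )
        cost <- tibble::tibble(
          feature = "avg_cost_huf",
          cluster_a = as.character(cls[ia]), cluster_b = as.character(cls[ib]),
          value_a = oa$avg_cost_huf, value_b = ob$avg_cost_huf,
          percent_difference = percent_difference(oa$avg_cost_huf, ob$avg_cost_huf),
          p_value = NA_real_
        )
        res <- dplyr::bind_rows(res, rv, mort, cost)
      }
    }
    res
  })
  out
}

#' Run the full pathway-mining pipeline
#'
#' Convenience wrapper chaining every stage: phantom-event merging, series
#' extraction and classification, primary-center voting, per-center
#' spectra, the correlation network, Louvain clustering (hierarchical to
#' `max_depth`), centralities, outcome summaries and cluster
#' characterization.
#'
#' @param events Registry event tibble.
#' @param gap_days Series-delimiting event-free gap (days).
#' @param observation_end Last observation day (default: latest event day).
#' @param merge_windows Per-procedure phantom-merge windows.
#' @param tariff Tariff tibble.
#' @param offset Correlation-to-weight offset (see [build_network()]).
#' @param n_random_starts,n_iterations,seed Louvain parameters.
#' @param max_depth Hierarchical clustering depth.
#' @return A list of class `careflow_analysis` with components `classified`,
#'   `series_events`, `assignment`, `spectra`, `corr`, `network`,
#'   `partition`, `hierarchy`, `outcomes`, `cluster_summary`, `pairwise`,
#'   `correlation_summary`, `centrality`, `parameters`.
#' @export
run_pipeline <- function(events, gap_days = 180, observation_end = NULL,
                         merge_windows = c(SPECT = 2),
                         tariff = default_tariff(), offset = 2,
                         n_random_starts = 10, n_iterations = 10, seed = 1,
                         max_depth = 3) {
  if (is.null(observation_end)) observation_end <- max(events$day)
  merged <- merge_phantom_events(events, merge_windows)
  series_events <- extract_event_series(merged, gap_days, observation_end)
  classified <- classify_series(series_events)
  assignment <- assign_dominant_centers(merged, "primary")
  classified <- assign_series_centers(classified, assignment)
  # restrict events to attributed series for the outcome computations
  keys <- paste(classified$patient_id, classified$series_idx)
  series_events <- series_events[
    paste(series_events$patient_id, series_events$series_idx) %in% keys, ]
  spectra <- compute_spectra(classified, by = "center_id")
  corr <- correlation_matrix(spectra)
  network <- build_network(corr, offset = offset)
  partition <- louvain_cluster(network, n_random_starts, n_iterations, seed)
  hierarchy <- hierarchical_cluster(network, partition, max_depth,
                                    n_random_starts, n_iterations, seed)
  deaths <- patient_deaths(events)
  cluster_of <- partition$membership
  classified$cluster <- as.character(cluster_of[classified$center_id])
  outcomes <- summarize_outcomes(classified, series_events, deaths, tariff,
                                 by = "cluster")
  outcomes <- dplyr::bind_rows(
    outcomes,
    summarize_outcomes(classified, series_events, deaths, tariff, by = NULL)
  )
  n_ca <- classified |>
    dplyr::left_join(
      series_events |>
        dplyr::filter(.data$procedure == "CA") |>
        dplyr::distinct(.data$patient_id, .data$series_idx) |>
        dplyr::mutate(has_ca = TRUE),
      by = c("patient_id", "series_idx")
    ) |>
    dplyr::group_by(scope = .data$cluster) |>
    dplyr::summarise(n_ca = sum(!is.na(.data$has_ca)), .groups = "drop")
  outcomes <- dplyr::left_join(outcomes, n_ca, by = "scope")
  cluster_summary <- summarize_clusters(spectra, partition, outcomes, corr)
  pairwise <- compare_clusters(spectra, partition, outcomes)
  correlation_summary <- cluster_correlation_summary(corr, partition)
  centrality <- centralities(network, partition)
  structure(list(
    classified = classified,
    series_events = series_events,
    assignment = assignment,
    spectra = spectra,
    corr = corr,
    network = network,
    partition = partition,
    hierarchy = hierarchy,
    outcomes = outcomes,
    cluster_summary = cluster_summary,
    pairwise = pairwise,
    correlation_summary = correlation_summary,
    centrality = centrality,
    parameters = list(gap_days = gap_days, observation_end = observation_end,
                      offset = offset, n_random_starts = n_random_starts,
                      n_iterations = n_iterations, seed = seed,
                      max_depth = max_depth)
  ), class = "careflow_analysis")
}

#' @export
print.careflow_analysis <- function(x, ...) {
  cat("<careflow analysis>\n")
  cat(sprintf("  %d series across %d centers; %d clusters, Q = %.4f\n",
              nrow(x$classified), nrow(x$spectra),
              x$partition$n_communities, x$partition$Q))
  invisible(x)
}

#' Write the analysis report bundle
#'
#' One versioned JSON report (cluster summaries, pairwise comparisons,
#' modularity, correlation summaries, centrality percentiles, parameter
#' echo) plus CSV twins of the characterization and comparison tables.
#' Rerunning the same analysis writes byte-identical files.
#'
#' @param analysis A `careflow_analysis` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "careflow_analysis"))
  required <- c("cluster_summary", "pairwise", "partition",
                "correlation_summary", "centrality")
  missing <- required[vapply(required, function(f) is.null(analysis[[f]]), logical(1))]
  if (length(missing) > 0) {
    stop("analysis is missing stage(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    schema_version = "1.0",
    parameters = analysis$parameters,
    modularity = analysis$partition$Q,
    n_clusters = analysis$partition$n_communities,
    cluster_summary = analysis$cluster_summary,
    pairwise_comparisons = analysis$pairwise,
    correlation_summary = analysis$correlation_summary,
    centrality = analysis$centrality
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  summary_path <- file.path(dir, "cluster_summary.csv")
  readr::write_csv(analysis$cluster_summary, summary_path)
  pairwise_path <- file.path(dir, "pairwise_comparisons.csv")
  readr::write_csv(analysis$pairwise, pairwise_path)
  invisible(c(json_path, summary_path, pairwise_path))
}
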