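## broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a community partition
#'
#' @param x A `careflow_partition`.
#' @param ... Unused.
#' @return A tibble with one row per node: `center_id`, `community`.
#' @export
tidy.careflow_partition <- function(x, ...) {
  tibble::tibble(center_id = names(x$membership),
                 community = unname(x$membership))
}

#' One-row summary of a community partition
#'
#' @param x A `careflow_partition`.
#' @param ... Unused.
#' @return A tibble with columns `Q`, `n_communities`, `n_nodes`, `level`.
#' @export
glance.careflow_partition <- function(x, ...) {
  tibble::tibble(Q = x$Q, n_communities = x$n_communities,
                 n_nodes = length(x$membership), level = x$level)
}

#' One-row summary of a full analysis
#'
#' @param x A `careflow_analysis`.
#' @param ... Unused.
#' @return A tibble with the analysis' headline numbers.
#' @export
glance.careflow_analysis <- function(x, ...) {
  pooled <- x$outcomes[x$outcomes$scope == "all", ]
  tibble::tibble(
    n_series = nrow(x$classified),
    n_centers = nrow(x$spectra),
    n_clusters = x$partition$n_communities,
    Q = x$partition$Q,
    revasc_rate = pooled$revasc_rate,
    mort365 = pooled$mort365,
    avg_cost_huf = pooled$avg_cost_huf
  )
}
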