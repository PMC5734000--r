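## Node-importance measures ("opinion leaders") and intra/inter-cluster
## correlation summaries.

.as_igraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Degree and betweenness centralities
#'
#' Weighted degree (sum of incident edge weights) and shortest-path
#' betweenness for every node, on the whole network and on each cluster's
#' induced subnetwork, with percentile ranks per scope. Strong correlation
#' means proximity, so betweenness uses edge lengths `1/w` by default
#' (`edge_length = "unit"` treats every edge as length 1). Betweenness is
#' unnormalized: the number of shortest paths through the node, each
#' unordered pair counted once.
#'
#' @param network A `careflow_network`.
#' @param partition Optional `careflow_partition`; adds per-cluster scopes.
#' @param edge_length `"inverse"` (length `1/w`) or `"unit"`.
#' @return A tibble `scope` (`"network"` or `cluster_<id>`), `center_id`,
#'   `degree`, `betweenness`, `degree_percentile`, `betweenness_percentile`
#'   (percent ranks in `[0, 100]`, 100 = top).
#' @export
centralities <- function(network, partition = NULL,
                         edge_length = c("inverse", "unit")) {
  edge_length <- match.arg(edge_length)
  scopes <- list(network = seq_along(network$nodes))
  if (!is.null(partition)) {
    memb <- partition$membership[network$nodes]
    for (cl in sort(unique(memb))) {
      scopes[[paste0("cluster_", cl)]] <- which(memb == cl)
    }
  }
  purrr::map_dfr(names(scopes), function(sc) {
    idx <- scopes[[sc]]
    W <- network$weights[idx, idx, drop = FALSE]
    g <- .as_igraph(as_careflow_network(W))
    len <- if (edge_length == "inverse") 1 / igraph::E(g)$weight else rep(1, igraph::ecount(g))
    btw <- igraph::betweenness(g, weights = len, normalized = FALSE)
    deg <- rowSums(W)
    tibble::tibble(
      scope = sc,
      center_id = network$nodes[idx],
      degree = unname(deg),
      betweenness = unname(btw),
      degree_percentile = 100 * dplyr::percent_rank(deg),
      betweenness_percentile = 100 * dplyr::percent_rank(btw)
    )
  })
}

#' Intra- and inter-cluster correlation averages
#'
#' Simple averages of the pairwise Pearson coefficients: within each
#' cluster (over unordered pairs of distinct members) and between each
#' cluster pair (over all cross pairs). Diagonal self-correlations are
#' never included. Intra averages of singleton clusters are undefined
#' (`NA`, flagged with a message).
#'
#' @param corr Correlation matrix.
#' @param partition A `careflow_partition` (or named membership vector).
#' @return A tibble `cluster_a`, `cluster_b` (`a == b` rows are
#'   intra-cluster), `type`, `mean_correlation`, `n_pairs`.
#' @export
cluster_correlation_summary <- function(corr, partition) {
  memb <- if (inherits(partition, "careflow_partition")) partition$membership else partition
  memb <- memb[rownames(corr)]
  stopifnot(!anyNA(memb))
  cls <- sort(unique(memb))
  out <- purrr::map_dfr(seq_along(cls), function(ia) {
    purrr::map_dfr(seq(ia, length(cls)), function(ib) {
      a <- cls[ia]; b <- cls[ib]
      ra <- which(memb == a); rb <- which(memb == b)
      if (a == b) {
        n_pairs <- length(ra) * (length(ra) - 1) / 2
        vals <- corr[ra, ra, drop = FALSE][upper.tri(corr[ra, ra, drop = FALSE])]
      } else {
        n_pairs <- length(ra) * length(rb)
        vals <- as.vector(corr[ra, rb, drop = FALSE])
      }
      tibble::tibble(
        cluster_a = a, cluster_b = b,
        type = if (a == b) "intra" else "inter",
        mean_correlation = if (n_pairs == 0) NA_real_ else mean(vals),
        n_pairs = n_pairs
      )
    })
  })
  if (any(out$type == "intra" & out$n_pairs == 0)) {
    message("singleton cluster(s): intra-cluster average undefined")
  }
  out
}

#' Cluster-blocked ordering of centers for heat maps
#'
#' Orders centers so that members of one cluster are contiguous; within a
#' cluster, centers are sorted by decreasing average correlation with
#' their cluster mates (most typical members first). Invariant to the
#' input row order.
#'
#' @param corr Correlation matrix.
#' @param partition A `careflow_partition` (or named membership vector).
#' @return Character vector: the center ids in display order.
#' @export
heatmap_order <- function(corr, partition) {
  memb <- if (inherits(partition, "careflow_partition")) partition$membership else partition
  memb <- memb[rownames(corr)]
  within_mean <- vapply(seq_along(memb), function(i) {
    mates <- setdiff(which(memb == memb[i]), i)
    if (length(mates) == 0) return(NA_real_)
    mean(corr[i, mates])
  }, numeric(1))
  rownames(corr)[order(memb, -within_mean, rownames(corr), na.last = TRUE)]
}
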