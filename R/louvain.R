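## Native modularity computation and Louvain community detection with
## seeded random restarts, an iteration cap on local-moving passes, and
## deterministic tie-breaking; hierarchical re-clustering of the induced
## subnetworks up to depth 3.

#' Modularity of a partition
#'
#' Evaluates
#' \deqn{Q = \frac{1}{2m}\sum_{i,j}\left(A_{ij} -
#'   \frac{k_i k_j}{2m}\right)\delta(c_i, c_j)}
#' with \eqn{A_{ij}} the edge weights, \eqn{k_i = \sum_j A_{ij}} and
#' \eqn{m = \frac{1}{2}\sum_{ij} A_{ij}}. `Q` lies in `[-1, 1]`; the
#' all-in-one partition has `Q = 0` exactly.
#'
#' @param network A `careflow_network`.
#' @param membership Integer/character vector of community ids, one per
#'   node (named vectors are matched by node name), or a
#'   `careflow_partition`.
#' @return Modularity value.
#' @export
modularity_q <- function(network, membership) {
  stopifnot(inherits(network, "careflow_network"))
  if (inherits(membership, "careflow_partition")) membership <- membership$membership
  if (!is.null(names(membership))) membership <- membership[network$nodes]
  stopifnot(length(membership) == length(network$nodes))
  .modularity(network$weights, as.integer(factor(membership)))
}

# A may carry self-loops (aggregated graphs); A_ii counts once in sum(A)
.modularity <- function(A, memb) {
  m2 <- sum(A)
  if (m2 == 0) return(0)
  # all-in-one community: sum_ij (A_ij - k_i k_j / 2m) telescopes to 0 exactly
  if (length(unique(memb)) == 1) return(0)
  k <- rowSums(A)
  Kc <- rowsum(k, memb)
  tm <- rowsum(A, memb)          # communities x nodes
  Wc <- diag(as.matrix(rowsum(t(tm), memb)))
  sum(Wc) / m2 - sum((Kc / m2)^2)
}

# one local-moving phase: up to max_pass sweeps in shuffled node order;
# a node moves to the community with maximal gain if strictly better than
# staying, ties broken by smallest community id
.local_moving <- function(A, max_pass, init = NULL) {
  n <- nrow(A)
  memb <- if (is.null(init)) seq_len(n) else as.integer(factor(init))
  k <- rowSums(A)
  m2 <- sum(A)
  if (m2 == 0) return(memb)
  Ktot <- numeric(n)  # total degree per community id
  agg <- rowsum(k, memb)
  Ktot[as.integer(rownames(agg))] <- agg[, 1]
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (i in sample.int(n)) {
      a <- memb[i]
      v <- A[i, ]
      v[i] <- 0
      lc <- rowsum(v, memb)          # link weight from i to each community
      comm_ids <- as.integer(rownames(lc))
      o <- order(comm_ids)           # rowsum orders labels as characters
      comm_ids <- comm_ids[o]
      lw <- lc[o, 1]
      Ktot[a] <- Ktot[a] - k[i]
      gain <- lw - k[i] * Ktot[comm_ids] / m2
      best <- max(gain)
      target <- comm_ids[gain == best][1]  # smallest community id on ties
      cur <- gain[match(a, comm_ids)]
      if (best > cur && target != a) {
        memb[i] <- target
        moved <- TRUE
      }
      Ktot[memb[i]] <- Ktot[memb[i]] + k[i]
    }
    if (!moved) break
  }
  memb
}

.aggregate_graph <- function(A, memb) {
  t <- rowsum(A, memb)
  rowsum(t(t), memb)
}

# full multi-level run; the outer loop restarts node-level moving from the
# found partition (iterated refinement) until modularity stops improving
.louvain_once <- function(A, max_pass) {
  memb_global <- seq_len(nrow(A))
  repeat {
    q_before <- .modularity(A, memb_global)
    memb <- as.integer(factor(.local_moving(A, max_pass, init = memb_global)))
    glob <- memb
    Acur <- .aggregate_graph(A, memb)
    repeat {
      m2 <- as.integer(factor(.local_moving(Acur, max_pass)))
      if (max(m2) == nrow(Acur)) break   # nothing merged
      glob <- m2[glob]
      Acur <- .aggregate_graph(Acur, m2)
    }
    if (.modularity(A, glob) <= q_before + 1e-12) break
    memb_global <- glob
  }
  as.integer(factor(memb_global))
}

#' Louvain community detection
#'
#' Greedy modularity optimization: repeated local node moves to the
#' community with maximal positive modularity gain, followed by community
#' aggregation, until no improvement. Restarted `n_random_starts` times
#' with seeds `seed, seed + 1, ...` (node visit order is shuffled per
#' start); the partition with the highest modularity is returned, so its
#' `Q` is at least that of every intermediate partition of the winning
#' run. Deterministic given `seed`.
#'
#' @param network A `careflow_network` with positive edge weights (apply
#'   the [build_network()] transform first; negative weights are an error).
#' @param n_random_starts Number of seeded restarts.
#' @param n_iterations Cap on local-moving sweeps per aggregation level.
#' @param seed Base RNG seed.
#' @return An object of class `careflow_partition`: list with `membership`
#'   (named integer vector, community ids contiguous from 1), `Q`,
#'   `n_communities`, `level`, `seed`.
#' @export
louvain_cluster <- function(network, n_random_starts = 10, n_iterations = 10,
                            seed = 1) {
  stopifnot(inherits(network, "careflow_network"))
  A <- network$weights
  if (any(A < 0)) {
    stop("edge weights must be positive; apply the correlation transform first",
         call. = FALSE)
  }
  best <- NULL
  best_q <- -Inf
  for (s in seq_len(n_random_starts)) {
    memb <- withr::with_seed(seed + s - 1L, .louvain_once(A, n_iterations))
    q <- .modularity(A, memb)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  # canonical labels: communities numbered by first appearance
  best <- match(best, unique(best))
  structure(list(
    membership = setNames(as.integer(best), network$nodes),
    Q = best_q,
    n_communities = length(unique(best)),
    level = 1L,
    seed = as.integer(seed)
  ), class = "careflow_partition")
}

#' @export
print.careflow_partition <- function(x, ...) {
  cat(sprintf("<careflow partition: %d nodes, %d communities, Q = %.4f (level %d)>\n",
              length(x$membership), x$n_communities, x$Q, x$level))
  invisible(x)
}

#' Hierarchical (multi-level) Louvain clustering
#'
#' Re-runs Louvain on the induced subnetwork of every community (edge
#' weights retained) to produce second-level communities, and once more
#' inside those for the third level. Depth is capped at 3. Singleton
#' communities are returned unchanged.
#'
#' @param network A `careflow_network`.
#' @param partition Optional level-1 `careflow_partition` (computed if
#'   missing).
#' @param max_depth Hierarchy depth, 1 to 3.
#' @inheritParams louvain_cluster
#' @return A tibble of class `careflow_hierarchy` with columns `center_id`
#'   and `level1` ... `level<max_depth>`; labels are nested paths
#'   (`"2"`, `"2.1"`, `"2.1.3"`).
#' @export
hierarchical_cluster <- function(network, partition = NULL, max_depth = 3,
                                 n_random_starts = 10, n_iterations = 10,
                                 seed = 1) {
  stopifnot(inherits(network, "careflow_network"), max_depth >= 1, max_depth <= 3)
  if (is.null(partition)) {
    partition <- louvain_cluster(network, n_random_starts, n_iterations, seed)
  }
  labels <- matrix(NA_character_, nrow = length(network$nodes), ncol = max_depth,
                   dimnames = list(network$nodes, paste0("level", seq_len(max_depth))))
  labels[, 1] <- as.character(partition$membership[network$nodes])
  if (max_depth > 1) {
    for (lev in 2:max_depth) {
      parents <- unique(labels[, lev - 1])
      for (p in sort(parents)) {
        members <- which(labels[, lev - 1] == p)
        if (length(members) == 1) {
          labels[members, lev] <- paste0(p, ".1")
          next
        }
        sub <- as_careflow_network(
          network$weights[members, members, drop = FALSE]
        )
        subp <- louvain_cluster(sub, n_random_starts, n_iterations, seed)
        labels[members, lev] <- paste0(p, ".", subp$membership[sub$nodes])
      }
    }
  }
  out <- tibble::as_tibble(labels)
  out <- dplyr::bind_cols(tibble::tibble(center_id = network$nodes), out)
  class(out) <- c("careflow_hierarchy", class(out))
  attr(out, "Q_level1") <- partition$Q
  out
}
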