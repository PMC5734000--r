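# shared fixtures and independent oracles

make_events <- function(days, procedures, patient_id = "P1", zip = "Z0001",
                        provider_id = "C001", death_day = NULL) {
  ev <- tibble::tibble(
    patient_id = patient_id,
    day = as.integer(days),
    zip = zip,
    provider_id = provider_id,
    procedure = procedures,
    death = 0L
  )
  if (!is.null(death_day)) {
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      patient_id = patient_id[1], day = as.integer(death_day), zip = zip[1],
      provider_id = provider_id[1], procedure = "DEATH", death = 1L
    ))
  }
  ev
}

# every set partition of n elements, as restricted growth strings
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(rgs, mx) {
    if (length(rgs) == n) {
      out[[length(out) + 1]] <<- rgs
      return(invisible())
    }
    for (v in 1:(mx + 1)) rec(c(rgs, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

# exhaustive maximum modularity over all set partitions (oracle)
brute_max_modularity <- function(net) {
  qs <- vapply(all_set_partitions(length(net$nodes)),
               function(m) modularity_q(net, m), numeric(1))
  max(qs)
}

# two-sided Fisher exact p by hypergeometric enumeration (oracle);
# sums P(table) over tables with fixed margins whose probability does not
# exceed the observed one (standard two-sided convention, with the usual
# relative guard against floating-point ties)
fisher_brute <- function(xa, na, xb, nb) {
  c1 <- xa + xb
  support <- max(0, c1 - nb):min(na, c1)
  probs <- stats::dhyper(support, na, nb, c1)
  p_obs <- stats::dhyper(xa, na, nb, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random center spectra -> complete correlation network (the graph family
# this package clusters)
random_corr_network <- function(n) {
  X <- matrix(stats::rgamma(n * 15, shape = 0.5), n, 15)
  X <- X / rowSums(X)
  build_network(correlation_matrix(X))
}

# hand-built three-block weight matrix with two-level structure:
# block A (4 nodes) vs blocks B1+B2 (4+4) at level 1, B splitting at level 2
two_level_fixture <- function() {
  n <- 12
  W <- matrix(1, n, n)           # A-B cross weight
  blocks <- list(A = 1:4, B1 = 5:8, B2 = 9:12)
  for (b in blocks) W[b, b] <- 3
  W[blocks$B1, blocks$B2] <- 2
  W[blocks$B2, blocks$B1] <- 2
  diag(W) <- 0
  dimnames(W) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  list(net = as_careflow_network(W),
       level1 = rep(c(1, 2, 2), each = 4),
       level2 = rep(c(1, 2, 3), each = 4))
}
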