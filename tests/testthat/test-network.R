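test_that("the raw-sums and covariance correlation forms agree", {
  withr::with_seed(3, {
    for (rep in 1:30) {
      x <- runif(15)
      y <- runif(15)
      r1 <- pearson_correlation(x, y)
      # oracle: covariance form
      r2 <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(r1, r2, tolerance = 1e-12)
      expect_equal(r1, stats::cor(x, y), tolerance = 1e-12)
    }
  })
})

test_that("correlation endpoints and degeneracies behave", {
  x <- c(0.5, 0.25, 0.25, rep(0, 12))
  expect_equal(pearson_correlation(x, x), 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -3 * x + 2), -1, tolerance = 1e-12)
  y <- c(0.25, 0.5, 0.25, rep(0, 12))
  expect_equal(pearson_correlation(x, y), stats::cor(x, y), tolerance = 1e-12)
  expect_warning(r <- pearson_correlation(rep(1, 15), x), "constant")
  expect_true(is.na(r))
})

test_that("the correlation matrix is symmetric with unit diagonal", {
  withr::with_seed(5, {
    X <- matrix(rgamma(8 * 15, 0.7), 8, 15)
    X <- X / rowSums(X)
    rownames(X) <- sprintf("C%02d", 1:8)
    C <- correlation_matrix(X)
    expect_equal(C, t(C), tolerance = 1e-12)
    expect_equal(unname(diag(C)), rep(1, 8))
    expect_true(all(abs(C) <= 1 + 1e-12))
    # matches the scalar implementation entrywise
    expect_equal(C[2, 5], pearson_correlation(X[2, ], X[5, ]), tolerance = 1e-12)
  })
  # constant spectra are excluded with a message
  X2 <- rbind(a = rep(1 / 15, 15), b = c(0.5, rep(0.5 / 14, 14)),
              d = c(0.3, 0.2, rep(0.5 / 13, 13)))
  expect_message(C2 <- correlation_matrix(X2), "constant")
  expect_equal(rownames(C2), c("b", "d"))
})

test_that("confidence intervals bracket the estimates", {
  withr::with_seed(11, {
    X <- matrix(rgamma(5 * 15, 0.7), 5, 15)
    X <- X / rowSums(X)
    ci <- correlation_ci(correlation_matrix(X))
    expect_equal(nrow(ci), choose(5, 2))
    expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
    expect_true(all(ci$lower >= -1 & ci$upper <= 1))
  })
})

test_that("the weight transform shifts correlations into positive range", {
  C <- matrix(c(1, 0, -1, 0, 1, 1, -1, 1, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  net <- build_network(C)
  expect_equal(net$weights["a", "b"], 2)  # c = 0 -> w = 2
  expect_equal(net$weights["a", "c"], 1)  # c = -1 -> w = 1
  expect_equal(net$weights["b", "c"], 3)  # c = +1 -> w = 3
  expect_equal(unname(diag(net$weights)), rep(0, 3))  # no self-loops
  expect_error(build_network(C, offset = 1), "offset")
  expect_error(build_network(C, transform = function(c) c), "positive")
})

test_that("centralities identify hubs and bridges", {
  # star on 5 nodes, unit weights
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- 1
  W <- W + t(W)
  net <- as_careflow_network(W)
  ct <- centralities(net, edge_length = "unit")
  expect_equal(which.max(ct$degree), 1L)
  expect_equal(ct$betweenness[1], choose(4, 2))  # all leaf pairs via hub
  expect_equal(ct$betweenness[2:5], rep(0, 4))
  expect_equal(ct$betweenness_percentile[1], 100)
  # path of 3: middle node lies on the single shortest path
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 3] <- 1
  P <- P + t(P)
  ctp <- centralities(as_careflow_network(P), edge_length = "unit")
  expect_equal(ctp$betweenness, c(0, 1, 0))
  # inverse-length convention: strong edges are short
  ct2 <- centralities(net)
  expect_equal(ct2$degree, ct$degree)
})

test_that("per-cluster centrality scopes rank within the cluster", {
  net <- two_level_fixture()$net
  part <- louvain_cluster(net, seed = 1)
  ct <- centralities(net, part)
  expect_setequal(unique(ct$scope),
                  c("network", paste0("cluster_", unique(part$membership))))
  in_cl <- ct[ct$scope != "network", ]
  expect_true(all(in_cl$degree_percentile >= 0 & in_cl$degree_percentile <= 100))
})

test_that("intra/inter correlation averages match direct enumeration", {
  C <- matrix(c(
    1.0, 0.8, -0.1, -0.3,
    0.8, 1.0, 0.0, -0.2,
    -0.1, 0.0, 1.0, 0.6,
    -0.3, -0.2, 0.6, 1.0
  ), 4, 4, byrow = TRUE, dimnames = list(c("A", "B", "C", "D"),
                                         c("A", "B", "C", "D")))
  memb <- c(A = 1L, B = 1L, C = 2L, D = 2L)
  s <- cluster_correlation_summary(C, memb)
  expect_equal(s$mean_correlation[s$cluster_a == 1 & s$cluster_b == 1], 0.8)
  expect_equal(s$mean_correlation[s$cluster_a == 2 & s$cluster_b == 2], 0.6)
  # inter: mean of the 4 cross entries
  expect_equal(s$mean_correlation[s$type == "inter"],
               mean(c(-0.1, -0.3, 0.0, -0.2)))
  expect_equal(s$n_pairs, c(1, 4, 1))
  # identical spectra within clusters -> intra exactly 1
  X <- rbind(a = c(0.6, 0.3, 0.1), b = c(0.6, 0.3, 0.1),
             c = c(0.1, 0.2, 0.7), d = c(0.1, 0.2, 0.7))
  C2 <- correlation_matrix(X)
  s2 <- cluster_correlation_summary(C2, c(a = 1L, b = 1L, c = 2L, d = 2L))
  expect_equal(s2$mean_correlation[s2$type == "intra"], c(1, 1), tolerance = 1e-12)
  # all-zero off-diagonal -> all averages zero
  Z <- diag(4)
  dimnames(Z) <- dimnames(C)
  expect_equal(cluster_correlation_summary(Z, memb)$mean_correlation, c(0, 0, 0))
  # singleton cluster flagged
  expect_message(
    s3 <- cluster_correlation_summary(C, c(A = 1L, B = 2L, C = 2L, D = 2L)),
    "singleton")
  expect_true(is.na(s3$mean_correlation[s3$cluster_a == 1 & s3$cluster_b == 1]))
})

test_that("heat-map ordering is block-contiguous and input-order invariant", {
  fx <- two_level_fixture()
  C <- fx$net$weights - 2  # back to correlation-like scale
  diag(C) <- 1
  memb <- setNames(fx$level1, fx$net$nodes)
  ord <- heatmap_order(C, memb)
  runs <- rle(unname(memb[ord]))$values
  expect_equal(sort(runs), sort(unique(fx$level1)))  # each cluster contiguous
  perm <- rev(rownames(C))
  ord2 <- heatmap_order(C[perm, perm], memb)
  expect_equal(ord, ord2)
  # block-diagonal dominance on a planted structure
  within <- mean(C[memb[rownames(C)[row(C)]] == memb[rownames(C)[col(C)]] &
                     row(C) != col(C)])
  between <- mean(C[memb[rownames(C)[row(C)]] != memb[rownames(C)[col(C)]]])
  expect_gt(within, between)
})
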