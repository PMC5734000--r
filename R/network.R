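## Center-center Pearson correlation matrix and the positive-weight network
## derived from it.

#' Pearson correlation of two spectra
#'
#' Product-moment correlation computed with the raw-sums form
#' \deqn{r = \frac{n\sum x_i y_i - \sum x_i \sum y_i}
#'   {\sqrt{n\sum x_i^2 - (\sum x_i)^2}\sqrt{n\sum y_i^2 - (\sum y_i)^2}}.}
#' For pathway spectra `n = 15` (the 15 relative occurrence rates).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`; `NA` with a warning if a
#'   vector is constant (undefined correlation).
#' @export
#' @examples
#' pearson_correlation(c(0.5, 0.25, 0.25), c(0.25, 0.5, 0.25))
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  den2x <- n * sum(x^2) - sum(x)^2
  den2y <- n * sum(y^2) - sum(y)^2
  if (den2x <= 0 || den2y <= 0) {
    warning("correlation undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  (n * sum(x * y) - sum(x) * sum(y)) / sqrt(den2x * den2y)
}

#' Correlation matrix of center spectra
#'
#' Pairwise Pearson correlations of the centers' 15-component pathway
#' spectra (the same raw-sums form as [pearson_correlation()], evaluated in
#' matrix form). Centers with constant spectra (undefined correlation) are
#' excluded with a message.
#'
#' @param spectra Output of [compute_spectra()], or a numeric matrix with
#'   one row per center.
#' @return Symmetric correlation matrix with unit diagonal, dimnames =
#'   center ids.
#' @export
correlation_matrix <- function(spectra) {
  X <- if (inherits(spectra, "careflow_spectra")) spectrum_matrix(spectra) else as.matrix(spectra)
  if (is.null(rownames(X))) rownames(X) <- paste0("node_", seq_len(nrow(X)))
  n <- ncol(X)
  s1 <- rowSums(X)
  den2 <- n * rowSums(X^2) - s1^2
  const <- den2 <= .Machine$double.eps * n * pmax(rowSums(X^2), 1)
  if (any(const)) {
    message(sum(const), " center(s) with constant spectra excluded: ",
            paste(utils::head(rownames(X)[const], 5), collapse = ", "))
    X <- X[!const, , drop = FALSE]
    s1 <- s1[!const]
    den2 <- den2[!const]
  }
  if (nrow(X) < 2) stop("need at least 2 non-constant spectra", call. = FALSE)
  num <- n * tcrossprod(X) - outer(s1, s1)
  C <- num / outer(sqrt(den2), sqrt(den2))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

#' Fisher-z confidence intervals for spectrum correlations
#'
#' Confidence bounds for each off-diagonal coefficient via the Fisher
#' z-transform with `n_obs - 3` effective degrees of freedom. Reported for
#' transparency only: the network applies no cutoff, so no edge is filtered
#' on significance.
#'
#' @param corr Correlation matrix (see [correlation_matrix()]).
#' @param n_obs Number of paired observations behind each coefficient
#'   (15 pathway-type rates).
#' @param conf_level Confidence level.
#' @return A tibble `center_a`, `center_b`, `estimate`, `lower`, `upper`.
#' @export
correlation_ci <- function(corr, n_obs = 15, conf_level = 0.95) {
  ids <- rownames(corr)
  pairs <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[pairs]
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n_obs - 3)
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    center_a = ids[pairs[, 1]],
    center_b = ids[pairs[, 2]],
    estimate = r,
    lower = tanh(z - q * se),
    upper = tanh(z + q * se)
  )
}

#' Build the weighted center network
#'
#' Complete graph on the centers (no correlation cutoff) with edge weights
#' `w_ij = c_ij + offset`; the default offset 2 maps correlations from
#' `[-1, 1]` into `[1, 3]`, eliminating non-positive weights that
#' modularity-based clustering cannot handle. An arbitrary monotone
#' `transform` of the correlations can be supplied instead (e.g.
#' `function(c) (c + 2)^2`) to probe robustness of downstream clustering.
#'
#' @param x A correlation matrix or a `careflow_spectra` table.
#' @param offset Constant added to the correlations (must be `> 1` so all
#'   weights stay positive).
#' @param transform Optional function applied to the correlation matrix in
#'   place of the offset shift; resulting edge weights must be positive.
#' @return An object of class `careflow_network`: list with `nodes`
#'   (character) and `weights` (symmetric matrix, zero diagonal — no
#'   self-loops).
#' @export
build_network <- function(x, offset = 2, transform = NULL) {
  C <- if (is.matrix(x)) x else correlation_matrix(x)
  if (nrow(C) < 2) stop("need at least 2 centers", call. = FALSE)
  if (is.null(transform)) {
    if (offset <= 1) {
      stop("offset must be > 1: correlations reach -1, so smaller offsets ",
           "produce non-positive edge weights", call. = FALSE)
    }
    W <- C + offset
  } else {
    W <- transform(C)
  }
  diag(W) <- 0
  if (any(W < 0) || any(W[upper.tri(W)] == 0)) {
    stop("transformed edge weights must be positive", call. = FALSE)
  }
  structure(list(nodes = rownames(C), weights = W), class = "careflow_network")
}

#' @export
print.careflow_network <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<careflow network: %d nodes, complete, weights in [%.3f, %.3f]>\n",
              length(x$nodes), min(w), max(w)))
  invisible(x)
}

#' Wrap a weight matrix as a careflow network
#'
#' For hand-built or sparse graphs (entries of 0 mean "no edge"); negative
#' weights are rejected. Mainly useful for experiments and tests of the
#' clustering machinery on graphs that are not correlation-derived.
#'
#' @param W Square (symmetric) weight matrix.
#' @return A `careflow_network`.
#' @export
as_careflow_network <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (is.null(rownames(W))) {
    dimnames(W) <- list(paste0("n", seq_len(nrow(W))), paste0("n", seq_len(nrow(W))))
  }
  if (any(W < 0)) stop("edge weights must be nonnegative", call. = FALSE)
  diag(W) <- 0
  structure(list(nodes = rownames(W), weights = (W + t(W)) / 2),
            class = "careflow_network")
}
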