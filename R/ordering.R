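# Ordering probabilities for independent normals.
#
# P(X_1 < X_2 < ... < X_K) for independent X_k ~ N(m_k, v_k) is the positive
# orthant probability of the successive differences D_j = X_{j+1} - X_j,
# a (K-1)-variate normal with mean diff(m) and tridiagonal covariance
#   Var(D_j)       = v_j + v_{j+1}
#   Cov(D_j,D_j+1) = -v_{j+1}.
# The covariance is positive definite whenever all v_k > 0.

#' Probability that independent normals fall in a given order
#'
#' Computes \eqn{P(X_{\pi(1)} < X_{\pi(2)} < \dots < X_{\pi(K)})} for
#' independent \eqn{X_k \sim N(m_k, v_k)} deterministically, as the positive
#' orthant probability of the successive differences. Dimension K-1 = 1 uses
#' the normal CDF; dimensions 2 and 3 use the Plackett-quadrature TVPACK
#' routine and dimensions 4 and 5 the Miwa recursive-integration algorithm of
#' \pkg{mvtnorm}, all deterministic with absolute error well below
#' \code{abs_tol}.
#'
#' @param means numeric vector of means.
#' @param variances numeric vector of positive variances, same length.
#' @param order permutation of \code{seq_along(means)} defining the ordering;
#'   default identity.
#' @param abs_tol absolute tolerance requested from the integration backend.
#' @return a probability in \eqn{[0, 1]}.
#' @examples
#' ordering_probability(c(0, 0, 0), c(1, 1, 1))      # exchangeable: 1/6
#' ordering_probability(c(0, 10), c(1, 1))           # pnorm(10 / sqrt(2))
#' @seealso [ordering_probability_mc()] for the seeded sampling backend.
#' @export
ordering_probability <- function(means, variances, order = seq_along(means),
                                 abs_tol = 1e-7) {
  K <- length(means)
  if (length(variances) != K)
    stop_config("`means` and `variances` must have the same length")
  if (any(!is.finite(variances)) || any(variances <= 0))
    stop_config("all variances must be positive and finite")
  if (length(order) != K || !setequal(order, seq_len(K)))
    stop_config("`order` must be a permutation of 1:", K)
  if (K < 2) stop_config("at least two groups are needed")
  m <- means[order]
  v <- variances[order]
  d <- diff(m)
  if (K == 2L) return(stats::pnorm(d / sqrt(sum(v))))
  S <- diff_covariance(v)
  algo <- if (K <= 4L) mvtnorm::TVPACK(abseps = abs_tol)
          else mvtnorm::Miwa(steps = 512)
  p <- mvtnorm::pmvnorm(lower = rep(0, K - 1L), upper = rep(Inf, K - 1L),
                        mean = d, sigma = S, algorithm = algo)
  min(max(as.numeric(p), 0), 1)
}

diff_covariance <- function(v) {
  K <- length(v)
  S <- diag(v[-K] + v[-1L], K - 1L)
  if (K > 2L) {
    idx <- cbind(seq_len(K - 2L), seq_len(K - 2L) + 1L)
    S[idx] <- -v[2:(K - 1L)]
    S[idx[, 2:1, drop = FALSE]] <- -v[2:(K - 1L)]
  }
  S
}

#' Monte Carlo ordering probability
#'
#' The sampling counterpart of [ordering_probability()]: draws independent
#' normal vectors, counts the proportion respecting the ordering, and reports
#' a binomial standard error. Reproducible given \code{seed}; the caller's
#' RNG state is left untouched.
#'
#' @inheritParams ordering_probability
#' @param n_draws number of draws, at least 1e4.
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @return a list with elements \code{probability}, \code{se} and
#'   \code{n_draws}.
#' @export
ordering_probability_mc <- function(means, variances,
                                    order = seq_along(means),
                                    n_draws = 1e5, seed = NULL) {
  K <- length(means)
  if (length(variances) != K)
    stop_config("`means` and `variances` must have the same length")
  if (any(variances <= 0)) stop_config("all variances must be positive")
  if (length(order) != K || !setequal(order, seq_len(K)))
    stop_config("`order` must be a permutation of 1:", K)
  if (n_draws < 1e4) stop_config("`n_draws` must be at least 1e4")
  m <- means[order]
  s <- sqrt(variances[order])
  hits <- local_seed(seed, {
    total <- 0
    left <- as.integer(n_draws)
    while (left > 0L) {
      b <- min(left, 1e6L)
      X <- matrix(stats::rnorm(b * K, mean = rep(m, each = b),
                               sd = rep(s, each = b)), ncol = K)
      total <- total + sum(rowSums(X[, -1L, drop = FALSE] >
                                   X[, -K, drop = FALSE]) == K - 1L)
      left <- left - b
    }
    total
  })
  p <- hits / n_draws
  list(probability = p, se = sqrt(p * (1 - p) / n_draws), n_draws = n_draws)
}

# evaluate an expression under a temporary seed, restoring the caller's state
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## ---- batched evaluation over many designs of one problem -----------------
## The design search evaluates the same (means, variances) at thousands of
## allocations; these internal kernels vectorize over allocations where a
## closed form or a smooth 1-d quadrature exists and fall back to pmvnorm
## per design otherwise. They are cross-checked against ordering_probability
## in the test suite.

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1L, ]^2))
}
.gl48 <- gauss_legendre(48L)

# vectorized upper-orthant probability P(Z1 > a1, Z2 > a2) for standard
# bivariate normals with correlation rho, via the Plackett identity
#   d Phi2 / d rho = phi2,
# integrating the bivariate density from independence (rho = 0) to rho.
# Accurate to ~1e-14 for |rho| <= 0.925; beyond that, per-element pmvnorm.
orthant2_batch <- function(a1, a2, rho) {
  out <- stats::pnorm(-a1) * stats::pnorm(-a2)
  h <- rho / 2
  for (j in seq_along(.gl48$x)) {
    r <- h * (1 + .gl48$x[j])
    out <- out + h * .gl48$w[j] *
      exp(-(a1^2 - 2 * r * a1 * a2 + a2^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  hard <- which(abs(rho) > 0.925)
  for (i in hard) {
    S <- matrix(c(1, rho[i], rho[i], 1), 2L)
    out[i] <- mvtnorm::pmvnorm(lower = c(a1[i], a2[i]), upper = c(Inf, Inf),
                               sigma = S, algorithm = mvtnorm::TVPACK())
  }
  pmin(pmax(out, 0), 1)
}

# fit and complexity for a matrix of designs (rows) under one problem;
# means/variances already permuted to hypothesis order
bf_batch <- function(m, v, sizes) {
  K <- length(m)
  d <- diff(m)
  n <- lapply(seq_len(K), function(k) sizes[, k])
  vk <- lapply(seq_len(K), function(k) v[k] / n[[k]])
  if (K == 2L) {
    s <- sqrt(vk[[1L]] + vk[[2L]])
    return(list(fit = stats::pnorm(d / s), complexity = rep(0.5, nrow(sizes))))
  }
  sd_d <- lapply(seq_len(K - 1L), function(j) sqrt(vk[[j]] + vk[[j + 1L]]))
  rho <- lapply(seq_len(K - 2L), function(j)
    -vk[[j + 1L]] / (sd_d[[j]] * sd_d[[j + 1L]]))
  if (K == 3L) {
    fit <- orthant2_batch(-d[1L] / sd_d[[1L]], -d[2L] / sd_d[[2L]], rho[[1L]])
    # zero-mean bivariate orthant: 1/4 + asin(rho) / (2 pi)
    complexity <- 0.25 + asin(rho[[1L]]) / (2 * pi)
    return(list(fit = fit, complexity = complexity))
  }
  if (K == 4L) {
    # zero-mean trivariate orthant: 1/8 + (asin r12 + asin r13 + asin r23)/(4 pi);
    # here Corr(D1, D3) = 0, so only the adjacent terms remain
    complexity <- 0.125 + (asin(rho[[1L]]) + asin(rho[[2L]])) / (4 * pi)
  } else {
    complexity <- vapply(seq_len(nrow(sizes)), function(i)
      ordering_probability(rep(0, K), v / sizes[i, ]), numeric(1))
  }
  fit <- vapply(seq_len(nrow(sizes)), function(i)
    ordering_probability(m, v / sizes[i, ]), numeric(1))
  list(fit = fit, complexity = complexity)
}
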