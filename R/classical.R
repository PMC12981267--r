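# Classical allocations from the significance-testing framework: equal group
# sizes, the A-optimal allocation maximizing Welch-test power, and the
# D-optimal allocation minimizing the volume of the confidence ellipsoid.

#' Welch noncentrality parameter of a design
#'
#' \eqn{\lambda = K \sum_k (\bar\mu - \mu_k)^2 / \sum_k (\sigma_k^2 / n_k)},
#' the noncentrality of Welch's heteroscedastic F statistic at the plug-in
#' parameter values, with \eqn{\bar\mu} the unweighted mean of the K group
#' means. Power to reject the classical null increases with \eqn{\lambda};
#' at fixed means it is maximized by minimizing the A-criterion in the
#' denominator.
#'
#' @inheritParams bf_fit
#' @return a nonnegative scalar.
#' @export
welch_noncentrality <- function(problem, sizes) {
  check_sizes(sizes, problem)
  mbar <- mean(problem$means)
  problem$K * sum((mbar - problem$means)^2) /
    sum(problem$variances / sizes)
}

#' A- and D-optimality criteria of a design
#'
#' The A-criterion is the trace \eqn{\sum_k \sigma_k^2 / n_k} and the
#' D-criterion the determinant \eqn{\prod_k \sigma_k^2 / n_k} of the
#' (diagonal) covariance of the group-mean estimates; both are to be
#' minimized.
#'
#' @inheritParams bf_fit
#' @return a positive scalar.
#' @export
a_criterion <- function(problem, sizes) {
  check_sizes(sizes, problem)
  sum(problem$variances / sizes)
}

#' @rdname a_criterion
#' @export
d_criterion <- function(problem, sizes) {
  check_sizes(sizes, problem)
  prod(problem$variances / sizes)
}

#' Equal group sizes under the budget
#'
#' The common size \eqn{n = \lfloor B / \sum_k c_k \rfloor} (with a fixed
#' total, \eqn{\lfloor N / K \rfloor}), rounded downwards when not an
#' integer. Groups whose maximum size is below the common share are capped
#' at their maximum; a common share below a group's minimum size is an
#' error.
#'
#' @param problem a [design_problem()].
#' @return an integer length-K vector of group sizes.
#' @export
equal_design <- function(problem) {
  n <- (budget_cents(problem) %/% sum(cost_cents(problem)))
  sizes <- pmin(rep(as.integer(n), problem$K), problem$max_sizes)
  if (any(sizes < problem$min_sizes))
    stop_infeasible("equal design of ", n,
                    " per group falls below a minimum group size")
  as.integer(sizes)
}

#' A-optimal group sizes
#'
#' The continuous A-optimal allocation follows the square-root rule
#' \eqn{n_k / n_1 = \sqrt{(\sigma_k^2 / \sigma_1^2)(c_1 / c_k)}}: sizes are
#' proportional to \eqn{\sqrt{\sigma_k^2 / c_k}}, scaled to spend the budget
#' exactly (or to sum to \eqn{N}). Groups whose continuous size violates a
#' min/max bound are clamped first and the remainder re-scaled. The integer
#' design floors the continuous sizes and then adds one subject per group in
#' decreasing order of fractional remainder while the budget allows (with a
#' fixed total, until the sizes sum to \eqn{N}).
#'
#' @param problem a [design_problem()].
#' @return an integer length-K vector, with the continuous allocation
#'   attached as attribute \code{"continuous"}.
#' @export
a_optimal_design <- function(problem) {
  weights <- sqrt(problem$variances / problem$costs)
  round_allocation(problem, weights)
}

#' D-optimal group sizes
#'
#' Minimizes \eqn{\prod_k \sigma_k^2 / n_k} over the integer design space by
#' exhaustive enumeration, equivalent to maximizing \eqn{\prod_k n_k}
#' (variances only rescale the criterion and cannot move the argmin). Ties
#' within relative 1e-9 are all recorded; the lexicographically smallest is
#' returned.
#'
#' @param problem a [design_problem()].
#' @return an integer length-K vector, with any tied designs attached as
#'   attribute \code{"ties"} (a matrix, one row per tied design).
#' @export
d_optimal_design <- function(problem) {
  res <- search_designs(problem, function(sizes) rowSums(log(sizes)),
                        top_m = 1L)
  best <- res$best
  structure(best[1L, ], ties = best)
}

# continuous allocation proportional to `weights` spending the budget
# exactly, clamped to bounds, then floored with greedy largest-remainder
# budget repair; shared by the A-optimal rule
round_allocation <- function(problem, weights) {
  K <- problem$K
  cc <- problem$costs
  cont <- numeric(K)
  free <- rep(TRUE, K)
  budget_left <- problem$budget
  # clamp bound violators and rescale the remaining groups
  repeat {
    scale <- budget_left / sum(cc[free] * weights[free])
    cont[free] <- scale * weights[free]
    viol_lo <- free & cont < problem$min_sizes
    viol_hi <- free & cont > problem$max_sizes
    if (!any(viol_lo | viol_hi)) break
    cont[viol_lo] <- problem$min_sizes[viol_lo]
    cont[viol_hi] <- problem$max_sizes[viol_hi]
    free <- free & !(viol_lo | viol_hi)
    budget_left <- problem$budget - sum(cc[!free] * cont[!free])
    if (!any(free)) break
  }
  sizes <- pmax(floor(cont), problem$min_sizes)
  cents <- cost_cents(problem)
  spent <- sum(cents * sizes)
  cap <- budget_cents(problem)
  if (spent > cap)
    stop_infeasible("min/max bounds leave no budget-feasible A-optimal design")
  for (k in order(-(cont - floor(cont)))) {
    if (problem$fixed_n && sum(sizes) >= problem$total_n) break
    if (sizes[k] + 1 > problem$max_sizes[k]) next
    if (spent + cents[k] <= cap) {
      sizes[k] <- sizes[k] + 1
      spent <- spent + cents[k]
    }
  }
  if (problem$fixed_n && sum(sizes) != problem$total_n)
    stop_infeasible("bounds prevent the A-optimal design from reaching N")
  structure(as.integer(sizes), continuous = cont)
}
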