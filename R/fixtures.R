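# Reproducible randomized design problems for property-style testing.

#' Generate a random design problem
#'
#' Draws a reproducible random K-group problem of the kind the optimal
#' design methodology targets: group means sorted ascending from standard
#' normal draws (so the identity ordering is the hypothesis), within-group
#' variances log-uniform on [0.25, 4], per-subject costs log-uniform on
#' [50, 800] rounded to cents, and a budget chosen so that the equal design
#' allocates roughly 20 to 200 subjects per group. Minimum group sizes are
#' 2 and maxima unbounded. In fixed-total mode the same per-group target
#' sets \eqn{N}.
#'
#' Generated problems always pass [validate_design_problem()]; identical
#' seeds yield identical problems and the caller's RNG state is preserved.
#'
#' @param K number of groups, 2 to 6.
#' @param seed integer seed.
#' @param mode \code{"budget"} (default) or \code{"fixed_n"}.
#' @return a [design_problem()].
#' @examples
#' random_design_problem(3, seed = 1)
#' @export
random_design_problem <- function(K, seed, mode = c("budget", "fixed_n")) {
  mode <- match.arg(mode)
  if (K < 2 || K > 6) stop_config("K must be between 2 and 6")
  local_seed(seed, {
    means <- sort(stats::rnorm(K))
    variances <- exp(stats::runif(K, log(0.25), log(4)))
    per_group <- sample(20:200, 1L)
    if (mode == "budget") {
      costs <- round(exp(stats::runif(K, log(50), log(800))), 2)
      design_problem(means = means, variances = variances, costs = costs,
                     budget = round(per_group * sum(costs), 2))
    } else {
      design_problem(means = means, variances = variances,
                     total_n = K * per_group)
    }
  })
}
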