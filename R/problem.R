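# Design problems: a priori group parameters, costs and the budgetary
# constraint that together define the integer design space.

#' Specify a group-comparison design problem
#'
#' A design problem collects everything needed to plan group sizes for a
#' K-group comparison of means under the order hypothesis
#' \eqn{H_1:\ \mu_1 < \mu_2 < \dots < \mu_K}: a priori group means,
#' within-group variances, per-subject costs and a budget \eqn{B}, or
#' alternatively a fixed total sample size \eqn{N}. A design
#' \eqn{\xi = (n_1, \dots, n_K)} is feasible when
#' \eqn{\sum_k c_k n_k \le B} and every \eqn{n_k} lies within its bounds;
#' with a fixed total, \eqn{\sum_k n_k = N} exactly. The fixed-total problem
#' is represented internally as the budget problem with unit costs and
#' \eqn{B = N} plus an exact-total flag.
#'
#' Group means should be supplied in the hypothesized increasing order; an
#' explicit permutation can be given through \code{order} instead. Minimum
#' group sizes default to 2, the smallest size that still permits estimating
#' a within-group variance.
#'
#' Currency is handled exactly: costs and budget are interpreted as decimal
#' amounts with at most two decimals (cents) and feasibility is decided by
#' exact integer comparison in cents, so budgets such as 101766.22 are spent
#' to the cent with no floating-point slack.
#'
#' @param means numeric length-K vector of a priori group means (outcome
#'   units).
#' @param variances numeric length-K vector of within-group variances
#'   \eqn{\sigma_k^2} (outcome units squared), all positive.
#' @param costs numeric length-K vector of per-subject costs \eqn{c_k}
#'   (currency). Ignored (forced to 1) when \code{total_n} is given.
#' @param budget total budget \eqn{B} (currency). Exactly one of
#'   \code{budget} and \code{total_n} must be supplied.
#' @param total_n fixed total sample size \eqn{N}; implies unit costs and
#'   the exact-total constraint \eqn{\sum_k n_k = N}.
#' @param min_sizes integer, scalar or length-K: minimum group sizes
#'   (default 2).
#' @param max_sizes integer, scalar or length-K: maximum group sizes
#'   (default unbounded, \code{Inf}).
#' @param labels optional character length-K group labels.
#' @param order optional permutation of \code{1:K} giving the hypothesized
#'   ordering: \eqn{\mu_{\pi(1)} < \dots < \mu_{\pi(K)}}. Default identity.
#'
#' @return An object of class \code{"design_problem"}: a validated list with
#'   elements \code{K}, \code{means}, \code{variances}, \code{costs},
#'   \code{budget}, \code{total_n}, \code{fixed_n}, \code{min_sizes},
#'   \code{max_sizes}, \code{labels} and \code{order}.
#'
#' @examples
#' # three groups, small equally spaced effects, equal costs
#' prob <- design_problem(means = c(0.2, 0.4, 0.6), variances = c(1, 1, 1),
#'                        costs = c(100, 100, 100), budget = 30000)
#' prob
#' design_cost(c(100, 100, 100), prob)
#'
#' # the same comparison with the total sample size fixed instead
#' design_problem(means = c(0.2, 0.4, 0.6), variances = c(1, 1, 1),
#'                total_n = 300)
#' @seealso [bayes_factor()], [bf_optimal_design()], [compare_designs()],
#'   [read_design_problem()]
#' @export
design_problem <- function(means, variances, costs = NULL, budget = NULL,
                           total_n = NULL, min_sizes = 2L, max_sizes = Inf,
                           labels = NULL, order = NULL) {
  if (is.null(total_n) == is.null(budget))
    stop_config("exactly one of `budget` and `total_n` must be supplied")
  K <- length(means)
  fixed_n <- !is.null(total_n)
  if (fixed_n) {
    if (!is.null(costs) && !all(costs == 1))
      stop_config("`costs` must be omitted (or all 1) when `total_n` is given")
    costs <- rep(1, K)
    budget <- total_n
  }
  if (length(min_sizes) == 1L) min_sizes <- rep(min_sizes, K)
  if (length(max_sizes) == 1L) max_sizes <- rep(max_sizes, K)
  if (is.null(order)) order <- seq_len(K)
  if (is.null(labels)) labels <- paste0("group", seq_len(K))
  problem <- structure(
    list(K = K, means = as.numeric(means), variances = as.numeric(variances),
         costs = as.numeric(costs), budget = as.numeric(budget),
         total_n = if (fixed_n) as.integer(total_n) else NULL,
         fixed_n = fixed_n, min_sizes = as.numeric(min_sizes),
         max_sizes = as.numeric(max_sizes), labels = as.character(labels),
         order = as.integer(order)),
    class = "design_problem")
  validate_design_problem(problem)
}

#' Validate a design problem
#'
#' Checks every invariant of a design problem: 2 <= K <= 6, matching vector
#' lengths, positive variances and costs, minimum sizes of at least 2,
#' elementwise min <= max, a valid hypothesis permutation, and a non-empty
#' design space (the all-minimum design must satisfy the budget; with a fixed
#' total, \eqn{\sum_k} min \eqn{\le N \le \sum_k} max so the exact total is
#' attainable). Idempotent: validating a validated problem returns it
#' unchanged.
#'
#' @param problem a \code{"design_problem"} object (or a bare list with the
#'   same fields).
#' @return the validated problem, invisibly classed \code{"design_problem"}.
#' @export
validate_design_problem <- function(problem) {
  K <- problem$K
  if (!is.numeric(K) || K != round(K) || K < 2 || K > 6)
    stop_config("K must be an integer between 2 and 6, got ", K)
  for (f in c("means", "variances", "costs", "min_sizes", "max_sizes"))
    if (length(problem[[f]]) != K)
      stop_config("`", f, "` must have length K = ", K,
                  ", got ", length(problem[[f]]))
  if (any(!is.finite(problem$variances)) || any(problem$variances <= 0))
    stop_config("all variances must be positive and finite")
  if (any(!is.finite(problem$costs)) || any(problem$costs <= 0))
    stop_config("all per-subject costs must be positive and finite")
  if (!is.finite(problem$budget) || problem$budget <= 0)
    stop_config("the budget must be positive and finite")
  if (any(problem$min_sizes < 2))
    stop_config("minimum group sizes must be at least 2 ",
                "(needed to estimate within-group variances)")
  if (any(problem$min_sizes > problem$max_sizes))
    stop_config("minimum group sizes must not exceed maximum group sizes")
  if (problem$fixed_n && problem$total_n != round(problem$total_n))
    stop_config("`total_n` must be a whole number")
  if (length(problem$order) != K || !setequal(problem$order, seq_len(K)))
    stop_config("`order` must be a permutation of 1:", K)
  # non-empty design space
  min_cost <- sum(cost_cents(problem) * problem$min_sizes)
  if (min_cost > budget_cents(problem))
    stop_infeasible(
      "empty design space: the smallest admissible design costs ",
      format(min_cost / 100, nsmall = 2), " which exceeds the budget ",
      format(problem$budget, nsmall = 2))
  if (problem$fixed_n && sum(problem$min_sizes) > problem$total_n)
    stop_infeasible("empty design space: sum of minimum group sizes exceeds N")
  if (problem$fixed_n && sum(problem$max_sizes) < problem$total_n)
    stop_infeasible("empty design space: maximum group sizes cannot reach ",
                    "the exact total N = ", problem$total_n)
  class(problem) <- "design_problem"
  problem
}

# currency as exact integer cents; costs are read at two-decimal precision
cost_cents <- function(problem) as.integer(round(problem$costs * 100))
budget_cents <- function(problem) round(problem$budget * 100)

#' Total cost of a design
#'
#' Returns \eqn{\sum_k c_k n_k} exactly (currency arithmetic in cents), the
#' left-hand side of the budgetary constraint \eqn{\sum_k c_k n_k \le B}.
#'
#' @param sizes integer length-K vector of group sizes.
#' @param problem a [design_problem()].
#' @return the total cost, a scalar in the problem's currency.
#' @examples
#' prob <- design_problem(means = c(17.3, 23.9, 45.9),
#'                        variances = c(61.6225, 397.2049, 528.5401),
#'                        costs = c(2328.58, 2695.12, 6281.18),
#'                        budget = 101766.22)
#' design_cost(c(9, 16, 6), prob)  # 101766.22, to the cent
#' @export
design_cost <- function(sizes, problem) {
  check_sizes(sizes, problem, require_integer = FALSE)
  sum(cost_cents(problem) * sizes) / 100
}

#' Is a design feasible?
#'
#' A design is feasible when all group sizes are integers within their
#' min/max bounds and the total cost does not exceed the budget; under a
#' fixed total sample size, the sizes must additionally sum to \eqn{N}
#' exactly.
#'
#' @inheritParams design_cost
#' @return a single logical.
#' @export
is_feasible <- function(sizes, problem) {
  if (length(sizes) != problem$K) return(FALSE)
  if (any(sizes != round(sizes)) || any(sizes < problem$min_sizes) ||
      any(sizes > problem$max_sizes))
    return(FALSE)
  cost <- sum(cost_cents(problem) * sizes)
  if (cost > budget_cents(problem)) return(FALSE)
  if (problem$fixed_n && sum(sizes) != problem$total_n) return(FALSE)
  TRUE
}

check_sizes <- function(sizes, problem, require_integer = TRUE) {
  if (length(sizes) != problem$K)
    stop_config("`sizes` must have length K = ", problem$K,
                ", got ", length(sizes))
  if (any(!is.finite(sizes)) || any(sizes < 1))
    stop_config("group sizes must be positive")
  if (require_integer && any(sizes != round(sizes)))
    stop_config("group sizes must be whole numbers")
  invisible(sizes)
}

#' Read a design problem from a JSON or YAML config file
#'
#' The config carries a \code{groups} list (each entry with \code{label},
#' \code{mean}, \code{variance}, optional \code{cost}, \code{min_n},
#' \code{max_n}) plus either \code{budget} or \code{total_n}, and optionally
#' \code{hypothesis_order}: the group labels in hypothesized increasing order
#' of their means (default: the order in which groups are listed).
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return a validated [design_problem()].
#' @examples
#' cfg <- system.file("extdata", "pain_budget.json", package = "bfdesign")
#' read_design_problem(cfg)
#' @export
read_design_problem <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: ", path)
  cfg <- tryCatch(
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else
      jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) stop_config("cannot parse config: ", conditionMessage(e)))
  if (is.null(cfg$groups) || !length(cfg$groups))
    stop_config("config must contain a non-empty `groups` list")
  grab <- function(field, default = NULL) {
    vapply(cfg$groups, function(g) {
      v <- g[[field]]
      if (is.null(v)) {
        if (is.null(default)) stop_config("group entry is missing `", field, "`")
        v <- default
      }
      as.numeric(v)
    }, numeric(1))
  }
  labels <- vapply(seq_along(cfg$groups), function(i) {
    lb <- cfg$groups[[i]]$label
    if (is.null(lb)) paste0("group", i) else as.character(lb)
  }, character(1))
  order <- NULL
  if (!is.null(cfg$hypothesis_order)) {
    order <- match(unlist(cfg$hypothesis_order), labels)
    if (anyNA(order))
      stop_config("`hypothesis_order` contains labels not present in `groups`")
  }
  design_problem(
    means = grab("mean"), variances = grab("variance"),
    costs = if (is.null(cfg$total_n)) grab("cost") else NULL,
    budget = if (is.null(cfg$total_n)) cfg$budget else NULL,
    total_n = cfg$total_n,
    min_sizes = grab("min_n", default = 2),
    max_sizes = grab("max_n", default = Inf),
    labels = labels, order = order)
}

#' @export
print.design_problem <- function(x, ...) {
  cat("Design problem with K =", x$K, "groups",
      if (x$fixed_n) sprintf("(fixed total N = %d)", x$total_n)
      else sprintf("(budget B = %s)", format(x$budget, big.mark = ",")),
      "\n")
  tab <- data.frame(label = x$labels, mean = x$means, variance = x$variances,
                    cost = x$costs, min_n = x$min_sizes, max_n = x$max_sizes)
  print(tab, row.names = FALSE)
  ord <- paste(x$labels[x$order], collapse = " < ")
  cat("Hypothesis H1:", ord, "\n")
  invisible(x)
}

# condition helpers: distinct classes so the CLI can map errors to exit codes
stop_config <- function(...) {
  stop(structure(class = c("bfdesign_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_infeasible <- function(...) {
  stop(structure(class = c("bfdesign_infeasible_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_io <- function(...) {
  stop(structure(class = c("bfdesign_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
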