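# The approximated adjusted fractional Bayes factor for an order hypothesis
# against its complement, evaluated at the design stage with plug-in
# parameter values.
#
# Posterior of mu:  N(mu_hat, diag(sigma_k^2 / n_k))         (plug-in)
# Prior of mu:      N(0,      diag(sigma_k^2 / (b n_k)))     (fraction b)
# The common fraction b rescales all prior variances together, and a
# zero-mean ordering probability is invariant to such a rescaling, so the
# complexity -- and with it the Bayes factor -- does not depend on b.

#' Fit of the order hypothesis at a design
#'
#' The fit \eqn{f_1} is the posterior probability mass in agreement with
#' \eqn{H_1}: the ordering probability of the plug-in posterior
#' \eqn{N(\mu_k, \sigma_k^2 / n_k)}. At the design stage, the a priori means
#' and variances stand in for the estimates that the posterior would be built
#' from.
#'
#' @param problem a [design_problem()].
#' @param sizes integer length-K vector of group sizes.
#' @return the fit, a probability.
#' @export
bf_fit <- function(problem, sizes) {
  check_sizes(sizes, problem)
  ordering_probability(problem$means, problem$variances / sizes,
                       order = problem$order)
}

#' Complexity of the order hypothesis at a design
#'
#' The complexity \eqn{c_1} is the prior probability mass in agreement with
#' \eqn{H_1}: the ordering probability of the zero-mean prior whose variances
#' are \eqn{\sigma_k^2 / (b\, n_k)}. The common fraction \eqn{b} cancels, so
#' the computation uses variances \eqn{\sigma_k^2 / n_k} directly. When all
#' prior variances are equal (equal \eqn{\sigma_k^2 / n_k}), every ordering
#' is equally likely and \eqn{c_1 = 1 / K!}.
#'
#' @inheritParams bf_fit
#' @return the complexity, a probability.
#' @export
bf_complexity <- function(problem, sizes) {
  check_sizes(sizes, problem)
  ordering_probability(rep(0, problem$K), problem$variances / sizes,
                       order = problem$order)
}

#' Prior specification behind the fractional Bayes factor
#'
#' Documents the adjusted fractional prior used at a design: zero prior
#' means, per-group fractions \eqn{b_k = b = J / N} of the likelihood (with
#' \eqn{J = K - 1} the number of equality constraints in the corresponding
#' null hypothesis and \eqn{N = \sum_k n_k}), and prior variances
#' \eqn{\sigma_k^2 / (b\, n_k)}. Because inequality-constrained hypotheses
#' are invariant to the common fraction, these values are informational: the
#' Bayes factor computed by [bayes_factor()] does not change with \eqn{b}.
#'
#' @inheritParams bf_fit
#' @return a list with \code{fractions}, \code{prior_means} and
#'   \code{prior_variances}.
#' @export
prior_spec <- function(problem, sizes) {
  check_sizes(sizes, problem)
  b <- (problem$K - 1) / sum(sizes)
  list(fractions = rep(b, problem$K),
       prior_means = rep(0, problem$K),
       prior_variances = problem$variances / (b * sizes))
}

#' Bayes factor for the order hypothesis against its complement
#'
#' Computes \eqn{BF_{1c} = (f_1 / c_1) / ((1 - f_1) / (1 - c_1))} from the
#' fit and complexity at a candidate design, together with
#' \eqn{BF_{1u} = f_1 / c_1} (against the unconstrained hypothesis) and the
#' conventional verbal label from [interpret_bf()]. If the fit is numerically
#' indistinguishable from 1 the Bayes factor is reported as \code{Inf} with
#' \code{diverged = TRUE} rather than dividing by zero.
#'
#' The design need not be feasible for the problem's budget: published or
#' user-chosen allocations can be evaluated as-is.
#'
#' @inheritParams bf_fit
#' @return an object of class \code{"bf_result"}: a list with \code{sizes},
#'   \code{fit}, \code{complexity}, \code{bf_1c}, \code{bf_1u}, \code{label}
#'   and \code{diverged}.
#' @examples
#' pain <- design_problem(means = c(17.3, 23.9, 45.9),
#'                        variances = c(61.6225, 397.2049, 528.5401),
#'                        total_n = 31)
#' bayes_factor(pain, c(9, 16, 6))
#' @export
bayes_factor <- function(problem, sizes) {
  f <- bf_fit(problem, sizes)
  c1 <- bf_complexity(problem, sizes)
  diverged <- f >= 1 - 1e-12
  bf <- if (diverged) Inf else (f / c1) / ((1 - f) / (1 - c1))
  structure(list(sizes = as.integer(sizes), fit = f, complexity = c1,
                 bf_1c = bf, bf_1u = f / c1,
                 label = if (diverged) "Decisive support for H1"
                         else interpret_bf(bf),
                 diverged = diverged),
            class = "bf_result")
}

#' Verbal interpretation of a Bayes factor
#'
#' Maps a Bayes factor \eqn{BF_{1c}} to the conventional ten-category
#' evidence scale (decisive / very strong / strong / substantial / mild, for
#' \eqn{H_1} above 1 and for the complement below 1). The printed ranges
#' touch at 3, 10, 30 and 100; a boundary value is assigned to the
#' lower-support bin on its side of 1, i.e. the bins above 1 are
#' \eqn{(1, 3], (3, 10], (10, 30], (30, 100], (100, \infty)} and mirrored
#' below 1, with \eqn{BF = 1} labelled "Mild support for H1".
#'
#' @param bf a vector of positive Bayes factors.
#' @return a character vector of labels.
#' @examples
#' interpret_bf(c(5, 26.9, 1, 0.02))
#' @export
interpret_bf <- function(bf) {
  if (any(!is.na(bf) & bf <= 0)) stop_config("Bayes factors must be positive")
  cuts <- c(1 / 100, 1 / 30, 1 / 10, 1 / 3, 1, 3, 10, 30, 100)
  labels <- c("Decisive support for H1c", "Very strong support for H1c",
              "Strong support for H1c", "Substantial support for H1c",
              "Mild support for H1c", "Mild support for H1",
              "Substantial support for H1", "Strong support for H1",
              "Very strong support for H1", "Decisive support for H1")
  # bins right-closed above 1 and (mirrored) left-closed below 1
  idx <- vapply(bf, function(x) {
    if (is.na(x)) return(NA_integer_)
    if (x >= 1) max(sum(x > cuts) + 1L, 6L)  # (1,3] and BF = 1 -> mild H1
    else sum(x >= cuts) + 1L                 # [1/3,1) -> mild H1c
  }, integer(1))
  labels[idx]
}

#' @export
print.bf_result <- function(x, digits = 4, ...) {
  cat("Order-hypothesis Bayes factor at design (",
      paste(x$sizes, collapse = ", "), ")\n", sep = "")
  cat("  fit f1         =", format(x$fit, digits = digits), "\n")
  cat("  complexity c1  =", format(x$complexity, digits = digits), "\n")
  cat("  BF_1c          =", format(x$bf_1c, digits = digits),
      if (x$diverged) " (fit at numerical ceiling)" else "", "\n")
  cat("  BF_1u          =", format(x$bf_1u, digits = digits), "\n")
  cat("  interpretation:", x$label, "\n")
  invisible(x)
}
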