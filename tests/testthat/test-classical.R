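test_that("Welch noncentrality matches hand arithmetic", {
  p <- design_problem(means = c(0, 1), variances = c(1, 1), total_n = 20)
  # K * sum((mbar - mu_k)^2) / sum(v_k / n_k) = 2 * 0.5 / 0.2
  expect_equal(welch_noncentrality(p, c(10, 10)), 5)
  # equal means: lambda vanishes
  q <- design_problem(means = c(2, 2, 2), variances = c(1, 2, 3),
                      total_n = 30)
  expect_equal(welch_noncentrality(q, c(10, 10, 10)), 0)
  # doubling every group size doubles lambda
  pain <- pain_problem("fixed_n")
  expect_equal(welch_noncentrality(pain, 2 * c(9, 16, 6)),
               2 * welch_noncentrality(pain, c(9, 16, 6)))
})

test_that("A- and D-criteria are the trace and determinant of the covariance", {
  p <- design_problem(means = c(0, 1, 2), variances = c(1, 1, 1),
                      total_n = 300)
  expect_equal(a_criterion(p, c(100, 100, 100)), 0.03)
  expect_equal(d_criterion(p, c(100, 100, 100)), 1e-6)
  # increasing any group size decreases both criteria
  pain <- pain_problem("fixed_n")
  for (k in 1:3) {
    n <- c(9, 16, 6); m <- n; m[k] <- m[k] + 1
    expect_lt(a_criterion(pain, m), a_criterion(pain, n))
    expect_lt(d_criterion(pain, m), d_criterion(pain, n))
  }
  # A-optimal allocation beats a more balanced one on the A-criterion
  expect_lt(a_criterion(pain, c(5, 12, 14)), a_criterion(pain, c(10, 10, 11)))
})

test_that("equal designs floor the per-group budget share", {
  expect_identical(equal_design(fictional_problem()), rep(100L, 3))
  expect_identical(equal_design(pain_problem("budget")), rep(9L, 3))
  expect_identical(equal_design(asthma_problem("budget")), rep(15L, 4))
  expect_identical(equal_design(pain_problem("fixed_n")), rep(10L, 3))
  expect_identical(equal_design(asthma_problem("fixed_n")), rep(18L, 4))
  # a floor below a minimum group size is an error, not a silent bump
  p <- design_problem(means = c(0, 1, 2), variances = c(1, 1, 1),
                      costs = c(1, 1, 1), budget = 12,
                      min_sizes = c(5, 2, 2))
  expect_error(equal_design(p), class = "bfdesign_infeasible_error")
})

test_that("A-optimal designs follow the square-root allocation rule", {
  painN <- pain_problem("fixed_n")
  expect_identical(as.integer(a_optimal_design(painN)), c(5L, 12L, 14L))
  painB <- pain_problem("budget")
  expect_identical(as.integer(a_optimal_design(painB)), c(5L, 12L, 9L))
  # equal variances and costs: the rule gives equal allocation
  expect_identical(as.integer(a_optimal_design(fictional_problem())),
                   rep(100L, 3))
  # continuous allocation satisfies n_k / n_1 = sqrt((v_k / v_1)(c_1 / c_k))
  for (i in 1:5) {
    prob <- random_design_problem(3, seed = 600 + i)
    cont <- attr(a_optimal_design(prob), "continuous")
    expect_equal(cont / cont[1],
                 sqrt((prob$variances / prob$variances[1]) *
                      (prob$costs[1] / prob$costs)), tolerance = 1e-10)
    # and spends the budget exactly before rounding
    expect_equal(sum(prob$costs * cont), prob$budget, tolerance = 1e-6)
  }
})

test_that("the A-optimal continuous allocation maximizes Welch power under the budget", {
  # lambda depends on the allocation only through the A-criterion in the
  # denominator, so perturbing the continuous optimum along the budget
  # surface can only reduce lambda
  prob <- random_design_problem(3, seed = 77)
  cont <- attr(a_optimal_design(prob), "continuous")
  lambda <- function(n) prob$K * sum((mean(prob$means) - prob$means)^2) /
    sum(prob$variances / n)
  set.seed(77)
  for (i in 1:30) {
    d <- rnorm(3)
    d <- d - prob$costs * sum(d * prob$costs) / sum(prob$costs^2)
    pert <- cont + 0.05 * sqrt(sum(cont^2)) * d / sqrt(sum(d^2))
    if (any(pert <= 0)) next
    expect_lte(lambda(pert), lambda(cont) + 1e-12)
  }
})

test_that("D-optimal designs maximize the product of group sizes", {
  painN <- pain_problem("fixed_n")
  d <- d_optimal_design(painN)
  expect_identical(as.integer(d), c(10L, 10L, 11L))
  # the tie set holds the permutations of the canonical design
  ties <- attr(d, "ties")
  expect_equal(nrow(ties), 3)
  expect_true(all(apply(ties, 1,
                        function(r) identical(sort(r), c(10L, 10L, 11L)))))
  expect_identical(as.integer(d_optimal_design(pain_problem("budget"))),
                   c(14L, 14L, 5L))
  expect_identical(as.integer(d_optimal_design(asthma_problem("fixed_n"))),
                   c(18L, 18L, 18L, 19L))
  # equal costs with budget K * c * m: all groups get m subjects
  p <- design_problem(means = c(0, 1, 2), variances = c(1, 2, 3),
                      costs = c(10, 10, 10), budget = 300)
  expect_identical(as.integer(d_optimal_design(p)), rep(10L, 3))
})

test_that("the D-optimal argmin ignores common variance rescalings", {
  for (i in 1:5) {
    prob <- random_design_problem(3, seed = 700 + i)
    scaled <- design_problem(means = prob$means,
                             variances = 7.3 * prob$variances,
                             costs = prob$costs, budget = prob$budget)
    expect_identical(as.integer(d_optimal_design(prob)),
                     as.integer(d_optimal_design(scaled)))
  }
})

test_that("the D-optimal design dominates random feasible designs", {
  prob <- design_problem(means = c(0, 0.5, 1), variances = c(1, 2, 3),
                         costs = c(3, 5, 7), budget = 400)
  dopt <- d_optimal_design(prob)
  best <- prod(dopt)
  set.seed(123)
  for (i in 1:1000) {
    n <- c(sample(2:60, 1), sample(2:40, 1), sample(2:30, 1))
    if (is_feasible(n, prob)) expect_lte(prod(n), best)
  }
})
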