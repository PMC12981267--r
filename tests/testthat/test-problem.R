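test_that("problem validation rejects malformed inputs with specific errors", {
  ok <- function(...) design_problem(...)
  base <- list(means = c(0, 1, 2), variances = c(1, 1, 1),
               costs = c(1, 1, 1), budget = 100)
  expect_s3_class(do.call(ok, base), "design_problem")

  expect_error(design_problem(means = rep(0, 7), variances = rep(1, 7),
                              costs = rep(1, 7), budget = 100),
               "between 2 and 6")
  expect_error(design_problem(means = c(0, 1), variances = c(1, 1, 1),
                              costs = c(1, 1), budget = 10),
               "length")
  expect_error(design_problem(means = c(0, 1), variances = c(1, -1),
                              costs = c(1, 1), budget = 10),
               "variances")
  expect_error(design_problem(means = c(0, 1), variances = c(1, 1),
                              costs = c(0, 1), budget = 10),
               "costs")
  expect_error(design_problem(means = c(0, 1), variances = c(1, 1),
                              costs = c(1, 1), budget = 10, min_sizes = 1),
               "at least 2")
  expect_error(design_problem(means = c(0, 1), variances = c(1, 1),
                              costs = c(1, 1), budget = 10,
                              min_sizes = 4, max_sizes = 3),
               "exceed maximum")
  # empty design space: the all-minimum design costs 600 > 500
  expect_error(design_problem(means = c(0, 1, 2), variances = c(1, 1, 1),
                              costs = c(100, 100, 100), budget = 500),
               class = "bfdesign_infeasible_error")
  # fixed total unattainable under the caps fails validation outright
  expect_error(design_problem(means = c(0, 1, 2), variances = c(1, 1, 1),
                              total_n = 50, max_sizes = c(10, 10, 10)),
               class = "bfdesign_infeasible_error")
  expect_error(design_problem(means = c(0, 1), variances = c(1, 1),
                              costs = c(1, 1), budget = 10, total_n = 10),
               "exactly one")
})

test_that("validation fills defaults and is idempotent", {
  p <- design_problem(means = c(0, 1, 2), variances = c(1, 1, 1),
                      costs = c(1, 2, 3), budget = 100)
  expect_identical(p$min_sizes, rep(2, 3))
  expect_identical(p$order, 1:3)
  expect_false(p$fixed_n)
  expect_identical(validate_design_problem(p), p)

  q <- design_problem(means = c(0, 1, 2), variances = c(1, 1, 1),
                      total_n = 30)
  expect_true(q$fixed_n)
  expect_identical(q$costs, rep(1, 3))
  expect_identical(q$budget, 30)
})

test_that("design cost is exact currency arithmetic", {
  fict <- fictional_problem()
  expect_identical(design_cost(c(100, 100, 100), fict), 30000)
  pain <- pain_problem("budget")
  # dollar sums reproduce to the cent despite non-representable doubles
  expect_identical(design_cost(c(9, 16, 6), pain), 101766.22)
  asthma <- asthma_problem("budget")
  expect_identical(design_cost(c(28, 3, 2, 23), asthma), 21639.18)
  expect_identical(design_cost(c(39, 10, 10, 17), asthma), 21682.64)
  # unit design costs the sum of the per-subject costs
  expect_equal(design_cost(rep(1, 3), pain), sum(pain$costs))
  expect_error(design_cost(c(2, 2), pain), "length")
})

test_that("cost is linear in the allocation", {
  set.seed(11)
  p <- random_design_problem(4, seed = 11)
  for (i in 1:20) {
    n <- sample(2:50, 4, replace = TRUE)
    m <- sample(2:50, 4, replace = TRUE)
    expect_equal(design_cost(n + m, p),
                 design_cost(n, p) + design_cost(m, p))
  }
})

test_that("feasibility enforces budget, bounds and exact totals", {
  fict <- fictional_problem()
  expect_true(is_feasible(c(104, 92, 104), fict))    # cost 30000 = B
  expect_false(is_feasible(c(104, 92, 105), fict))   # one subject too many
  expect_false(is_feasible(c(104, 92, 1), fict))     # below minimum size

  asthma10 <- asthma_problem("fixed_n", min_n = 10)
  expect_false(is_feasible(c(20, 2, 2, 49), asthma10))
  expect_true(is_feasible(c(18, 10, 10, 35), asthma10))

  # fixed-N mode: feasible designs spend the whole sample size
  painN <- pain_problem("fixed_n")
  expect_false(is_feasible(c(10, 10, 10), painN))  # sums to 30, not 31
  expect_true(is_feasible(c(10, 10, 11), painN))
  for (i in 1:10) {
    n <- c(10, 10, 11)[sample(3)]
    if (is_feasible(n, painN)) expect_identical(design_cost(n, painN), 31)
  }
})

test_that("config files round-trip through JSON and YAML", {
  json <- system.file("extdata", "pain_budget.json", package = "bfdesign")
  p <- read_design_problem(json)
  expect_identical(p$means, c(17.3, 23.9, 45.9))
  expect_identical(p$budget, 101766.22)
  expect_identical(p$labels, c("NT", "CBT+PCT", "PCT"))

  # the same problem as YAML, with an explicit hypothesis order
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "groups:",
    "  - {label: PCT, mean: 45.9, variance: 528.5401, cost: 6281.18}",
    "  - {label: NT, mean: 17.3, variance: 61.6225, cost: 2328.58}",
    "  - {label: 'CBT+PCT', mean: 23.9, variance: 397.2049, cost: 2695.12}",
    "budget: 101766.22",
    "hypothesis_order: [NT, 'CBT+PCT', PCT]"), yml)
  q <- read_design_problem(yml)
  expect_identical(q$order, c(2L, 3L, 1L))
  # the permuted problem computes the same Bayes factor as the sorted one
  expect_equal(bayes_factor(q, c(6, 9, 16))$bf_1c,
               bayes_factor(p, c(9, 16, 6))$bf_1c, tolerance = 1e-10)

  expect_error(read_design_problem(file.path(tempdir(), "nope.json")),
               class = "bfdesign_io_error")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"budget": 10}', bad)
  expect_error(read_design_problem(bad), class = "bfdesign_config_error")
})
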