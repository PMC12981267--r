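# Canonical problems used across the suite, built in code.

# fictional three-group study: unit variances, equal costs, small equally
# spaced effects
fictional_problem <- function(fixed_n = FALSE) {
  if (fixed_n)
    design_problem(means = c(0.2, 0.4, 0.6), variances = c(1, 1, 1),
                   total_n = 300)
  else
    design_problem(means = c(0.2, 0.4, 0.6), variances = c(1, 1, 1),
                   costs = c(100, 100, 100), budget = 30000)
}

# pain-management study: three treatments, heteroscedastic, n = 31 total
pain_problem <- function(mode = c("fixed_n", "budget")) {
  mode <- match.arg(mode)
  means <- c(17.3, 23.9, 45.9)
  variances <- c(7.85, 19.93, 22.99)^2
  labels <- c("NT", "CBT+PCT", "PCT")
  if (mode == "fixed_n")
    design_problem(means, variances, total_n = 31, labels = labels)
  else
    design_problem(means, variances, costs = c(2328.58, 2695.12, 6281.18),
                   budget = 101766.22, labels = labels)
}

# asthma study: 2x2 factorial, four groups in hypothesized order of means
asthma_problem <- function(mode = c("fixed_n", "budget"), min_n = 2) {
  mode <- match.arg(mode)
  means <- c(0.13, 0.38, 0.42, 1.23)
  variances <- c(0.34, 0.77, 0.72, 0.83)^2
  labels <- c("CL", "CH", "AH", "AL")
  if (mode == "fixed_n")
    design_problem(means, variances, total_n = 73, min_sizes = min_n,
                   labels = labels)
  else
    design_problem(means, variances,
                   costs = c(82.94, 242.44, 267.96, 784.94),
                   budget = 21692.00, min_sizes = min_n, labels = labels)
}

# frozen Monte Carlo oracle values (1e7 independent draws, seed 20250925),
# computed once with plain rnorm sampling outside the package code path;
# tolerances are 4 binomial standard errors
mc_oracle <- list(
  pain_fit = list(value = 0.8606396, tol = 4 * 1.10e-4),
  pain_complexity = list(value = 0.1818675, tol = 4 * 1.22e-4),
  fictional_fit = list(value = 0.8430607, tol = 4 * 1.16e-4)
)

# tolerance for reproducing a Bayes factor printed to one decimal
bf_print_tol <- function(printed) max(0.1, 0.02 * printed)

# all permutations of 1:K, for summing ordering probabilities
permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (sub in permutations_of(K - 1)) {
    for (pos in 0:(K - 1)) {
      out[[length(out) + 1L]] <- as.integer(append(sub, K, after = pos))
    }
  }
  out
}
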