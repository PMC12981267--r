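---
title: "Planning group sizes that maximize the Bayes factor for an ordered-means hypothesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning group sizes that maximize the Bayes factor for an ordered-means hypothesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfdesign)
```

## The design problem

A study compares the mean of a continuous outcome across $K$ independent
groups ($2 \le K \le 6$), with subject $j$ in group $k$ modeled as

$$y_{jk} \sim N(\mu_k, \sigma_k^2),$$

allowing both the means and the within-group variances to differ. The group
means are estimated by the group averages, whose covariance is the diagonal
matrix with entries $\sigma_k^2 / n_k$. A design $\xi = (n_1, \dots, n_K)$ is
a vector of integer group sizes constrained by a budget,
$\sum_k c_k n_k \le B$, where $c_k$ is the per-subject cost in group $k$;
the familiar fixed-total-sample-size problem is the special case $c_k = 1$,
$B = N$, where feasible designs must additionally exhaust $N$ exactly
(with unit costs there is never a reason to leave subjects unused). Group
sizes of at least 2 are always required so that each within-group variance
remains estimable.

Rather than powering the classical null-hypothesis $F$ test, the design
criterion here is the evidence the planned study is expected to provide for
an *informative* hypothesis that orders the means,

$$H_1:\ \mu_1 < \mu_2 < \dots < \mu_K,$$

tested against its complement $H_{1c}$ (all other orderings), quantified by
a Bayes factor. The inputs are a priori values for the $\mu_k$ and
$\sigma_k^2$ — from a pilot, the literature, or expert judgment — plus costs
and a budget. The package searches the integer design space exhaustively for
the allocation that maximizes this Bayes factor and compares it with three
classical benchmarks.

## The Bayes factor for an ordering

For an inequality-constrained hypothesis the Bayes factor against the
complement is

$$BF_{1c} = \frac{f_1 / c_1}{(1 - f_1) / (1 - c_1)},$$

where the *fit* $f_1$ is the posterior probability mass in agreement with
the ordering and the *complexity* $c_1$ is the corresponding prior mass.
Both are computed from normal approximations in the style of the
approximated adjusted fractional Bayes factor: the posterior of $\mu$ is
$N(\hat\mu, \mathrm{diag}(\hat\sigma_k^2 / n_k))$ and the prior is centered
at zero mean differences with covariance equal to a fraction-inflated copy
of the posterior covariance, $\mathrm{diag}(\hat\sigma_k^2 / (b\, n_k))$. At
the design stage the a priori means and variances are plugged in for
$\hat\mu_k$ and $\hat\sigma_k^2$.

Two conventions for the fraction coexist in the fractional-Bayes-factor
literature: a *common* fraction $b$ of the full likelihood, which makes the
prior covariance proportional to the posterior covariance, and *group-wise*
fractions $b_k \propto 1/n_k$, which make the prior variances proportional
to $\sigma_k^2$ alone and hence make the complexity independent of the
allocation. The two agree for balanced designs but differ for unbalanced
ones. This package adopts the common-fraction convention (reported by
`prior_spec()` as $b = J/N$ with $J = K - 1$, the minimal fraction for the
$J$ constraints of the corresponding equality null): the prior then carries
the same relative information structure as the design itself, the complexity
reflects how the allocation shapes the a priori chance of the ordering, and
the resulting Bayes factors reproduce the published values of the worked
examples that this package's acceptance suite checks, which the group-wise
convention does not. Because the prior means are zero, any *common* positive
rescaling of the prior variances leaves $c_1$ unchanged, so the value of $b$
itself never matters for pure inequality constraints; only the relative
prior variances do. With equal prior variances — equal $\sigma_k^2 / n_k$ —
every ordering is equally likely a priori and $c_1 = 1/K!$.

### Ordering probabilities

Both $f_1$ and $c_1$ are probabilities of the event
$X_1 < X_2 < \dots < X_K$ for independent normals. The package evaluates
them deterministically by mapping the event to the positive orthant of the
successive differences $D_j = X_{j+1} - X_j$, a $(K-1)$-variate normal with
tridiagonal covariance ($\mathrm{Var}\, D_j = v_j + v_{j+1}$,
$\mathrm{Cov}(D_j, D_{j+1}) = -v_{j+1}$). Orthant probabilities come from
`mvtnorm`: the deterministic TVPACK quadrature in dimensions 2–3 and the
Miwa recursive-integration algorithm in dimensions 4–5, both with absolute
error far below the advertised `abs_tol = 1e-7`. A seeded Monte Carlo
backend (`ordering_probability_mc()`) mirrors the simulation approach of
sampling-based Bayes-factor software and serves as an independent
cross-check in the test suite.

The exhaustive search evaluates the same problem at up to a few hundred
thousand allocations, so the search path uses vectorized kernels: a
Gauss–Legendre quadrature of the Plackett identity for batches of bivariate
orthants ($K = 3$; 48 nodes, switching to per-design TVPACK when
$|\rho| > 0.925$), and the arcsine closed forms
$\tfrac14 + \tfrac{\arcsin\rho}{2\pi}$ and
$\tfrac18 + \tfrac{\arcsin\rho_{12} + \arcsin\rho_{23}}{4\pi}$ for the
zero-mean complexities at $K = 3, 4$ (the non-adjacent difference
correlation vanishes). These kernels are tested to agree with the
per-design path to at least `1e-7`.

### Interpreting the Bayes factor

`interpret_bf()` maps $BF_{1c}$ to the conventional ten-category verbal
scale (mild / substantial / strong / very strong / decisive, on either side
of 1). The published ranges touch at 3, 10, 30 and 100; the package
deterministically assigns a boundary value to the lower-support bin on its
side of 1 — bins $(1,3], (3,10], (10,30], (30,100], (100,\infty)$ and their
mirror images — and labels $BF_{1c} = 1$ "Mild support for H1". The scale is
a reading aid, not a decision rule.

## Classical benchmark designs

Three allocations from the significance-testing framework are derived for
comparison:

* **Equal sizes** — $n = \lfloor B / \sum_k c_k \rfloor$ per group
  (fixed total: $\lfloor N/K \rfloor$), the floor taken when fractional.
* **A-optimal** — minimizes $\sum_k \sigma_k^2 / n_k$, the trace of the
  covariance of the mean estimates; equivalently maximizes the Welch
  noncentrality $\lambda = K \sum_k (\bar\mu - \mu_k)^2 \big/ \sum_k
  (\sigma_k^2/n_k)$, whose numerator the allocation cannot touch. The
  continuous solution follows the square-root rule
  $n_k / n_1 = \sqrt{(\sigma_k^2/\sigma_1^2)(c_1/c_k)}$.
* **D-optimal** — minimizes $\prod_k \sigma_k^2 / n_k$, the determinant
  (confidence-ellipsoid volume); since variances only rescale the product,
  this simply maximizes $\prod_k n_k$ and is found by exact enumeration
  rather than a continuous solver, so it is immune to solver local optima.

$\bar\mu$ in $\lambda$ is the unweighted mean of the $K$ a priori group
means; $\lambda$ is reported for orientation only and no derived design
depends on this choice.

Continuous allocations must be rounded to integers, and the rounding rule is
genuinely open design space: the package floors the continuous sizes and
then grants one extra subject per group in decreasing order of fractional
remainder, skipping any increment that would break the budget or a maximum
size (fixed total: until the sizes sum to $N$). Groups whose continuous
allocation violates a bound are clamped first and the budget re-spread over
the rest. This single-pass largest-remainder repair is deterministic and
reproduces the published A-optimal allocations of the worked examples; it is
a heuristic, and for strongly heterogeneous costs the true integer A-optimum
can differ by a subject or two — users who care can enumerate, as the
D-optimal path does.

## The search

`bf_optimal_design()` enumerates the feasible integer designs in
lexicographic order and keeps the running best and a top-*m* list
(default $m = 5$: the optimum plus four near-alternatives). No closed form
for the optimum exists, and the space is desk-scale for $K \le 6$, so
exhaustive search is both exact and affordable. Budget-mode enumeration
prunes to the cost window $B - c_{\max} \le \sum_k c_k n_k \le B$: any
cheaper design can still afford one more subject in *any* group, and adding
a subject can only help the criteria considered here, so no optimum is lost
(when finite maximum sizes place the all-maximum design below that window,
the window is widened to include it). Fixed-total mode enumerates exact
compositions of $N$. Enumeration is chunked (50 000 designs per block by
default), so memory stays bounded regardless of the space's size, and the
full design stream is never materialized unless explicitly requested.

Currency is exact: costs and budgets are interpreted in integer cents, so
feasibility at the boundary (designs that spend the budget to the cent)
never depends on floating-point rounding, and budget-mode optima may
legitimately cost slightly less than $B$ when the budget is not exactly
attainable in integers.

Designs whose Bayes factors agree within a relative $10^{-9}$ are treated as
ties — symmetric problems genuinely produce mirror-image optima — and all
are reported, the lexicographically smallest taken as canonical.

## Sensitivity sweeps

`sweep_parameter()` re-derives all four designs while one group's cost,
mean or variance runs over a grid, each grid point recomputed independently
from a freshly validated problem. The qualitative patterns the sweeps expose
— Bayes factors falling with cost and variance and rising with the mean gap,
the BF-optimal design shifting subjects away from expensive or
well-separated groups and into high-variance ones, the classical designs'
indifference to the means — are asserted as weak monotonicity on coarse
grids in the acceptance suite. `plot()` on a sweep draws the group-size and
Bayes-factor panels; CSV/JSON via `write_results()` are the canonical
outputs.

## The fixture generator

`random_design_problem()` draws reproducible problems for property-style
testing: sorted standard-normal means (unit-scale effects), variances
log-uniform on $[0.25, 4]$ (up to 16-fold variance heterogeneity, matching
the span seen in applied examples), costs log-uniform on $[50, 800]$
currency units, and a budget targeting 20–200 subjects per group for the
equal design — the range where such multi-group studies are typically run.
The generator emulates the *planning* situation only: independent groups,
known-in-advance parameter values, normal outcomes. It does not emulate
misspecified a priori values, non-normal outcomes, dropout, or dependence
between groups, so passing property tests certify the design machinery, not
robustness of a chosen design to wrong inputs; for the latter, sweep the
inputs.

## Numerical choices and degenerate inputs

* Orthant tolerance `1e-7` absolute; batch kernels agree with the
  per-design path to the same order.
* A fit within $10^{-12}$ of 1 yields `bf_1c = Inf` with a `diverged` flag
  and the decisive label, rather than a division by zero.
* Validation rejects empty design spaces up front (the all-minimum design
  must fit the budget; a fixed total must lie between the bound sums), and
  rejects fixed-total problems whose caps make $\sum n_k = N$ unattainable
  rather than silently relaxing the total.
* Monte Carlo backends require at least $10^4$ draws and restore the
  caller's RNG state.

## Problem sizes exercised by the tests

The bundled examples span the sizes this methodology meets in practice:
three-group searches over $\approx 4.4 \times 10^4$ compositions
(fixed $N = 300$), four-group searches over $5 \times 10^4$ compositions
(fixed $N = 73$) and $\approx 2.2 \times 10^5$ budget-window designs, plus
batteries of 100 randomized three-group problems. These were chosen as
representative desk-scale workloads; larger spaces only scale linearly in
enumeration time.

## Known limitations

* Hypotheses are single full orderings. Equality constraints ("about
  equal" groups), multiple competing informative hypotheses, and
  order-uncertainty-robust (maximin-style) designs are out of scope.
* Outcomes are continuous and normal; binary outcomes or
  covariate-adjusted (regression) settings are not supported.
* The BF-optimal design is optimal *for the supplied a priori values*; if
  the true ordering differs, the design can perform poorly. Sweeps are the
  built-in sensitivity tool.
* The A-optimal integer rounding is a largest-remainder heuristic, exact
  rounding of the well-known continuous rule rather than exact integer
  optimization.
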