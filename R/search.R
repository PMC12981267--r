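# Exhaustive enumeration of the integer design space and the Bayes-factor
# search. Budget mode prunes to the cost window [B - cmax, B]: any design
# cheaper than B - cmax can still take one more subject in any group, so it
# cannot be optimal. Fixed-total mode enumerates exact compositions of N.

#' Enumerate the feasible design space
#'
#' Yields every design in the pruned design space in deterministic
#' lexicographic order: all integer allocations within the min/max bounds
#' with total cost in the window \eqn{[B - c_{max}, B]} (budget mode) or
#' summing exactly to \eqn{N} (fixed-total mode). Enumeration is chunked:
#' designs are produced in blocks bounded by \code{chunk_size} rows, so the
#' full space never needs to be materialized when a \code{chunk_fun} is
#' supplied.
#'
#' @param problem a [design_problem()].
#' @param chunk_fun optional \code{function(sizes_matrix)} called on each
#'   block of designs (one design per row). When supplied, the function's
#'   side effects are the output and \code{NULL} is returned invisibly.
#' @param chunk_size target number of rows per block.
#' @return with \code{chunk_fun = NULL}, an integer matrix with one design
#'   per row and K columns; otherwise \code{NULL}, invisibly.
#' @examples
#' prob <- design_problem(means = c(0, 1), variances = c(1, 1), total_n = 4)
#' enumerate_designs(prob)  # the single composition (2, 2)
#' @export
enumerate_designs <- function(problem, chunk_fun = NULL,
                              chunk_size = 50000L) {
  problem <- validate_design_problem(problem)
  collect <- is.null(chunk_fun)
  out <- if (collect) vector("list", 0L)
  sink <- function(block) {
    if (collect) out[[length(out) + 1L]] <<- block else chunk_fun(block)
  }
  walk_designs(problem, sink, chunk_size)
  if (collect) {
    if (!length(out)) matrix(integer(0), 0L, problem$K)
    else do.call(rbind, out)
  } else invisible(NULL)
}

# core enumerator: recursive over the first K-2 groups, vectorized over the
# last two; emits integer matrices of at most ~chunk_size rows
walk_designs <- function(problem, sink, chunk_size) {
  K <- problem$K
  cents <- as.numeric(cost_cents(problem))
  cap <- budget_cents(problem)
  mins <- as.integer(problem$min_sizes)
  maxs <- problem$max_sizes
  if (problem$fixed_n) {
    lo_w <- cap  # unit costs: the window degenerates to cost == N
  } else {
    lo_w <- cap - max(cents)
    # a generous budget can place the all-maximum design below the usual
    # window; lower the window so the dominant corner is still enumerated
    if (all(is.finite(maxs))) lo_w <- min(lo_w, sum(cents * maxs))
  }
  buf <- vector("list", 0L)
  buf_n <- 0L
  flush <- function() {
    if (buf_n > 0L) {
      sink(do.call(rbind, buf))
      buf <<- vector("list", 0L)
      buf_n <<- 0L
    }
  }
  emit <- function(block) {
    mode(block) <- "integer"
    buf[[length(buf) + 1L]] <<- block
    buf_n <<- buf_n + nrow(block)
    if (buf_n >= chunk_size) flush()
  }
  # tail_min[j]: minimal cents needed for groups j..K at their minimum sizes
  tail_min <- rev(cumsum(rev(cents * mins)))
  rec <- function(prefix, spent, depth) {
    if (depth == K - 1L) {
      # vectorize the last two groups in one shot
      k1 <- K - 1L; k2 <- K
      hi1 <- floor((cap - spent - cents[k2] * mins[k2]) / cents[k1])
      hi1 <- min(hi1, maxs[k1])
      if (problem$fixed_n)
        hi1 <- min(hi1, problem$total_n - sum(prefix) - mins[k2])
      if (hi1 < mins[k1]) return()
      a <- mins[k1]:hi1
      if (problem$fixed_n) {
        b_lo <- b_hi <- problem$total_n - sum(prefix) - a
        ok <- b_lo >= mins[k2] & b_lo <= maxs[k2]
      } else {
        left <- cap - spent - cents[k1] * a
        b_lo <- pmax(mins[k2],
                     ceiling((lo_w - spent - cents[k1] * a) / cents[k2]))
        b_hi <- pmin(maxs[k2], floor(left / cents[k2]))
        ok <- b_hi >= b_lo
      }
      if (!any(ok)) return()
      a <- a[ok]; b_lo <- b_lo[ok]; b_hi <- b_hi[ok]
      counts <- b_hi - b_lo + 1
      block <- matrix(0L, sum(counts), K)
      if (depth > 1L)
        block[, seq_len(depth - 1L)] <- matrix(prefix, sum(counts),
                                               depth - 1L, byrow = TRUE)
      block[, k1] <- rep(a, counts)
      block[, k2] <- sequence(counts, from = b_lo)
      emit(block)
      return()
    }
    hi <- floor((cap - spent - tail_min[depth + 1L]) / cents[depth])
    hi <- min(hi, maxs[depth])
    if (problem$fixed_n)
      hi <- min(hi, problem$total_n - sum(prefix) -
                  sum(mins[(depth + 1L):K]))
    if (hi < mins[depth]) return()
    for (a in mins[depth]:hi)
      rec(c(prefix, a), spent + cents[depth] * a, depth + 1L)
  }
  rec(integer(0), 0L, 1L)
  flush()
  invisible(NULL)
}

# generic chunked maximization over the design space; `objective` maps a
# sizes matrix to a numeric vector. Designs within a relative tolerance of
# the maximum count as tied; rows are visited in lexicographic order.
search_designs <- function(problem, objective, top_m = 5L,
                           rel_tol = 1e-9, verbose = FALSE) {
  best_val <- -Inf
  best <- NULL
  top <- NULL           # data.frame of running top candidates
  n_eval <- 0L
  last_report <- 0L
  keep_n <- max(top_m + 8L, 32L)
  step <- function(sizes) {
    val <- objective(sizes)
    n_eval <<- n_eval + nrow(sizes)
    if (verbose && n_eval - last_report >= 1e4) {
      message("evaluated ", n_eval, " designs; best so far ",
              format(max(best_val, max(val)), digits = 6))
      last_report <<- n_eval
    }
    keep <- utils::head(order(-val), keep_n)
    cand <- data.frame(sizes[keep, , drop = FALSE], value = val[keep])
    top <<- if (is.null(top)) cand else rbind(top, cand)
    top <<- utils::head(top[order(-top$value), , drop = FALSE], keep_n)
    mx <- val[keep[1L]]
    tol <- if (!is.finite(mx)) 0
           else rel_tol * max(1, abs(mx),
                              if (is.finite(best_val)) abs(best_val) else 0)
    if (mx > best_val + tol || is.null(best)) {
      tied_old <- if (!is.null(best) && best_val >= mx - tol) best else NULL
      best <<- rbind(tied_old,
                     sizes[keep[val[keep] >= mx - tol], , drop = FALSE])
      best_val <<- max(best_val, mx)
    } else if (mx >= best_val - tol) {
      best <<- rbind(best,
                     sizes[keep[val[keep] >= best_val - tol], ,
                           drop = FALSE])
    }
  }
  enumerate_designs(problem, chunk_fun = step)
  if (n_eval == 0L) stop_infeasible("the pruned design space is empty")
  # lexicographic canonical order within the tie set
  best <- best[do.call(order, as.data.frame(best)), , drop = FALSE]
  best <- best[!duplicated(best), , drop = FALSE]
  rownames(top) <- NULL
  list(best = best, best_value = best_val,
       top = utils::head(top, top_m), n_evaluated = n_eval)
}

#' Find the Bayes-factor-optimal design
#'
#' Evaluates \eqn{BF_{1c}} at every design in the pruned design space and
#' returns the maximizer together with the near-optimal alternatives. The
#' search is exhaustive and deterministic; designs whose Bayes factors agree
#' within relative 1e-9 are reported as ties, with the lexicographically
#' smallest taken as canonical.
#'
#' @param problem a [design_problem()].
#' @param top_m number of top designs to report (default 5: the optimum and
#'   four designs that perform almost as well).
#' @param verbose log progress every 1e4 evaluations.
#' @return an object of class \code{"bf_search"}: a list with \code{best}
#'   (matrix of tied optimal designs, canonical row first), \code{best_bf},
#'   \code{top} (data frame of the \code{top_m} best designs with their cost
#'   and Bayes factor), \code{n_evaluated}, \code{mode} and
#'   \code{pruning_window}.
#' @examples
#' pain <- design_problem(means = c(17.3, 23.9, 45.9),
#'                        variances = c(61.6225, 397.2049, 528.5401),
#'                        total_n = 31)
#' bf_optimal_design(pain)
#' @export
bf_optimal_design <- function(problem, top_m = 5L, verbose = FALSE) {
  problem <- validate_design_problem(problem)
  m <- problem$means[problem$order]
  v <- problem$variances[problem$order]
  ord <- problem$order
  objective <- function(sizes) {
    parts <- bf_batch(m, v, sizes[, ord, drop = FALSE])
    f <- parts$fit
    c1 <- parts$complexity
    bf <- (f / c1) / ((1 - f) / (1 - c1))
    # same numerical-ceiling sentinel as bayes_factor()
    bf[f >= 1 - 1e-12] <- Inf
    bf
  }
  res <- search_designs(problem, objective, top_m = top_m, verbose = verbose)
  top <- res$top
  names(top) <- c(problem$labels, "bf")
  top$cost <- apply(top[, seq_len(problem$K), drop = FALSE], 1L,
                    design_cost, problem = problem)
  top <- top[, c(problem$labels, "cost", "bf")]
  structure(list(best = res$best, best_bf = res$best_value, top = top,
                 n_evaluated = res$n_evaluated,
                 mode = if (problem$fixed_n) "fixed-n" else "budget",
                 pruning_window = if (problem$fixed_n)
                   c(problem$total_n, problem$total_n)
                 else c(problem$budget - max(problem$costs), problem$budget),
                 problem = problem),
            class = "bf_search")
}

#' @export
print.bf_search <- function(x, digits = 4, ...) {
  cat("Bayes-factor-optimal design search (", x$mode, " mode)\n", sep = "")
  cat("  designs evaluated:", x$n_evaluated, "\n")
  cat("  best design: (", paste(x$best[1L, ], collapse = ", "),
      ")  BF_1c = ", format(x$best_bf, digits = digits), "\n", sep = "")
  if (nrow(x$best) > 1L)
    cat("  ", nrow(x$best), "designs tie within relative 1e-9\n")
  cat("  top designs:\n")
  print(format(x$top, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.bf_search <- function(object, ...) {
  cat("Search over", object$n_evaluated, "designs in", object$mode,
      "mode; cost window [",
      paste(format(object$pruning_window, nsmall = 2), collapse = ", "),
      "]\n")
  ev <- evaluate_design(object$problem, object$best[1L, ])
  print(ev)
  invisible(ev)
}

#' Evaluate one design on every criterion
#'
#' Collects, for a single allocation, its cost, A- and D-criterion values,
#' Welch noncentrality and the order-hypothesis Bayes factor.
#'
#' @inheritParams bf_fit
#' @return an object of class \code{"design_evaluation"}.
#' @export
evaluate_design <- function(problem, sizes) {
  check_sizes(sizes, problem)
  structure(list(sizes = as.integer(sizes),
                 feasible = is_feasible(sizes, problem),
                 cost = design_cost(sizes, problem),
                 a_value = a_criterion(problem, sizes),
                 d_value = d_criterion(problem, sizes),
                 welch_lambda = welch_noncentrality(problem, sizes),
                 bf = bayes_factor(problem, sizes),
                 problem = problem),
            class = "design_evaluation")
}

#' @export
print.design_evaluation <- function(x, digits = 4, ...) {
  cat("Design (", paste(x$sizes, collapse = ", "), ")",
      if (!x$feasible) "  [infeasible for this problem]", "\n", sep = "")
  cat("  total n =", sum(x$sizes),
      "  cost =", format(x$cost, nsmall = 2), "\n")
  cat("  A-criterion =", format(x$a_value, digits = digits),
      "  D-criterion =", format(x$d_value, digits = digits),
      "  Welch lambda =", format(x$welch_lambda, digits = digits), "\n")
  cat("  BF_1c =", format(x$bf$bf_1c, digits = digits),
      paste0("(", x$bf$label, ")"), "\n")
  invisible(x)
}

#' Compare the equal, A-, D- and BF-optimal designs
#'
#' Derives all four allocations for one problem and tabulates their group
#' sizes, cost, criterion values and Bayes factors; optionally a
#' user-supplied design (for instance the allocation of an already published
#' study) is evaluated alongside.
#'
#' @param problem a [design_problem()].
#' @param extra_design optional integer length-K design to include as its own
#'   row.
#' @param extra_label row label for \code{extra_design}.
#' @param top_m passed to [bf_optimal_design()].
#' @return a data frame of class \code{"design_comparison"} with one row per
#'   design and columns for the sizes, total n, cost, A/D criteria, Welch
#'   noncentrality, fit, complexity, Bayes factor and its interpretation. The
#'   full search result is attached as attribute \code{"search"}.
#' @examples
#' pain <- design_problem(means = c(17.3, 23.9, 45.9),
#'                        variances = c(61.6225, 397.2049, 528.5401),
#'                        total_n = 31)
#' compare_designs(pain, extra_design = c(9, 16, 6),
#'                 extra_label = "original study")
#' @export
compare_designs <- function(problem, extra_design = NULL,
                            extra_label = "user design", top_m = 5L) {
  problem <- validate_design_problem(problem)
  search <- bf_optimal_design(problem, top_m = top_m)
  designs <- list(equal = equal_design(problem),
                  `A-optimal` = as.integer(a_optimal_design(problem)),
                  `D-optimal` = d_optimal_design(problem),
                  `BF-optimal` = search$best[1L, ])
  if (!is.null(extra_design)) {
    designs <- c(stats::setNames(list(as.integer(extra_design)), extra_label),
                 designs)
  }
  rows <- lapply(names(designs), function(nm) {
    ev <- evaluate_design(problem, designs[[nm]])
    sz <- as.list(ev$sizes)
    names(sz) <- problem$labels
    data.frame(design = nm, sz, total_n = sum(ev$sizes), cost = ev$cost,
               a_value = ev$a_value, d_value = ev$d_value,
               welch_lambda = ev$welch_lambda, fit = ev$bf$fit,
               complexity = ev$bf$complexity, bf = ev$bf$bf_1c,
               interpretation = ev$bf$label, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "search") <- search
  class(out) <- c("design_comparison", "data.frame")
  out
}

#' @export
print.design_comparison <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) signif(col, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
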