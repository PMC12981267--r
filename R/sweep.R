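# Parameter sweeps: re-derive all four designs while one group's cost, mean
# or variance moves over a grid. Each grid point is recomputed independently
# from a freshly validated problem, so results are deterministic and grid
# points could be distributed across workers.

#' Sweep one parameter of one group across a grid
#'
#' For every value in \code{grid}, replaces the chosen parameter
#' (per-subject cost, a priori mean or within-group variance) of one group,
#' re-validates the problem and recomputes the equal, A-optimal, D-optimal
#' and BF-optimal designs with their Bayes factors. This is the engine
#' behind cost/mean/variance sensitivity analyses of the optimal design.
#'
#' @param problem the base [design_problem()].
#' @param parameter one of \code{"cost"}, \code{"mean"}, \code{"variance"}.
#' @param group index (1..K) of the group whose parameter is swept.
#' @param grid strictly increasing numeric vector of parameter values.
#' @return an object of class \code{"design_sweep"}: a list with
#'   \code{parameter}, \code{group}, \code{grid} and \code{table}, a long
#'   data frame with one row per grid point and design type.
#' @examples
#' \donttest{
#' base <- design_problem(means = c(0.2, 0.4, 0.6), variances = c(1, 1, 1),
#'                        costs = c(100, 100, 100), budget = 30000)
#' sw <- sweep_parameter(base, "cost", group = 3, grid = c(50, 100, 200))
#' subset(sw$table, design == "BF-optimal")
#' }
#' @export
sweep_parameter <- function(problem,
                            parameter = c("cost", "mean", "variance"),
                            group, grid) {
  problem <- validate_design_problem(problem)
  parameter <- match.arg(parameter)
  if (length(group) != 1L || !group %in% seq_len(problem$K))
    stop_config("`group` must be a single index in 1:", problem$K)
  if (length(grid) < 1L || is.unsorted(grid, strictly = TRUE))
    stop_config("`grid` must be strictly increasing")
  if (parameter != "mean" && any(grid <= 0))
    stop_config("cost and variance grids must be positive")
  if (parameter == "cost" && problem$fixed_n)
    stop_config("cannot sweep costs of a fixed-total-N problem")
  rows <- lapply(grid, function(value) {
    p <- problem
    field <- switch(parameter, cost = "costs", mean = "means",
                    variance = "variances")
    p[[field]][group] <- value
    p <- validate_design_problem(p)
    cmp <- compare_designs(p)
    data.frame(value = value, as.data.frame(cmp), check.names = FALSE)
  })
  table <- do.call(rbind, rows)
  names(table)[1L] <- parameter
  rownames(table) <- NULL
  structure(list(parameter = parameter, group = group, grid = grid,
                 table = table, problem = problem),
            class = "design_sweep")
}

#' @export
print.design_sweep <- function(x, digits = 4, ...) {
  cat("Sweep of", x$parameter, "in group", x$group, "over",
      length(x$grid), "grid points\n")
  df <- x$table
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) signif(col, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.design_sweep <- function(x, ...) {
  K <- x$problem$K
  labels <- x$problem$labels
  types <- unique(x$table$design)
  old <- graphics::par(mfrow = c(2, ceiling((length(types) + 1) / 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (tp in types) {
    sub <- x$table[x$table$design == tp, ]
    sizes <- as.matrix(sub[, labels])
    graphics::matplot(sub[[x$parameter]], sizes, type = "b", pch = seq_len(K),
                      lty = 1, xlab = x$parameter, ylab = "group size",
                      main = tp, ...)
  }
  bf <- stats::reshape(x$table[, c(x$parameter, "design", "bf")],
                       direction = "wide", idvar = x$parameter,
                       timevar = "design")
  graphics::matplot(bf[[x$parameter]], as.matrix(bf[, -1L]), type = "b",
                    pch = seq_along(types), lty = 1, xlab = x$parameter,
                    ylab = "Bayes factor", main = "Bayes factors", ...)
  graphics::legend("topright", legend = types, pch = seq_along(types),
                   col = seq_along(types), bty = "n", cex = 0.8)
  invisible(x)
}

#' Write results to CSV or JSON
#'
#' Serializes a [compare_designs()] table, a [bf_optimal_design()] search
#' result or a [sweep_parameter()] result. JSON output is lossless (full
#' double precision) and round-trips through \code{jsonlite}; CSV output is
#' a flat table with numeric columns at 6 significant digits.
#'
#' @param x the object to write.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}; default guessed from the
#'   file extension.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else stop_config("cannot guess format from extension of ", path)
  }
  flat <- function(obj) {
    if (inherits(obj, "design_sweep")) obj$table
    else if (inherits(obj, "bf_search")) obj$top
    else if (inherits(obj, "design_comparison")) as.data.frame(obj)
    else if (is.data.frame(obj)) obj
    else stop_config("cannot serialize objects of class ",
                     paste(class(obj), collapse = "/"))
  }
  if (format == "csv") {
    df <- flat(x)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(col) signif(col, 6))
  } else {
    payload <- if (inherits(x, "bf_search"))
      list(best = x$best, best_bf = x$best_bf, top = x$top,
           n_evaluated = x$n_evaluated, mode = x$mode,
           pruning_window = x$pruning_window)
    else flat(x)
  }
  ok <- tryCatch({
    if (format == "csv") utils::write.csv(df, path, row.names = FALSE)
    else jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                              dataframe = "columns")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io("failed to write ", path, ": ",
                           conditionMessage(ok))
  invisible(path)
}
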