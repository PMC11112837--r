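SWEEPABLE <- c("screening_cost", "transport_cost_round_trip",
               "patient_time_hours", "time_cost_per_hour", "visits",
               "transport_trips_per_visit")

#' Define a parameter grid for a sensitivity analysis
#'
#' @param strategy name of the strategy whose parameter is varied
#'   (must match the `name` of one of the base strategies).
#' @param parameter one of the [screening_strategy()] numeric fields.
#' @param values ordered numeric vector of values to evaluate (non-empty,
#'   finite). `grid_seq()` builds an inclusive equally spaced grid.
#' @return A `parameter_grid` list.
#' @export
parameter_grid <- function(strategy, parameter, values) {
  if (!parameter %in% SWEEPABLE)
    stop(sprintf("unknown parameter '%s'; one of: %s", parameter,
                 paste(SWEEPABLE, collapse = ", ")), call. = FALSE)
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("grid values must be non-empty and finite", call. = FALSE)
  structure(list(strategy = strategy, parameter = parameter, values = values),
            class = "parameter_grid")
}

#' @rdname parameter_grid
#' @param min,max inclusive endpoints.
#' @param steps number of grid points (>= 2).
#' @export
grid_seq <- function(strategy, parameter, min, max, steps = 25L) {
  parameter_grid(strategy, parameter, seq(min, max, length.out = steps))
}

# substitute one parameter value into a copy of whichever base matches
substitute_param <- function(a, b, grid, value) {
  if (identical(grid$strategy, a$name)) {
    a[[grid$parameter]] <- value
  } else if (identical(grid$strategy, b$name)) {
    b[[grid$parameter]] <- value
  } else {
    stop(sprintf("grid strategy '%s' matches neither base ('%s', '%s')",
                 grid$strategy, a$name, b$name), call. = FALSE)
  }
  list(a = a, b = b)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates both strategies' per-patient totals and their difference
#' at each value of one varied parameter; the base strategies are never
#' mutated.
#'
#' @param base_a,base_b base [screening_strategy()] objects (the
#'   difference is `total_a - total_b`; positive favours `b`).
#' @param grid a [parameter_grid()].
#' @return A `sweep_result` data frame: `value`, `total_a`, `total_b`,
#'   `difference`, with the grid recorded in attributes.
#' @export
one_way_sweep <- function(base_a, base_b, grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  rows <- lapply(grid$values, function(v) {
    s <- substitute_param(base_a, base_b, grid, v)
    ta <- per_patient_cost(s$a)$per_patient_total
    tb <- per_patient_cost(s$b)$per_patient_total
    data.frame(value = v, total_a = ta, total_b = tb, difference = ta - tb)
  })
  out <- do.call(rbind, rows)
  attr(out, "grid") <- grid
  attr(out, "strategies") <- c(a = base_a$name, b = base_b$name)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Two-way deterministic sensitivity analysis
#'
#' Full cartesian product of two parameter grids; entry `(i, j)` of each
#' result matrix uses `grid1$values[i]` and `grid2$values[j]`.
#'
#' @param base_a,base_b base [screening_strategy()] objects.
#' @param grid1,grid2 [parameter_grid()]s over two distinct
#'   (strategy, parameter) targets.
#' @return A `sweep_result2` list of matrices `total_a`, `total_b`,
#'   `difference` (rows = `grid1`, columns = `grid2`).
#' @export
two_way_sweep <- function(base_a, base_b, grid1, grid2) {
  stopifnot(inherits(grid1, "parameter_grid"), inherits(grid2, "parameter_grid"))
  if (identical(grid1$strategy, grid2$strategy) &&
      identical(grid1$parameter, grid2$parameter))
    stop("the two grids must vary distinct parameters", call. = FALSE)
  n1 <- length(grid1$values); n2 <- length(grid2$values)
  ta <- tb <- matrix(NA_real_, n1, n2,
                     dimnames = list(format(grid1$values, trim = TRUE),
                                     format(grid2$values, trim = TRUE)))
  for (i in seq_len(n1)) {
    s1 <- substitute_param(base_a, base_b, grid1, grid1$values[i])
    for (j in seq_len(n2)) {
      s2 <- substitute_param(s1$a, s1$b, grid2, grid2$values[j])
      ta[i, j] <- per_patient_cost(s2$a)$per_patient_total
      tb[i, j] <- per_patient_cost(s2$b)$per_patient_total
    }
  }
  structure(list(total_a = ta, total_b = tb, difference = ta - tb,
                 grid1 = grid1, grid2 = grid2,
                 strategies = c(a = base_a$name, b = base_b$name)),
            class = "sweep_result2")
}

#' @export
print.sweep_result2 <- function(x, ...) {
  cat(sprintf("Two-way sweep: %s$%s (rows) x %s$%s (cols); difference %s - %s:\n",
              x$grid1$strategy, x$grid1$parameter,
              x$grid2$strategy, x$grid2$parameter,
              x$strategies[["a"]], x$strategies[["b"]]))
  print(round(x$difference, 2))
  invisible(x)
}

#' Break-even value of a cost-model parameter
#'
#' Finds the value of one parameter at which the two strategies' total
#' costs are equal. The per-patient total is affine in every parameter,
#' so the root is computed in closed form from two evaluations; a
#' bisection fallback (`method = "bisection"`) covers non-affine
#' extensions. Returns `NA` when no root lies inside the bracket.
#'
#' @param base_a,base_b base [screening_strategy()] objects.
#' @param strategy,parameter the varied target, as in [parameter_grid()].
#' @param bracket numeric `c(low, high)` with `low < high`.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @param tol root tolerance for bisection.
#' @return The break-even parameter value, or `NA_real_`.
#' @export
break_even <- function(base_a, base_b, strategy, parameter,
                       bracket = c(0, 1000), method = c("closed_form", "bisection"),
                       tol = 1e-9) {
  method <- match.arg(method)
  if (length(bracket) != 2L || bracket[1] >= bracket[2])
    stop("bracket must be c(low, high) with low < high", call. = FALSE)
  grid <- parameter_grid(strategy, parameter, bracket)
  d_at <- function(v) {
    s <- substitute_param(base_a, base_b, grid, v)
    cost_difference(s$a, s$b)
  }
  lo <- bracket[1]; hi <- bracket[2]
  d_lo <- d_at(lo); d_hi <- d_at(hi)
  if (method == "closed_form") {
    slope <- (d_hi - d_lo) / (hi - lo)
    if (abs(slope) < 1e-12)
      return(if (abs(d_lo) < 1e-12) lo else NA_real_)
    root <- lo - d_lo / slope
    if (root < lo - 1e-12 || root > hi + 1e-12) return(NA_real_)
    return(min(max(root, lo), hi))
  }
  if (d_lo * d_hi > 0) return(NA_real_)
  stats::uniroot(d_at, lower = lo, upper = hi, tol = tol)$root
}

#' Write a sweep result as long-format CSV
#'
#' One row per grid point with the axis value(s), both per-patient totals
#' and the difference.
#'
#' @param x a `sweep_result` or `sweep_result2`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  if (inherits(x, "sweep_result2")) {
    g1 <- x$grid1; g2 <- x$grid2
    df <- expand.grid(i = seq_along(g1$values), j = seq_along(g2$values))
    out <- data.frame(df$i, g1$values[df$i], g2$values[df$j],
                      x$total_a[cbind(df$i, df$j)],
                      x$total_b[cbind(df$i, df$j)],
                      x$difference[cbind(df$i, df$j)])[-1]
    names(out) <- c(paste0(g1$strategy, ".", g1$parameter),
                    paste0(g2$strategy, ".", g2$parameter),
                    "total_a", "total_b", "difference")
  } else {
    g <- attr(x, "grid")
    out <- as.data.frame(x)
    names(out)[1] <- paste0(g$strategy, ".", g$parameter)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
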