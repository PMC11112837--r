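#' Binarize ordinal DR grades
#'
#' Positive iff `grade >= threshold`. Threshold 1 is "any DR" (the
#' headline analysis: no DR vs any DR); threshold 2 is "referable DR"
#' (moderate NPDR and above).
#'
#' @param grades integer grade vector, codes 0--3, no `NA`.
#' @param threshold 1 (any DR) or 2 (referable DR).
#' @return Logical vector.
#' @export
binarize <- function(grades, threshold = 1L) {
  if (!threshold %in% c(1L, 2L))
    stop("threshold must be 1 (any DR) or 2 (referable DR)", call. = FALSE)
  if (anyNA(grades))
    stop("ungradable (NA) grades present; apply filter_gradable() first",
         call. = FALSE)
  grades >= threshold
}

#' Cross-classify a binary reference and test grader
#'
#' Reference standard = manual/ophthalmologist grading; index test = AI.
#'
#' @param reference,test equal-length logical vectors.
#' @return A `confusion_2x2` list with counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_2x2 <- function(reference, test) {
  if (length(reference) != length(test))
    stop("reference and test must have equal length", call. = FALSE)
  reference <- as.logical(reference); test <- as.logical(test)
  if (anyNA(reference) || anyNA(test))
    stop("NA values in binary vectors", call. = FALSE)
  structure(list(tp = sum(reference & test),
                 fp = sum(!reference & test),
                 fn = sum(reference & !test),
                 tn = sum(!reference & !test)),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("+", "-"), reference = c("+", "-")))
  cat("2x2 confusion (reference = manual, test = AI):\n")
  print(m)
  invisible(x)
}

#' Binomial confidence interval for a proportion
#'
#' Three standard methods for `x` successes in `n` trials:
#' * `wald`: normal approximation `x/n +/- z * sqrt(p(1-p)/n)`, clipped
#'   to `[0,1]`;
#' * `clopper_pearson`: exact interval from beta quantiles,
#'   `lo = qbeta(a/2, x, n-x+1)` (0 when `x = 0`),
#'   `hi = qbeta(1-a/2, x+1, n-x)` (1 when `x = n`) — guarantees
#'   at-least-nominal coverage;
#' * `wilson`: score interval, inherently inside `[0,1]`.
#'
#' @param x number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param method `"clopper_pearson"`, `"wald"` or `"wilson"` (`"cp"` is
#'   accepted for `"clopper_pearson"`).
#' @param level confidence level in (0,1), default 0.95.
#' @return Numeric `c(low, high)`.
#' @export
binomial_ci <- function(x, n, method = c("clopper_pearson", "wald", "wilson", "cp"),
                        level = 0.95) {
  method <- match.arg(method)
  if (method == "cp") method <- "clopper_pearson"
  if (!is.numeric(x) || !is.numeric(n) || length(x) != 1L || length(n) != 1L ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("need integer 0 <= x <= n with n >= 1", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)", call. = FALSE)
  a <- 1 - level
  p <- x / n
  ci <- switch(method,
    wald = {
      z <- stats::qnorm(1 - a / 2)
      half <- z * sqrt(p * (1 - p) / n)
      c(max(0, p - half), min(1, p + half))
    },
    clopper_pearson = c(
      if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1),
      if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
    ),
    wilson = {
      z <- stats::qnorm(1 - a / 2)
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      # algebraically inside [0,1]; pmin/pmax only absorbs float roundoff
      c(max(0, centre - half), min(1, centre + half))
    })
  names(ci) <- c("low", "high")
  ci
}

# Table-1 reproducing defaults: normal-approximation interval for DR
# prevalence, exact intervals elsewhere.
default_ci_methods <- function() {
  c(prevalence = "wald", sensitivity = "clopper_pearson",
    specificity = "clopper_pearson", accuracy = "clopper_pearson")
}

#' Diagnostic accuracy metrics with confidence intervals
#'
#' Prevalence `(tp+fn)/n`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)` and accuracy `(tp+tn)/n`, each with a binomial CI. A
#' metric whose denominator is zero is reported as `NA` (undefined), never
#' as 0.
#'
#' @param confusion a [confusion_2x2()].
#' @param ci_method single method name applied to every metric, or a named
#'   vector per metric; the default uses Wald for prevalence and
#'   Clopper-Pearson for sensitivity/specificity/accuracy.
#' @param ci_level confidence level, default 0.95.
#' @return A `diagnostic_metrics` data frame: one row per metric with
#'   `estimate`, `ci_low`, `ci_high`, `ci_method`, `x`, `n`.
#' @export
diagnostic_metrics <- function(confusion, ci_method = NULL, ci_level = 0.95) {
  stopifnot(inherits(confusion, "confusion_2x2"))
  n <- with(confusion, tp + fp + fn + tn)
  if (n <= 0) stop("empty confusion table", call. = FALSE)
  methods <- default_ci_methods()
  if (!is.null(ci_method)) {
    if (is.null(names(ci_method))) methods[] <- ci_method
    else methods[names(ci_method)] <- ci_method
  }
  num <- with(confusion, c(prevalence = tp + fn, sensitivity = tp,
                           specificity = tn, accuracy = tp + tn))
  den <- with(confusion, c(prevalence = n, sensitivity = tp + fn,
                           specificity = tn + fp, accuracy = n))
  rows <- lapply(names(num), function(m) {
    if (den[[m]] == 0)
      return(data.frame(metric = m, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, ci_method = methods[[m]],
                        x = num[[m]], n = den[[m]]))
    ci <- binomial_ci(num[[m]], den[[m]], methods[[m]], ci_level)
    data.frame(metric = m, estimate = num[[m]] / den[[m]],
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               ci_method = methods[[m]], x = num[[m]], n = den[[m]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$metric
  attr(out, "ci_level") <- ci_level
  class(out) <- c("diagnostic_metrics", "data.frame")
  out
}

#' @export
print.diagnostic_metrics <- function(x, digits = 1, ...) {
  lvl <- attr(x, "ci_level")
  cat(sprintf("Diagnostic accuracy (n = %d, %g%% CI):\n",
              x$n[x$metric == "accuracy"], 100 * lvl))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-12s undefined (denominator 0)\n", x$metric[i]))
    } else {
      cat(sprintf("  %-12s %5s%% (%s%%-%s%%, %s)\n", x$metric[i],
                  format(round_half_up(100 * x$estimate[i], digits)),
                  format(round_half_up(100 * x$ci_low[i], digits)),
                  format(round_half_up(100 * x$ci_high[i], digits)),
                  x$ci_method[i]))
    }
  }
  invisible(x)
}

# round half away from zero (reports use half-up, not banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
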