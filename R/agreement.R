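#' Cross-tabulate two graders' ordinal grades
#'
#' @param grades_a,grades_b integer vectors of codes in `0..k-1`
#'   (grader A = rows, grader B = columns). No `NA` allowed: filter
#'   ungradable eyes first with [filter_gradable()].
#' @param k number of categories (default 4).
#' @param labels optional category labels (length `k`).
#' @return A `contingency_table`: `k x k` integer matrix with a
#'   `labels` attribute.
#' @export
contingency_table <- function(grades_a, grades_b, k = K_GRADES,
                              labels = NULL) {
  if (length(grades_a) != length(grades_b))
    stop("grade vectors must have equal length", call. = FALSE)
  if (anyNA(grades_a) || anyNA(grades_b))
    stop("NA grades present; apply filter_gradable() first", call. = FALSE)
  if (any(grades_a < 0L | grades_a >= k) || any(grades_b < 0L | grades_b >= k))
    stop(sprintf("grade codes must lie in 0..%d", k - 1L), call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(k) - 1L)
  counts <- table(factor(grades_a, levels = 0:(k - 1L)),
                  factor(grades_b, levels = 0:(k - 1L)))
  m <- matrix(as.integer(counts), k, k, dimnames = list(A = labels, B = labels))
  structure(m, class = c("contingency_table", class(m)), labels = labels)
}

#' Agreement weight schemes for weighted kappa
#'
#' Builds the `k x k` agreement-weight matrix `w` with `w[i,i] = 1`:
#' `identity` gives 1 on the diagonal and 0 off it (unweighted kappa),
#' `linear` gives `1 - |i-j|/(k-1)`, `quadratic` gives
#' `1 - (|i-j|/(k-1))^2`.
#'
#' @param scheme `"identity"`, `"linear"`, `"quadratic"`, or `"custom"`.
#' @param k number of categories.
#' @param weights custom `k x k` weight matrix in `[0,1]` with unit
#'   diagonal (only for `scheme = "custom"`).
#' @return A `k x k` numeric weight matrix with attribute `scheme`.
#' @export
kappa_weights <- function(scheme = c("linear", "quadratic", "identity", "custom"),
                          k = K_GRADES, weights = NULL) {
  scheme <- match.arg(scheme)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- switch(scheme,
    identity  = (d == 0) + 0,
    linear    = 1 - d / (k - 1),
    quadratic = 1 - (d / (k - 1))^2,
    custom = {
      if (is.null(weights)) stop("custom scheme needs a weight matrix", call. = FALSE)
      weights <- as.matrix(weights)
      if (!identical(dim(weights), c(k, k)) || any(weights < 0) ||
          any(weights > 1) || any(abs(diag(weights) - 1) > 1e-12))
        stop("custom weights must be k x k in [0,1] with unit diagonal",
             call. = FALSE)
      weights
    })
  structure(w, scheme = scheme)
}

#' Weighted and unweighted Cohen's kappa
#'
#' Chance-corrected agreement between two raters on `k` ordinal
#' categories. With cell proportions `p_ij`, row marginals `r_i`, column
#' marginals `c_j` and agreement weights `w_ij`:
#' `Po = sum(w * p)`, `Pe = sum(w * (r %o% c))`, and
#' `kappa = (Po - Pe) / (1 - Pe)`.
#'
#' The standard error is the asymptotic large-sample form for weighted
#' kappa (Fleiss, Cohen & Everitt); the p-value tests `kappa = 0` with the
#' null-variance version of the same form. `cohen_kappa()` is the
#' identity-weight special case.
#'
#' @param table a [contingency_table()] (any square count matrix works).
#' @param scheme weight scheme name or a matrix from [kappa_weights()].
#' @return An `agreement_result` list: `kappa`, `po`, `pe`, `se`,
#'   `p_value`, `band` (Landis-Koch label), `scheme`, `n`.
#' @export
weighted_kappa <- function(table, scheme = "linear") {
  m <- as.matrix(unclass(table))
  k <- nrow(m)
  if (ncol(m) != k) stop("contingency table must be square", call. = FALSE)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  n <- sum(m)
  if (n <= 0) stop("contingency table total must be > 0", call. = FALSE)
  w <- if (is.matrix(scheme)) scheme else kappa_weights(scheme, k = k)
  if (!identical(dim(w), dim(m)))
    stop("weight matrix dimensions do not match the table", call. = FALSE)

  p <- m / n
  r <- rowSums(p)
  cc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * (r %o% cc))
  if (abs(1 - pe) < 1e-12)
    stop("expected agreement is 1; kappa is undefined for this table",
         call. = FALSE)
  kappa <- (po - pe) / (1 - pe)

  # asymptotic variance (Fleiss-Cohen-Everitt); wbar_i. / wbar_.j are the
  # marginal-weighted mean weights for row i / column j
  wri <- as.vector(w %*% cc)        # wbar_i. = sum_j c_j w_ij
  wcj <- as.vector(t(w) %*% r)      # wbar_.j = sum_i r_i w_ij
  wsum <- outer(wri, wcj, "+")
  var_ha <- (sum(p * (w - wsum * (1 - kappa))^2) -
               (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  var_h0 <- (sum((r %o% cc) * (w - wsum)^2) - pe^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_ha, 0))
  se0 <- sqrt(max(var_h0, 0))
  p_value <- if (se0 > 0) 2 * stats::pnorm(-abs(kappa) / se0) else NA_real_

  scheme_name <- if (is.matrix(scheme))
    attr(scheme, "scheme") %||% "custom" else scheme
  structure(list(kappa = kappa, po = po, pe = pe, se = se,
                 p_value = p_value, band = landis_koch_band(kappa),
                 scheme = scheme_name, n = n),
            class = "agreement_result")
}

#' @rdname weighted_kappa
#' @export
cohen_kappa <- function(table) {
  res <- weighted_kappa(table, scheme = "identity")
  res$scheme <- "identity"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s weights), n = %d\n", x$scheme, x$n))
  cat(sprintf("  kappa = %.4f (SE %.4f), Po = %.4f, Pe = %.4f\n",
              x$kappa, x$se, x$po, x$pe))
  cat(sprintf("  H0 kappa = 0: p %s; agreement: %s\n",
              format.pval(x$p_value, digits = 3), x$band))
  invisible(x)
}

#' Serialize an agreement result to JSON
#'
#' @param x an `agreement_result`.
#' @param statistic label recorded in the report (e.g. `"weighted_kappa"`).
#' @return A JSON string.
#' @export
agreement_json <- function(x, statistic = "weighted_kappa") {
  jsonlite::toJSON(list(statistic = statistic, scheme = x$scheme,
                        kappa = x$kappa, po = x$po, pe = x$pe, se = x$se,
                        p_value = x$p_value, band = x$band, n = x$n),
                   auto_unbox = TRUE, digits = NA)
}

#' Spearman rank correlation between two graders
#'
#' Rank correlation with average ranks for ties, with the p-value from
#' [stats::cor.test()].
#'
#' @param grades_a,grades_b equal-length numeric/integer vectors
#'   (length >= 3), no `NA`.
#' @return List with `rho` and `p_value`.
#' @export
spearman_rho <- function(grades_a, grades_b) {
  if (length(grades_a) != length(grades_b))
    stop("grade vectors must have equal length", call. = FALSE)
  if (length(grades_a) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(grades_a) || anyNA(grades_b))
    stop("NA grades present; apply filter_gradable() first", call. = FALSE)
  if (stats::var(grades_a) == 0 || stats::var(grades_b) == 0)
    stop("rank correlation undefined: a grade vector has zero variance",
         call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(grades_a, grades_b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Landis-Koch verbal interpretation of a kappa value
#'
#' Bands with upper-inclusive boundaries: `<= 0.20` poor, `0.21--0.40`
#' fair, `0.41--0.60` moderate, `0.61--0.80` good, `0.81--1.00` very good.
#'
#' @param kappa numeric in `[-1, 1]`.
#' @return Character label.
#' @export
landis_koch_band <- function(kappa) {
  if (!is.numeric(kappa) || anyNA(kappa) || any(kappa < -1) || any(kappa > 1))
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  cut_pts <- c(-1, 0.20, 0.40, 0.60, 0.80, 1)
  labs <- c("poor", "fair", "moderate", "good", "very good")
  as.character(cut(kappa, cut_pts, labs, include.lowest = TRUE, right = TRUE))
}
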