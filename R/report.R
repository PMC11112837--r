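#' Per-grader grade distribution
#'
#' Shares of the four DR grades for each grader over the gradable eyes,
#' as counts and as whole-number percentages (half-up rounding).
#'
#' @param records a `grading_cohort`; ungradable eyes are dropped first.
#' @return Data frame: `grade`, `label`, `manual_n`, `ai_n`,
#'   `manual_pct`, `ai_pct`.
#' @export
grade_distribution <- function(records) {
  g <- filter_gradable(records)
  if (nrow(g) == 0L)
    stop("no gradable eyes: cannot compute a grade distribution", call. = FALSE)
  codes <- 0:(K_GRADES - 1L)
  mn <- as.integer(table(factor(g$manual_grade, levels = codes)))
  an <- as.integer(table(factor(g$ai_grade, levels = codes)))
  data.frame(grade = codes, label = unname(icdr_levels()),
             manual_n = mn, ai_n = an,
             manual_pct = round_half_up(100 * mn / nrow(g)),
             ai_pct = round_half_up(100 * an / nrow(g)))
}

binary_agreement <- function(x, y) {
  tab <- contingency_table(as.integer(x), as.integer(y), k = 2L,
                           labels = c("negative", "positive"))
  tryCatch(cohen_kappa(tab), error = function(e) NULL)
}

#' Run the full screening-evaluation pipeline
#'
#' Executes, in order: gradable-eye filtering; grade distributions;
#' inter-grader agreement (4-level weighted kappa, binary DR kappa,
#' maculopathy kappa, Spearman rho); diagnostic accuracy of the AI
#' grader against the manual reference for DR and maculopathy; the
#' cost-minimization model (per-patient, cohort and mixed totals) and a
#' one-way sensitivity sweep over the second strategy's screening cost.
#' Deterministic given its inputs.
#'
#' @param records a `grading_cohort` (e.g. [oslo_fixture()],
#'   [generate_cohort()] or [read_grading()]).
#' @param config cost configuration as returned by [read_cost_config()];
#'   the first strategy is the comparator `a`, the second the test `b`.
#' @param threshold DR binarization threshold: 1 = any DR (default),
#'   2 = referable DR.
#' @param weights weight scheme for the 4-level kappa (default linear).
#' @param ci_method CI method override passed to [diagnostic_metrics()].
#' @param ci_level confidence level (default 0.95).
#' @param seed optional integer recorded in provenance (the pipeline
#'   itself draws no random numbers).
#' @return A `dr_report` list: `cohort`, `grade_distribution`,
#'   `agreement`, `diagnostics`, `costs`, `sweep`, `provenance`.
#' @export
run_analysis <- function(records, config = read_cost_config(),
                         threshold = 1L, weights = "linear",
                         ci_method = NULL, ci_level = 0.95, seed = NULL) {
  stopifnot(inherits(records, "grading_cohort"))
  gradable <- filter_gradable(records)
  if (nrow(gradable) == 0L)
    stop("no eyes gradable by both graders; nothing to analyse", call. = FALSE)

  cohort <- list(n_patients = length(unique(records$patient_id)),
                 n_eyes = nrow(records), n_gradable = nrow(gradable))

  tab4 <- contingency_table(gradable$manual_grade, gradable$ai_grade)
  dr_ref <- binarize(gradable$manual_grade, threshold)
  dr_test <- binarize(gradable$ai_grade, threshold)
  agreement <- list(
    ordinal = weighted_kappa(tab4, scheme = weights),
    dr_binary = binary_agreement(dr_ref, dr_test),
    maculopathy = binary_agreement(gradable$manual_maculopathy,
                                   gradable$ai_maculopathy),
    spearman = tryCatch(spearman_rho(gradable$manual_grade, gradable$ai_grade),
                        error = function(e) NULL)
  )

  # DR uses the per-metric defaults (normal-approximation interval for the
  # prevalence); the rarer maculopathy outcome uses the exact interval for
  # every metric, where the approximation is unreliable
  diagnostics <- list(
    dr = diagnostic_metrics(confusion_2x2(dr_ref, dr_test),
                            ci_method = ci_method, ci_level = ci_level),
    maculopathy = diagnostic_metrics(
      confusion_2x2(gradable$manual_maculopathy, gradable$ai_maculopathy),
      ci_method = ci_method %||% "clopper_pearson", ci_level = ci_level)
  )

  a <- config$strategies[[1L]]
  b <- config$strategies[[2L]] %||% a
  costs <- list(
    per_patient = lapply(config$strategies, per_patient_cost),
    difference = cost_difference(a, b),
    cohort_totals = lapply(config$strategies, cohort_cost,
                           n_patients = config$n_patients),
    mixed_total = mixed_strategy_cost(a, b, config$fraction_a,
                                      config$n_patients),
    n_patients = config$n_patients, fraction_a = config$fraction_a
  )

  sweep_vals <- sort(unique(c(b$screening_cost, 64, 113, a$screening_cost)))
  sweep <- one_way_sweep(a, b, parameter_grid(b$name, "screening_cost",
                                              sweep_vals))

  provenance <- list(
    package = "drscreen",
    version = as.character(utils::packageVersion("drscreen")),
    seed = seed, threshold = threshold, weights = weights,
    ci_level = ci_level,
    config = list(strategies = lapply(config$strategies, unclass),
                  n_patients = config$n_patients,
                  fraction_a = config$fraction_a,
                  nok_per_usd = config$nok_per_usd)
  )

  structure(list(cohort = cohort,
                 grade_distribution = grade_distribution(records),
                 agreement = agreement, diagnostics = diagnostics,
                 costs = costs, sweep = sweep, provenance = provenance),
            class = "dr_report")
}

#' @export
print.dr_report <- function(x, ...) {
  cat("=== DR screening evaluation report ===\n")
  cat(sprintf("Cohort: %d patients, %d eyes, %d gradable by both graders\n\n",
              x$cohort$n_patients, x$cohort$n_eyes, x$cohort$n_gradable))
  cat("Grade distribution (% of gradable eyes):\n")
  print(x$grade_distribution, row.names = FALSE)
  cat("\nAgreement (4-level):\n")
  print(x$agreement$ordinal)
  if (!is.null(x$agreement$dr_binary))
    cat(sprintf("Binary DR kappa: %.4f\n", x$agreement$dr_binary$kappa))
  if (!is.null(x$agreement$maculopathy))
    cat(sprintf("Maculopathy kappa: %.4f\n", x$agreement$maculopathy$kappa))
  if (!is.null(x$agreement$spearman))
    cat(sprintf("Spearman rho: %.4f\n", x$agreement$spearman$rho))
  cat("\nDiagnostic accuracy, DR:\n"); print(x$diagnostics$dr)
  cat("Diagnostic accuracy, maculopathy:\n"); print(x$diagnostics$maculopathy)
  cat("\nCosts (USD):\n")
  for (pc in x$costs$per_patient)
    cat(sprintf("  per patient, %-8s $%s\n", paste0(pc$strategy, ":"),
                format(round_half_up(pc$per_patient_total))))
  cat(sprintf("  difference (a - b): $%s per patient\n",
              format(round_half_up(x$costs$difference))))
  for (nm in names(x$costs$cohort_totals))
    cat(sprintf("  cohort (n=%d), %-8s $%s\n", x$costs$n_patients,
                paste0(nm, ":"),
                format(round_half_up(x$costs$cohort_totals[[nm]]))))
  cat(sprintf("  mixed program (fraction_a=%g): $%s\n",
              x$costs$fraction_a, format(round_half_up(x$costs$mixed_total))))
  invisible(x)
}

#' @export
summary.dr_report <- function(object, ...) {
  cat(sprintf(
    "kappa(%s) = %.2f [%s]; sens = %s; spec = %s; cost difference $%s/patient\n",
    object$agreement$ordinal$scheme, object$agreement$ordinal$kappa,
    object$agreement$ordinal$band,
    format(object$diagnostics$dr["sensitivity", "estimate"]),
    format(object$diagnostics$dr["specificity", "estimate"]),
    format(round_half_up(object$costs$difference))))
  invisible(object)
}

agreement_list <- function(a) {
  if (is.null(a)) return(NULL)
  list(kappa = a$kappa, po = a$po, pe = a$pe, se = a$se,
       p_value = a$p_value, band = a$band, scheme = a$scheme, n = a$n)
}

#' Serialize a report to JSON
#'
#' Lossless machine-readable form of a [run_analysis()] report; every
#' number is recomputable from the provenance-echoed inputs.
#'
#' @param report a `dr_report`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  x <- list(
    cohort = report$cohort,
    grade_distribution = report$grade_distribution,
    agreement = lapply(report$agreement[c("ordinal", "dr_binary",
                                          "maculopathy")], agreement_list),
    spearman = report$agreement$spearman,
    diagnostics = lapply(report$diagnostics, function(d)
      as.data.frame(unclass(d), stringsAsFactors = FALSE)),
    costs = list(
      per_patient = lapply(report$costs$per_patient, unclass),
      difference = report$costs$difference,
      cohort_totals = report$costs$cohort_totals,
      mixed_total = report$costs$mixed_total,
      n_patients = report$costs$n_patients,
      fraction_a = report$costs$fraction_a),
    sweep = as.data.frame(report$sweep),
    provenance = report$provenance
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(js))
  }
  js
}
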