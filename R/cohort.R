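#' Grade labels of the 4-level analysis scale
#'
#' Ordinal codes 0--3 on the ICDR-derived analysis scale: 0 = no DR,
#' 1 = mild NPDR, 2 = moderate NPDR, 3 = severe NPDR/PDR (collapsed).
#' Ungradable eyes carry `NA` in the grade columns.
#'
#' @return Character vector of length 4, names `"0"`..`"3"`.
#' @export
icdr_levels <- function() {
  c(`0` = "no DR", `1` = "mild NPDR", `2` = "moderate NPDR",
    `3` = "severe NPDR/PDR")
}

K_GRADES <- 4L

#' Construct a grading cohort
#'
#' A grading cohort is a data frame with one row per eye, carrying both
#' graders' ICDR grades (integer 0--3, `NA` = ungradable) and maculopathy
#' flags (logical, `NA` when the corresponding grade is ungradable).
#'
#' @param patient_id character vector of patient identifiers.
#' @param eye character vector, `"left"` or `"right"`.
#' @param manual_grade,ai_grade integer grades in 0--3 or `NA` (ungradable).
#' @param manual_maculopathy,ai_maculopathy logical maculopathy flags;
#'   must be `NA` exactly where the corresponding grade is `NA`.
#' @return A `grading_cohort` (data frame).
#' @export
grading_cohort <- function(patient_id, eye, manual_grade, ai_grade,
                           manual_maculopathy, ai_maculopathy) {
  df <- data.frame(
    patient_id = as.character(patient_id),
    eye = as.character(eye),
    manual_grade = as.integer(manual_grade),
    ai_grade = as.integer(ai_grade),
    manual_maculopathy = as.logical(manual_maculopathy),
    ai_maculopathy = as.logical(ai_maculopathy),
    stringsAsFactors = FALSE
  )
  validate_grading_cohort(df)
  class(df) <- c("grading_cohort", "data.frame")
  df
}

validate_grading_cohort <- function(df) {
  if (anyDuplicated(df[c("patient_id", "eye")]))
    stop("duplicate (patient_id, eye) pairs in grading table", call. = FALSE)
  if (!all(df$eye %in% c("left", "right")))
    stop("eye must be 'left' or 'right'", call. = FALSE)
  for (col in c("manual_grade", "ai_grade")) {
    g <- df[[col]]
    bad <- !is.na(g) & (g < 0L | g >= K_GRADES)
    if (any(bad))
      stop(sprintf("%s outside 0-%d: %s", col, K_GRADES - 1L,
                   paste(unique(g[bad]), collapse = ", ")), call. = FALSE)
  }
  # maculopathy flags exist exactly where the grade is gradable
  if (any(is.na(df$manual_grade) != is.na(df$manual_maculopathy)) ||
      any(is.na(df$ai_grade) != is.na(df$ai_maculopathy)))
    stop("maculopathy flags must be present iff the corresponding grade is gradable",
         call. = FALSE)
  invisible(df)
}

#' @export
print.grading_cohort <- function(x, ...) {
  n_pat <- length(unique(x$patient_id))
  n_grad <- sum(!is.na(x$manual_grade) & !is.na(x$ai_grade))
  cat(sprintf("Grading cohort: %d patients, %d eyes (%d gradable by both graders)\n",
              n_pat, nrow(x), n_grad))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Simulation parameters for a synthetic two-grader cohort
#'
#' Defaults emulate the screening-day cohort the package's analyses are
#' built around: 33 patients, two eyes each, manual grade shares
#' (81, 3, 11, 5)% over codes 0--3, maculopathy prevalence 3.1%, a small
#' per-eye ungradable rate (2/66), and an AI grader that agrees with the
#' manual grader except for occasional moderate-to-mild down-grading.
#'
#' @param n_patients number of patients.
#' @param eyes_per_patient eyes per patient (default 2).
#' @param grade_probs probability vector over grades 0--3 (sums to 1).
#' @param maculopathy_prob per-eye maculopathy probability.
#' @param ungradable_prob per-eye probability of an ungradable image.
#' @param ai_confusion 4x4 row-stochastic matrix, `P(ai = j | manual = i)`;
#'   rows index the manual grade.
#' @param ungradable_concordance probability the AI flags the same eye
#'   ungradable when the manual grader does (default 1: concordant).
#' @param seed integer seed; every call uses its own RNG stream.
#' @return A `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(n_patients = 33L,
                              eyes_per_patient = 2L,
                              grade_probs = c(0.81, 0.03, 0.11, 0.05),
                              maculopathy_prob = 0.031,
                              ungradable_prob = 2 / 66,
                              ai_confusion = default_ai_confusion(),
                              ungradable_concordance = 1,
                              seed = 1L) {
  p <- list(n_patients = as.integer(n_patients),
            eyes_per_patient = as.integer(eyes_per_patient),
            grade_probs = as.numeric(grade_probs),
            maculopathy_prob = maculopathy_prob,
            ungradable_prob = ungradable_prob,
            ai_confusion = as.matrix(ai_confusion),
            ungradable_concordance = ungradable_concordance,
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "cohort_sim_params"
  p
}

#' Default AI-vs-manual grade confusion matrix
#'
#' Mostly diagonal; manual moderate (code 2) is down-graded to mild by the
#' AI with probability 2/7, mirroring the observed disagreement pattern
#' (2 of 7 moderate eyes graded mild).
#'
#' @return 4x4 row-stochastic matrix.
#' @export
default_ai_confusion <- function() {
  m <- diag(4)
  m[3, ] <- c(0, 2 / 7, 5 / 7, 0)
  dimnames(m) <- list(manual = 0:3, ai = 0:3)
  m
}

validate_sim_params <- function(p) {
  if (p$n_patients < 0L || p$eyes_per_patient < 1L)
    stop("n_patients must be >= 0 and eyes_per_patient >= 1", call. = FALSE)
  if (length(p$grade_probs) != K_GRADES || any(p$grade_probs < 0) ||
      abs(sum(p$grade_probs) - 1) > 1e-9)
    stop("grade_probs must be 4 non-negative values summing to 1", call. = FALSE)
  for (f in c("maculopathy_prob", "ungradable_prob", "ungradable_concordance")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(sprintf("%s must be a probability in [0,1]", f), call. = FALSE)
  }
  cm <- p$ai_confusion
  if (!identical(dim(cm), c(K_GRADES, K_GRADES)) || any(cm < 0) ||
      any(abs(rowSums(cm) - 1) > 1e-9))
    stop("ai_confusion must be a 4x4 row-stochastic matrix", call. = FALSE)
  invisible(p)
}

#' Generate a synthetic two-grader screening cohort
#'
#' Manual grades are drawn from `grade_probs`; the AI grade for a gradable
#' eye is drawn from the `ai_confusion` row of the manual grade. An eye is
#' ungradable (both grades `NA`... or manual-only, depending on
#' `ungradable_concordance`) with probability `ungradable_prob`.
#' Maculopathy is drawn per eye and recorded identically by both graders.
#'
#' @param params a [cohort_sim_params()] object.
#' @return A `grading_cohort` with `n_patients * eyes_per_patient` rows.
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_sim_params"))
    params <- do.call(cohort_sim_params, params)
  validate_sim_params(params)
  n_eyes <- params$n_patients * params$eyes_per_patient
  # local RNG stream; global .Random.seed untouched
  rng <- local_rng(params$seed)
  on.exit(rng$restore(), add = TRUE)

  patient_id <- rep(sprintf("P%03d", seq_len(params$n_patients)),
                    each = params$eyes_per_patient)
  eye <- rep_len(c("right", "left"), n_eyes)
  if (params$eyes_per_patient > 2L)
    eye <- paste0(eye, "_", rep_len(seq_len(params$eyes_per_patient), n_eyes))

  manual <- sample.int(K_GRADES, n_eyes, replace = TRUE,
                       prob = params$grade_probs) - 1L
  ai <- integer(n_eyes)
  for (g in 0:(K_GRADES - 1L)) {
    idx <- which(manual == g)
    if (length(idx))
      ai[idx] <- sample.int(K_GRADES, length(idx), replace = TRUE,
                            prob = params$ai_confusion[g + 1L, ]) - 1L
  }
  macul <- stats::runif(n_eyes) < params$maculopathy_prob
  ungrad <- stats::runif(n_eyes) < params$ungradable_prob
  ai_ungrad <- ungrad & (stats::runif(n_eyes) < params$ungradable_concordance)

  manual[ungrad] <- NA_integer_
  ai[ai_ungrad] <- NA_integer_
  manual_mac <- ifelse(is.na(manual), NA, macul)
  ai_mac <- ifelse(is.na(ai), NA, macul)

  grading_cohort(patient_id, eye, manual, ai, manual_mac, ai_mac)
}

# Seeded RNG scoped to one call: saves and restores .Random.seed.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

#' Reconstructed screening-day cohort (Oslo fixture)
#'
#' Deterministic 66-eye cohort (33 patients) reproducing the published
#' grade distributions: 2 eyes ungradable by both graders; among the 64
#' gradable eyes, manual grade counts (52, 2, 7, 3) and AI counts
#' (52, 4, 5, 3) over codes 0--3, the only disagreements being 2 eyes
#' graded moderate manually and mild by the AI (binary any-DR agreement is
#' therefore perfect, 12 positives per grader); 2 eyes are
#' maculopathy-positive by both graders.
#'
#' The cell counts derive from largest-remainder rounding of the printed
#' percentage shares to integers over 64 eyes; the off-diagonal placement
#' is the unique structure consistent with both marginals and perfect
#' binary agreement.
#'
#' @return A `grading_cohort` with 66 rows.
#' @export
oslo_fixture <- function() {
  # 64 gradable eyes: manual counts (52,2,7,3); AI re-grades 2 moderates as mild
  manual <- c(rep(0L, 52L), rep(1L, 2L), rep(2L, 7L), rep(3L, 3L))
  ai <- manual
  ai[55:56] <- 1L  # first two moderate eyes: AI says mild
  # maculopathy in 2 eyes, concordant; placed on two severe-grade eyes
  mac <- rep(FALSE, 64L)
  mac[62:63] <- TRUE

  # patients P001/P002 contribute the ungradable eyes (left eye each)
  ids <- rep(sprintf("P%03d", 1:33), each = 2L)
  sides <- rep(c("right", "left"), 33L)
  ungradable <- c(2L, 4L)  # P001 left eye, P002 left eye
  keep <- setdiff(seq_len(66L), ungradable)

  manual_full <- integer(66L); ai_full <- integer(66L)
  mac_full <- logical(66L)
  manual_full[keep] <- manual; ai_full[keep] <- ai; mac_full[keep] <- mac
  manual_full[ungradable] <- NA_integer_; ai_full[ungradable] <- NA_integer_
  mac_m <- ifelse(is.na(manual_full), NA, mac_full)
  mac_a <- ifelse(is.na(ai_full), NA, mac_full)

  grading_cohort(ids, sides, manual_full, ai_full, mac_m, mac_a)
}

#' Keep eyes gradable by both graders
#'
#' An eye enters the paired analysis only if neither grader flagged it
#' ungradable.
#'
#' @param records a `grading_cohort`.
#' @return The subset of `records` with no `NA` grade, same class.
#' @export
filter_gradable <- function(records) {
  keep <- !is.na(records$manual_grade) & !is.na(records$ai_grade)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a grading table
#'
#' Delimited-text interchange format: header
#' `patient_id,eye,manual_grade,ai_grade,manual_maculopathy,ai_maculopathy`,
#' grades serialized as `0|1|2|3|U`, booleans as `0|1` (empty for
#' ungradable eyes), UTF-8. The reader rejects duplicate
#' `(patient_id, eye)` pairs.
#'
#' @param path file path.
#' @param records a `grading_cohort` (for the writer).
#' @return `read_grading`: a `grading_cohort`; `write_grading`: `path`,
#'   invisibly.
#' @export
read_grading <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  need <- c("patient_id", "eye", "manual_grade", "ai_grade",
            "manual_maculopathy", "ai_maculopathy")
  if (!all(need %in% names(df)))
    stop("grading table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  parse_grade <- function(x, col) {
    out <- suppressWarnings(as.integer(ifelse(x == "U", NA, x)))
    bad <- which(is.na(out) & x != "U")
    if (length(bad))
      stop(sprintf("%s: unparseable grade '%s' at line %d", col,
                   x[bad[1]], bad[1] + 1L), call. = FALSE)
    out
  }
  parse_bool <- function(x) ifelse(x %in% c("", "NA"), NA, x == "1")
  grading_cohort(df$patient_id, df$eye,
                 parse_grade(df$manual_grade, "manual_grade"),
                 parse_grade(df$ai_grade, "ai_grade"),
                 parse_bool(df$manual_maculopathy),
                 parse_bool(df$ai_maculopathy))
}

#' @rdname read_grading
#' @export
write_grading <- function(records, path) {
  ser_grade <- function(g) ifelse(is.na(g), "U", as.character(g))
  ser_bool <- function(b) ifelse(is.na(b), "", as.character(as.integer(b)))
  out <- data.frame(patient_id = records$patient_id,
                    eye = records$eye,
                    manual_grade = ser_grade(records$manual_grade),
                    ai_grade = ser_grade(records$ai_grade),
                    manual_maculopathy = ser_bool(records$manual_maculopathy),
                    ai_maculopathy = ser_bool(records$ai_maculopathy))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
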