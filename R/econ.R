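#' Define a screening strategy's cost parameters
#'
#' Per-patient cost components of one screening modality, in USD:
#' the screening fee (DRG reimbursement weight), round-trip transport cost
#' per visit, patient time per visit (hours) and its hourly valuation.
#'
#' `transport_trips_per_visit` defaults to 1: the transport figure is
#' already a round-trip amount. It is exposed as a knob so a doubled
#' transport assumption can be explored.
#'
#' @param name strategy label.
#' @param screening_cost screening fee per patient (USD).
#' @param transport_cost_round_trip round-trip transport cost per visit (USD).
#' @param patient_time_hours patient time per visit (hours).
#' @param time_cost_per_hour value of patient time (USD/hour).
#' @param visits number of visits (default 1).
#' @param transport_trips_per_visit multiplier on the transport amount
#'   (default 1).
#' @return A `screening_strategy` list.
#' @export
screening_strategy <- function(name, screening_cost, transport_cost_round_trip,
                               patient_time_hours, time_cost_per_hour,
                               visits = 1L, transport_trips_per_visit = 1) {
  s <- list(name = as.character(name),
            screening_cost = screening_cost,
            transport_cost_round_trip = transport_cost_round_trip,
            patient_time_hours = patient_time_hours,
            time_cost_per_hour = time_cost_per_hour,
            visits = visits,
            transport_trips_per_visit = transport_trips_per_visit)
  for (f in c("screening_cost", "transport_cost_round_trip",
              "patient_time_hours", "time_cost_per_hour",
              "transport_trips_per_visit")) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("%s must be a non-negative number", f), call. = FALSE)
  }
  if (!is.numeric(s$visits) || s$visits < 1)
    stop("visits must be >= 1", call. = FALSE)
  class(s) <- "screening_strategy"
  s
}

#' Baseline strategies of the cost model
#'
#' Manual/ophthalmologist screening: $164 DRG fee, $73 round-trip
#' transport, 1.5 h patient time at $24/h, one visit (total $273).
#' AI screening: $33 fee, same transport, 1 h patient time (total $130).
#'
#' @return Named list with `manual` and `ai` [screening_strategy()] objects.
#' @export
baseline_strategies <- function() {
  list(manual = screening_strategy("manual", 164, 73, 1.5, 24),
       ai = screening_strategy("ai", 33, 73, 1.0, 24))
}

#' Total cost per patient for one strategy
#'
#' `visits * (screening + trips * transport + hours * hourly_rate)`,
#' itemized. Grader labor is excluded (assumed equal across strategies).
#'
#' @param s a [screening_strategy()].
#' @return A `cost_result` list: `per_patient_total`, `components`
#'   (screening, transport, time), `strategy`.
#' @export
per_patient_cost <- function(s) {
  stopifnot(inherits(s, "screening_strategy"))
  comp <- c(screening = s$screening_cost,
            transport = s$transport_trips_per_visit * s$transport_cost_round_trip,
            time = s$patient_time_hours * s$time_cost_per_hour)
  comp <- comp * s$visits
  structure(list(per_patient_total = sum(comp), components = as.list(comp),
                 strategy = s$name),
            class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("Per-patient cost, strategy '%s': $%s\n", x$strategy,
              format(round_half_up(x$per_patient_total))))
  for (nm in names(x$components))
    cat(sprintf("  %-10s $%g\n", nm, x$components[[nm]]))
  invisible(x)
}

#' Per-patient cost difference between two strategies
#'
#' `per_patient_cost(a) - per_patient_cost(b)`: positive means strategy
#' `b` is cost-saving relative to `a`.
#'
#' @param a,b [screening_strategy()] objects.
#' @return Numeric (USD per patient).
#' @export
cost_difference <- function(a, b) {
  per_patient_cost(a)$per_patient_total - per_patient_cost(b)$per_patient_total
}

#' Total cohort cost
#'
#' @param s a [screening_strategy()].
#' @param n_patients cohort size (>= 0).
#' @return Numeric (USD).
#' @export
cohort_cost <- function(s, n_patients) {
  if (!is.numeric(n_patients) || n_patients < 0)
    stop("n_patients must be >= 0", call. = FALSE)
  n_patients * per_patient_cost(s)$per_patient_total
}

#' Total cost of a mixed screening program
#'
#' A fraction of the cohort is screened with strategy `a`, the rest with
#' `b`: `n * f * cost(a) + n * (1-f) * cost(b)`.
#'
#' @param a,b [screening_strategy()] objects.
#' @param fraction_a proportion screened by `a`, in `[0,1]`.
#' @param n_patients cohort size.
#' @return Numeric (USD).
#' @export
mixed_strategy_cost <- function(a, b, fraction_a, n_patients) {
  if (!is.numeric(fraction_a) || fraction_a < 0 || fraction_a > 1)
    stop("fraction_a must lie in [0, 1]", call. = FALSE)
  fraction_a * cohort_cost(a, n_patients) +
    (1 - fraction_a) * cohort_cost(b, n_patients)
}

#' Convert Norwegian kroner to US dollars
#'
#' @param amount_nok amount in NOK.
#' @param nok_per_usd exchange rate, NOK per USD (default 9.89).
#' @return Amount in USD.
#' @export
nok_to_usd <- function(amount_nok, nok_per_usd = 9.89) {
  if (!is.numeric(nok_per_usd) || nok_per_usd <= 0)
    stop("nok_per_usd must be strictly positive", call. = FALSE)
  amount_nok / nok_per_usd
}

#' Read a cost-model configuration
#'
#' YAML (or JSON) file with a `strategies` mapping (each entry holding the
#' [screening_strategy()] fields) plus optional scalars `n_patients`,
#' `fraction_a` and `nok_per_usd`. The packaged default mirrors the
#' baseline parameters, with `n_patients = 33`.
#'
#' @param path file path; the default reads the packaged configuration.
#' @return List with `strategies` (list of `screening_strategy`),
#'   `n_patients`, `fraction_a`, `nok_per_usd`.
#' @export
read_cost_config <- function(path = default_cost_config_path()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$strategies) || length(cfg$strategies) < 1L)
    stop("cost config must define at least one strategy", call. = FALSE)
  strategies <- lapply(names(cfg$strategies), function(nm) {
    do.call(screening_strategy, c(list(name = nm), cfg$strategies[[nm]]))
  })
  names(strategies) <- names(cfg$strategies)
  list(strategies = strategies,
       n_patients = cfg$n_patients %||% 33L,
       fraction_a = cfg$fraction_a %||% 0.5,
       nok_per_usd = cfg$nok_per_usd %||% 9.89)
}

#' @rdname read_cost_config
#' @export
default_cost_config_path <- function() {
  system.file("extdata", "default_costs.yaml", package = "drscreen",
              mustWork = TRUE)
}
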