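# Scenario engine: turns a required-events count into days of
# mass-vaccination throughput needed to accrue it, per jurisdiction and per
# pooled set of jurisdictions.
#
# Two conventions matter for reproducing whole-day tables consistently:
# per-jurisdiction daily throughputs are floored to whole doses *before*
# pooling, and days-to-detect always divides by the unrounded events/day
# (never by a 2-decimal display value). Floors and ceilings are guarded
# against floating-point representation error by rounding to 6 decimals
# first (e.g. 47 / (50000 * 1e-6) evaluates to 940 + 2e-13).

guarded_floor <- function(x) floor(round(x, 6))
guarded_ceiling <- function(x) ceiling(round(x, 6))

#' Throughput models
#'
#' Three ways to assign a daily vaccination throughput to a jurisdiction:
#'
#' * `throughput_anchored()`: scale an anchor jurisdiction's absolute
#'   throughput by relative population size, i.e.
#'   `floor(population * anchor_doses_per_day / anchor_population)`. This
#'   expresses "the same relative throughput as the anchor" (about 0.35% of
#'   the population per day for 50,000 doses/day in Ontario).
#' * `throughput_flat()`: a fixed fraction of the population per day,
#'   `floor(population * daily_fraction)`.
#' * `throughput_explicit()`: a stated absolute number of doses per day,
#'   independent of population (used e.g. for subgroups whose population
#'   count is not separately tabulated).
#'
#' @param anchor_doses_per_day Doses per day achieved by the anchor
#'   jurisdiction.
#' @param anchor_population The anchor jurisdiction's population in the
#'   stratum under study.
#' @param daily_fraction Fraction of the population vaccinated per day,
#'   in (0, 1).
#' @param doses_per_day Absolute throughput in doses per day.
#' @return An object of class `"throughput_model"`.
#' @examples
#' ontario_pace <- throughput_anchored(50000, 14223942)
#' jurisdiction_throughput(1342153, ontario_pace)  # 4,717 doses/day
#' @name throughput_model
NULL

#' @rdname throughput_model
#' @export
throughput_anchored <- function(anchor_doses_per_day, anchor_population) {
  stopifnot(anchor_doses_per_day > 0, anchor_population > 0)
  structure(list(mode = "anchored",
                 anchor_doses_per_day = anchor_doses_per_day,
                 anchor_population = anchor_population),
            class = "throughput_model")
}

#' @rdname throughput_model
#' @export
throughput_flat <- function(daily_fraction) {
  stopifnot(daily_fraction > 0, daily_fraction < 1)
  structure(list(mode = "flat", daily_fraction = daily_fraction),
            class = "throughput_model")
}

#' @rdname throughput_model
#' @export
throughput_explicit <- function(doses_per_day) {
  stopifnot(doses_per_day > 0)
  structure(list(mode = "explicit", doses_per_day = doses_per_day),
            class = "throughput_model")
}

#' Daily throughput of one jurisdiction under a throughput model
#'
#' @param population Person count of the jurisdiction stratum (> 0).
#' @param model A [throughput_model].
#' @return Whole doses per day (floored for the population-scaled modes).
#' @examples
#' jurisdiction_throughput(4517570, throughput_flat(0.0035))  # 15,811
#' @export
jurisdiction_throughput <- function(population, model) {
  stopifnot(inherits(model, "throughput_model"))
  if (population <= 0) stop("'population' must be positive", call. = FALSE)
  switch(model$mode,
    anchored = guarded_floor(population * model$anchor_doses_per_day /
                               model$anchor_population),
    flat = guarded_floor(population * model$daily_fraction),
    explicit = model$doses_per_day)
}

#' Expected adverse events accrued per day of vaccination
#'
#' @param throughput Doses administered per day (>= 0).
#' @param per_dose_risk Probability of the adverse event per dose.
#' @return Expected events per day (real-valued, unrounded).
#' @examples
#' expected_events_per_day(50000, 1e-5)  # 0.5
#' @export
expected_events_per_day <- function(throughput, per_dose_risk) {
  if (any(throughput < 0)) stop("'throughput' must be >= 0", call. = FALSE)
  throughput * per_dose_risk
}

#' Days of throughput needed to accrue the required events
#'
#' Ceiling of `n_required / events_per_day`, always computed from the
#' unrounded events-per-day value.
#'
#' @param n_required Required event count (from [required_events()]).
#' @param events_per_day Expected events per day (> 0).
#' @return Whole days.
#' @examples
#' days_to_detect(47, 0.5)   # 94
#' days_to_detect(20, 0.75)  # 27
#' @export
days_to_detect <- function(n_required, events_per_day) {
  if (any(events_per_day <= 0))
    stop("signal never accrues: events per day must be positive",
         call. = FALSE)
  guarded_ceiling(n_required / events_per_day)
}

#' Parse a risk or rate given as a decimal or a "1/100000" fraction
#'
#' @param x Numeric, or a character like `"1.5/100000"`.
#' @return Numeric rate.
#' @export
parse_rate <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  stopifnot(is.character(x), length(x) == 1)
  x <- gsub("[ ,]", "", x)
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("cannot parse rate '", x, "'", call. = FALSE)
    return(as.numeric(parts[1]) / as.numeric(parts[2]))
  }
  out <- suppressWarnings(as.numeric(x))
  if (is.na(out)) stop("cannot parse rate '", x, "'", call. = FALSE)
  out
}

#' Specify a days-to-detect scenario
#'
#' Bundles an SCCS design, a per-dose adverse-event risk, a population
#' stratum, a throughput model and the jurisdiction sets to evaluate.
#'
#' @param design An [sccs_design()].
#' @param per_dose_risk Probability of the adverse event per administered
#'   dose; numeric or a `"1.5/100000"` string.
#' @param throughput A [throughput_model].
#' @param rows List of character vectors of jurisdiction names; each entry
#'   yields one result row (singletons and pools). Optional names on the
#'   list override the automatic row labels.
#' @param stratum Population stratum (`"total"` or `"18-39"`).
#' @param national_aggregation How a `"Canada"` row's throughput is formed
#'   under a population-scaled model: `"summed"` adds the 13 per-jurisdiction
#'   floored throughputs; `"direct"` applies the model to the published
#'   national count. The two agree on days-to-detect for all shipped
#'   scenarios.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(design, per_dose_risk, throughput, rows,
                          stratum = "total",
                          national_aggregation = c("summed", "direct")) {
  stopifnot(inherits(design, "sccs_design"),
            inherits(throughput, "throughput_model"),
            is.list(rows), length(rows) >= 1)
  per_dose_risk <- parse_rate(per_dose_risk)
  if (per_dose_risk <= 0 || per_dose_risk >= 1)
    stop("'per_dose_risk' must lie in (0, 1)", call. = FALSE)
  structure(
    list(design = design, per_dose_risk = per_dose_risk,
         stratum = stratum, throughput = throughput, rows = rows,
         national_aggregation = match.arg(national_aggregation)),
    class = "scenario_spec")
}

row_throughput <- function(members, spec, registry) {
  model <- spec$throughput
  if (model$mode == "explicit") return(model$doses_per_day)
  if (length(members) == 1 && members == "Canada") {
    if (spec$national_aggregation == "summed") {
      all_names <- setdiff(unique(registry$jurisdiction[
        registry$stratum == spec$stratum]), "Canada")
      return(sum(vapply(all_names, function(nm) {
        jurisdiction_throughput(stratum_count(nm, spec$stratum), model)
      }, numeric(1))))
    }
    return(jurisdiction_throughput(stratum_count("Canada", spec$stratum),
                                   model))
  }
  if ("Canada" %in% members)
    stop("'Canada' cannot be pooled with other jurisdictions", call. = FALSE)
  sum(vapply(members, function(nm) {
    jurisdiction_throughput(stratum_count(nm, spec$stratum), model)
  }, numeric(1)))
}

row_label <- function(members) {
  if (length(members) == 1) return(members)
  abbrevs <- vapply(members, function(nm) get_jurisdiction(nm)$abbrev,
                    character(1))
  paste(abbrevs, collapse = " + ")
}

#' Evaluate a scenario: one days-to-detect row per jurisdiction set
#'
#' For each requested set of jurisdictions: pools the stratum populations,
#' assigns throughput (per-member floored throughputs are summed for pools),
#' converts throughput to expected events per day, and reports the days
#' needed to accrue the design's required event count.
#'
#' @param spec A [scenario_spec()].
#' @param registry Population registry data frame; defaults to the packaged
#'   [census_registry()].
#' @return A data frame with one row per requested set: `label`,
#'   `population`, `throughput_per_day`, `events_per_day` (full precision),
#'   `days_to_detect`.
#' @examples
#' spec <- scenario_spec(
#'   design = sccs_design(3),
#'   per_dose_risk = "1/100000",
#'   throughput = throughput_anchored(50000, 14223942),
#'   rows = list("Ontario", c("Ontario", "Quebec")))
#' run_scenario(spec)
#' @export
run_scenario <- function(spec, registry = census_registry()) {
  stopifnot(inherits(spec, "scenario_spec"))
  n_req <- required_events(spec$design)$n_required
  labels <- names(spec$rows)
  out <- lapply(seq_along(spec$rows), function(i) {
    members <- spec$rows[[i]]
    popn <- sum(vapply(members, stratum_count, numeric(1),
                       stratum = spec$stratum))
    thr <- row_throughput(members, spec, registry)
    epd <- expected_events_per_day(thr, spec$per_dose_risk)
    lab <- if (!is.null(labels) && !is.na(labels[i]) && nzchar(labels[i]))
      labels[i] else row_label(members)
    data.frame(label = lab, population = popn, throughput_per_day = thr,
               events_per_day = epd,
               days_to_detect = days_to_detect(n_req, epd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Adverse events averted by detecting a signal sooner
#'
#' If pooling detects the signal `days_alone - days_pooled` days earlier,
#' vaccination at the pooled pace accrues that many days' worth of expected
#' events which an earlier intervention could avert. Rounded up to whole
#' events (an interrupted day still exposes people that day).
#'
#' @param days_alone Days to detect using the single jurisdiction.
#' @param days_pooled Days to detect using the pool (<= `days_alone`).
#' @param pooled_events_per_day Expected events per day at the pooled pace.
#' @return Whole events averted.
#' @examples
#' events_averted(85, 36, 0.55641)  # 28
#' @export
events_averted <- function(days_alone, days_pooled, pooled_events_per_day) {
  if (days_alone < days_pooled)
    stop("'days_alone' must be at least 'days_pooled'", call. = FALSE)
  guarded_ceiling((days_alone - days_pooled) * pooled_events_per_day)
}

#' Deaths averted given a case-fatality rate
#'
#' Floor of `events * case_fatality`: only whole realized deaths are
#' counted.
#'
#' @param events Whole events averted.
#' @param case_fatality Case-fatality probability in \[0, 1\].
#' @return Whole deaths.
#' @examples
#' deaths_averted(28, 0.23)  # 6
#' @export
deaths_averted <- function(events, case_fatality) {
  if (case_fatality < 0 || case_fatality > 1)
    stop("'case_fatality' must lie in [0, 1]", call. = FALSE)
  guarded_floor(events * case_fatality)
}

#' Expected adverse-event count in a population
#'
#' Planning arithmetic: `population * acceptance * ae_risk`, the expected
#' number of adverse events if a fraction `acceptance` of the population is
#' vaccinated and each vaccinee carries risk `ae_risk`.
#'
#' @param population Person count.
#' @param acceptance Vaccine acceptance (uptake) probability.
#' @param ae_risk Adverse-event probability per vaccinee.
#' @return Expected events (real-valued).
#' @export
expected_adverse_events <- function(population, acceptance, ae_risk) {
  stopifnot(acceptance >= 0, acceptance <= 1, ae_risk >= 0, ae_risk <= 1)
  population * acceptance * ae_risk
}
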