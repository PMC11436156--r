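# Report surface: JSON scenario configs, CSV emission and printable tables.
# The shipped example configs under extdata regenerate the package's
# reference scenario tables cell for cell; analysis/ scripts drive these
# functions from the command line.

#' Read a scenario configuration from JSON
#'
#' The document carries keys `design` (`relative_incidence`, `risk_days`,
#' `observation_days`, `alpha`, `power`), `per_dose_risk`, `stratum`,
#' `throughput` (`mode` plus the mode's parameters; anchored mode may name
#' an `anchor_jurisdiction` instead of an `anchor_population`, resolved
#' against the registry in the config's stratum), `rows` (array of arrays
#' of jurisdiction names), optional `labels`, and `national_aggregation`.
#' Probabilities may be decimals or `"1.5/100000"` strings.
#'
#' @param path Path to the JSON config. The packaged examples live under
#'   `system.file("extdata", package = "sccspool")`:
#'   `myocarditis_table1.json`, `vitt_table2.json`,
#'   `hypothetical_table3_rare.json`, `hypothetical_table3_common.json`.
#' @param registry Population registry used to resolve an anchor
#'   jurisdiction.
#' @return A [scenario_spec()].
#' @export
read_scenario_config <- function(path, registry = census_registry()) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- cfg$design
  design <- sccs_design(relative_incidence = as.numeric(d$relative_incidence),
                        risk_days = as.integer(d$risk_days),
                        observation_days = as.integer(d$observation_days),
                        alpha = as.numeric(d$alpha),
                        target_power = as.numeric(d$power))
  stratum <- if (is.null(cfg$stratum)) "total" else as.character(cfg$stratum)
  tp <- cfg$throughput
  model <- switch(as.character(tp$mode),
    anchored = {
      apop <- if (!is.null(tp$anchor_population)) {
        as.numeric(tp$anchor_population)
      } else {
        stratum_count(as.character(tp$anchor_jurisdiction), stratum)
      }
      throughput_anchored(as.numeric(tp$anchor_doses_per_day), apop)
    },
    flat = throughput_flat(parse_rate(tp$daily_fraction[[1]])),
    explicit = throughput_explicit(as.numeric(tp$doses_per_day)),
    stop("unknown throughput mode '", tp$mode, "'", call. = FALSE))
  rows <- lapply(cfg$rows, function(r) unlist(r, use.names = FALSE))
  if (!is.null(cfg$labels)) names(rows) <- unlist(cfg$labels)
  scenario_spec(design = design,
                per_dose_risk = parse_rate(cfg$per_dose_risk[[1]]),
                throughput = model, rows = rows, stratum = stratum,
                national_aggregation =
                  if (is.null(cfg$national_aggregation)) "summed"
                  else as.character(cfg$national_aggregation))
}

#' Run a JSON scenario config, optionally writing machine-readable CSV
#'
#' @param path Path to a scenario config (see [read_scenario_config()]).
#' @param output Optional CSV path; written with full-precision
#'   events-per-day.
#' @param registry Population registry.
#' @return The scenario result data frame, invisibly when `output` is set.
#' @export
run_scenario_config <- function(path, output = NULL,
                                registry = census_registry()) {
  spec <- read_scenario_config(path, registry)
  res <- run_scenario(spec, registry)
  if (!is.null(output)) {
    write_scenario_csv(res, output)
    return(invisible(res))
  }
  res
}

#' Write scenario rows to CSV at full precision
#'
#' @param rows Result data frame from [run_scenario()].
#' @param path Output CSV path.
#' @export
write_scenario_csv <- function(rows, path) {
  out <- rows
  out$events_per_day <- format(out$events_per_day, digits = 15,
                               scientific = FALSE, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Format scenario rows as a human-readable table
#'
#' Events/day are shown to 2 decimals, with values below 0.005 rendered as
#' `"<0.01"`; days and throughput are whole numbers. The unrounded
#' events/day always remains available in the data frame itself.
#'
#' @param rows Result data frame from [run_scenario()].
#' @return Character vector of table lines (also printed).
#' @export
format_scenario_table <- function(rows) {
  epd <- ifelse(rows$events_per_day < 0.005, "<0.01",
                sprintf("%.2f", rows$events_per_day))
  lines <- sprintf("%-32s %12s %12s %8s %6d",
                   rows$label,
                   format(rows$population, big.mark = ","),
                   format(rows$throughput_per_day, big.mark = ","),
                   epd, rows$days_to_detect)
  header <- sprintf("%-32s %12s %12s %8s %6s", "Jurisdiction(s)",
                    "Population", "Doses/day", "Ev/day", "Days")
  out <- c(header, lines)
  cat(out, sep = "\n")
  invisible(out)
}

#' Print a sample-size report for an SCCS design
#'
#' Computes [required_events()] and prints the required event count,
#' critical value, attained power and the null/alternative case-position
#' probabilities.
#'
#' @param design An [sccs_design()].
#' @param ... Passed to [required_events()] (e.g. `method`).
#' @return The `"sccs_samplesize"` object, invisibly.
#' @export
samplesize_report <- function(design, ...) {
  res <- required_events(design, ...)
  print(design)
  print(res)
  invisible(res)
}
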