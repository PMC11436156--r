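#!/usr/bin/env Rscript
# What is earlier detection worth? Compares the VITT-type scenario's
# Ontario-alone timeline against the pooled timelines and converts the days
# saved into expected adverse events averted (ceiling: a partial day still
# exposes that day's vaccinees) and, via a ~23% case-fatality rate, deaths
# averted (floor: only whole realized deaths).
#
# Finding: the six-province pool detects the signal 49 days sooner than
# Ontario alone, averting up to 28 events and 6 deaths at the pooled
# accrual rate (30 events at the slightly higher national rate).

suppressPackageStartupMessages(library(sccspool))
dir.create("results", showWarnings = FALSE)

vitt <- run_scenario_config(system.file("extdata", "vitt_table2.json",
                                        package = "sccspool"))
alone <- vitt[vitt$label == "Ontario", ]
case_fatality <- 0.23

rows <- do.call(rbind, lapply(
  c("ON + PQ", "BC + AB + SK + MB + ON + PQ", "Canada"), function(lab) {
    pooled <- vitt[vitt$label == lab, ]
    saved <- alone$days_to_detect - pooled$days_to_detect
    ev <- events_averted(alone$days_to_detect, pooled$days_to_detect,
                         pooled$events_per_day)
    data.frame(pool = lab,
               days_alone = alone$days_to_detect,
               days_pooled = pooled$days_to_detect,
               days_saved = saved,
               pooled_events_per_day = pooled$events_per_day,
               events_averted = ev,
               deaths_averted = deaths_averted(ev, case_fatality))
  }))

write.csv(rows, "results/averted_harm.csv", row.names = FALSE)
print(rows, row.names = FALSE)
cat("wrote results/averted_harm.csv\n")
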