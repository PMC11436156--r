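ontario_anchor <- function() throughput_anchored(50000, 14223942)

myo_spec <- function() {
  read_scenario_config(extdata("myocarditis_table1.json"))
}
vitt_spec <- function() {
  read_scenario_config(extdata("vitt_table2.json"))
}

test_that("throughput models reproduce their reference values", {
  expect_equal(jurisdiction_throughput(14223942, ontario_anchor()), 50000)
  expect_equal(jurisdiction_throughput(1342153, ontario_anchor()), 4717)
  expect_equal(jurisdiction_throughput(4517570, throughput_flat(0.0035)),
               15811)
  expect_equal(jurisdiction_throughput(123, throughput_explicit(7500)), 7500)
  expect_error(jurisdiction_throughput(0, ontario_anchor()), "positive")
})

test_that("events per day and days-to-detect follow the accrual arithmetic", {
  expect_equal(expected_events_per_day(50000, 1e-5), 0.5)
  expect_equal(expected_events_per_day(0, 0.9), 0)
  expect_equal(expected_events_per_day(15811, 1.5e-5), 0.237165)
  expect_equal(days_to_detect(47, 0.5), 94)
  expect_equal(days_to_detect(20, 0.75), 27)
  expect_equal(days_to_detect(47, 0.09126), 516)
  # representation-error guard: 50000 * 1e-6 is a hair below 0.05
  expect_equal(days_to_detect(47, expected_events_per_day(50000, 1e-6)), 940)
  expect_error(days_to_detect(47, 0), "never accrues")
})

test_that("rates parse from decimals and fraction strings alike", {
  expect_equal(parse_rate("1/100000"), 1e-5)
  expect_equal(parse_rate("1.5/100,000"), 1.5e-5)
  expect_equal(parse_rate(0.00001), 1e-5)
  expect_equal(parse_rate("0.0035"), 0.0035)
  expect_error(parse_rate("one in ten"), "cannot parse")
})

test_that("the myocarditis scenario reproduces its reference table", {
  res <- run_scenario(myo_spec())
  expect_equal(res$days_to_detect, table1_days)
  expect_equal(res$throughput_per_day[1], 50000)
  expect_equal(res$throughput_per_day[2], 29885)
  expect_equal(res$events_per_day[1], 0.5)
  # national row: 13 summed per-jurisdiction floored throughputs
  expect_equal(res$throughput_per_day[13], 130028)
  expect_equal(res$label[11], "ON + PQ")
})

test_that("the VITT 18-39 scenario reproduces its reference table", {
  res <- run_scenario(vitt_spec())
  expect_equal(res$days_to_detect, table2_days)
  expect_equal(res$throughput_per_day[1], 15811)
  expect_equal(res$throughput_per_day[11], 23993)
  expect_equal(res$population[13], 11287640)
})

test_that("both hypothetical-rate scenarios reproduce their tables", {
  rare <- run_scenario(read_scenario_config(extdata(
    "hypothetical_table3_rare.json")))
  common <- run_scenario(read_scenario_config(extdata(
    "hypothetical_table3_common.json")))
  expect_equal(rare$days_to_detect, table3_rare_days)
  expect_equal(common$days_to_detect, table3_common_days)
  expect_equal(rare$label[11:12], c("ON/PQ", "BC/AB/SK/MB/ON"))
})

test_that("singleton rows equal their own pool of one", {
  spec <- scenario_spec(myo_design(), "1/100000", ontario_anchor(),
                        rows = list("Quebec", c("Quebec")))
  res <- run_scenario(spec)
  expect_equal(res$days_to_detect[1], res$days_to_detect[2])
  expect_equal(res$throughput_per_day[1], res$throughput_per_day[2])
})

test_that("a pool is never slower than its fastest member", {
  for (spec in list(myo_spec(), vitt_spec())) {
    res <- run_scenario(spec)
    singles <- res$days_to_detect[1:10]
    expect_lte(res$days_to_detect[11], min(singles[c(1, 2)]))
    expect_lte(res$days_to_detect[12], min(singles[1:6]))
    expect_lte(res$days_to_detect[13], min(singles))
  }
})

test_that("every emitted row brackets the required event count", {
  for (spec in list(myo_spec(), vitt_spec())) {
    n_req <- required_events(spec$design)$n_required
    res <- run_scenario(spec)
    expect_true(all(res$days_to_detect * res$events_per_day >= n_req - 1e-6))
    expect_true(all((res$days_to_detect - 1) * res$events_per_day <
                      n_req + 1e-6))
  }
})

test_that("pooled anchored throughput is the exact sum of member floors", {
  spec <- myo_spec()
  res <- run_scenario(spec)
  members <- c("British Columbia", "Alberta", "Saskatchewan", "Manitoba",
               "Ontario", "Quebec")
  summed <- sum(vapply(members, function(nm) {
    jurisdiction_throughput(get_jurisdiction(nm)$strata[["total"]],
                            spec$throughput)
  }, numeric(1)))
  expect_equal(res$throughput_per_day[12], summed)
})

test_that("summed and direct national aggregation agree on days to detect", {
  for (cfg in c("myocarditis_table1.json", "vitt_table2.json",
                "hypothetical_table3_rare.json",
                "hypothetical_table3_common.json")) {
    spec <- read_scenario_config(extdata(cfg))
    spec_sum <- spec; spec_sum$national_aggregation <- "summed"
    spec_dir <- spec; spec_dir$national_aggregation <- "direct"
    d_sum <- run_scenario(spec_sum)$days_to_detect[13]
    d_dir <- run_scenario(spec_dir)$days_to_detect[13]
    expect_equal(d_sum, d_dir)
  }
  expect_error(run_scenario(scenario_spec(
    myo_design(), 1e-5, ontario_anchor(),
    rows = list(c("Canada", "Ontario")))), "cannot be pooled")
})

test_that("a tenfold rarer event takes about tenfold longer to detect", {
  t1 <- run_scenario(myo_spec())
  t3 <- run_scenario(read_scenario_config(extdata(
    "hypothetical_table3_rare.json")))
  ratio <- t3$days_to_detect[1:10] / t1$days_to_detect[1:10]
  expect_true(all(abs(ratio - 10) / 10 < 0.01))
  expect_equal(t3$days_to_detect[1], 940)  # vs 94 at the tenfold rate
})

test_that("explicit-throughput scenarios cover unstratified subgroups", {
  # women 18-39 at ~7,500 doses/day under the VITT design
  women <- scenario_spec(vitt_design(), "1.5/100000",
                         throughput_explicit(7500),
                         rows = list(women_18_39 = "Ontario"),
                         stratum = "18-39")
  expect_equal(run_scenario(women)$days_to_detect, 178)
  # the whole-population Ontario VITT pace of 50,000 doses/day
  whole <- scenario_spec(vitt_design(), "1.5/100000",
                         throughput_explicit(50000),
                         rows = list("Ontario"))
  expect_equal(run_scenario(whole)$days_to_detect, 27)
})

test_that("averted-harm arithmetic matches the pooled VITT comparison", {
  res <- run_scenario(vitt_spec())
  six_epd <- res$events_per_day[12]
  expect_equal(six_epd, 0.55641)
  expect_equal(events_averted(85, 36, six_epd), 28)
  expect_equal(deaths_averted(28, 0.23), 6)
  expect_equal(events_averted(85, 85, six_epd), 0)
  expect_equal(events_averted(85, 34, 0.59259), 31)  # ceiling of 30.22
  expect_equal(deaths_averted(30, 0.23), 6)          # floor of 6.9
  expect_equal(deaths_averted(0, 0.23), 0)
  expect_error(events_averted(30, 40, 0.5), "at least")
  # national-rate variant of the headline comparison
  expect_equal(events_averted(85, 36, res$events_per_day[13]), 30)
})

test_that("expected adverse-event counts are the plain product", {
  expect_equal(expected_adverse_events(1000, 0.5, 0.01), 5)
  expect_equal(expected_adverse_events(14223942, 0.9, 0.01), 128015.478)
  expect_equal(expected_adverse_events(5e6, 0, 0.01), 0)
})

test_that("scenario CSV output round-trips at full precision", {
  res <- run_scenario(vitt_spec())
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_scenario_csv(res, path)
  back <- utils::read.csv(path)
  expect_equal(back$days_to_detect, res$days_to_detect)
  expect_equal(back$events_per_day, res$events_per_day, tolerance = 1e-12)
  lines <- format_scenario_table(res)
  expect_length(lines, nrow(res) + 1)
  expect_match(lines[11], "<0.01")  # Prince Edward Island's events/day
})
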