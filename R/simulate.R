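# Synthetic SCCS case series: generator, conditional estimator, and Monte
# Carlo verification of the analytic power and type-I error.
#
# The generative model follows directly from the design: a case's single
# event day falls in the risk window (placed at days 1..e of the window; a
# labelling convention, since only the in/out dichotomy enters the
# statistics) with probability rho*e / (rho*e + (T - e)), and uniformly
# within whichever segment it falls in.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Vectorized draw of N event days under a design.
r_event_days <- function(n, design) {
  e <- design$risk_days
  t_obs <- design$observation_days
  rho <- design$relative_incidence
  p_risk <- rho * e / (rho * e + (t_obs - e))
  in_risk <- stats::rbinom(n, 1, p_risk) == 1
  day <- integer(n)
  day[in_risk] <- sample.int(e, sum(in_risk), replace = TRUE)
  day[!in_risk] <- e + sample.int(t_obs - e, sum(!in_risk), replace = TRUE)
  day
}

#' Simulate a synthetic SCCS case series
#'
#' @param n_cases Number of cases (each contributes one event day).
#' @param design An [sccs_design()]; its relative incidence is the true
#'   effect of the generated data.
#' @param seed Optional integer seed; a fixed seed reproduces the dataset
#'   exactly and leaves the session RNG state untouched.
#' @return An object of class `"sccs_dataset"`: a list with `event_days`
#'   (day indices in `1..observation_days`), `risk_days`,
#'   `observation_days`, `n_cases`.
#' @examples
#' ds <- simulate_sccs(100, sccs_design(3), seed = 1)
#' count_in_risk(ds)
#' @export
simulate_sccs <- function(n_cases, design, seed = NULL) {
  stopifnot(inherits(design, "sccs_design"),
            n_cases >= 1, n_cases == round(n_cases))
  days <- with_seed(seed, r_event_days(n_cases, design))
  structure(list(event_days = days,
                 risk_days = design$risk_days,
                 observation_days = design$observation_days,
                 n_cases = as.integer(n_cases)),
            class = "sccs_dataset")
}

#' @export
print.sccs_dataset <- function(x, ...) {
  cat(sprintf("SCCS case series: %d cases, risk window 1..%d of %d days, %d in risk\n",
              x$n_cases, x$risk_days, x$observation_days, count_in_risk(x)))
  invisible(x)
}

#' Count events falling in the risk window
#'
#' The risk window occupies days `1..risk_days`, so day `risk_days` itself
#' is in-risk.
#'
#' @param dataset An [simulate_sccs()] dataset (or one read back from CSV).
#' @return Integer count of in-risk events.
#' @export
count_in_risk <- function(dataset) {
  stopifnot(inherits(dataset, "sccs_dataset"))
  sum(dataset$event_days <= dataset$risk_days)
}

#' Conditional maximum-likelihood estimate of the relative incidence
#'
#' For the single-risk-interval SCCS with all cases fully observed, the
#' conditional MLE given X of n events in risk is
#' `rho_hat = (X / (n - X)) * ((T - e) / e)`, with log-scale Wald variance
#' `1/X + 1/(n - X)`. Degenerate counts (X = 0 or X = n) yield sentinel
#' estimates (0 or `Inf`) with `NA` confidence bounds rather than errors.
#'
#' @param dataset An `"sccs_dataset"`.
#' @param confidence Confidence level of the Wald interval.
#' @return An object of class `"sccs_estimate"`: list with `rho_hat`,
#'   `ci_low`, `ci_high`, `n_in_risk`, `n_cases`.
#' @examples
#' ds <- simulate_sccs(500, sccs_design(3), seed = 7)
#' estimate_relative_incidence(ds)
#' @export
estimate_relative_incidence <- function(dataset, confidence = 0.95) {
  stopifnot(inherits(dataset, "sccs_dataset"),
            confidence > 0, confidence < 1)
  x <- count_in_risk(dataset)
  n <- dataset$n_cases
  e <- dataset$risk_days
  t_obs <- dataset$observation_days
  if (x == 0 || x == n) {
    est <- if (x == 0) 0 else Inf
    out <- list(rho_hat = est, ci_low = NA_real_, ci_high = NA_real_,
                n_in_risk = as.integer(x), n_cases = n)
    return(structure(out, class = "sccs_estimate"))
  }
  rho_hat <- (x / (n - x)) * ((t_obs - e) / e)
  se_log <- sqrt(1 / x + 1 / (n - x))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  structure(list(rho_hat = rho_hat,
                 ci_low = exp(log(rho_hat) - z * se_log),
                 ci_high = exp(log(rho_hat) + z * se_log),
                 n_in_risk = as.integer(x), n_cases = n),
            class = "sccs_estimate")
}

#' @export
print.sccs_estimate <- function(x, ...) {
  cat(sprintf("relative incidence %.3f (CI %.3f-%.3f), %d/%d events in risk\n",
              x$rho_hat, x$ci_low, x$ci_high, x$n_in_risk, x$n_cases))
  invisible(x)
}

#' Monte Carlo power of the exact SCCS signal test
#'
#' Simulates `reps` case series of `n_cases` events under the design's
#' relative incidence and reports the fraction in which the in-risk count
#' reaches the critical value of [binomial_critical_value()] at the null
#' probability e/T. The binomial Monte Carlo standard error accompanies the
#' estimate, alongside the analytic [attained_power()] it verifies.
#'
#' @param design An [sccs_design()].
#' @param n_cases Events per replicate.
#' @param reps Number of replicates (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @param method Critical-value convention, see [binomial_critical_value()].
#' @return List with `power`, `mc_se`, `critical_value`, `analytic_power`,
#'   `reps`.
#' @examples
#' empirical_power(sccs_design(3), 47, reps = 500, seed = 1)
#' @export
empirical_power <- function(design, n_cases, reps = 10000, seed = NULL,
                            method = c("normal", "exact")) {
  stopifnot(inherits(design, "sccs_design"), reps >= 100)
  method <- match.arg(method)
  p0 <- exposed_fraction(design)
  cc <- binomial_critical_value(n_cases, p0, design$alpha, method)
  if (is.na(cc)) {
    warning("cannot-reject: no rejection region at n = ", n_cases,
            "; power is 0", call. = FALSE)
    return(list(power = 0, mc_se = 0, critical_value = NA_integer_,
                analytic_power = 0, reps = reps))
  }
  counts <- with_seed(seed, {
    days <- r_event_days(reps * n_cases, design)
    colSums(matrix(days <= design$risk_days, nrow = n_cases))
  })
  phat <- mean(counts >= cc)
  list(power = phat,
       mc_se = sqrt(phat * (1 - phat) / reps),
       critical_value = cc,
       analytic_power = attained_power(n_cases, design, method),
       reps = reps)
}

#' Monte Carlo type-I error of the exact SCCS signal test
#'
#' [empirical_power()] with the relative incidence forced to 1: the
#' rejection fraction under the null, to be compared with the upper-tail
#' budget alpha/2.
#'
#' @inheritParams empirical_power
#' @return As [empirical_power()].
#' @export
empirical_type1 <- function(design, n_cases, reps = 10000, seed = NULL,
                            method = c("normal", "exact")) {
  null_design <- sccs_design(relative_incidence = 1,
                             risk_days = design$risk_days,
                             observation_days = design$observation_days,
                             alpha = design$alpha,
                             target_power = design$target_power)
  empirical_power(null_design, n_cases, reps = reps, seed = seed,
                  method = match.arg(method))
}

#' Run a power study and tabulate (optionally to CSV)
#'
#' Runs [empirical_power()] and [empirical_type1()] for one design and
#' event count, returning one tidy row per quantity; reps below 100 are
#' rejected.
#'
#' @inheritParams empirical_power
#' @param path Optional CSV output path.
#' @return Data frame with columns `quantity`, `relative_incidence`,
#'   `n_cases`, `reps`, `seed`, `estimate`, `mc_se`, `analytic`.
#' @export
power_study <- function(design, n_cases, reps = 10000, seed = NULL,
                        path = NULL) {
  if (reps < 100) stop("'reps' must be at least 100", call. = FALSE)
  pw <- empirical_power(design, n_cases, reps = reps, seed = seed)
  t1 <- empirical_type1(design, n_cases, reps = reps,
                        seed = if (is.null(seed)) NULL else seed + 1)
  out <- data.frame(
    quantity = c("power", "type1"),
    relative_incidence = c(design$relative_incidence, 1),
    n_cases = n_cases, reps = reps,
    seed = if (is.null(seed)) NA_integer_ else c(seed, seed + 1),
    estimate = c(pw$power, t1$power),
    mc_se = c(pw$mc_se, t1$mc_se),
    analytic = c(pw$analytic_power, t1$analytic_power),
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Round-trip a case series to CSV
#'
#' @param dataset An `"sccs_dataset"`.
#' @param path CSV path (`case_id,event_day`).
#' @export
write_sccs_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "sccs_dataset"))
  utils::write.csv(data.frame(case_id = seq_len(dataset$n_cases),
                              event_day = dataset$event_days),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sccs_csv
#' @param risk_days,observation_days Design windows of the stored series.
#' @export
read_sccs_csv <- function(path, risk_days, observation_days) {
  df <- utils::read.csv(path)
  days <- as.integer(df$event_day)
  if (any(days < 1 | days > observation_days))
    stop("event days outside 1..observation_days", call. = FALSE)
  structure(list(event_days = days,
                 risk_days = as.integer(risk_days),
                 observation_days = as.integer(observation_days),
                 n_cases = length(days)),
            class = "sccs_dataset")
}
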