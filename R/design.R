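#' Define an SCCS surveillance design
#'
#' A self-controlled case series (SCCS) design for a single post-vaccination
#' risk window: each case contributes one event day inside a `observation_days`
#' window, and the `risk_days` immediately following vaccination carry a
#' relative incidence of `relative_incidence` compared with the remaining
#' control time. Because every fixed between-person confounder cancels within
#' a case, power is driven entirely by the number of observed events.
#'
#' @param relative_incidence Ratio of event incidence during the risk window
#'   to incidence during the rest of the observation window (rho > 0).
#' @param risk_days Length of the post-vaccination risk window in days
#'   (0 < `risk_days` < `observation_days`).
#' @param observation_days Total observation window length in days.
#' @param alpha Two-sided significance level of the signal-detection test.
#' @param target_power Desired probability of detecting a true elevated risk.
#'
#' @return An object of class `"sccs_design"`.
#' @examples
#' myocarditis <- sccs_design(relative_incidence = 3)
#' vitt <- sccs_design(relative_incidence = 5)
#' @export
sccs_design <- function(relative_incidence, risk_days = 28,
                        observation_days = 180, alpha = 0.05,
                        target_power = 0.90) {
  stopifnot(is.numeric(relative_incidence), length(relative_incidence) == 1,
            is.numeric(risk_days), length(risk_days) == 1,
            is.numeric(observation_days), length(observation_days) == 1)
  if (relative_incidence <= 0)
    stop("'relative_incidence' must be positive", call. = FALSE)
  if (risk_days <= 0 || risk_days != round(risk_days) ||
      observation_days != round(observation_days))
    stop("'risk_days' and 'observation_days' must be positive whole days",
         call. = FALSE)
  if (risk_days >= observation_days)
    stop("'risk_days' must be strictly less than 'observation_days'",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (target_power <= 0 || target_power >= 1)
    stop("'target_power' must lie in (0, 1)", call. = FALSE)
  structure(
    list(relative_incidence = as.numeric(relative_incidence),
         risk_days = as.integer(risk_days),
         observation_days = as.integer(observation_days),
         alpha = as.numeric(alpha),
         target_power = as.numeric(target_power)),
    class = "sccs_design")
}

#' @export
print.sccs_design <- function(x, ...) {
  cat("SCCS design\n")
  cat(sprintf("  relative incidence : %.3g\n", x$relative_incidence))
  cat(sprintf("  risk window        : %d days of %d\n",
              x$risk_days, x$observation_days))
  cat(sprintf("  alpha (two-sided)  : %.3g\n", x$alpha))
  cat(sprintf("  target power       : %.3g\n", x$target_power))
  invisible(x)
}

#' Fraction of the observation window spent in the risk window
#'
#' Under the null hypothesis of no elevated risk, a fully observed,
#' vaccinated case's single event falls in the risk window with probability
#' equal to this fraction r = risk_days / observation_days.
#'
#' @param design An [sccs_design()].
#' @return The exposed fraction, a probability in (0, 1).
#' @examples
#' exposed_fraction(sccs_design(3))  # 28/180
#' @export
exposed_fraction <- function(design) {
  stopifnot(inherits(design, "sccs_design"))
  design$risk_days / design$observation_days
}

#' Probability a case's event falls in the risk window
#'
#' The single-risk-interval SCCS reduces to a binomial problem: under
#' relative incidence rho with exposed fraction r, each case's event lands in
#' the risk window independently with probability
#' p = rho * r / (1 + (rho - 1) * r). At rho = 1 this is r itself.
#'
#' @param relative_incidence Relative incidence rho (> 0).
#' @param exposed_fraction Exposed fraction r in (0, 1); see
#'   [exposed_fraction()].
#' @return The case-position probability, in (0, 1).
#' @examples
#' case_position_probability(3, 28 / 180)  # ~0.3559
#' @export
case_position_probability <- function(relative_incidence, exposed_fraction) {
  if (any(relative_incidence <= 0))
    stop("'relative_incidence' must be positive", call. = FALSE)
  if (any(exposed_fraction <= 0) || any(exposed_fraction >= 1))
    stop("'exposed_fraction' must lie strictly between 0 and 1",
         call. = FALSE)
  relative_incidence * exposed_fraction /
    (1 + (relative_incidence - 1) * exposed_fraction)
}
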