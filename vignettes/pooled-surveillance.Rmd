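---
title: "Methods: SCCS power and pooled days-to-detect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SCCS power and pooled days-to-detect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccspool)
```

## The model

`sccspool` plans surveillance for adverse events following immunization
with the self-controlled case series (SCCS) design restricted to its
simplest, most robust form: one risk interval per case. Each case is
observed for `observation_days` = $T$ days; the `risk_days` = $e$ days
immediately after vaccination carry relative incidence $\rho$ relative to
the remaining $T - e$ control days. Every case is assumed vaccinated and
fully observed for the whole window, so conditioning on a case having
exactly one event reduces the design to a Bernoulli trial per case: the
event lands in the risk window with probability

$$p(\rho) = \frac{\rho r}{1 + (\rho - 1) r}, \qquad r = e/T,$$

and the in-risk count $X$ among $n$ events is $\mathrm{Binomial}(n,
p(\rho))$, with $p(1) = r$ under the null. Note that the in-risk odds are
exactly $\rho$ times the null odds, which is what the conditional
maximum-likelihood estimator inverts:
$\hat\rho = \frac{X}{n - X}\cdot\frac{T - e}{e}$, with log-scale Wald
variance $1/X + 1/(n - X)$.

Power therefore depends only on the number of observed *events*, not on
cohort size — the property that makes pooled multi-jurisdiction
surveillance attractive: jurisdictions need only contribute cases, and the
question "how long until we can see the signal?" becomes "how long until
enough events accrue?".

The reference designs use $e = 28$, $T = 180$, two-sided $\alpha = 0.05$,
target power $0.90$, and $\rho = 3$ (a myocarditis-like signal) or $\rho =
5$ (a VITT-like signal). All parameters of `sccs_design()` are free, so
other windows (e.g. the 24-day risk interval in a 90-day window used in
some VITT analyses) are a constructor call away.

## The signal test and its critical value

Surveillance flags only *elevated* risk, so the two-sided level is spent
entirely on the upper tail: reject when $X \ge c$ at level $\alpha/2$.
Two conventions for $c$ are implemented, and the choice matters at the
small event counts this field operates at:

* **`method = "normal"` (default)** — the continuity-corrected normal
  deviate, $c = \lceil n p_0 + \tfrac12 + z_{1-\alpha/2}\sqrt{n p_0 q_0}
  \rceil$. Attained power is always computed exactly (binomial tail at
  $p(\rho)$); only the rejection threshold uses the approximation.
* **`method = "exact"`** — the smallest $c$ with
  $P(X \ge c \mid n, p_0) \le \alpha/2$, guaranteeing the realized size
  never exceeds the budget at any $n$.

The default was chosen because it is the convention under which the
package's reference scenario tables are internally consistent: it yields
47 required events for the $\rho = 3$ design and 20 for the $\rho = 5$
design (critical values 13 and 7), and those counts are the ones the
days-to-detect tables are built on. The exact-tail variant agrees at
$\rho = 3$ (47) but, because the upper tail at $c = 7$, $n = 20$ is
$0.0264$, a hair above $0.025$, it pushes the $\rho = 5$ requirement to 22
events. That two-event premium buys a strict size guarantee; the default's
realized size on the reference designs stays at or below $0.0264$, well
inside what 10,000-replicate simulation can distinguish from the nominal
budget (the test suite checks both claims). When no $c \le n$ satisfies
the criterion, a cannot-reject sentinel (`NA`) is returned and power is
defined as 0 — at $n = 5$, $p_0 = 0.5$, for instance, even five of five
in-risk events (probability $1/32$) cannot reach the $0.025$ level.

`required_events()` searches $n$ upward from 1. Exact-test power is
sawtoothed in $n$ (it drops each time the critical value steps up), so the
contract is "the smallest $n$ whose attained power meets the target"; an
optional `strict` mode additionally requires every larger $n$ up to a
horizon to pass. The default, non-strict contract is the one under which
the shipped results are computed; for both reference designs every $n$
below the reported minimum fails the target, so the two contracts differ
only in pathological corners of the design space. Asymptotic closed forms
(`approx_required_events()`, Wald-mixed and likelihood-ratio/KL) are
provided purely as cross-checks; both give 44 where the exact search gives
47, a reminder that normal approximations understate discreteness at these
sample sizes.

All binomial tails in the package are summed directly from log-scale
probability masses; the closed-form CDF (`pbinom`) appears only in the
test suite, as an independent oracle.

## From events to days: throughput and pooling

`run_scenario()` converts a required event count into days of vaccination
throughput. A jurisdiction administering $D$ doses/day against a per-dose
adverse-event risk $\pi$ accrues $D\pi$ expected events per day, and the
signal needs $\lceil n / (D\pi) \rceil$ days. Three throughput models are
supported, because the tabulated scenarios genuinely use all three:

* **anchored** — every jurisdiction vaccinates at the same *relative* pace
  as an anchor (the reference tables anchor to Ontario's 50,000 doses/day,
  about 0.35% of its population daily);
* **flat** — a stated fraction of the stratum population per day (the
  18–39 scenario uses exactly 0.35%/day);
* **explicit** — an absolute doses/day figure, for subgroups with no
  tabulated population (e.g. women aged 18–39 at roughly 7,500 doses/day).

Two rounding conventions are load-bearing and fixed package-wide:
per-jurisdiction throughputs are floored to whole doses *before* pooling
(a pool's throughput is the exact integer sum of member floors), and
days-to-detect always divides by the unrounded events/day — never by the
two-decimal display value (Quebec's 158 days comes from
$\lceil 47/0.29885 \rceil$, not $\lceil 47/0.30 \rceil = 157$). Floors and
ceilings are guarded by rounding to six decimals first, because binary
floating point makes, e.g., $47/(50{,}000 \times 10^{-6})$ land at
$940 + 2\times10^{-13}$, which a naive ceiling would print as 941.

A national (`"Canada"`) row can aggregate two ways: `"summed"` adds all 13
per-jurisdiction floored throughputs, `"direct"` applies the model to the
published national count. They can differ by a few doses/day (130,028 vs
130,034 in the anchored whole-population scenario, because flooring
happens in 13 places instead of one); the test suite asserts the resulting
days-to-detect agree in every shipped scenario.

## The packaged census registry

The registry ships 2021 Canadian census counts (strata `"total"` and
`"18-39"`) for the ten provinces, three territories, and Canada. The
territorial 18–39 counts are not published at that stratification; they
are a proportional split of the national 18–39 residual (42,223 persons),
constrained to sum to it exactly and flagged `basis = "synthetic"` in the
CSV. They exist so nation-wide pooled throughput can be assembled from all
13 jurisdictions; days-to-detect is insensitive to the split (both
national aggregation modes give the same days in every shipped scenario,
which the tests assert).

## Averted-harm arithmetic

If pooling detects a signal $\Delta$ days sooner, vaccination at the
pooled pace accrues $\Delta \times D\pi$ expected events that earlier
intervention could avert. `events_averted()` takes the ceiling (a partial
day still exposes that day's vaccinees); `deaths_averted()` multiplies by
a case-fatality probability and takes the floor (only whole realized
deaths). This ceiling/floor pairing is the one convention consistent with
both headline numbers of the VITT comparison — 28 events from 49 days at
the six-province pace of 0.55641 events/day, and 6 deaths at 23% case
fatality. The choice of pooled pace is itself a modelling decision: the
same 49 days at the slightly higher *national* pace of 0.59259 events/day
averts 30 events. The package computes both and leaves the choice of
denominator to the analyst.

## The synthetic-data generator and what passing tests show

`simulate_sccs()` draws each case's event day hierarchically: in-risk with
probability $\rho e / (\rho e + T - e)$ (which equals $p(\rho)$), then
uniformly within the chosen segment. The risk window is placed at days
$1..e$ by convention — only the in/out dichotomy enters any statistic, so
placement is labelling, not modelling, and is deliberately not
configurable. Seeded runs are bit-reproducible and restore the session RNG
state on exit. `empirical_power()` simulates full case series through this
generator (not just binomial counts) and rejects when the in-risk count
reaches the critical value, so the Monte Carlo path exercises the same
machinery users call.

The generator emulates exactly what the power engine assumes: fully
observed, vaccinated cases; constant baseline incidence across the window;
one event per case; no censoring. It does *not* emulate age-varying
baseline risk, event-dependent observation ends, time-varying vaccination
uptake, or between-jurisdiction rate heterogeneity. Agreement between
`empirical_power()` and `attained_power()` therefore validates the
arithmetic chain (generator → counting → critical value → power), not the
design's robustness on real data, where those departures are the
first-order worries.

Problem sizes in the shipped suite were chosen to keep the full run within
a coffee break while leaving Monte Carlo error far below the margins being
checked: 10,000 replicates for the headline power and type-I checks
(binomial standard error ≈ 0.003), 2,000–4,000 for grid checks across
$n \in \{20, 47, 100\}$ and $\rho \in \{2, 3, 5\}$, 400 replicates of
$n = 500$ cases for estimator recovery (median $\hat\rho$ within 5% of
truth), and brute-force oracle comparisons at every $n \le 200$.

## Degenerate inputs and numerical choices

* $\hat\rho$ at $X = 0$ or $X = n$: sentinel point estimates (0, `Inf`)
  with `NA` Wald bounds — degenerate counts are reported, never thrown.
* Cannot-reject sample sizes: critical value `NA`, power 0, and
  `empirical_power()` warns rather than fails.
* `required_events()` refuses $\rho \le 1$ ("no finite sample size for
  non-elevated risk") rather than looping forever.
* Rates parse as decimals or `"1.5/100,000"` strings, since planning
  documents mix both notations.

## Known limitations

Single risk interval, no pre-exposure washout, no age stratification or
semiparametric baseline, no dose-specific exposures, no time-varying
throughput or uptake curves, and no sub-provincial geography. These are
deliberate scope edges: the planning question answered here — how many
events, and how many days of throughput, before a signal can surface — is
driven by the binomial reduction, and each extension would change the
answer only through second-order effects on $r$ and $\rho$ that a planner
can probe directly by varying the design parameters.
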