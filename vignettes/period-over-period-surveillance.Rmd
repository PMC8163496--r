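---
title: "Period-over-period surveillance with a sliding-window quasi-control distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Period-over-period surveillance with a sliding-window quasi-control distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emspop)
```

## The surveillance question

County EMS systems see opioid overdoses within minutes, not the year-plus lag
of verified mortality data. Given weekly counts of opioid-related EMS runs,
naloxone administrations, and multiple-naloxone runs, the question this
package answers is: **is the change observed in a recent focal window large
relative to the changes this series has itself produced historically?**

A focal window of $n$ weeks has mean weekly count $p_t$; a comparison window
of the same length has mean $p_{t-1}$. The period-over-period change is

$$\Delta_p = \frac{p_t - p_{t-1}}{p_{t-1}},$$

the familiar year-over-year growth rate from business analytics, generalized
to an arbitrary window length and shift. Two comparison modes are supported:

* **previous period** — the $n$ weeks immediately preceding the focal
  window. Sensitive, but confounded by seasonality when $n$ is near a half
  year (the two windows then sit in opposite seasonal phases).
* **same period, previous year** — the focal weeks shifted back 52 whole
  weeks. Seasonal effects largely cancel; residual trend remains.

A single focal window gives a treatment "group" of $n=1$ period, which rules
out regression-style difference-in-differences inference. Instead the same
statistic is computed for every admissible historical window position,
sliding back one calendar week at a time. This **quasi-control distribution**
is an empirical null: the focal change is summarized by its percentile
within it. The complementary Welch unequal-variances $t$ test compares the
two windows' weekly means directly, treating weeks as independent samples.

## Window conventions

Weeks are ISO-8601 calendar weeks (Monday start) by default; an MMWR
(Sunday-start) option exists because US surveillance systems use it. The
focal window is the $n$ weeks starting with the week *containing* the focal
start date. All windows consist of whole weeks; partial weeks at the data
boundaries stay in the weekly series (flagged `complete = FALSE`) but are
never used in windows.

The enumeration convention is exact and auditable: a control observation
exists for every week start such that both the primary and comparison
windows lie entirely within complete-week data and the primary window ends
strictly before the focal week's start. With $W$ complete pre-focal weeks
the control count is the closed form

$$N = W - \mathrm{span} + 1, \qquad
\mathrm{span} = \begin{cases} 2n & \text{previous-period mode} \\
n + 52 & \text{year-over-year mode.} \end{cases}$$

On 2014-01-01 to 2020-09-30 with $n = 29$ this gives $W = 322$, so 265
previous-period and 242 year-over-year controls. Published county analyses
of the same date range report counts a few weeks higher (270 and 246); their
enumeration convention is not stated precisely enough to reproduce, which is
why `table2` surfaces `n_controls` in every output. A 29-week "previous
period" written as September 2019 to March 2020 spans only 27 whole weeks;
under the whole-week convention the previous-period comparison is the 29 ISO
weeks 2019-08-19 through 2020-03-08.

Percentiles use a strict-less rule, $100 \cdot \#\{d : d < \Delta_{focal}\} / N$
(ties excluded from the numerator); a midrank option gives ties half weight.
Controls whose comparison-window mean is zero have no defined change and are
dropped with a warning — possible for the rare multiple-naloxone outcome in
sparse data. The year shift is 52 weeks, not 365 days, to preserve
whole-week alignment; the cost is a ~1.25-day seasonal phase drift per year,
visible as a small nonzero year-over-year change on a purely seasonal series.

## Outcomes and run reconstruction

Deidentified extracts carry one row per treatment administered. Runs are
rebuilt with the composite key (incident date, birth date, gender); any
record missing a demographic component becomes its own run under a
deterministic record-unique fallback key, which can only split true runs,
never merge unrelated ones. A run is opioid-related if *either* impression
field matches the configured vocabulary (case-insensitive, trimmed); the
vocabulary ships as an illustrative default because real code lists are
agency-specific. "Naloxone administrations" counts **runs receiving
naloxone**, not total doses, so the three weekly outcomes nest (multiple ≤
naloxone ≤ runs) and the multiple-naloxone outcome is a subset of the
naloxone outcome; total-dose counting is available via
`aggregate_weekly(count_doses = TRUE)`. Exact duplicate rows are kept by
default — two identical naloxone rows may be two genuine doses — with a
`dedupe` flag for extracts known to double-log.

## Inference

`welch_test()` computes
$t = (m_1 - m_2)\big/\sqrt{s_1^2/n_1 + s_2^2/n_2}$ with Welch–Satterthwaite
degrees of freedom, from summary statistics — the form needed to check
published tables — and `welch_test_counts()` feeds it two count windows.
p-values come from the Student-$t$ distribution function and render
journal-style (three decimals, `<.001` below 0.001). No multiple-testing
adjustment is applied across the six outcome × mode tests, matching common
surveillance practice; treat the p-values as descriptive. Weekly counts are
Poisson-like, not normal, and adjacent weeks are correlated; the package
documents rather than corrects this. On identical Poisson groups with
$n = 29$ weeks the realized type-I error at $\alpha = .05$ stays within
$0.05 \pm 0.02$ (`welch_type1_rate()`, checked over 2,000 simulated pairs in
the test suite).

`seasonal_decompose()` is the classical additive decomposition (centered
moving average trend; per-week-of-cycle means of the detrended series,
centered; residual remainder), delegated to `stats::decompose()`. Classical
rather than STL because it is fully specified with no tuning parameters; it
is a diagnostic for whether the year-over-year mode is warranted, not part
of the estimator.

## The synthetic generator

`simulate_runs()` draws weekly counts around
$\lambda_w = \mu \cdot \mathrm{trend}(d) \cdot
(1 + a\sin(2\pi(\mathrm{yearfrac}(d) + \phi))) \cdot m^{[d \ge d_{step}]}$
and then fills in record-level structure. Defaults are the study conditions
the package is designed around:

| parameter | default | why |
|---|---|---|
| range | 2014-01-01 to 2020-09-30 | the 6.75-year history a county extract provides |
| $\mu$ (`baseline_weekly_mean`) | 20 runs/week | weekly scale of a large metropolitan county |
| $a$ (`seasonal_amplitude`) | 0.15 | mild but decomposition-visible yearly seasonality |
| seasonal period | 365.25 d, single sinusoid | simplest shape exhibiting yearly seasonality; peak near 1 April at $\phi = 0$ |
| trend knots | 0.75 → 1.25 (2017-07) → 0.90 (2020), flat after | rise-to-2017-then-decline shape of county overdose series |
| step | ×1.5 at 2020-03-10 | an emergency-declaration-scale surge |
| dose mixture | (.15, .60, .18, .07) for 0–3 doses | illustrative: ~25% of dosed runs get multiple doses; real mixture unpublished |
| counts | Poisson (negative binomial optional) | overdispersion is real but secondary |
| birth-date pool | 20,000 dates | expected identifier collisions < 0.1% of runs; shrink to stress deduplication |

Dates are uniform within each week; demographics make the composite key
quasi-unique (collisions possible, rare); with probability 0.2 the opioid
code appears only in the secondary impression, exercising the classifier's
OR rule. Everything is reproducible from `seed`
(`withr::with_seed`, byte-identical CSVs).

What the generator deliberately does **not** emulate: geographic structure,
patient-level recurrence across dates, COVID-19 case co-dynamics,
missing-field patterns, or an emergency-period shift in the dose mixture
(the step multiplies all three outcomes equally, whereas real emergencies
may raise severity faster than occurrence). Tests passing on this generator
therefore validate the *machinery* — counting, enumeration, percentile
placement — not the epidemiology of any real county.

## Problem sizes used in validation

The test suite validates enumeration against a brute-force scan on 200
randomized small series; recovers a pure step of $m = 1.5$ with mean focal
delta error under 2 percentage points (200 replicates at baseline 50);
and demonstrates percentile saturation — a ×1.5 step over realistic
seasonality and trend placing all three outcomes at or above the 95th
percentile of the previous-period control distribution in at least 90% of
200 replicates, also at baseline 50 (chosen to keep the rare
multiple-naloxone outcome out of the small-count noise regime while
preserving every structural feature). The previous-period mode is the
demonstration target because it is the mode whose historical percentiles a
strong surge saturates; the year-over-year mode trades power for seasonal
robustness and sits lower by construction.

## Worked run

```{r example}
cfg <- sim_config(seed = 1)
weekly <- aggregate_weekly(
  build_runs(runs_to_records(simulate_runs(cfg))),
  cfg$start_date, cfg$end_date
)
report <- build_report(weekly, analysis_config())
report$table2
```

```{r figure, fig.width = 7, fig.height = 3, eval = requireNamespace("ggplot2", quietly = TRUE)}
plot_pop_series(report$figure_series$runs.previous_period,
                "Runs: period-over-period change, previous-period mode")
```

## Known limitations

* Weeks are treated as independent in the Welch tests; positive
  autocorrelation makes the p-values anti-conservative.
* Sliding windows overlap, so the quasi-control distribution's observations
  are strongly dependent; the percentile is a descriptive placement, not a
  calibrated p-value.
* The percent-change columns in `table1` are recomputed from the rounded
  means displayed, so the printed table is always internally consistent;
  unrounded changes are available from `focal_comparison()`.
* With only one focal period, nothing distinguishes the named emergency from
  any other event in the same window; causal language should be avoided.
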