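---
title: "Screening and testing lifestyle triggers in daily symptom diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and testing lifestyle triggers in daily symptom diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nof1diary)
```

## The problem

Chronic recurrent conditions — migraine, chronic pain flares, anxiety
episodes — recur often enough that a single patient can serve as their own
control. The N-of-1 approach alternates two questions: *is factor A
associated with my condition?* (hypothesis generation) and *does changing
factor A reduce how often it occurs?* (hypothesis testing). This package
implements that loop for daily **binary** diaries: one row per calendar
day, each variable recorded as happened / did not happen, with an outcome
(the condition) and candidate risk factors (exposures the user thinks may
matter).

Three modelling commitments shape everything downstream:

* **A day is the unit of analysis.** "Multiple times per day" collapses to
  "occurred that day". Within-day intensity or multiplicity is out of
  model.
* **An unlogged day is not a zero.** Absence of a row means no
  information; a logged 0 means the event did not occur. Lag-1 analysis
  pairs only *consecutive calendar days*, so a gap in logging breaks the
  pair rather than silently pairing day 5 with day 9. (Whether consecutive
  entries or consecutive days is the "right" reading of a daily tracker is
  genuinely open; consecutive calendar days is adopted because the causal
  question — does yesterday's exposure raise today's risk — is only
  well-posed for adjacent days.)
* **Days without an explicit phase are baseline.** A single-phase diary
  needs no phase column; an intervention phase is declared per day, and
  the phase boundary is taken literally (no washout handling — a
  documented limitation, since carry-over from the baseline regime will
  dilute an intervention contrast).

## Hypothesis generation: the phi screen

For each outcome–factor pair and each lag in {0, 1}, the complete day
pairs are cross-tabulated into a 2×2 table and summarised by the phi
coefficient,

$$\phi = \frac{n_{11}n_{00} - n_{10}n_{01}}
             {\sqrt{r_1\, r_0\, c_1\, c_0}},$$

with $r$ and $c$ the row (factor) and column (outcome) totals. Phi is
exactly the Pearson correlation of the two underlying 0/1 day series —
the property the test suite verifies against a brute-force oracle — so it
is symmetric in its arguments, lies in $[-1, 1]$, and flips sign when
either variable's coding is flipped.

When a marginal is zero (a constant column, routine in short diaries) phi
is undefined; the screen reports `NA` with a machine-readable reason
rather than erroring, and undefined results always sort after defined
ones. Results are ranked by $|\phi|$, ties broken by more supporting days,
then factor name.

Screening begins at **three complete pairs** — below that no value is
reported at all — and each result carries a qualitative reliability tier
driven purely by its pair count: `insufficient` (< 3), `low` (3–13),
`moderate` (14–29), `high` (≥ 30). The tiers put a documented, testable
form on the fact that a correlation from a week of data is an unstable
estimate (the standard error of phi is roughly $1/\sqrt{n}$: about 0.3 at
10 days, 0.1 at 90). Thresholds are configurable via `tier_thresholds()`.

No multiplicity adjustment is applied by default: the screen mimics a
tracker that surfaces raw correlations as *candidates for the user to test
by intervention*, not as confirmatory findings. `adjust = "bonferroni"`
adds exact-test p-values corrected across factors for research use.

## Hypothesis testing: phase comparison

`compare_phases()` contrasts the outcome's events-per-logged-day rate
between baseline and intervention, with a two-sided p-value from the exact
test on the phase × event-day table. Unlogged days are excluded from the
denominators rather than imputed — missingness in self-logged diaries is
plausibly informative (bad days may go unlogged), and any imputation would
be unvalidated here. `nof1_cycle()` packages one full loop: the screen run
on the baseline slice, plus the phase comparison when an intervention
exists.

## Exact tests

Tests of proportions use the exact conditional approach. For a 2×2 table
the first cell is hypergeometric given the margins; the two-sided p-value
follows the probability-ordering rule — the total null probability of all
tables with the observed margins whose probability does not exceed the
observed table's. This is the dominant convention for the test (it is what
`stats::fisher.test` computes), chosen over doubling the one-sided tail;
probabilities are compared with a relative tie tolerance of 1e-7 so
enumeration is reproducible across arithmetic orderings. Zero-margin
tables admit a single configuration and return p = 1.

For R×C tables, `fisher_exact_rxc()` enumerates the full lattice of
margin-preserving tables when it contains at most `max_enumeration`
(default 1e5) tables — the lattice is counted first by dynamic
programming — and otherwise estimates the same quantity by Monte Carlo
over `stats::r2dtable()` draws with a fixed seed, reporting which method
was used and the add-one estimate $(1 + \#\{\text{as extreme}\})/(B+1)$
with its standard error. Chi-square approximations, continuity corrections
and mid-p variants are deliberately out of scope.

## The packaged survey fixtures

The package ships verbatim transcriptions of the summary tables from a
180-participant feasibility pilot of a daily symptom tracker:
demographics, conditions chosen for tracking (212 condition choices),
recurrence frequency, attitude changes, and follow-up/adoption by
demographic category, plus the usage counts reported in the study's
running text. `pct()` reproduces the printed percentages with
half-away-from-zero rounding (46/80 → 58; banker's rounding would give
57.5 → 58 too, but fails elsewhere, e.g. 2/16 → 12 instead of the printed
13), and the test suite recomputes **every** printed percentage from the
counts.

Source quirks are preserved and flagged rather than corrected:

* the demographics table lists 1 grade-school-only participant where the
  follow-up table uses a denominator of 4 (0/4); both appear as printed;
* the education section states n = 177, but its doctorate cell (3.9) was
  evidently divided by the full 180; the fixture records the divisor that
  reproduces the print, with the discrepancy noted in the code;
* the printed follow-up p-values for education (.04) and race adoption
  (.05) do not reproduce under this package's exact test (which agrees
  with `stats::fisher.test` to enumeration accuracy, giving ≈ .005 and
  ≈ .61 respectively), nor under chi-square or trend variants we tried.
  The producing software/variant is unstated in the source, so recomputed
  and printed values are reported side by side and never gated against
  each other. The attitude-change table's p-values cannot be reconstructed
  at all (the underlying paired tables are not printed) and are out of
  scope.

## The simulator

`nof1_scenario()` + `simulate_diary()` generate diaries from a transparent
generative model: each factor is an independent daily Bernoulli exposure;
the outcome on day $t$ is Bernoulli with probability

$$p_t = \mathrm{clip}_{[0,1]}\Big(p_0 + \sum_j \delta_j\, x_{j,\,t-\ell_j}\Big),$$

base rate $p_0$, risk differences $\delta_j$, lags $\ell_j \in \{0,1\}$
(day 1 receives no lag-1 contribution). Risk differences are the default
effect scale because they are the most transparent for day-count tests; an
odds-ratio mode (`effect_scale = "odds_ratio"`) composes effects
multiplicatively on the odds scale instead. Each day is then logged
independently with probability `adherence` — completely-at-random
missingness, chosen to mirror the reported adherence pattern (most users
missed few days; a few missed more than half). What the generator does
*not* emulate, and what passing tests therefore do not establish for real
diaries: informative missingness, weekly/seasonal periodicity,
autocorrelated exposures, carry-over effects longer than one day, and
continuous symptom intensity.

Base rates can be given as recurrence-frequency categories. Categories at
or slower than daily map to one event per period (weekly → 1/7, monthly →
1/30, every few months → 1/90, "less" → 1/240); "daily" maps to 0.8 and
"multiple times per day" to 0.95. The last is a modelling choice worth
dwelling on: a daily-binary diary cannot represent within-day
multiplicity, so the category collapses to a near-saturated daily
probability — and a near-constant outcome column has almost no variance
for any correlation to explain. The harness is expected to *surface* that
detection is close to impossible in this regime, not to hide it; it is a
real limitation of daily-binary tracking for very-high-frequency
conditions.

## Power, type-I error, and a non-monotonicity worth knowing about

`estimate_power()` simulates replicate diaries, screens each, and scores a
`detection_rule()`: by default the true factor must rank first with
$|\phi| \ge 0.3$ and tier at least `moderate`. The default rule is an
artifact convention (the emulated tracker defines none), and every piece
of it is explicit and replaceable.

For type-I error, a fixed threshold is dishonest unless calibrated:
`calibrate_phi_threshold()` simulates the null design, takes the empirical
$(1-\alpha)$ exceedance point of $|\phi|$, and — because phi is discrete
on finite tables — reports the *achieved* level alongside the threshold.
The harness default is $\alpha = 0.10$, a conventional screening level
that also keeps Monte Carlo error manageable at the replicate counts used
here. Acceptance-level checks compare a fresh 500-replicate detection rate
against the achieved level within three Monte Carlo standard errors.

One genuine finding from building the harness: with a **fixed** phi
threshold, power is *not* monotone in follow-up length when the population
phi sits below the threshold. More days concentrate the estimate around
its true value, so if that value is 0.22 and the cutoff is 0.3, longer
diaries detect *less* often. Monotonicity in horizon is a property of
level-calibrated tests, not of fixed cutoffs; the package's monotonicity
checks therefore run in the regime where the population phi exceeds the
threshold (risk differences 0.35–0.55 at base rate 0.2 and exposure 0.5,
population phi ≈ 0.36–0.55), and users comparing horizons at small
effects should calibrate the threshold per design instead.

Problem sizes used by the packaged checks — 500 replicates per power
estimate, 2000 for calibration, horizons of 30–90 days — are the
package's chosen balance of Monte Carlo error (se ≈ 0.013–0.022 on a
rate) against run time; all are arguments, not constants.

## Numerical and degenerate-input choices

* Phi on a zero-margin table is `NA` with a reason, never an exception;
  an `NA` phi can never satisfy a detection rule.
* Exact-test tie comparison uses relative tolerance 1e-7 (above).
* Probability clipping in the simulator applies only when co-occurring
  effects push $p_t$ outside $[0,1]$; scenarios whose *individual*
  effects already do so are rejected at construction.
* Per-replicate seeds are derived arithmetically from the master seed and
  kept inside R's 32-bit integer range; simulation never perturbs the
  caller's RNG stream.
* Diary CSV round-trips are exact by construction (ISO dates, blanks for
  missing, roles and subject id in `#` comment lines) and are
  property-tested over generated diaries.

## A worked cycle

```{r}
baseline <- nof1_scenario(
  n_days = 60, base_rate = 0.2,
  factors = data.frame(name = "late_caffeine", exposure_prob = 0.5,
                       lag = 1, effect = 0.4),
  seed = 11
)
d <- simulate_diary(baseline)
nof1_screen(d)

# the user intervenes: cuts the exposure entirely
intervention <- nof1_scenario(
  n_days = 60, base_rate = 0.2,
  factors = data.frame(name = "late_caffeine", exposure_prob = 0,
                       lag = 1, effect = 0.4),
  seed = 12
)
trial <- bind_phases(d, simulate_diary(intervention))
nof1_cycle(trial)
```

## Limitations

Beyond those noted above: lags are restricted to {0, 1} by design (longer
lags are rejected, not silently computed); multi-crossover (ABAB) designs
and Bayesian updating are out of scope; and the feasibility statistics the
fixtures reproduce are descriptive properties of one pilot cohort, not
estimates this package can generalise.
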