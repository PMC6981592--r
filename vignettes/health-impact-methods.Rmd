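---
title: "Estimating the health impact of a mass participation sporting event"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the health impact of a mass participation sporting event}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpseimpact)
```

## The model

Mass participation sporting events (MPSEs) — open-entry running, cycling
or swimming events — make many of their entrants train harder than they
otherwise would. `mpseimpact` quantifies that effect as a health impact
in quality-adjusted life years (QALYs) and in money, through a simple
multiplicative chain:

* an event attracts $A$ participants;
* a fraction $B$ of them performed *additional* vigorous physical
  activity (PA) to prepare;
* a fraction $C$ of those would, without the event, not have met the WHO
  guideline of at least 75 vigorous minutes per week — the *initially
  inactive*;
* each initially inactive preparer adds, on average, $D \times (F - E)$
  minutes of vigorous PA, where $D$ is the preparation length in weeks,
  $F$ the weekly vigorous minutes during preparation and $E$ the weekly
  minutes they report they would have done anyway.

The total additional vigorous activity attributable to the event is

$$G = A \times B \times C \times D \times (F - E),$$

converted to QALYs with a linear coefficient $q$ (default
$7.4\times10^{-6}$ QALY per additional vigorous minute, derived from an
estimated 0.0106768 QALYs for 30 extra weekly minutes sustained over a
48-week year: $0.0106768 / (30 \times 48)$, rounded at 7 decimals), and
monetized at reference values $V$ per QALY (defaults EUR 20,000, a
common cost-effectiveness threshold, and EUR 80,000, the Dutch ceiling
for spending per QALY):

$$H = G q, \qquad I_v = H v.$$

Two deliberate model assumptions are inherited from the framework's
epidemiological grounding and are *not* configurable away: participants
who already met the WHO vigorous guideline contribute zero impact (a
guard against assuming linear returns at high activity levels), and
negative per-person additional activity is floored at zero — the
framework values additional activity only; floored records are counted
and reported.

## Two computation modes

`run_framework()` takes the aggregate parameters directly.
`run_framework_from_records()` estimates them from a participant-level
survey cohort: $B$ is the extra-training fraction, $C$ the
initially-inactive fraction among extra trainers, and the total is the
*sum of per-record products* `prep_weeks * (weekly_prep - weekly_cf)`
over the initially inactive extra trainers, optionally scaled from the
cohort to a full event population.

The distinction matters. The mean of per-person products exceeds the
product of means whenever preparation length and weekly additional
minutes covary, and restricting to the initially inactive raises the
mean weekly gap further (a low counterfactual is half of a large gap).
For the bundled 2017 event parameterization the published chain uses
the survey mean of per-person totals over *all* extra trainers
(565 min) rather than $D(F-E) = 8.8 \times 63 = 554.4$; the inputs
object accepts `mean_additional_total` for exactly this reason and the
result reports both values so the discrepancy stays visible. On a
synthetic cohort drawn from the same marginal distributions, per-record
mode therefore lands systematically *above* the aggregate headline
(about 9.8 rather than 6.6 QALYs in the large-cohort limit): the
aggregate chain applies the all-trainer mean total to the inactive
subgroup, while per-record mode uses the inactive subgroup's own, larger
totals. We regard both as faithful answers to slightly different
questions and test per-record mode against a component-level
Monte-Carlo oracle rather than against the aggregate headline.

```{r chain}
res <- run_framework(marikenloop_framework_inputs())
res
```

All chained values are carried unrounded; presentation rounding
(counts to integers, minute totals and currency to the nearest 1,000,
QALYs to one decimal) lives only in the `presented` element and the
`rounding_report`, and never feeds back into the computation. Chaining
the *raw* inactive count (1589.35...) is what reproduces the published
EUR 532,000 upper value; chaining the printed 1589 would give 531,000.

## The survey schema and derived variables

A cohort is a CSV (see `cohort_schema()`) with one row per respondent:
demographics (age, weight, height), event distance (5/7.5/10 km),
training mode, self-rated health (1–5), habitual vigorous PA during
preparation (sessions/week × minutes/session), an extra-training flag,
and — for extra trainers only — preparation weeks, counterfactual PA
and self-rated health change (−2..+2). `derive()` computes BMI and its
WHO category (left-closed cutoffs at 18.5, 25, 30), weekly minutes as
sessions × minutes/session, the additional minutes per week and in
total, the initially-inactive flag (counterfactual weekly minutes
strictly below 75; exactly 75 meets the guideline) and the improvement
dichotomy (health change of +1 or +2). Records failing validation are
handled by listwise deletion with a reported count, the convention of
the survey analysis the schema mirrors; `strict = TRUE` turns any
violation into an error naming the row and field.

## The synthetic cohort generator

No raw survey data ship with the package, so the generator exists to
make every downstream stage testable. `marikenloop_preset()` encodes
the study conditions of the 2017 women-only running event sample:
n = 468 respondents, 32% extra trainers, age 42.3 ± 11.9, the
45/22/33% distance split, 8.8 ± 5.4 preparation weeks, and so on.
Continuous variables are normals truncated by rejection (not clipping,
which would put probability atoms on the boundaries) to the observed
survey ranges; session counts and preparation weeks are rounded to
integers after sampling; the fixed preset seed (20170521, the event
date) makes the preset cohort reproducible.

The only modelled dependency between variables is the injected
improvement association: the probability of reporting improved health
follows a two-level logistic model, with baseline probability 0.30 for
extra trainers at or below 450 total additional minutes and odds
multiplied by 2.49 above it. The baseline 0.30 is a free parameter
chosen so the pooled improved fraction is near the observed 0.42; the
conditional health-change splits (+1/+2 at 88/12% given improvement,
0/−1 at 93/7% otherwise) reproduce the observed 5% "much improved" vs
37% "somewhat improved" shares and the observed −1..2 range. No other
correlations are modelled — the source tables publish no covariance
information — so the generator reproduces marginals, not joint
structure. Consequences worth knowing: the derived additional-PA
variables have larger spread than the survey reports (their SD is
induced from independent components), and the initially-inactive
fraction among extra trainers converges to about 0.63 rather than the
observed 0.68. Passing tests therefore demonstrate correctness of the
pipeline under these stated conditions, not distributional fidelity of
real survey data.

## Statistical layer

Descriptives (`summarize_cohort()`) report n/min/max/mean/sample-SD per
variable, conditional variables over extra trainers only. Group
comparisons use Welch's unequal-variance t-test (the safer default when
group variances differ; the source analysis says only "independent
t-tests") and Pearson chi-square without continuity correction. The 2×2
odds ratio uses the cross-product with Wald log-scale intervals and the
Haldane–Anscombe 0.5 correction only when a cell is zero. Logistic
regression is fitted by iteratively reweighted least squares (tight
tolerance, 100 iterations max) with explicit separation and
rank-deficiency errors; with a single binary predictor its
exponentiated slope equals the 2×2 cross-product OR, which the test
suite verifies over a sweep of small tables. No multiple-testing
correction is applied, matching the analysis the layer mirrors.

The sample-size check uses $n_0 = z^2 p (1-p) / e^2$ with
$z = 1.959964$ for 95% confidence and the finite-population correction
$n = n_0 / (1 + n_0 / N)$, rounded to the nearest integer — for
$N = 7304$, $e = 0.05$, $p = 0.5$ this gives 365. The $(n_0 - 1)$
variant of the correction rounds to the same value here.

```{r stats}
sample_size_finite_population(7304)
odds_ratio_2x2(30, 70, 15, 85)
```

## Numerical and design choices

* The 450-minute additional-PA split is a configurable parameter
  (`pa_split_min`), defaulting to the published value; "strictly
  greater" defines the high group.
* The WHO boundary is inclusive (75 min/week meets the guideline); BMI
  categories use left-closed intervals.
* Odds-ratio estimation refuses tables with a zero margin; logistic
  fits refuse separation rather than returning divergent estimates.
* Probability vectors must sum to 1 within 1e−9; truncated-normal
  parameters with zero SD degenerate to point masses only when the mean
  lies inside the truncation range.
* Test problem sizes: generator moments are checked at n = 50,000
  against numerically integrated truncated-normal moments (within 3
  standard errors); odds-ratio recovery at n = 5,000 and 50,000;
  the logistic/cross-product identity over an exhaustive 4^4 grid of
  small tables. These sizes give Monte-Carlo error comfortably inside
  the asserted bands while keeping the default suite fast.

## Limitations

The framework is associational: it cannot separate the event's causal
effect from self-selection into preparation. It values vigorous PA
only (no moderate-intensity pathway, per its WHO-guideline framing),
assumes linear QALY returns below the guideline and zero above it,
ignores injuries and post-event maintenance, and treats survey
respondents as representative of the event population when scaling.
The synthetic generator reproduces marginal distributions and one
injected association; conclusions about real cohorts require real
records through the same interfaces.
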