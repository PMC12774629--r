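---
title: "SROI methodology: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SROI methodology: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sroikit)
```

## The model

Social Return on Investment (SROI) is a pragmatic form of cost-benefit
analysis: every input and every outcome is expressed in money, and the
headline result is the ratio of the discounted social value of outcomes to
the value of inputs,

$$\mathrm{SROI} = \frac{\sum_o \mathrm{PV}_o}{\sum_j I_j},$$

where $I_j$ are input items (cash, in-kind contributions, and stakeholder
time valued at replacement cost) and each outcome $o$ contributes

$$\mathrm{PV}_o = \sum_{t=1}^{D_o} q_o \, v_o \, m_o
  \frac{(1-\delta_o)^{t-1}}{(1+r)^{t-1}},$$

with $q_o$ the number of people with material change (the evidenced
quantity), $v_o$ the financial proxy (money value of one person-year of the
outcome, taken from a social-value databank), $m_o$ the combined impact
adjustment, $D_o$ the duration in years, $\delta_o$ the drop-off per year
after year 1, and $r$ the annual discount rate.

The combined impact adjustment
$m_o = (1-\text{deadweight})(1-\text{displacement})\times\text{attribution}$
removes, in turn: change that would have happened anyway, change merely
displaced from elsewhere, and change caused by something other than the
program. `sroikit` stores either the three components or a single
pre-combined multiplier per outcome row; both forms validate to $[0,1]$, so
the adjusted value can never exceed the raw value.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `discount_rate` | 0.035 | /year | UK Treasury rate for costs and outcomes after year 1; preferred over the 1.5% public-health rate because dementia is progressive and long horizons are implausible |
| `time_rate_pwd` | 7.20 | GBP/h | 2016 UK National Minimum Wage, the assumed wage of home care workers |
| `time_rate_caregiver` | 19 | GBP/h | average cost of replacing caregiver time with a paid home care worker |
| `hours_pwd_per_session` | 3 | h | 2 h activity + 1 h travel/preparation |
| `hours_family_per_session` | 2 | h | organizational and transport tasks per session attended by a loved one |
| `hours_staff_per_attendance` | 0.5 | h | on-site organization only, no travel |
| `duration_years` | 1 | years | cautious base case: well-being in a progressive condition is unlikely to persist untreated |
| `drop_off` | 0 | /year | inert while durations are 1; scenario analyses that extend duration should set it explicitly |

## Discounting conventions

Under the default convention (`"after_year1"`) year 1 is undiscounted and
year $t$ is divided by $(1+r)^{t-1}$, i.e. discounting applies to value
occurring *after* the first year. The alternative (`"from_year1"`) divides
year $t$ by $(1+r)^t$. All base-case durations are 1 year, so the base case
is convention-invariant; the two conventions only separate in multi-year
scenarios, and because the per-outcome drop-off rates behind the published
2-year scenario are not available, neither convention is asserted against
that scenario's ratio. Drop-off is applied as geometric decay from year 2
onward, the standard SROI treatment. Inputs are not discounted: all are
incurred during the 12-week delivery window.

Full precision is kept through every intermediate computation; rounding
(half-up, matching published whole-pound tables and two-decimal ratios)
happens only at the reporting boundary. `round_half_up()` guards the
floating-point tie case so that e.g. $909 \times 0.5 \times 19 = 8635.5$
rounds to 8636 even though the binary product falls a hair below the tie.

## The packaged worked example

`fixture_dementia_imagination()` encodes a complete impact map for a
12-week visual-arts program delivered to 125 people living with dementia
(plus 88 family and 58 staff caregivers) across residential-care, hospital
and community settings: five input lines totalling 189,498 GBP and thirteen
outcome rows valued with social-value-bank proxies.

One design question was genuinely open: the per-outcome deadweight,
displacement and attribution percentages live only in the source study's
supplementary impact map, which is not available. Three per-outcome adjusted
values *are* independently reported (well-being 373,350; feeling of control
150,889; confidence 109,003), and all three imply the same combined
multiplier to four decimals:

```{r multiplier}
373350 / (36 * 20323)
18 * 16427 * 0.5103003   # reported: 150,889
17 * 12565 * 0.5103003   # reported: 109,003
```

The fixture therefore carries a single calibrated multiplier
(0.5103003, from the well-being row) on all thirteen rows. Applied uniformly
it yields 914,143.8, while the reported output total is 980,717; the
difference, 66,573.2, is stored as an explicit map-level `residual` rather
than being smeared invisibly across rows. The residual represents adjusted
first-year value whose row-level attribution is unknown; it carries its own
duration and drop-off fields and so participates in duration scenarios like
any first-year value. Reports print it as its own labelled row. This keeps
the discrepancy visible and auditable; analyses that need strictly row-sum
totals can drop the residual and work with the 13 reconstructed rows.

Two further fixture constants were reverse-engineered from printed pairs
rather than copied from a source: the currency rates (1 GBP = 1.4740 USD =
1.3580 EUR, from 189,498 -> 279,320 / 257,338) and the 909 attendances
behind the participant-time line (from 8,636 / (0.5 x 19)). The
family-caregiver time line (13,090 GBP at 2 h x 19 GBP) implies a
non-integer 344.5 caregiver-session units; the fixture stores the printed
total with `unit_count = NA`, and the time-consistency invariant is enforced
only where a unit count is present.

## Evidencing

Outcome quantities come from three-wave longitudinal records (baseline T1,
~12 weeks T2, ~6 months T3). Classification of a (baseline, follow-up) score
pair is deterministic given the indicator's direction and rule:
`strict_improvement` counts only beneficial strict change, with ties
classified as `maintained` — a conservative choice that avoids over-claiming
benefits; `maintain_or_increase` also counts `maintained` (used for the
art-activity row, whose wording is explicitly "maintain or increase", unlike
the strict "increase" rows); `endorsed_at_followup` classifies from a single
follow-up endorsement (used for the T3-only yes/no questions asked of
caregivers). Assessability is complete-case *per outcome*, which is why the
thirteen denominators differ (98, 100, 61, ...), and the evidencing endpoint
wave is declared per indicator rather than assumed globally.

When a person with dementia has no reported self-score for a wave, the
informant (proxy) response substitutes, and substitutions are tallied per
outcome. Resolution prefers any reported self-score, is idempotent, and
ignores row order.

## The synthetic cohort generator

`generate_cohort()` exists so the evidencing stage is testable without any
study data. Its defaults *are* the study conditions: group sizes 125/88/58;
per-outcome improvement probabilities equal to the evidenced proportions
(e.g. well-being 36/98); assessability probabilities equal to
denominator/group size (98/125 for well-being); attendance drawn from a
normal with mean 7 and SD 3.83 truncated to [0, 12] and rounded (truncation
rather than resampling — simpler, deterministic, and the published moments
only support an approximate match); and a per-wave missing-self-report
probability of 0.21, chosen once so that the expected number of
proxy-substituted change scores among ~98 assessable pairs,
$(1-(1-0.21)^2) \times 98 \approx 37$, matches the substitution counts the
study reports (37 and 44). Substitution is simulated only for participants
with dementia, mirroring its actual use.

Scores are drawn so that `classify_change()` recovers each participant's
latent improvement flag *exactly* (improvers receive a beneficial shift
within the instrument's declared range; non-improvers a non-qualifying one).
Counted proportions are therefore exactly binomial with the specification's
parameters — the statistical contract every downstream test relies on. Two
assignment methods are provided: `"exact"` reproduces the expected counts
exactly (only the identities and scores vary with the seed) and is the
default because the worked example's quantities are fixed study results,
while `"binomial"` draws per-participant Bernoulli flags and backs the
parameter-recovery tests (200 replicates keep each mean counted proportion
within two binomial standard errors of its true probability).

What the generator deliberately does **not** emulate: site-level effects,
wave-specific dropout schedules (attrition enters only through per-outcome
assessability), correlation between outcomes within a participant, and any
relationship between attendance and improvement. Passing tests on synthetic
cohorts therefore demonstrate that the *accounting* — resolution,
classification, counting, valuation — is correct under known truth; they say
nothing about whether a real program works.

## Sensitivity scenarios

Scenarios are declarative edit lists applied to a copy of the map (the
original is never mutated): zeroing time inputs, scaling one stakeholder's
outcomes, setting all durations, scaling one proxy. Of the six packaged
scenarios, only the zero-time case is exactly reproducible from the packaged
map (it touches the input side alone: 980,717 / 148,138 = 6.62). The other
five depend on the unavailable per-outcome adjustment and drop-off detail;
they are shipped flagged `verified = FALSE` and the tests assert only that
their ratios stay above 1:1 and move in the reported direction — asserting
their exact published values would be fitting to numbers the packaged map
cannot reconstruct. The "well-being proxy 75% lower" scenario scales only
the good-overall-health proxy, per its wording.

## Numerical and degenerate-input choices

* Validation collects *all* violations and reports them with field paths in
  one error, so a malformed document is fixable in one pass; dangling ids
  are additionally classed as reference errors.
* A map with zero outcomes is valid and values to 0; a ratio with zero total
  inputs is an error (undefined), while zero outputs give ratio 0.
* Money is GBP-based; arithmetic across currencies is refused unless routed
  through an explicit conversion table in which GBP is exactly 1.
* JSON round-trips preserve whole-unit amounts exactly and proportions to
  15 significant digits.
* An empty evidencing denominator ("no assessable participants") is an error
  for a single outcome but is caught per row by `evidence_all()`, which
  keeps the fixture quantity, records the failure in the provenance table,
  and continues with the remaining outcomes.

## Problem sizes

Everything here is desk-scale. The full test suite generates dozens of
synthetic cohorts of 271 participants; the largest single computation is the
parameter-recovery experiment (200 replicates x 13 outcomes), which runs in
well under a minute on one core.

## Known limitations

The uniform calibrated multiplier is validated on only three of thirteen
rows; the residual quantifies exactly how much of the output total the
uniform rule cannot attribute. Multi-year scenario ratios are sensitive to
drop-off rates the packaged map does not contain and should be read as
directional. Financial proxies are map constants — there is no live
social-value-bank lookup and no willingness-to-pay elicitation — and no
QALY/cost-utility computation is attempted, as SROI and cost-utility answer
different questions.
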