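# sroikit

Social Return on Investment (SROI) analysis for health and care programs.

SROI is a pragmatic form of cost-benefit analysis: every input (cash,
in-kind contributions, stakeholder time) and every outcome (well-being,
confidence, social connection, ...) is expressed in money, and the headline
result is the social value generated per unit of currency invested,

```
SROI = Σ_o PV_o / Σ_j I_j,     PV_o = Σ_{t=1..D} q·v·m · (1-δ)^(t-1) / (1+r)^(t-1)
```

where `q` is the evidenced quantity (people with material change), `v` a
financial proxy (money value of one person-year of the outcome, from a
social-value databank), `m = (1-deadweight)·(1-displacement)·attribution`
the combined impact adjustment, `D` the outcome duration, `δ` the drop-off
per year after year 1 and `r` the discount rate (default 3.5%/year).

The package is aimed at health economists and evaluators of psychosocial
interventions whose benefits (e.g. for people living with dementia and their
caregivers) are poorly captured by cost-per-QALY frameworks. It provides:

* a schema-validated **impact map** data model (stakeholders → inputs →
  outcomes → indicators → financial proxies), with JSON/YAML readers and
  writers (`impact_map()`, `load_impact_map()`, `write_impact_map()`);
* **evidencing** of outcome quantities from three-wave participant-level
  records, with self-vs-proxy respondent resolution
  (`count_outcome()`, `evidence_all()`);
* **valuation** with impact adjustments, drop-off and discounting
  (`adjusted_value()`, `present_value()`, `total_inputs()`,
  `total_outputs()`);
* the **SROI ratio** and a declarative one-way **sensitivity-scenario
  engine** (`sroi_ratio()`, `apply_scenario()`, `sensitivity_suite()`);
* a seedable **synthetic cohort generator** with known ground truth for
  testing the evidencing stage (`generate_cohort()`,
  `recovery_experiment()`);
* a fully worked impact map for a 12-week visual-arts program for people
  living with dementia (`fixture_dementia_imagination()`), used throughout
  the documentation and tests.

## Worked example

```r
library(sroikit)

map <- fixture_dementia_imagination()
map
#> <impact_map> schema 1.0
#>   10 stakeholders, 5 input items, 13 outcomes, 10 proxies, 13 indicators
#>   discount rate 3.5%/year; currencies: GBP, USD, EUR
#>   residual adjusted value: GBP 66,573.18

sroi_ratio(map)
#> <sroi_result> scenario 'base'
#>   inputs:   GBP 189,498.00
#>   outputs:  GBP 980,717.00 (present value)
#>   SROI ratio: 5.18 : 1
```

An input of 189,498 GBP (state funding 103,292; partner in-kind 44,846; and
participant, family and staff time at 19,634 / 13,090 / 8,636, valued at
7.20 and 19 GBP/h) generated 980,717 GBP of social value across 13 outcomes,
i.e. **5.18 GBP of social value per 1 GBP invested**. The largest single
contribution is improved well-being for people with dementia
(36 of 98 assessable participants × the good-overall-health proxy of
20,323 GBP/person-year × combined adjustment 0.5103 ≈ 373,350 GBP).

One-way sensitivity scenarios are declarative map edits:

```r
suite <- sensitivity_suite(map, scenarios_sensitivity_suite())
suite[, c("scenario_id", "ratio_2dp", "verified")]
#>          scenario_id ratio_2dp verified
#>                 base      5.18     TRUE
#>            zero_time      6.62     TRUE
#>             pwd_half      3.13    FALSE
#>          family_half      4.98    FALSE
#>           staff_half      5.00    FALSE
#>            two_years     10.18    FALSE
#>  wellbeing_proxy_low      3.70    FALSE
```

Valuing all stakeholder time at zero raises the ratio to 6.62 (a smaller
denominator); halving the outcomes of any one stakeholder group or cutting
the well-being proxy by 75% lowers it, and every scenario stays above 1:1.
Rows flagged `verified = FALSE` depend on per-outcome adjustment and
drop-off detail the packaged map does not contain, so only their direction —
not their exact value — is meaningful (see the methodology vignette).

Evidencing runs on participant-level records; a synthetic cohort with known
ground truth stands in for study data:

```r
gen <- generate_cohort(study_spec(seed = 42))
ev <- attr(evidence_all(gen$records, map), "evidence")
head(ev[, c("outcome_id", "numerator", "denominator", "percent",
            "n_proxy_substituted")], 3)
#>       outcome_id numerator denominator percent n_proxy_substituted
#> 1      wellbeing        36          98    36.7                  34
#> 2 art_engagement        53         100    53.0                  36
#> 3     confidence        17          61    27.9                  20
```

36 of 98 assessable people with dementia improved on the quality-of-life
total (36.7%), with 34 of those change scores relying on an informant
(proxy) response because a self-report was missing.

See `vignettes/sroi-methodology.Rmd` for the model, the calibration of the
combined adjustment multiplier, the residual reconciliation constant, and
what the synthetic generator does and does not emulate.

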