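#' Packaged impact map: 12-week visual-arts program for people with dementia
#'
#' A fully worked impact map for a UK visual-arts program delivered to people
#' living with dementia across residential care, hospital and community
#' settings: 11 groups x 12 weekly sessions (132 sessions), 125 participants
#' with dementia, 88 family caregivers and 58 staff caregivers.
#'
#' Inputs (2015/16 GBP): state funding 103,292; partner in-kind contributions
#' 44,846 (venues, curating exhibitions); participant time 19,634 (909
#' attendances x 3 h x 7.20 GBP National Minimum Wage); family-caregiver time
#' 13,090 (2 h per session attended by a loved one x 19 GBP, home-care-worker
#' rate; the printed total implies a non-integer 344.5 caregiver-session
#' units, so the unit count is stored as `NA` and only the total is kept);
#' staff-caregiver time 8,636 (909 attendances x 0.5 h x 19 GBP). Total
#' 189,498.
#'
#' Outcomes: 13 rows (6 for people with dementia, 3 for family caregivers, 4
#' for staff), each with the evidenced quantity/denominator, a one-year
#' duration, and a social-value-bank financial proxy. Impact adjustments
#' (deadweight, displacement, attribution) are carried as a single combined
#' multiplier calibrated on the well-being row: 373,350 / (36 x 20,323) =
#' 0.5103003. The same multiplier reproduces the two other independently
#' reported row values (feeling of control 150,889; confidence 109,003) to
#' within 0.1%, validating the uniform rule where it is checkable. Applied
#' uniformly to all 13 rows it yields 914,143.8, short of the reported output
#' total of 980,717; the difference (66,573.2) reflects per-row adjustment
#' detail available only in the source's supplementary impact map and is
#' stored explicitly as the map's `residual` — a documented reconciliation
#' constant, not hidden in any row.
#'
#' Currency rates (2016-01-01): 1 GBP = 1.4740 USD = 1.3580 EUR, recovered
#' from the reported conversion 189,498 GBP = 279,320 USD = 257,338 EUR.
#'
#' @return a validated `impact_map`.
#' @examples
#' map <- fixture_dementia_imagination()
#' total_inputs(map)   # GBP 189,498
#' sroi_ratio(map)     # 5.18 : 1
#' @export
fixture_dementia_imagination <- function() {
  stakeholders <- rbind(
    stakeholder("state", "The state", "inputs_only",
                "Funder of the art groups; no material outcomes assumed."),
    stakeholder("partners", "Partner organizations", "inputs_only",
                "Contributed venues and curation in kind; footfall effects not measured."),
    stakeholder("pwd", "People living with dementia", "included",
                "Primary stakeholders attending the groups.", group = "pwd"),
    stakeholder("family", "Family caregivers", "included",
                "Anticipated impact on art engagement, social connectivity and attitudes.",
                group = "family_caregiver"),
    stakeholder("staff", "Staff caregivers", "included",
                "Regular contact with participants could change engagement and attitudes.",
                group = "staff_caregiver"),
    stakeholder("artists", "Artists delivering the sessions", "excluded",
                "Negligible material impact anticipated."),
    stakeholder("nhs", "NHS", "excluded",
                "Health-care use was not collected."),
    stakeholder("nonparticipants", "Nonparticipating residents", "excluded",
                "Did not meet inclusion criteria or did not consent."),
    stakeholder("social_networks", "Participants' wider social networks", "excluded",
                "Beyond the scope of the evaluation."),
    stakeholder("public", "General public in the study settings", "excluded",
                "Engagement activities' public impact not included.")
  )

  inputs <- rbind(
    input_item("state", "cash", "Running costs for 132 sessions (excluding research costs)",
               103292),
    input_item("partners", "in_kind", "Use of venues, promoting and curating exhibitions",
               44846),
    input_item("pwd", "time", "3 h per session attended (2 h group + 1 h travel/preparation) at minimum wage",
               19634, hours_per_unit = 3, unit_count = 909, hourly_rate = 7.20),
    input_item("family", "time", "2 h organizational tasks per session attended by a loved one at home-care-worker rate",
               13090, hours_per_unit = 2, unit_count = NA_real_, hourly_rate = 19),
    input_item("staff", "time", "0.5 h organizational tasks per attendance at home-care-worker rate",
               8636, hours_per_unit = 0.5, unit_count = 909, hourly_rate = 19)
  )

  indicators <- rbind(
    indicator("demqol_total", "DEMQOL total", "higher_is_better",
              "strict_improvement", "T1", "T3", 28, 112),
    indicator("art_activity", "art activity count", "higher_is_better",
              "maintain_or_increase", "T1", "T3", 0, 12),
    indicator("demqol_q5", "DEMQOL Q5 felt confident", "higher_is_better",
              "strict_improvement", "T1", "T3", 1, 4),
    indicator("demqol_q13", "DEMQOL Q13 wanted to do but could not", "lower_is_better",
              "strict_improvement", "T1", "T3", 1, 4),
    indicator("lonely_item", "feels lonely item", "lower_is_better",
              "strict_improvement", "T1", "T3", 1, 4),
    indicator("demqol_q10", "DEMQOL Q10 felt lively", "higher_is_better",
              "strict_improvement", "T1", "T3", 1, 4),
    indicator("family_art", "family art activity at followup", "higher_is_better",
              "endorsed_at_followup", "T1", "T3", 0, 1),
    indicator("family_network", "family kept in touch with art-group contacts", "higher_is_better",
              "endorsed_at_followup", "T1", "T3", 0, 1),
    indicator("adq_family", "ADQ total (family)", "higher_is_better",
              "strict_improvement", "T1", "T3", 19, 95),
    indicator("staff_art", "staff art activity at followup", "higher_is_better",
              "endorsed_at_followup", "T1", "T3", 0, 1),
    indicator("staff_practice", "staff working-practice or visitor-perception change", "higher_is_better",
              "endorsed_at_followup", "T1", "T3", 0, 1),
    indicator("adq_staff", "ADQ total (staff)", "higher_is_better",
              "strict_improvement", "T1", "T3", 19, 95),
    indicator("staff_network", "staff kept in touch with art-group contacts", "higher_is_better",
              "endorsed_at_followup", "T1", "T3", 0, 1)
  )

  proxies <- rbind(
    financial_proxy("HEA1603", "Good overall health age 50+", 20323, "Social value bank"),
    financial_proxy("HOB1602_50", "Hobbies age 50+", 2424, "Social value bank"),
    financial_proxy("HEA1601", "High confidence age 50+", 12565, "Social value bank"),
    financial_proxy("HEA1406", "Feel in control of life age 50+", 16427, "Social value bank"),
    financial_proxy("ENV1609_50", "Feel belonging to neighborhood age 50+", 6004, "Social value bank"),
    financial_proxy("SPO1607", "Frequent mild exercise age 50+", 5527, "Social value bank"),
    financial_proxy("HOB1602", "Hobbies any age", 1515, "Social value bank"),
    financial_proxy("ENV1609", "Feel belonging to neighborhood any age", 3753, "Social value bank"),
    financial_proxy("EMP1610", "General training for the job", 1567, "Social value bank"),
    financial_proxy("EMP1611", "Employment training any age", 807, "Social value bank")
  )

  # combined deadweight/displacement/attribution multiplier calibrated on the
  # well-being row: reported adjusted value / (quantity x proxy)
  m <- 373350 / (36 * 20323)

  outcomes <- rbind(
    outcome("wellbeing", "pwd", "Increased well-being / improved mood",
            "demqol_total", 36, 98, "HEA1603", multiplier = m),
    outcome("art_engagement", "pwd", "Increased engagement with art",
            "art_activity", 53, 100, "HOB1602_50", multiplier = m),
    outcome("confidence", "pwd", "Increased confidence / self-esteem",
            "demqol_q5", 17, 61, "HEA1601", multiplier = m),
    outcome("control", "pwd", "Increased feeling of control over life / personal environment",
            "demqol_q13", 18, 61, "HEA1406", multiplier = m),
    outcome("loneliness", "pwd", "Reduced social isolation / increased belonging",
            "lonely_item", 6, 58, "ENV1609_50", multiplier = m),
    outcome("liveliness", "pwd", "Increased physical activity (felt lively)",
            "demqol_q10", 21, 98, "SPO1607", multiplier = m),
    outcome("family_art", "family", "Increased engagement with art",
            "family_art", 27, 54, "HOB1602", multiplier = m),
    outcome("family_network", "family", "Increased social support network",
            "family_network", 13, 47, "ENV1609", multiplier = m),
    outcome("family_attitude", "family", "Improved attitude toward dementia",
            "adq_family", 34, 70, "EMP1610", multiplier = m),
    outcome("staff_art", "staff", "Increased engagement with art",
            "staff_art", 23, 29, "HOB1602", multiplier = m),
    outcome("staff_prof_dev", "staff", "Professional development / increased prestige",
            "staff_practice", 28, 33, "EMP1611", multiplier = m),
    outcome("staff_attitude", "staff", "Improved attitude toward dementia",
            "adq_staff", 18, 45, "EMP1610", multiplier = m),
    outcome("staff_network", "staff", "Increased community engagement",
            "staff_network", 11, 20, "ENV1609", multiplier = m)
  )

  annual <- proxies$annual_value[match(outcomes$proxy_code, proxies$code)]
  raw_total <- sum(outcomes$quantity * annual)
  # reconciliation constant: reported output total minus what the uniform
  # calibrated multiplier yields from the 13 rows (= 66,573.2); documents
  # per-row adjustment detail that exists only in the source's supplementary
  # impact map
  residual <- list(
    value = 980717 - raw_total * m,
    duration_years = 1,
    drop_off = 0,
    note = paste("Adjusted first-year value not attributable to a printed",
                 "outcome row; reconciles the uniform calibrated multiplier",
                 "to the reported output total of 980,717 GBP.")
  )

  impact_map(
    stakeholders = stakeholders, inputs = inputs, indicators = indicators,
    proxies = proxies, outcomes = outcomes,
    discount_rate = 0.035,
    currency_table = currency_table(c(GBP = 1, USD = 1.4740, EUR = 1.3580)),
    residual = residual
  )
}

#' Packaged sensitivity scenarios for the worked example
#'
#' The six one-way scenarios reported alongside the base case: valuing all
#' stakeholder time at zero; only 50% of outcomes materializing for each of
#' the three included stakeholder groups in turn; all outcomes lasting 2
#' years instead of 1; and the well-being financial proxy being 75% lower.
#'
#' Only the zero-time scenario is exactly reproducible from the packaged map
#' (it touches the input side alone). The other five depend on per-outcome
#' adjustment and drop-off detail available only in the source's
#' supplementary impact map; their `verified` flag is `FALSE` and analyses
#' should assert direction, not value, for them.
#'
#' @return a named list of `scenario` objects, each carrying a `verified`
#'   field and, where applicable, a provenance `note`.
#' @export
scenarios_sensitivity_suite <- function() {
  unprinted <- paste("requires supplementary adjustment/drop-off rates --",
                     "not regression-tested")
  list(
    zero_time = scenario(
      "zero_time", "Zero value for the time of participants and caregivers",
      list(edit_zero_time_inputs("all")), verified = TRUE
    ),
    pwd_half = scenario(
      "pwd_half", "Only 50% of outcomes materialize for people with dementia",
      list(edit_scale_outcomes("pwd", 0.5)), verified = FALSE, note = unprinted
    ),
    family_half = scenario(
      "family_half", "Only 50% of outcomes materialize for family caregivers",
      list(edit_scale_outcomes("family", 0.5)), verified = FALSE, note = unprinted
    ),
    staff_half = scenario(
      "staff_half", "Only 50% of outcomes materialize for staff caregivers",
      list(edit_scale_outcomes("staff", 0.5)), verified = FALSE, note = unprinted
    ),
    two_years = scenario(
      "two_years", "All outcomes last 2 years instead of 1",
      list(edit_set_duration(2)), verified = FALSE, note = unprinted
    ),
    wellbeing_proxy_low = scenario(
      "wellbeing_proxy_low", "Well-being financial proxy 75% lower",
      list(edit_scale_proxy("HEA1603", 0.25)), verified = FALSE, note = unprinted
    )
  )
}
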