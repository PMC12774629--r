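# a minimal, residual-free impact map used for algebraic contracts
# (linearity, scaling) that the worked-example residual would obscure
tiny_map <- function(duration = 1, drop_off = 0, discount_rate = 0.035) {
  impact_map(
    stakeholders = rbind(
      stakeholder("funder", inclusion = "inputs_only"),
      stakeholder("a", group = "pwd"),
      stakeholder("b", group = "family_caregiver")
    ),
    inputs = rbind(
      input_item("funder", "cash", "grant", 1000),
      input_item("a", "time", "participant time", 216,
                 hours_per_unit = 3, unit_count = 10, hourly_rate = 7.20)
    ),
    indicators = rbind(
      indicator("up", "score", "higher_is_better", "strict_improvement",
                score_min = 0, score_max = 100),
      indicator("down", "pain", "lower_is_better", "strict_improvement",
                score_min = 0, score_max = 10)
    ),
    proxies = rbind(
      financial_proxy("P1", "proxy one", 500),
      financial_proxy("P2", "proxy two", 250)
    ),
    outcomes = rbind(
      outcome("o1", "a", "better score", "up", 4, 10, "P1",
              duration_years = duration, multiplier = 0.5, drop_off = drop_off),
      outcome("o2", "b", "less pain", "down", 3, 8, "P2",
              duration_years = duration, deadweight = 0.2, displacement = 0.1,
              attribution = 0.8, drop_off = drop_off)
    ),
    discount_rate = discount_rate
  )
}

# long-format records for one small hand-built cohort:
# participants p1..p5 measured on "score" (higher better) at T1/T3
hand_records <- function() {
  data.frame(
    participant_id = rep(c("p1", "p2", "p3", "p4", "p5"), each = 2),
    group = "pwd",
    site = "community",
    wave = rep(c("T1", "T3"), 5),
    respondent = "self",
    instrument = "score",
    score = c(80, 86,   # improved
              80, 80,   # maintained
              70, 60,   # declined
              50, NA,   # not assessable
              40, 45),  # improved
    sessions_attended = 7,
    stringsAsFactors = FALSE
  )
}
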