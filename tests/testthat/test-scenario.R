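test_that("the base case reproduces the published ratio", {
  res <- sroi_ratio(fixture_dementia_imagination())
  expect_equal(res$ratio_2dp, 5.18)
  expect_equal(res$ratio, 980717 / 189498, tolerance = 1e-9)
  expect_equal(as.numeric(res$total_inputs), 189498)
})

test_that("applying a scenario never mutates its input map", {
  map <- fixture_dementia_imagination()
  before <- write_impact_map(map)
  edited <- apply_scenario(map, scenarios_sensitivity_suite()$zero_time)
  expect_identical(write_impact_map(map), before)
  expect_false(identical(write_impact_map(edited), before))
  # empty edit list is the identity
  same <- apply_scenario(map, scenario("id", edits = list()))
  expect_identical(write_impact_map(same), before)
})

test_that("zeroing time inputs reproduces the published scenario", {
  map <- fixture_dementia_imagination()
  zt <- apply_scenario(map, scenarios_sensitivity_suite()$zero_time)
  expect_equal(as.numeric(total_inputs(zt)), 148138)
  expect_equal(sroi_ratio(zt)$ratio_2dp, 6.62)
})

test_that("scaling one stakeholder's outcomes touches only that stakeholder", {
  map <- fixture_dementia_imagination()
  half <- apply_scenario(map, scenario("h", edits = list(
    edit_scale_outcomes("pwd", 0.5))))
  v0 <- total_outputs(map)$per_outcome
  v1 <- total_outputs(half)$per_outcome
  is_pwd <- v0$stakeholder_id == "pwd"
  expect_equal(v1$present_value[is_pwd], v0$present_value[is_pwd] / 2)
  expect_equal(v1$present_value[!is_pwd], v0$present_value[!is_pwd])
})

test_that("scaled-outcome ratios agree with the closed-form oracle", {
  # new ratio = (T - (1 - f) V_s) / I, with V_s the stakeholder's PV share
  map <- fixture_dementia_imagination()
  T0 <- as.numeric(total_outputs(map)$total)
  I0 <- as.numeric(total_inputs(map))
  per <- total_outputs(map)$per_outcome
  for (s in c("pwd", "family", "staff")) {
    for (f in c(0, 0.5, 0.8)) {
      Vs <- sum(per$present_value[per$stakeholder_id == s])
      edited <- apply_scenario(map, scenario("x", edits = list(
        edit_scale_outcomes(s, f))))
      expect_equal(sroi_ratio(edited)$ratio, (T0 - (1 - f) * Vs) / I0,
                   tolerance = 1e-12)
    }
  }
})

test_that("ratio algebra: proxy doubling doubles, zero outputs give zero", {
  map <- tiny_map()
  base <- sroi_ratio(map)$ratio
  doubled <- apply_scenario(map, scenario("d", edits = list(
    edit_scale_proxy("P1", 2), edit_scale_proxy("P2", 2))))
  expect_equal(sroi_ratio(doubled)$ratio, 2 * base, tolerance = 1e-12)

  none <- apply_scenario(map, scenario("z", edits = list(
    edit_scale_outcomes("a", 0), edit_scale_outcomes("b", 0))))
  expect_equal(sroi_ratio(none)$ratio_2dp, 0)

  no_inputs <- impact_map(
    stakeholders = stakeholder("a", group = "pwd"),
    indicators = indicator("i", "x"),
    proxies = financial_proxy("P", "p", 1),
    outcomes = outcome("o", "a", "d", "i", 1, 1, "P", multiplier = 1)
  )
  expect_error(sroi_ratio(no_inputs), "undefined ratio")
})

test_that("unknown references in edits raise reference errors", {
  map <- tiny_map()
  expect_error(apply_scenario(map, scenario("x", edits = list(
    edit_scale_outcomes("ghost", 0.5)))), class = "sroi_reference_error")
  expect_error(apply_scenario(map, scenario("x", edits = list(
    edit_scale_proxy("GHOST", 0.5)))), class = "sroi_reference_error")
  expect_error(apply_scenario(map, scenario("x", edits = list(
    edit_zero_time_inputs(c("a", "ghost"))))), class = "sroi_reference_error")
})

test_that("the sensitivity suite runs every scenario and summarizes the range", {
  map <- fixture_dementia_imagination()
  suite <- sensitivity_suite(map, scenarios_sensitivity_suite())
  expect_equal(nrow(suite), 7)  # base + 6 scenarios
  expect_equal(suite$scenario_id[1], "base")
  expect_equal(suite$ratio_2dp[suite$scenario_id == "base"], 5.18)
  expect_equal(suite$ratio_2dp[suite$scenario_id == "zero_time"], 6.62)
  expect_true(all(suite$error == ""))

  # every scenario stays above 1:1 — social value exceeds the investment
  expect_true(all(suite$ratio > 1))

  # direction of change matches the reported table for the unverified rows
  base <- suite$ratio[suite$scenario_id == "base"]
  lower <- c("pwd_half", "family_half", "staff_half", "wellbeing_proxy_low")
  expect_true(all(suite$ratio[suite$scenario_id %in% lower] < base))
  expect_true(suite$ratio[suite$scenario_id == "two_years"] > base)
  expect_false(any(suite$verified[suite$scenario_id %in%
                                    c(lower, "two_years")]))

  rng <- attr(suite, "range")
  expect_equal(rng, range(suite$ratio_2dp))

  # restricted to the two verified rows the range is exactly as published
  verified <- sensitivity_suite(map, scenarios_sensitivity_suite()["zero_time"])
  expect_equal(attr(verified, "range"), c(5.18, 6.62))

  # empty scenario list: base case only
  base_only <- sensitivity_suite(map)
  expect_equal(nrow(base_only), 1)

  # a failing scenario is recorded, the suite continues
  broken <- scenario("bad", edits = list(edit_scale_proxy("GHOST", 2)))
  mixed <- sensitivity_suite(map, list(broken, scenarios_sensitivity_suite()$zero_time))
  expect_match(mixed$error[mixed$scenario_id == "bad"], "unknown proxy")
  expect_equal(mixed$ratio_2dp[mixed$scenario_id == "zero_time"], 6.62)
})
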