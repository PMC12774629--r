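test_that("the default cohort has the study's size and wave structure", {
  gen <- generate_cohort(study_spec(seed = 3))
  rec <- gen$records
  ids <- unique(rec$participant_id)
  expect_equal(length(ids), 125 + 88 + 58)
  expect_equal(length(unique(rec$participant_id[rec$group == "pwd"])), 125)
  expect_equal(length(unique(rec$participant_id[rec$group == "family_caregiver"])), 88)
  expect_equal(length(unique(rec$participant_id[rec$group == "staff_caregiver"])), 58)
  # every participant appears at all three waves
  waves_per_id <- tapply(rec$wave, rec$participant_id,
                         function(w) length(unique(w)))
  expect_true(all(waves_per_id == 3))
  # attendance is whole sessions within 0..12, for people with dementia
  att <- rec$sessions_attended[rec$group == "pwd"]
  expect_true(all(att >= 0 & att <= 12 & att == round(att)))
  expect_true(all(is.na(rec$sessions_attended[rec$group != "pwd"])))
})

test_that("generated scores classify exactly to the latent flags", {
  # the generator-classifier contract: counting recovers the ground truth,
  # whichever assignment method produced it
  map <- fixture_dementia_imagination()
  for (method in c("exact", "binomial")) {
    gen <- generate_cohort(study_spec(seed = 17), map, method = method)
    ev <- attr(evidence_all(gen$records, map), "evidence")
    truth <- gen$truth$counts
    expect_equal(ev$numerator, truth$n_improved,
                 info = paste("method", method))
    expect_equal(ev$denominator, truth$n_assessable,
                 info = paste("method", method))
  }
})

test_that("exact assignment reproduces the study's outcome table", {
  map <- fixture_dementia_imagination()
  gen <- generate_cohort(study_spec(seed = 5), map, method = "exact")
  ev <- attr(evidence_all(gen$records, map), "evidence")
  expect_equal(ev$numerator, c(36, 53, 17, 18, 6, 21, 27, 13, 34, 23, 28, 18, 11))
  expect_equal(ev$denominator, c(98, 100, 61, 61, 58, 98, 54, 47, 70, 29, 33, 45, 20))
  expect_equal(ev$percent[1], 36.7)  # well-being 36/98
})

test_that("degenerate probabilities hit the extremes", {
  probs0 <- stats::setNames(rep(0, 13), fixture_dementia_imagination()$outcomes$id)
  probs1 <- stats::setNames(rep(1, 13), names(probs0))
  spec0 <- cohort_spec(improvement_probs = probs0, seed = 2)
  gen0 <- generate_cohort(spec0)
  expect_true(all(gen0$truth$counts$n_improved == 0))

  spec1 <- cohort_spec(improvement_probs = probs1,
                       assessable_probs = probs1, proxy_only_prob = 0, seed = 2)
  gen1 <- generate_cohort(spec1)
  expect_equal(gen1$truth$counts$n_improved, gen1$truth$counts$n_assessable)
  n_group <- c(pwd = 125, family_caregiver = 88, staff_caregiver = 58)
  expect_equal(gen1$truth$counts$n_assessable,
               unname(n_group[gen1$truth$counts$group]))
})

test_that("the same seed yields byte-identical CSV output", {
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_participant_records(generate_cohort(study_spec(seed = 9))$records, p1)
  write_participant_records(generate_cohort(study_spec(seed = 9))$records, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  p3 <- tempfile(fileext = ".csv")
  write_participant_records(generate_cohort(study_spec(seed = 10))$records, p3)
  expect_false(identical(readBin(p1, "raw", file.size(p1)),
                         readBin(p3, "raw", file.size(p3))))
  unlink(c(p1, p2, p3))
})

test_that("proxy substitution is simulated for people with dementia only", {
  map <- fixture_dementia_imagination()
  gen <- generate_cohort(study_spec(seed = 21), map)
  rec <- gen$records
  expect_true(all(rec$respondent[rec$group != "pwd"] == "self"))
  expect_true(any(rec$respondent == "proxy"))
  ev <- attr(evidence_all(rec, map), "evidence")
  # substitutions occur on PwD rows; caregiver rows have none
  expect_true(all(ev$n_proxy_substituted[1:6] > 0))
  expect_true(all(ev$n_proxy_substituted[7:13] == 0))
  # expected substitution count for a pair outcome among ~98 assessable:
  # (1 - (1 - 0.21)^2) * 98 = 37; allow a generous stochastic band
  expect_gt(ev$n_proxy_substituted[1], 20)
  expect_lt(ev$n_proxy_substituted[1], 55)
})

test_that("the study spec carries the published probabilities", {
  spec <- study_spec()
  expect_equal(spec$improvement_probs[["wellbeing"]], 36 / 98)
  expect_equal(spec$improvement_probs[["staff_prof_dev"]], 28 / 33)
  expect_equal(spec$assessable_probs[["wellbeing"]], 98 / 125)
  expect_equal(round(125 * spec$assessable_probs[["wellbeing"]]), 98)
  expect_error(cohort_spec(improvement_probs = c(wellbeing = 1.2)), "\\[0, 1\\]")
})

test_that("recovery experiments are deterministic and track the truth", {
  spec <- study_spec(seed = 31)
  s1 <- recovery_experiment(spec, replicates = 5)
  s2 <- recovery_experiment(spec, replicates = 5)
  expect_equal(s1, s2)
  expect_equal(nrow(s1), 13)
  # even 5 replicates should keep the mean in a broad band around truth
  expect_true(all(abs(s1$bias) < 0.15))
})

test_that("empirical spread shrinks roughly like 1/sqrt(n)", {
  probs <- c(wellbeing = 0.4)
  assess <- c(wellbeing = 1)
  map <- impact_map(
    stakeholders = stakeholder("pwd", group = "pwd"),
    inputs = input_item("pwd", "cash", "x", 1),
    indicators = indicator("demqol_total", "DEMQOL total",
                           score_min = 28, score_max = 112),
    proxies = financial_proxy("P", "p", 100),
    outcomes = outcome("wellbeing", "pwd", "d", "demqol_total", 1, 100, "P",
                       multiplier = 1)
  )
  small <- cohort_spec(n_pwd = 100, n_family = 0, n_staff = 0,
                       improvement_probs = probs, assessable_probs = assess,
                       proxy_only_prob = 0, seed = 41)
  big <- cohort_spec(n_pwd = 400, n_family = 0, n_staff = 0,
                     improvement_probs = probs, assessable_probs = assess,
                     proxy_only_prob = 0, seed = 41)
  sd_small <- recovery_experiment(small, 60, map)$sd_prop
  sd_big <- recovery_experiment(big, 60, map)$sd_prop
  # quadrupling n should halve the SD, within a tolerant band
  expect_gt(sd_small / sd_big, 2 * 0.7)
  expect_lt(sd_small / sd_big, 2 * 1.4)
})
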