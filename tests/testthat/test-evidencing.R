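test_that("change classification follows direction and rule", {
  up <- indicator("u", "score", "higher_is_better", "strict_improvement",
                  score_min = 0, score_max = 100)
  expect_equal(classify_change(80, 86, up), "improved")
  expect_equal(classify_change(80, 80, up), "maintained")
  expect_equal(classify_change(80, 70, up), "declined")
  expect_true(is.na(classify_change(80, NA, up)))

  lonely <- indicator("l", "lonely", "lower_is_better", "strict_improvement",
                      score_min = 1, score_max = 4)
  expect_equal(classify_change(3, 1, lonely), "improved")  # often -> rarely
  expect_equal(classify_change(1, 3, lonely), "declined")
  expect_equal(classify_change(2, 2, lonely), "maintained")

  endorse <- indicator("e", "kept in touch", rule = "endorsed_at_followup",
                       score_min = 0, score_max = 1)
  expect_equal(classify_change(NA, 1, endorse), "improved")
  expect_equal(classify_change(NA, 0, endorse), "maintained")
  expect_true(is.na(classify_change(NA, NA, endorse)))

  expect_error(classify_change(80, 120, up), "outside the declared range")
})

test_that("qualifying sets distinguish strict improvement from maintenance", {
  expect_equal(qualifying_set(indicator("a", "x", rule = "strict_improvement")),
               "improved")
  expect_setequal(qualifying_set(indicator("a", "x", rule = "maintain_or_increase")),
                  c("improved", "maintained"))
  expect_equal(qualifying_set(indicator("a", "x", rule = "endorsed_at_followup")),
               "improved")
})

test_that("respondent resolution prefers reported self over proxy", {
  both <- data.frame(participant_id = "p1", respondent = c("self", "proxy"),
                     score = c(80, 75), stringsAsFactors = FALSE)
  pick <- resolve_respondent(both)
  expect_equal(pick$respondent, "self")
  expect_false(attr(pick, "substituted"))

  proxy_only <- both[both$respondent == "proxy", ]
  pick <- resolve_respondent(proxy_only)
  expect_equal(pick$respondent, "proxy")
  expect_true(attr(pick, "substituted"))

  # a self row whose score was not reported does not block substitution
  self_na <- both; self_na$score[self_na$respondent == "self"] <- NA
  pick <- resolve_respondent(self_na)
  expect_equal(pick$respondent, "proxy")
  expect_true(attr(pick, "substituted"))

  none <- both[0, ]
  pick <- resolve_respondent(none)
  expect_equal(nrow(pick), 0)
  expect_false(attr(pick, "substituted"))

  # idempotent and order-independent
  shuffled <- both[2:1, ]
  expect_equal(resolve_respondent(shuffled)$score,
               resolve_respondent(both)$score)
  expect_equal(resolve_respondent(resolve_respondent(both))$score,
               resolve_respondent(both)$score)
})

test_that("outcome counting uses per-outcome complete cases", {
  map <- tiny_map()
  out <- map$outcomes[1, , drop = FALSE]
  ind <- map$indicators[map$indicators$id == "up", , drop = FALSE]
  cnt <- count_outcome(hand_records(), out, ind, group = "pwd")
  # p4 has no follow-up: 4 assessable, 2 improved
  expect_equal(cnt$denominator, 4)
  expect_equal(cnt$numerator, 2)
  expect_equal(cnt$proportion, 0.5)
  expect_equal(cnt$percent, 50.0)
  expect_equal(cnt$n_proxy_substituted, 0)

  # nobody improves
  rec <- hand_records()
  rec$score[rec$wave == "T3"] <- rec$score[rec$wave == "T1"] - 1
  expect_equal(count_outcome(rec, out, ind)$numerator, 0)

  # empty denominator
  rec$score[rec$wave == "T3"] <- NA
  expect_error(count_outcome(rec, out, ind), "no assessable participants")
})

test_that("proxy substitution feeds the count and is tallied", {
  rec <- hand_records()
  # p1's T3 self-report missing; proxy reports the same improvement
  proxy_row <- rec[rec$participant_id == "p1" & rec$wave == "T3", ]
  proxy_row$respondent <- "proxy"
  rec$score[rec$participant_id == "p1" & rec$wave == "T3"] <- NA
  rec <- rbind(rec, proxy_row)
  map <- tiny_map()
  cnt <- count_outcome(rec, map$outcomes[1, ],
                       map$indicators[map$indicators$id == "up", ])
  expect_equal(cnt$denominator, 4)
  expect_equal(cnt$numerator, 2)
  expect_equal(cnt$n_proxy_substituted, 1)
})

test_that("counted proportions sit inside the binomial interval", {
  # binomial oracle: with true p = 0.30 and n = 400 assessable, the count
  # lies inside the central 99% binomial interval
  spec <- cohort_spec(n_pwd = 400, n_family = 0, n_staff = 0,
                      improvement_probs = c(wellbeing = 0.30),
                      assessable_probs = c(wellbeing = 1),
                      proxy_only_prob = 0, seed = 11L)
  map <- impact_map(
    stakeholders = stakeholder("pwd", group = "pwd"),
    inputs = input_item("pwd", "cash", "x", 1),
    indicators = indicator("demqol_total", "DEMQOL total",
                           score_min = 28, score_max = 112),
    proxies = financial_proxy("P", "p", 100),
    outcomes = outcome("wellbeing", "pwd", "d", "demqol_total", 1, 400, "P",
                       multiplier = 1)
  )
  gen <- generate_cohort(spec, map, method = "binomial")
  cnt <- count_outcome(gen$records, map$outcomes[1, ], map$indicators[1, ])
  ci <- stats::qbinom(c(0.005, 0.995), 400, 0.30) / 400
  expect_equal(cnt$denominator, 400)
  expect_gte(cnt$proportion, ci[1])
  expect_lte(cnt$proportion, ci[2])
})

test_that("evidencing the whole map rewrites quantities with provenance", {
  map <- tiny_map()
  rec <- hand_records()
  evd <- evidence_all(rec, map)
  ev <- attr(evd, "evidence")
  expect_equal(ev$source, c("counted", "fixture"))  # no records for group b
  expect_equal(evd$outcomes$quantity[1], 2)
  expect_equal(evd$outcomes$denominator[1], 4)
  # outcome o2 keeps its fixture quantity
  expect_equal(evd$outcomes$quantity[2], map$outcomes$quantity[2])
  expect_match(ev$error[2], "no assessable participants")
})

test_that("doubling every participant doubles counts, not proportions", {
  map <- tiny_map()
  rec <- hand_records()
  rec2 <- rec
  rec2$participant_id <- paste0(rec2$participant_id, "_dup")
  both <- rbind(rec, rec2)
  out <- map$outcomes[1, ]
  ind <- map$indicators[map$indicators$id == "up", ]
  c1 <- count_outcome(rec, out, ind)
  c2 <- count_outcome(both, out, ind)
  expect_equal(c2$numerator, 2 * c1$numerator)
  expect_equal(c2$denominator, 2 * c1$denominator)
  expect_equal(c2$proportion, c1$proportion)
})

test_that("adding a record never decreases a denominator", {
  map <- tiny_map()
  out <- map$outcomes[1, ]
  ind <- map$indicators[map$indicators$id == "up", ]
  rec <- hand_records()
  base_den <- count_outcome(rec, out, ind)$denominator
  extra <- data.frame(participant_id = "p9", group = "pwd", site = "community",
                      wave = c("T1", "T3"), respondent = "self",
                      instrument = "score", score = c(10, 20),
                      sessions_attended = 3, stringsAsFactors = FALSE)
  expect_gte(count_outcome(rbind(rec, extra), out, ind)$denominator, base_den)
  # an unrelated instrument's record changes nothing
  noise <- extra
  noise$instrument <- "other"
  expect_equal(count_outcome(rbind(rec, noise), out, ind)$denominator, base_den)
})

test_that("the CSV dialect round-trips and rejects bad headers", {
  path <- tempfile(fileext = ".csv")
  rec <- hand_records()
  write_participant_records(rec, path)
  back <- read_participant_records(path)
  expect_equal(back$score, rec$score)
  expect_equal(back$participant_id, rec$participant_id)

  bad <- tempfile(fileext = ".csv")
  writeLines("id,who,when\n1,2,3", bad)
  expect_error(read_participant_records(bad), "header")
  unlink(c(path, bad))
})
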