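test_that("item recoding follows the configured table in both orientations", {
  expect_equal(recode_item(3, 1), 0)
  expect_equal(recode_item(3, 3), 100)
  expect_equal(recode_item(21, 1), 100)
  expect_equal(recode_item(21, 6), 0)
  expect_equal(recode_item(1, 1:5), c(100, 75, 50, 25, 0))
  expect_true(is.na(recode_item(5, NA)))
  expect_error(recode_item(13, 7), "7")
  expect_error(recode_item(13, 7), "13")
})

test_that("subscale scoring aggregates recoded member items", {
  # physical functioning: ten 3-point items (items 3..12)
  responses <- rep(NA_real_, 36)
  recoded_target <- c(0, 0, 50, 50, 100, 100, 0, 50, 100, 50)
  responses[3:12] <- recoded_target / 50 + 1   # invert item 3..12 recode
  expect_equal(score_subscale(responses, "physical_functioning"), 50)
  expect_equal(score_subscale(responses, "physical_functioning",
                              aggregator = "median"), 50)
  expect_error(score_subscale(responses, "not_a_subscale"))
})

test_that("complete-case rule blanks any subscale with a missing member item", {
  responses <- uniform_record("best")
  responses[21] <- NA   # pain member item
  scores <- score_all(responses)
  expect_true(is.na(scores[["pain"]]))
  expect_false(anyNA(scores[setdiff(names(scores), "pain")]))
  # half rule still scores pain from its one answered item
  half <- score_all(responses, missing_policy = "half_rule")
  expect_equal(half[["pain"]], 100)
})

test_that("best and worst response records score exactly 100 and 0 everywhere", {
  best <- score_all(uniform_record("best"))
  worst <- score_all(uniform_record("worst"))
  subscales <- names(rand36_subscales())
  expect_equal(unname(best[subscales]), rep(100, 8))
  expect_equal(unname(worst[subscales]), rep(0, 8))
  # health change is the reverse-recoded ordinal item 2 (higher = better)
  expect_equal(best[["health_change"]], 5)
  expect_equal(worst[["health_change"]], 1)
})

test_that("record missing only item 2 keeps all eight scores, drops health change", {
  responses <- uniform_record("best")
  responses[2] <- NA
  scores <- score_all(responses)
  expect_false(anyNA(scores[names(rand36_subscales())]))
  expect_true(is.na(scores[["health_change"]]))
})

test_that("improving any single item never decreases a subscale score", {
  set.seed(31)
  recode <- rand36_recode_table()
  nmax <- vapply(1:36, function(i) max(recode$raw[recode$item == i]), numeric(1))
  for (rep in 1:20) {
    responses <- vapply(1:36, function(i) sample(nmax[i], 1), numeric(1))
    base <- score_all(responses)
    i <- sample(36, 1)
    s <- recode[recode$item == i, ]
    better <- s$raw[s$score > s$score[s$raw == responses[i]]]
    if (!length(better)) next
    responses2 <- responses
    responses2[i] <- better[1]
    expect_true(all(score_all(responses2) >= base))
  }
})

test_that("completeness summary counts patients complete at both occasions", {
  cfg <- latent_cohort_config(n_subjects = 30, seed = 5, missing_rate = 0)
  coh <- generate_rand36_cohort(cfg)
  cs <- completeness_summary(coh)
  expect_equal(cs$n_complete, rep(30, 9))
  expect_equal(cs$percent, rep(100, 9))

  # one patient missing item 21 at baseline: only pain drops
  coh2 <- coh
  coh2[coh2$patient_id == "P0001" & coh2$occasion == "baseline", "q21"] <- NA
  cs2 <- completeness_summary(coh2)
  expect_equal(cs2$n_complete[cs2$subscale == "pain"], 29)
  expect_equal(cs2$n_complete[cs2$subscale != "pain"], rep(30, 8))

  # unpaired patients are excluded with a warning
  expect_warning(cs3 <- completeness_summary(coh[-1, ]), "unpaired")
  expect_equal(attr(cs3, "n_pairs"), 29)

  # MCAR missingness matches a direct tally
  cfg4 <- latent_cohort_config(n_subjects = 50, seed = 6, missing_rate = 0.05)
  coh4 <- generate_rand36_cohort(cfg4)
  cs4 <- completeness_summary(coh4)
  map <- c(rand36_subscales(), list(health_change = 2))
  for (s in names(map)) {
    qs <- paste0("q", map[[s]])
    ok_by_patient <- tapply(rowSums(is.na(coh4[qs])) == 0, coh4$patient_id, all)
    expect_equal(cs4$n_complete[cs4$subscale == s], sum(ok_by_patient))
  }
})
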