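test_that("index episodes respect the relatively-new-user rules", {
  # a single fill with an empty pre-period qualifies immediately
  ep <- identify_index_episode(
    data.frame(day = 0, drug_class = "index_aripiprazole",
               days_supplied = 30))
  expect_equal(ep$index_day, 0)
  expect_equal(ep$index_drug, "aripiprazole")
  # an other-antipsychotic fill 30 days before disqualifies
  expect_null(identify_index_episode(
    data.frame(day = c(-30, 0),
               drug_class = c("other_antipsychotic", "index_olanzapine"),
               days_supplied = c(30, 30))))
  # 60 days supplied inside one 90-day window disqualifies: with more than
  # one fill the sum of days supplied may not exceed 30 per 90-day period
  expect_null(identify_index_episode(
    data.frame(day = c(-80, -50, 0),
               drug_class = rep("index_olanzapine", 3),
               days_supplied = c(30, 30, 30)),
    observed_from = -210))
  # but 30 pre-period days more than 90 days before the index are fine
  ep2 <- identify_index_episode(
    data.frame(day = c(-170, 0),
               drug_class = rep("index_olanzapine", 2),
               days_supplied = c(30, 30)),
    observed_from = -210)
  expect_equal(ep2$index_day, 0)
  expect_equal(ep2$prior_days, 30)
  expect_error(identify_index_episode(
    data.frame(day = 0, drug_class = "index_olanzapine",
               days_supplied = -5)), "days_supplied")
})

test_that("eligibility failures are reported in the fixed order", {
  demo <- data.frame(person_id = "X", birth_day = -40 * 365,
                     death_day = NA)
  fills <- data.frame(day = 0, drug_class = "index_aripiprazole",
                      days_supplied = 30)
  dx0 <- data.frame(day = numeric(0), setting = character(0),
                    position = character(0), code_group = character(0))
  enr <- data.frame(start_day = -400, end_day = 400)
  ep <- list(index_day = 0, index_drug = "aripiprazole")

  ok <- apply_eligibility(ep, fills, dx0, enr, demo)
  expect_true(ok$eligible)
  expect_equal(ok$reason, "none")

  gap <- apply_eligibility(ep, fills, dx0,
                           data.frame(start_day = -150, end_day = 400),
                           demo)
  expect_false(gap$eligible)
  expect_equal(gap$reason, "enrolment_gap")

  dx_db <- data.frame(day = c(-90, -30), setting = "outpatient",
                      position = "primary", code_group = "type2_diabetes")
  db <- apply_eligibility(ep, fills, dx_db, enr, demo)
  expect_equal(db$reason, "prior_diabetes_or_cardiometabolic")

  # an other-antipsychotic violation outranks a diabetes exclusion
  both <- apply_eligibility(
    ep, rbind(fills, data.frame(day = -20,
                                drug_class = "other_antipsychotic",
                                days_supplied = 30)),
    dx_db, enr, demo)
  expect_equal(both$reason, "other_antipsychotic_pre_period")

  old <- demo
  old$birth_day <- -66 * 365
  expect_equal(apply_eligibility(ep, fills, dx0, enr, old)$reason,
               "age_out_of_range")
  expect_error(apply_eligibility(ep, fills, dx0, enr,
                                 transform(demo, birth_day = NA)), "birth")
})

test_that("outcome ascertainment implements the three qualifying rules", {
  no_fills <- data.frame(day = numeric(0), drug_class = character(0),
                         days_supplied = numeric(0))
  inpt <- ascertain_outcome(
    data.frame(day = 185, setting = "inpatient", position = "primary",
               code_group = "type2_diabetes"), no_fills, 0)
  expect_equal(inpt$event_month, 7)
  expect_equal(inpt$rule, "inpatient_primary")

  two <- ascertain_outcome(
    data.frame(day = c(130, 400), setting = "outpatient",
               position = c("primary", "secondary"),
               code_group = "type2_diabetes"), no_fills, 0)
  expect_equal(two$event_month, 5)
  expect_equal(two$rule, "two_outpatient_12mo")

  # two outpatient claims more than 365 days apart never pair
  far <- ascertain_outcome(
    data.frame(day = c(130, 520), setting = "outpatient",
               position = "primary", code_group = "type2_diabetes"),
    no_fills, 0)
  expect_equal(far$rule, "none")

  oral <- ascertain_outcome(
    data.frame(day = 130, setting = "outpatient", position = "primary",
               code_group = "type2_diabetes"),
    data.frame(day = 135, drug_class = "oral_antidiabetic",
               days_supplied = 30), 0)
  expect_equal(oral$event_month, 5)
  expect_equal(oral$rule, "outpatient_plus_oral_antidiabetic")

  insulin <- ascertain_outcome(
    data.frame(day = 130, setting = "outpatient", position = "primary",
               code_group = "type2_diabetes"),
    data.frame(day = 135, drug_class = "insulin", days_supplied = 30), 0)
  expect_equal(insulin$rule, "none")
  expect_true(is.na(insulin$event_month))
})

test_that("censoring ties resolve by the fixed hierarchy, order-invariant", {
  tie <- determine_censoring(
    data.frame(month = c(5, 5), cause = c("switch", "death")), 24)
  expect_equal(tie$month, 5)
  expect_equal(tie$cause, "death")
  none <- determine_censoring(
    data.frame(month = numeric(0), cause = character(0)), 24)
  expect_equal(none$month, 24)
  expect_equal(none$cause, "study_end")
  expect_true(none$administrative)
  earlier <- determine_censoring(
    data.frame(month = c(3, 4), cause = c("discontinuation",
                                          "augmentation")), 24)
  expect_equal(earlier$month, 3)
  expect_equal(earlier$cause, "discontinuation")
  expect_error(determine_censoring(
    data.frame(month = 2, cause = "vacation"), 24), "cause")

  # permuting same-month events never changes the recorded cause
  set.seed(5)
  for (r in 1:20) {
    ev <- data.frame(month = sample(1:6, 4, TRUE),
                     cause = sample(monotmle:::CENSOR_CAUSES, 4))
    ref <- determine_censoring(ev, 24)
    prm <- determine_censoring(ev[sample(4), ], 24)
    expect_identical(ref[c("month", "cause")], prm[c("month", "cause")])
  }
})

test_that("standardised mean differences use the aripiprazole SD", {
  co <- data.frame(drug = rep(c("aripiprazole", "olanzapine"), each = 4),
                   x = c(1, 1, 0, 0, 1, 1, 1, 0))
  b <- compute_smd(co, "x")
  expect_equal(b$smd, (0.75 - 0.5) / sd(c(1, 1, 0, 0)))
  ident <- compute_smd(data.frame(drug = co$drug, x = rep(0:1, 4)), "x")
  expect_equal(ident$smd, 0)
  expect_false(ident$unbalanced)
  # the 0.10 threshold flags exactly
  mk <- function(target) {
    n <- 4000
    data.frame(drug = rep(c("aripiprazole", "olanzapine"), each = n),
               x = c(rnorm(n, 0, 1), rnorm(n, 0, 1)) +
                 rep(c(0, target), each = n))
  }
  set.seed(2)
  expect_true(abs(compute_smd(mk(0.3), "x")$smd) > 0.1)
  degenerate <- compute_smd(
    data.frame(drug = rep(c("aripiprazole", "olanzapine"), each = 3),
               x = c(1, 1, 1, 0, 1, 0)), "x")
  expect_true(is.na(degenerate$smd))
})

test_that("the hand-written fixture screens and labels exactly", {
  bundle <- make_claims_fixture()
  co <- build_cohort(bundle, horizon = 24)
  expect_setequal(co$cohort$person_id, sprintf("P%02d", 1:5))
  att <- setNames(co$attrition$n, co$attrition$reason)
  expect_equal(att[["eligible"]], 5)
  for (r in c("other_antipsychotic_pre_period", "not_new_user",
              "enrolment_gap", "prior_diabetes_or_cardiometabolic",
              "pcos", "age_out_of_range"))
    expect_equal(att[[r]], 1)
  expect_equal(sum(att), 11)

  ch <- co$cohort[match(sprintf("P%02d", 1:5), co$cohort$person_id), ]
  expect_equal(ch$event_month, c(7, 5, 4, NA, NA))
  expect_equal(ch$outcome_rule,
               c("inpatient_primary", "two_outpatient_12mo",
                 "outpatient_plus_oral_antidiabetic", "none", "none"))
  expect_equal(ch$censor_cause[4:5], c("discontinuation", "death"))
  expect_equal(ch$censor_month[4:5], c(10, 5))
  expect_true(ch$administrative_end[1])

  pan <- co$panel
  p1 <- pan[pan$person_id == "P01", ]
  expect_equal(max(p1$month), 7)
  expect_equal(p1$Y[7], 1)
  expect_true(all(p1$A == 1))
  p5 <- pan[pan$person_id == "P05", ]
  expect_equal(max(p5$month), 5)
  expect_equal(p5$C[5], 1)
  expect_equal(p5$cause[5], "death")
  expect_true(is.na(p5$Y[5]))
})

test_that("augmentation keeps the index drug, switching does not", {
  base <- make_claims_fixture()
  d0 <- 400L
  one <- function(fills) {
    b <- base
    b$fills <- fills
    b$dx_claims <- b$dx_claims[b$dx_claims$person_id == "P01" &
                                 b$dx_claims$code_group ==
                                   "smi_schizophrenia", ]
    b$enrolment <- b$enrolment[b$enrolment$person_id == "P01", ]
    b$demographics <- b$demographics[b$demographics$person_id == "P01", ]
    build_cohort(b, horizon = 24)
  }
  # index supply runs through month 6; risperidone added mid-month 6
  aug <- one(data.frame(person_id = "P01",
                        day = c(d0 + 30 * (0:5), d0 + 165),
                        drug_code = c(rep("aripiprazole", 6), "risperidone"),
                        drug_class = c(rep("index_aripiprazole", 6),
                                       "other_antipsychotic"),
                        days_supplied = 30))
  expect_equal(aug$cohort$censor_cause, "augmentation")
  expect_equal(aug$cohort$censor_month, 6)
  p <- aug$panel
  expect_true(all(p$A[p$month <= 5] == 1))
  expect_equal(p$A[p$month == 6], 0)
  expect_equal(p$C[p$month == 6], 1)

  # index supply stops after month 5; risperidone starts in month 6
  sw <- one(data.frame(person_id = "P01",
                       day = c(d0 + 30 * (0:4), d0 + 155),
                       drug_code = c(rep("aripiprazole", 5), "risperidone"),
                       drug_class = c(rep("index_aripiprazole", 5),
                                      "other_antipsychotic"),
                       days_supplied = 30))
  expect_equal(sw$cohort$censor_cause, "switch")
  expect_equal(sw$cohort$censor_month, 6)

  # uninterrupted fills, no other drugs: adherent all 24 months
  full <- one(data.frame(person_id = "P01", day = d0 + 30 * (0:23),
                         drug_code = "aripiprazole",
                         drug_class = "index_aripiprazole",
                         days_supplied = 30))
  expect_true(full$cohort$administrative_end)
  expect_equal(nrow(full$panel), 24)
  expect_true(all(full$panel$A == 1))
})

test_that("claims round-trip the latent panel exactly on clean configs", {
  cfg <- small_cfg(n = 400, seed = 7)
  b <- generate_claims(cfg)
  co <- build_cohort(b, horizon = 24)
  lat <- b$latent$panel
  built <- co$panel
  key <- function(d) paste(d$person_id, d$month)
  expect_setequal(key(lat), key(built))
  built <- built[match(key(lat), key(built)), ]
  for (v in c("A", "C", "Y", "cause", "comorbid", "acute_care",
              "metabolic_test", "diagnosis", "age", "female", "white",
              "prior_days", "drug", "state", "index_year")) {
    same <- (is.na(lat[[v]]) & is.na(built[[v]])) |
      (!is.na(lat[[v]]) & !is.na(built[[v]]) & lat[[v]] == built[[v]])
    expect_true(all(same), label = paste("column", v))
  }
  # exposure months form a prefix for every person
  a_pref <- tapply(built$A, built$person_id, function(a)
    all(a == cummin(a)))
  expect_true(all(a_pref))
})

test_that("distractors are excluded for their planted reasons and the
           default config recovers nearly every person-month", {
  cfg <- dgp_config(n_subjects = 2000, seed = 7, distractor_frac = 0.12)
  b <- generate_claims(cfg)
  co <- build_cohort(b, horizon = 24)
  att <- setNames(co$attrition$n, co$attrition$reason)
  planted <- table(b$distractors$reason)
  for (r in names(planted)) expect_equal(att[[r]], planted[[r]])
  expect_equal(att[["eligible"]], 2000)

  lat <- b$latent$panel
  built <- co$panel
  key <- function(d) paste(d$person_id, d$month)
  built <- built[match(key(lat), key(built)), ]
  agree <- rowMeans(cbind(
    lat$A == built$A, lat$C == built$C,
    (is.na(lat$Y) & is.na(built$Y)) | (lat$Y == built$Y)), na.rm = TRUE)
  expect_gt(mean(agree, na.rm = TRUE), 0.99)
})
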