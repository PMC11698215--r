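test_that("configuration validation names the offending field", {
  expect_error(dgp_config(horizon = 1), "horizon")
  expect_error(dgp_config(diagnosis_mix = c(schizophrenia = 0.6,
                                            bipolar = 0.6,
                                            severe_mdd = -0.2)),
               "diagnosis_mix")
  cfg <- dgp_config()
  cfg$monotherapy_end_mix <- c(discontinuation = 0.9, augmentation = 0.2,
                               switch = 0.2)
  expect_error(validate_dgp_config(cfg), "monotherapy_end_mix")
  cfg <- dgp_config()
  cfg$outcome$aripiprazole <- NULL
  expect_error(validate_dgp_config(cfg), "outcome\\$aripiprazole")
  cfg <- dgp_config()
  cfg$testing_rate[] <- 1.4
  expect_error(validate_dgp_config(cfg), "testing_rate")
})

test_that("the same seed reproduces panel and claims bit for bit", {
  cfg <- small_cfg(n = 120, seed = 42, distractor_frac = 0.1)
  s1 <- generate_panel(cfg)
  s2 <- generate_panel(cfg)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$persons, s2$persons)
  b1 <- generate_claims(cfg)
  b2 <- generate_claims(cfg)
  for (nm in c("fills", "dx_claims", "enrolment", "procedures",
               "demographics"))
    expect_identical(b1[[nm]], b2[[nm]])
})

test_that("degenerate hazards behave as their closed forms", {
  cfg <- small_cfg(n = 150, seed = 3)
  cfg$outcome$intercept[] <- -Inf
  sim <- generate_panel(cfg)
  expect_true(all(sim$panel$Y == 0, na.rm = TRUE))
  expect_true(all(sim$truth$curve$risk == 0))
  expect_equal(true_rmst(cfg, "olanzapine"), 24)
  expect_equal(true_counterfactual_risk(cfg, "aripiprazole", 12), 0)

  # censoring hazard 1 for one cause: everyone censored in month 1
  cfg2 <- small_cfg(n = 100, seed = 4)
  cfg2$censoring_rates["death"] <- 1
  sim2 <- generate_panel(cfg2)
  expect_true(all(sim2$panel$month == 1))
  expect_true(all(sim2$panel$C == 1))
  expect_true(all(sim2$panel$cause == "death"))
  expect_true(all(is.na(sim2$panel$Y)))
})

test_that("a covariate-independent constant hazard gives 1-(1-h)^t", {
  cfg <- small_cfg(n = 10)
  cfg$outcome$intercept[] <- qlogis(0.01)
  cfg$outcome$aripiprazole <- 0
  cfg$outcome$comorbid <- 0
  cfg$outcome$age_over45 <- 0
  expect_equal(true_counterfactual_risk(cfg, "olanzapine", 2), 0.0199,
               tolerance = 1e-12)
  expect_equal(true_counterfactual_risk(cfg, "aripiprazole", 24),
               1 - 0.99^24, tolerance = 1e-12)
  expect_equal(true_rmst(cfg, "olanzapine"),
               sum(0.99^(1:24)), tolerance = 1e-12)
  expect_error(true_counterfactual_risk(cfg, "quetiapine", 2), "drug")
  expect_error(true_counterfactual_risk(cfg, "olanzapine", 30), "month")
})

test_that("exact recursion matches an intervened Monte-Carlo simulation", {
  cfg <- dgp_config(n_subjects = 10)
  R <- 1e6
  set.seed(123)
  dx <- sample(names(cfg$diagnosis_mix), R, TRUE, cfg$diagnosis_mix)
  a45 <- rbinom(R, 1, cfg$baseline$p_age_over45)
  com <- rbinom(R, 1, cfg$baseline$p_comorbid)
  oc <- cfg$outcome
  for (drug in c("olanzapine", "aripiprazole")) {
    ev <- rep(FALSE, R)
    com_t <- com
    surv_months <- rep(0, R)
    for (t in 1:24) {
      h <- plogis(oc$intercept[dx] +
                    oc$aripiprazole * (drug == "aripiprazole") +
                    oc$comorbid * com_t + oc$age_over45 * a45)
      ev[!ev & runif(R) < h] <- TRUE
      surv_months <- surv_months + !ev
      on <- !ev & com_t == 0
      com_t[on] <- rbinom(sum(on), 1, cfg$comorbid_onset)
    }
    p_mc <- mean(ev)
    se <- sqrt(p_mc * (1 - p_mc) / R)
    expect_lt(abs(true_counterfactual_risk(cfg, drug, 24) - p_mc), 3 * se)
    rmst_mc <- mean(surv_months)
    se_rmst <- sd(surv_months) / sqrt(R)
    expect_lt(abs(true_rmst(cfg, drug) - rmst_mc), 3 * se_rmst)
  }
})

test_that("truth curves are monotone and RMST falls as hazard rises", {
  cfg <- dgp_config(n_subjects = 10)
  tr <- truth_report(cfg)
  for (d in c("aripiprazole", "olanzapine")) {
    r <- tr$curve$risk[tr$curve$drug == d]
    expect_true(all(diff(r) >= 0))
  }
  expect_equal(tr$contrasts$rd_pp,
               100 * (tr$curve$risk[tr$curve$drug == "olanzapine"] -
                        tr$curve$risk[tr$curve$drug == "aripiprazole"]))
  rmsts <- vapply(seq(-7, -5, by = 0.5), function(b0) {
    c2 <- cfg
    c2$outcome$intercept[] <- b0
    true_rmst(c2, "olanzapine")
  }, numeric(1))
  expect_true(all(diff(rmsts) < 0))
})

test_that("empirical monthly hazards among at-risk rows match the config", {
  cfg <- dgp_config(n_subjects = 50000, seed = 11)
  sim <- generate_panel(cfg)
  panel <- sim$panel
  oc <- cfg$outcome
  # month-1 outcome hazard within drug x comorbid cells
  m1 <- panel[panel$month == 1 & !is.na(panel$Y), ]
  for (d in c("aripiprazole", "olanzapine")) {
    for (cm in 0:1) {
      cell <- m1[m1$drug == d & m1$comorbid == cm, ]
      h_true <- mean(plogis(oc$intercept[cell$diagnosis] +
                              oc$aripiprazole * (d == "aripiprazole") +
                              oc$comorbid * cm +
                              oc$age_over45 * cell$age_over45))
      h_emp <- mean(cell$Y)
      se <- sqrt(h_true * (1 - h_true) / nrow(cell))
      expect_lt(abs(h_emp - h_true), 3 * se)
    }
  }
  # monotherapy-end hazard in month 2 (all three causes combined)
  ad <- cfg$adherence
  at2 <- sim$persons[sim$persons$censor_month >= 2 |
                       sim$persons$administrative_end, ]
  at2 <- at2[is.na(at2$event_month) | at2$event_month >= 2, ]
  for (d in c("aripiprazole", "olanzapine")) {
    cell <- at2[at2$drug == d & at2$comorbid0 == 1, ]
    left <- cell$censor_month == 2 & !cell$administrative_end &
      cell$censor_cause %in% c("discontinuation", "augmentation", "switch")
    h_true <- plogis(ad[["intercept"]] +
                       ad[["olanzapine"]] * (d == "olanzapine") +
                       ad[["comorbid"]])
    se <- sqrt(h_true * (1 - h_true) / nrow(cell))
    # comorbid may have onset between months; baseline flag is the
    # dominant term, allow the death/age-65 competing slack too
    expect_lt(abs(mean(left) - h_true), 4 * se + 0.003)
  }
})

test_that("crude follower risk sits near truth and exposure is a prefix", {
  cfg <- dgp_config(n_subjects = 5000, seed = 1)
  sim <- generate_panel(cfg)
  p <- sim$persons
  for (d in c("aripiprazole", "olanzapine")) {
    fol <- p$drug == d & p$administrative_end
    crude <- mean(!is.na(p$event_month[fol]))
    truth <- true_counterfactual_risk(cfg, d, 24)
    se <- sqrt(crude * (1 - crude) / sum(fol))
    expect_lt(abs(crude - truth), 3 * se)
  }
  # A is 1 on every row except a monotherapy-end censoring row
  pan <- sim$panel
  off <- pan[pan$A == 0, ]
  expect_true(all(off$C == 1))
  expect_true(all(off$cause %in% c("discontinuation", "augmentation",
                                   "switch")))
  # no rows after the earlier of outcome and censoring
  last <- tapply(pan$month, pan$person_id, max)
  expect_true(all(last[p$person_id] ==
                    pmin(ifelse(is.na(p$event_month), 24, p$event_month),
                         ifelse(p$administrative_end, 24, p$censor_month))))
})

test_that("the claims window constrains the horizon", {
  expect_error(
    generate_panel(dgp_config(n_subjects = 10, horizon = 40,
                              baseline = list(p_female = .5, p_white = .67,
                                              p_age_over45 = .52,
                                              p_comorbid = .22,
                                              p_prior_exposure = .76,
                                              n_states = 7,
                                              index_years = 2008))),
    "calendar window")
})

test_that("vaccination panel is the same world truncated at vaccination", {
  cfg <- small_cfg(n = 400, seed = 9)
  sim <- generate_panel(cfg)
  vp <- vaccination_panel(sim)
  p <- sim$persons
  last <- tapply(vp$month, vp$person_id, max)
  v <- p$vacc_month[match(names(last), p$person_id)]
  obs <- ifelse(p$administrative_end, 24,
                p$censor_month)[match(names(last), p$person_id)]
  expect_true(all(last == pmin(ifelse(is.na(v), 24, v), obs)))
  ev <- vp[!is.na(vp$Y) & vp$Y == 1, ]
  expect_true(all(ev$month == p$vacc_month[match(ev$person_id,
                                                 p$person_id)]))
})
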