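# single-period randomised world with no covariates: TMLE collapses to the
# per-arm event proportion
one_period_world <- function(n, seed, p_olz = 0.5, p_ari = 0.12,
                             p_olz_y = 0.07) {
  set.seed(seed)
  olz <- rbinom(n, 1, p_olz)
  y <- rbinom(n, 1, ifelse(olz == 1, p_olz_y, p_ari))
  data.frame(person_id = sprintf("P%04d", seq_len(n)), month = 1L,
             w = 0L, drug = ifelse(olz == 1, "olanzapine", "aripiprazole"),
             A = 1L, C = 0L, cause = NA_character_, Y = y,
             stringsAsFactors = FALSE)
}

test_that("with no confounding TMLE reduces to the plug-in proportion", {
  panel <- one_period_world(500, 21)
  fit <- tmle_survival(panel, months = 1, sl = sl_control("mean"),
                       baseline = character(0), timevarying = character(0),
                       isotonic = FALSE)
  for (arm in c("aripiprazole", "olanzapine")) {
    emp <- mean(panel$Y[panel$drug == arm])
    expect_equal(fit[[arm]]$risks$risk, emp, tolerance = 1e-10)
    n_arm <- sum(panel$drug == arm)
    se_ref <- sqrt(emp * (1 - emp) / n_arm)
    expect_lt(abs(fit[[arm]]$risks$se - se_ref) / se_ref, 0.02)
  }
})

test_that("nuisance g equals the empirical on-regime proportions", {
  panel <- make_two_period_world(800, 31)
  nu <- fit_nuisances(panel, "olanzapine", sl = sl_control("logistic"),
                      baseline = "w", timevarying = "l",
                      interactions = TRUE)
  # month 2: P(stay on regime | at risk, w, l) by exhaustive stratification
  m2 <- panel[panel$month == 2, ]
  ids <- panel$person_id[panel$month == 1]
  for (w in 0:1) for (l in 0:1) {
    cell <- m2[m2$w == w & m2$l == l, ]
    if (nrow(cell) < 5) next
    emp <- mean(cell$C == 0)
    est <- nu$g[match(cell$person_id, ids), 2]
    # the saturated model includes the drug column: average over the cell
    expect_equal(mean(est), emp, tolerance = 0.02)
  }
  # everyone is on regime in month 1 of this world
  expect_true(all(nu$g[, 1] == 1))
  # untargeted iterated regression at the final step equals stratified
  # means of the month-2 hazard among regime followers
  follow2 <- m2[m2$C == 0, ]
  for (w in 0:1) for (l in 0:1) {
    cell <- follow2[follow2$w == w & follow2$l == l &
                      follow2$drug == "olanzapine", ]
    if (nrow(cell) < 5) next
    est <- nu$Qbar[[2]][match(cell$person_id, ids)]
    expect_lt(max(abs(est - mean(cell$Y))), 1e-6)
  }
})

test_that("fully adherent uncensored panels give cumulative g of 1", {
  panel <- one_period_world(300, 5)
  nu <- fit_nuisances(panel, "olanzapine", sl = sl_control("mean"),
                      baseline = character(0), timevarying = character(0))
  expect_true(all(nu$g == 1))
  expect_true(all(nu$cumG == 1))
})

test_that("zero events give risk exactly 0 with degenerate SE", {
  panel <- one_period_world(200, 6)
  panel$Y <- 0L
  fit <- tmle_survival(panel, months = 1, sl = sl_control("mean"),
                       baseline = character(0), timevarying = character(0))
  expect_identical(fit$olanzapine$risks$risk, 0)
  expect_identical(fit$olanzapine$risks$se, 0)
})

test_that("saturated TMLE equals the brute-force g-formula", {
  panel <- make_two_period_world(4000, 11)
  fit <- tmle_survival(panel, months = 1:2, sl = sl_control("logistic"),
                       baseline = "w", timevarying = "l",
                       interactions = TRUE, isotonic = FALSE, clip = 1e-4)
  for (arm in c("olanzapine", "aripiprazole")) {
    oracle <- gformula_two_period(panel, arm)
    expect_lt(abs(fit[[arm]]$risks$risk[2] - oracle), 1e-6)
  }
  # month-1 estimate is the covariate-standardised single-period value
  m1 <- panel[panel$month == 1, ]
  h1 <- vapply(0:1, function(w)
    mean(m1$Y[m1$w == w & m1$drug == "olanzapine"]), numeric(1))
  expect_lt(abs(fit$olanzapine$risks$risk[1] - mean(h1[m1$w + 1])), 1e-6)
})

test_that("positivity failures are reported by month", {
  panel <- one_period_world(100, 41)
  expect_error(
    tmle_survival(panel, months = 1:2, sl = sl_control("mean"),
                  baseline = character(0), timevarying = character(0)),
    "at-risk rows at month 2")
  expect_error(
    fit_nuisances(panel, "olanzapine", target_month = 3,
                  sl = sl_control("mean"), baseline = character(0),
                  timevarying = character(0)),
    "at-risk rows")
})

test_that("the survival curve is the isotonic projection of risk", {
  el <- list(risks = data.frame(month = 2:3, drug = "olanzapine",
                                risk = c(0.02, 0.01), se = c(0.001, 0.001),
                                lo = 0, hi = 1),
             inf = matrix(0, 5, 2), n = 5)
  cv <- survival_curve(el)
  expect_equal(cv$curve$risk, c(0.015, 0.015))
  expect_equal(cv$curve$surv, c(0.985, 0.985))
  mono <- list(risks = data.frame(month = 1:3, drug = "olanzapine",
                                  risk = c(0.01, 0.02, 0.04),
                                  se = 0.001, lo = 0, hi = 1),
               inf = matrix(0, 5, 3), n = 5)
  expect_equal(survival_curve(mono)$curve$risk, mono$risks$risk)
})

test_that("discrete-time RMST is the sum of survival probabilities", {
  flat <- list(risks = data.frame(month = 1:24, drug = "olanzapine",
                                  risk = 0, se = 0, lo = 0, hi = 0),
               inf = matrix(0, 10, 24), n = 10)
  expect_equal(rmst(survival_curve(flat))$rmst, 24)
  half <- list(risks = data.frame(month = 1:24, drug = "olanzapine",
                                  risk = 0.5, se = 0, lo = 0, hi = 1),
               inf = matrix(0, 10, 24), n = 10)
  expect_equal(rmst(survival_curve(half))$rmst, 12)
  expect_error(rmst(survival_curve(half), horizon = 30), "cover")
})

test_that("contrasts reproduce the worked example and stay consistent", {
  ct <- contrast(0.04, 0.02)
  expect_equal(ct$rd_pp, 2)
  expect_equal(ct$rr, 2)
  eq <- contrast(0.03, 0.03)
  expect_equal(eq$rd_pp, 0)
  expect_equal(eq$rr, 1)
  zero <- contrast(0.02, 0)
  expect_true(is.na(zero$rr))
  expect_equal(zero$rd_pp, 2)

  panel <- make_two_period_world(2500, 51)
  fit <- tmle_survival(panel, months = 1:2, sl = sl_control("logistic"),
                       baseline = "w", timevarying = "l")
  c_o <- survival_curve(fit, "olanzapine")
  c_a <- survival_curve(fit, "aripiprazole")
  ct2 <- contrast(c_o, c_a, 2)
  expect_equal(ct2$rd_pp,
               100 * (c_o$curve$risk[2] - c_a$curve$risk[2]),
               tolerance = 1e-10)
  expect_equal(ct2$rr, c_o$curve$risk[2] / c_a$curve$risk[2],
               tolerance = 1e-10)
  d <- rmst_difference(c_o, c_a)
  expect_equal(d$diff, d$olanzapine$rmst - d$aripiprazole$rmst,
               tolerance = 1e-12)
})

test_that("influence-function CIs agree with a nonparametric bootstrap", {
  panel <- one_period_world(1500, 61, p_ari = 0.15, p_olz_y = 0.09)
  fit <- tmle_survival(panel, months = 1, sl = sl_control("mean"),
                       baseline = character(0), timevarying = character(0))
  c_o <- survival_curve(fit, "olanzapine")
  c_a <- survival_curve(fit, "aripiprazole")
  ct <- contrast(c_o, c_a, 1)
  width_if_rd <- ct$rd_hi - ct$rd_lo
  width_if_lrr <- log(ct$rr_hi) - log(ct$rr_lo)

  set.seed(62)
  olz <- panel$drug == "olanzapine"
  boot <- t(replicate(2000, {
    i <- sample.int(nrow(panel), replace = TRUE)
    po <- mean(panel$Y[i][olz[i]])
    pa <- mean(panel$Y[i][!olz[i]])
    c(rd = 100 * (po - pa), lrr = log(po / pa))
  }))
  width_boot_rd <- diff(quantile(boot[, "rd"], c(0.025, 0.975)))
  width_boot_lrr <- diff(quantile(boot[is.finite(boot[, "lrr"]), "lrr"],
                                  c(0.025, 0.975)))
  expect_lt(abs(width_if_rd - width_boot_rd) / width_boot_rd, 0.10)
  expect_lt(abs(width_if_lrr - width_boot_lrr) / width_boot_lrr, 0.10)
})

test_that("misspecified outcome regressions stay nearly unbiased when the
           adherence model is correct (double robustness)", {
  cfg <- dgp_config(n_subjects = 5000)
  truth24 <- true_counterfactual_risk(cfg, "olanzapine", 24)
  err <- vapply(1:8, function(r) {
    sim <- generate_panel(cfg, seed = 7000 + r)
    # mean-only outcome regressions, correctly specified adherence model
    fit <- tmle_survival(sim$panel, months = 24, sl = sl_control("mean"),
                         g_sl = sl_control("logistic"), isotonic = FALSE)
    fit$olanzapine$risks$risk[1] - truth24
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.015)
})
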