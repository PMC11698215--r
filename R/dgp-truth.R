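#' Exact counterfactual risk under continuous monotherapy
#'
#' Computes, by forward recursion over the finite covariate state space, the
#' exact cumulative outcome risk at a given month under the static regime
#' "everyone starts `drug`, remains on continuous monotherapy and is never
#' censored". The state space is (diagnosis group) x (age over 45) x
#' (chronic comorbidity), with the absorbing comorbidity flag evolving by its
#' configured onset probability; the iid monthly metabolic-testing flag is
#' marginalised exactly inside each month.
#'
#' @param config a [dgp_config()].
#' @param drug `"aripiprazole"` or `"olanzapine"`.
#' @param month target month in `1..horizon`.
#' @param outcome `"diabetes"` (default) or `"vaccination"` (the
#'   negative-control outcome).
#' @return The cumulative risk, a single probability.
#' @export
#' @examples
#' cfg <- dgp_config(n_subjects = 100)
#' true_counterfactual_risk(cfg, "olanzapine", 24)
true_counterfactual_risk <- function(config, drug, month,
                                     outcome = c("diabetes", "vaccination")) {
  outcome <- match.arg(outcome)
  validate_dgp_config(config)
  if (!drug %in% DRUGS)
    stop("unknown drug label: ", drug, call. = FALSE)
  if (!is.numeric(month) || length(month) != 1 || month < 1 ||
      month > config$horizon)
    stop("month must lie in 1..horizon", call. = FALSE)
  exact_risk_curve(config, drug, outcome)[month]
}

#' Exact restricted mean survival time under continuous monotherapy
#'
#' RMST over the full horizon, `sum_t S_a(t)` with `S_a(t) = 1 - psi_a(t)`
#' from the exact risk recursion: the expected number of event-free months
#' when everyone follows `drug` monotherapy uncensored.
#'
#' @inheritParams true_counterfactual_risk
#' @return RMST in months, in `[0, horizon]`.
#' @export
true_rmst <- function(config, drug, outcome = c("diabetes", "vaccination")) {
  outcome <- match.arg(outcome)
  validate_dgp_config(config)
  if (!drug %in% DRUGS)
    stop("unknown drug label: ", drug, call. = FALSE)
  sum(1 - exact_risk_curve(config, drug, outcome))
}

# forward recursion over (dx, age45, comorbid) mass; returns cumulative risk
# for months 1..horizon under the intervened regime.
exact_risk_curve <- function(config, drug, outcome = "diabetes") {
  bl <- config$baseline
  states <- expand.grid(dx = DX_GROUPS, age45 = 0:1, com = 0:1,
                        stringsAsFactors = FALSE)
  p_dx <- config$diagnosis_mix[states$dx]
  p_age <- ifelse(states$age45 == 1, bl$p_age_over45, 1 - bl$p_age_over45)
  p_com <- ifelse(states$com == 1, bl$p_comorbid, 1 - bl$p_comorbid)
  mass <- as.numeric(p_dx * p_age * p_com) # P(state, event-free so far)
  H <- config$horizon
  risk <- numeric(H)
  cum <- 0
  test_rate <- config$testing_rate[[drug]]
  for (t in seq_len(H)) {
    h <- month_hazard(config, drug, outcome, states, t, test_rate)
    cum <- cum + sum(mass * h)
    risk[t] <- cum
    mass <- mass * (1 - h)
    # absorbing comorbidity onset among survivors
    on <- config$comorbid_onset
    m0 <- mass[states$com == 0]
    mass[states$com == 1] <- mass[states$com == 1] + m0 * on
    mass[states$com == 0] <- m0 * (1 - on)
  }
  risk
}

# monthly Bernoulli hazard for each covariate state, with the iid testing
# flag marginalised: E_test plogis(lp + b_test * test)
month_hazard <- function(config, drug, outcome, states, t, test_rate) {
  if (outcome == "diabetes") {
    oc <- config$outcome
    ari <- as.numeric(drug == "aripiprazole")
    lp <- oc$intercept[states$dx] +
      oc$aripiprazole * ari +
      oc$comorbid * states$com +
      oc$age_over45 * states$age45 +
      oc$month * (t - 1) +
      oc$aripiprazole_month * ari * (t - 1)
    b_test <- oc$metabolic_test
    if (b_test == 0) return(stats::plogis(as.numeric(lp)))
    as.numeric((1 - test_rate) * stats::plogis(lp) +
                 test_rate * stats::plogis(lp + b_test))
  } else {
    vc <- config$vaccination
    lp <- vc[["intercept"]] +
      vc[["olanzapine"]] * as.numeric(drug == "olanzapine") +
      vc[["comorbid"]] * states$com
    stats::plogis(as.numeric(lp))
  }
}

#' Exact counterfactual truth report for a synthetic world
#'
#' Tabulates, per drug and month, the exact counterfactual cumulative risk
#' `psi_a(t)`, survival `S_a(t)`, the per-month risk difference (olanzapine
#' minus aripiprazole, percentage points) and risk ratio, and the per-drug
#' RMST with its difference.
#'
#' @param config a [dgp_config()].
#' @param outcome `"diabetes"` or `"vaccination"`.
#' @return A list of class `"truth_report"` with elements `curve` (data frame:
#'   month, drug, risk, surv), `contrasts` (month, rd_pp, rr), `rmst` (named
#'   per drug) and `rmst_diff` (olanzapine minus aripiprazole).
#' @export
truth_report <- function(config, outcome = c("diabetes", "vaccination")) {
  outcome <- match.arg(outcome)
  curves <- lapply(DRUGS, function(d) exact_risk_curve(config, d, outcome))
  names(curves) <- DRUGS
  H <- config$horizon
  curve <- data.frame(
    month = rep(seq_len(H), times = 2),
    drug = rep(DRUGS, each = H),
    risk = c(curves$aripiprazole, curves$olanzapine),
    surv = 1 - c(curves$aripiprazole, curves$olanzapine)
  )
  rr <- ifelse(curves$aripiprazole > 0,
               curves$olanzapine / curves$aripiprazole, NA_real_)
  contrasts <- data.frame(
    month = seq_len(H),
    rd_pp = 100 * (curves$olanzapine - curves$aripiprazole),
    rr = rr
  )
  rmst <- vapply(curves, function(r) sum(1 - r), numeric(1))
  out <- list(outcome = outcome, curve = curve, contrasts = contrasts,
              rmst = rmst,
              rmst_diff = unname(rmst["olanzapine"] - rmst["aripiprazole"]))
  class(out) <- "truth_report"
  out
}

#' @export
print.truth_report <- function(x, ...) {
  H <- max(x$curve$month)
  r24 <- x$curve[x$curve$month == H, ]
  cat("<truth_report>", x$outcome, "\n")
  cat(sprintf("  month-%d risk: aripiprazole %.4f, olanzapine %.4f\n", H,
              r24$risk[r24$drug == "aripiprazole"],
              r24$risk[r24$drug == "olanzapine"]))
  cat(sprintf("  RMST: aripiprazole %.3f, olanzapine %.3f, diff %+.3f\n",
              x$rmst[["aripiprazole"]], x$rmst[["olanzapine"]], x$rmst_diff))
  invisible(x)
}
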