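#' Configuration of the synthetic claims world
#'
#' `dgp_config()` assembles and validates the generative parameters of the
#' synthetic administrative-claims world: baseline covariate distributions,
#' treatment assignment, the monthly monotherapy-end (adherence) hazard, the
#' cause-specific censoring process, and the monthly diabetes and
#' influenza-vaccination hazards. All hazards are discrete-time Bernoulli
#' hazards over consecutive 30-day months anchored at the index fill.
#'
#' The defaults describe a publicly insured serious-mental-illness cohort
#' starting aripiprazole or olanzapine: 24-month diabetes risk around 5%
#' (schizophrenia stratum) to 9% (severe MDD stratum) under continuous
#' olanzapine monotherapy, a slightly higher hazard under aripiprazole,
#' moderate baseline and time-varying confounding through a chronic
#' comorbidity flag, and roughly half the cohort still on continuous
#' monotherapy at 24 months.
#'
#' @param n_subjects number of eligible subjects to simulate.
#' @param horizon follow-up horizon in 30-day months (>= 2).
#' @param seed optional integer master seed; every `generate_*` call is
#'   bit-reproducible given the same config and seed.
#' @param diagnosis_mix named probabilities over
#'   `c("schizophrenia", "bipolar", "severe_mdd")`; must sum to 1.
#' @param baseline list of baseline covariate parameters: `p_female`,
#'   `p_white`, `p_age_over45`, `p_comorbid` (baseline chronic comorbidity),
#'   `p_prior_exposure` (any pre-period index-drug days), `n_states`,
#'   `index_years`.
#' @param treatment named log-odds coefficients for
#'   P(index drug = olanzapine | baseline): `intercept`, `female`,
#'   `age_over45`, `comorbid`, `white`, `prior_days` (per 30 pre-period days).
#' @param adherence named log-odds coefficients for the monthly hazard of
#'   *leaving* continuous monotherapy (months 2+): `intercept`, `olanzapine`,
#'   `comorbid`.
#' @param monotherapy_end_mix named probabilities splitting a monotherapy-end
#'   month across causes `discontinuation`, `augmentation`, `switch`.
#' @param censoring_rates named monthly hazards for the covariate-independent
#'   censoring causes `death` (months 1+) and `coverage_loss` (months 7+;
#'   eligibility already requires enrolment through day +180). Turning 65 is
#'   deterministic from the simulated age; administrative study end occurs at
#'   the horizon.
#' @param outcome list of diabetes-hazard parameters: `intercept` (named
#'   vector per diagnosis group), and log-odds terms `aripiprazole`,
#'   `comorbid`, `age_over45`, `metabolic_test`, `month` (per elapsed month,
#'   `t - 1`) and `aripiprazole_month` (drug-by-duration interaction).
#' @param comorbid_onset monthly probability that the absorbing chronic
#'   comorbidity flag switches on.
#' @param acute_rate named vector `base`, `comorbid_extra`: monthly acute-care
#'   use probability is `base + comorbid_extra * comorbid`.
#' @param vaccination named log-odds coefficients for the monthly hazard of a
#'   first influenza vaccination (the negative-control outcome): `intercept`,
#'   `olanzapine`, `comorbid`.
#' @param testing_rate named per-month metabolic-testing probabilities, one
#'   per drug group.
#' @param distractor_frac fraction (of `n_subjects`) of extra ineligible
#'   persons written to the claims stream by [generate_claims()], cycling
#'   through the exclusion reasons.
#'
#' @return A validated list of class `"dgp_config"`.
#' @seealso [generate_panel()], [generate_claims()],
#'   [true_counterfactual_risk()], [true_rmst()]
#' @export
#' @examples
#' cfg <- dgp_config(n_subjects = 500, seed = 1)
#' cfg$outcome$aripiprazole
dgp_config <- function(n_subjects = 2000,
                       horizon = 24,
                       seed = NULL,
                       diagnosis_mix = c(schizophrenia = 0.52,
                                         bipolar = 0.26,
                                         severe_mdd = 0.22),
                       baseline = list(p_female = 0.50,
                                       p_white = 0.67,
                                       p_age_over45 = 0.52,
                                       p_comorbid = 0.22,
                                       p_prior_exposure = 0.76,
                                       n_states = 7,
                                       index_years = 2008:2011),
                       treatment = c(intercept = -0.0722,
                                     female = -0.25,
                                     age_over45 = -0.15,
                                     comorbid = -0.40,
                                     white = 0.10,
                                     prior_days = 0.30),
                       adherence = c(intercept = -3.10,
                                     olanzapine = 0.10,
                                     comorbid = 0.30),
                       monotherapy_end_mix = c(discontinuation = 0.60,
                                               augmentation = 0.20,
                                               switch = 0.20),
                       censoring_rates = c(death = 0.0008,
                                           coverage_loss = 0.004),
                       outcome = list(intercept = c(schizophrenia = -6.5926,
                                                    bipolar = -6.3740,
                                                    severe_mdd = -6.0485),
                                      aripiprazole = 0.26,
                                      comorbid = 0.55,
                                      age_over45 = 0.45,
                                      metabolic_test = 0.0,
                                      month = 0.0,
                                      aripiprazole_month = 0.0),
                       comorbid_onset = 0.012,
                       acute_rate = c(base = 0.04, comorbid_extra = 0.10),
                       vaccination = c(intercept = -4.0,
                                       olanzapine = 0.25,
                                       comorbid = 0.0),
                       testing_rate = c(aripiprazole = 0.065,
                                        olanzapine = 0.055),
                       distractor_frac = 0.0) {
  cfg <- list(n_subjects = n_subjects, horizon = horizon, seed = seed,
              diagnosis_mix = diagnosis_mix, baseline = baseline,
              treatment = treatment, adherence = adherence,
              monotherapy_end_mix = monotherapy_end_mix,
              censoring_rates = censoring_rates, outcome = outcome,
              comorbid_onset = comorbid_onset, acute_rate = acute_rate,
              vaccination = vaccination, testing_rate = testing_rate,
              distractor_frac = distractor_frac)
  class(cfg) <- "dgp_config"
  validate_dgp_config(cfg)
  cfg
}

cfg_stop <- function(field, msg) {
  stop(sprintf("invalid dgp_config field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    cfg_stop(field, "probabilities must lie in [0, 1]")
}

check_named_num <- function(x, field, names_req) {
  if (!is.numeric(x) || anyNA(x) || !all(names_req %in% names(x)))
    cfg_stop(field, paste("must be a numeric vector with names",
                          paste(names_req, collapse = ", ")))
}

#' Validate a DGP configuration
#'
#' Checks probability ranges, simplex constraints and coefficient shapes;
#' errors name the offending field.
#'
#' @param cfg a [dgp_config()] list.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_dgp_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1 ||
      cfg$n_subjects < 1)
    cfg_stop("n_subjects", "must be a positive count")
  if (!is.numeric(cfg$horizon) || length(cfg$horizon) != 1 || cfg$horizon < 2)
    cfg_stop("horizon", "must be >= 2 months")
  mix <- cfg$diagnosis_mix
  if (!all(c("schizophrenia", "bipolar", "severe_mdd") %in% names(mix)))
    cfg_stop("diagnosis_mix",
             "needs names schizophrenia, bipolar, severe_mdd")
  check_prob(mix, "diagnosis_mix")
  if (abs(sum(mix) - 1) > 1e-8)
    cfg_stop("diagnosis_mix", "must sum to 1")
  bl <- cfg$baseline
  for (p in c("p_female", "p_white", "p_age_over45", "p_comorbid",
              "p_prior_exposure")) {
    if (is.null(bl[[p]])) cfg_stop(paste0("baseline$", p), "is missing")
    check_prob(bl[[p]], paste0("baseline$", p))
  }
  if (is.null(bl$n_states) || bl$n_states < 1)
    cfg_stop("baseline$n_states", "must be a positive count")
  if (is.null(bl$index_years) || !is.numeric(bl$index_years))
    cfg_stop("baseline$index_years", "must be numeric years")
  check_named_num(cfg$treatment, "treatment",
                  c("intercept", "female", "age_over45", "comorbid", "white",
                    "prior_days"))
  check_named_num(cfg$adherence, "adherence",
                  c("intercept", "olanzapine", "comorbid"))
  mixm <- cfg$monotherapy_end_mix
  check_named_num(mixm, "monotherapy_end_mix",
                  c("discontinuation", "augmentation", "switch"))
  check_prob(mixm, "monotherapy_end_mix")
  if (abs(sum(mixm) - 1) > 1e-8)
    cfg_stop("monotherapy_end_mix", "must sum to 1")
  check_named_num(cfg$censoring_rates, "censoring_rates",
                  c("death", "coverage_loss"))
  check_prob(cfg$censoring_rates, "censoring_rates")
  oc <- cfg$outcome
  if (!is.list(oc)) cfg_stop("outcome", "must be a list")
  check_named_num(oc$intercept, "outcome$intercept",
                  c("schizophrenia", "bipolar", "severe_mdd"))
  for (p in c("aripiprazole", "comorbid", "age_over45", "metabolic_test",
              "month", "aripiprazole_month")) {
    if (is.null(oc[[p]]) || !is.numeric(oc[[p]]) || length(oc[[p]]) != 1)
      cfg_stop(paste0("outcome$", p), "must be a single numeric coefficient")
  }
  check_prob(cfg$comorbid_onset, "comorbid_onset")
  check_named_num(cfg$acute_rate, "acute_rate", c("base", "comorbid_extra"))
  check_prob(sum(cfg$acute_rate), "acute_rate")
  check_named_num(cfg$vaccination, "vaccination",
                  c("intercept", "olanzapine", "comorbid"))
  check_named_num(cfg$testing_rate, "testing_rate",
                  c("aripiprazole", "olanzapine"))
  check_prob(cfg$testing_rate, "testing_rate")
  check_prob(cfg$distractor_frac, "distractor_frac")
  invisible(cfg)
}

#' @export
print.dgp_config <- function(x, ...) {
  cat("<dgp_config>", x$n_subjects, "subjects,", x$horizon, "months\n")
  cat("  diagnosis mix:",
      paste(sprintf("%s=%.2f", names(x$diagnosis_mix), x$diagnosis_mix),
            collapse = " "), "\n")
  cat("  aripiprazole outcome log-OR:", x$outcome$aripiprazole, "\n")
  invisible(x)
}

# study drugs, censoring hierarchy and code-group vocabulary shared across
# modules; the hierarchy order is load-bearing for tie-breaking.
DRUGS <- c("aripiprazole", "olanzapine")
CENSOR_CAUSES <- c("death", "study_end", "age_65", "coverage_loss",
                   "discontinuation", "augmentation", "switch")
MONO_CAUSES <- c("discontinuation", "augmentation", "switch")
DX_GROUPS <- c("schizophrenia", "bipolar", "severe_mdd")
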