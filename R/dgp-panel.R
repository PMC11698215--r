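#' Generate a synthetic longitudinal cohort panel with known truth
#'
#' Simulates the person-month panel the estimator consumes: baseline
#' covariates, index-drug assignment, time-varying covariates (absorbing
#' chronic comorbidity, acute-care use, metabolic testing), the monthly
#' monotherapy-end and censoring processes, the incident-diabetes outcome and
#' the influenza-vaccination negative-control outcome. The exact
#' counterfactual [truth_report()] for the same configuration is attached.
#'
#' Within a month the ordering is: time-varying covariates are measured,
#' then censoring/adherence resolves, then (if still on regime) the outcome
#' may occur. A person censored in month `t` therefore contributes a row with
#' `C = 1` and an unobserved (`NA`) outcome for that month, and no later rows.
#' Administrative study end at the horizon is recorded in `persons` but never
#' appears as a `C = 1` row.
#'
#' @param config a [dgp_config()].
#' @param seed integer master seed (defaults to `config$seed`).
#' @return A list of class `"mono_sim"`:
#' \describe{
#'   \item{panel}{person-month data frame truncated at the earlier of the
#'     diabetes event and censoring: `person_id, month, diagnosis, age,
#'     age_over45, female, white, state, index_year, prior_days, drug,
#'     comorbid, acute_care, metabolic_test, A, C, cause, Y`.}
#'   \item{persons}{one row per person with baseline fields plus
#'     `event_month`, `censor_month`, `censor_cause`, `vacc_month`,
#'     `index_day`, `birth_day` (`NA` months mean "not observed").}
#'   \item{full_panel}{rows through the censoring month regardless of the
#'     diabetes event, with both `Y` and `vacc` columns; used to derive the
#'     negative-control panel via [vaccination_panel()].}
#'   \item{truth}{the exact [truth_report()] for the diabetes outcome.}
#'   \item{config}{the generating configuration.}
#' }
#' @export
#' @examples
#' sim <- generate_panel(dgp_config(n_subjects = 200, seed = 1))
#' head(sim$panel)
generate_panel <- function(config, seed = config$seed) {
  validate_dgp_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  persons <- draw_baseline(config)
  sim <- simulate_followup(persons, config)
  out <- list(panel = assemble_panel(sim, config, truncate_at = "diabetes"),
              persons = sim$persons,
              full_panel = assemble_panel(sim, config, truncate_at = "none"),
              truth = truth_report(config),
              config = config)
  class(out) <- "mono_sim"
  out
}

#' @export
print.mono_sim <- function(x, ...) {
  cat("<mono_sim>", nrow(x$persons), "persons,",
      nrow(x$panel), "person-months\n")
  print(table(x$persons$drug))
  invisible(x)
}

# last day (exclusive) of the simulated claims calendar
calendar_window_end <- function(config) {
  365L * (length(unique(config$baseline$index_years)) + 2L)
}

draw_baseline <- function(config) {
  n <- config$n_subjects
  bl <- config$baseline
  dx <- sample(DX_GROUPS, n, replace = TRUE, prob = config$diagnosis_mix)
  age45 <- stats::rbinom(n, 1, bl$p_age_over45)
  age <- ifelse(age45 == 1, sample(46:64, n, replace = TRUE),
                sample(18:45, n, replace = TRUE))
  female <- stats::rbinom(n, 1, bl$p_female)
  white <- stats::rbinom(n, 1, bl$p_white)
  state <- paste0("S", sample(seq_len(bl$n_states), n, replace = TRUE))
  comorbid0 <- stats::rbinom(n, 1, bl$p_comorbid)
  prior <- stats::rbinom(n, 1, bl$p_prior_exposure)
  prior_days <- ifelse(prior == 1, sample(5:30, n, replace = TRUE), 0L)
  # calendar: day 0 = Jan 1 of the first index year; the claims window runs
  # two calendar years past the last index year, and index fills are placed
  # so the 180-day pre-period and the 30-day-month follow-up both fit inside
  yr0 <- min(bl$index_years)
  nyr <- length(unique(bl$index_years))
  window_end <- calendar_window_end(config)
  max_index <- window_end - 30L * config$horizon - 60L
  if (max_index < 180L)
    stop("horizon of ", config$horizon,
         " months does not fit inside the simulated calendar window; ",
         "extend baseline$index_years or shorten the horizon", call. = FALSE)
  index_day <- 180L + sample.int(max_index - 180L + 1L, n,
                                 replace = TRUE) - 1L
  index_year <- yr0 + index_day %/% 365L
  # fractional age in days fixes both the birth date and the (deterministic)
  # month of turning 65
  age_days <- age * 365L + sample.int(364L, n, replace = TRUE)
  birth_day <- index_day - age_days
  days_to_65 <- 65L * 365L - age_days
  age65_month <- ifelse(days_to_65 <= 30L * config$horizon,
                        (days_to_65 - 1L) %/% 30L + 1L, NA_integer_)
  tr <- config$treatment
  lp <- tr[["intercept"]] + tr[["female"]] * female +
    tr[["age_over45"]] * age45 + tr[["comorbid"]] * comorbid0 +
    tr[["white"]] * white + tr[["prior_days"]] * prior_days / 30
  drug <- ifelse(stats::runif(n) < stats::plogis(lp),
                 "olanzapine", "aripiprazole")
  data.frame(person_id = sprintf("P%05d", seq_len(n)), diagnosis = dx,
             age = age, age_over45 = age45, female = female, white = white,
             state = state, index_year = index_year, prior_days = prior_days,
             comorbid0 = comorbid0, drug = drug, index_day = index_day,
             birth_day = birth_day, age65_month = age65_month,
             stringsAsFactors = FALSE)
}

simulate_followup <- function(persons, config) {
  n <- nrow(persons)
  H <- config$horizon
  oc <- config$outcome
  ad <- config$adherence
  vc <- config$vaccination
  cr <- config$censoring_rates
  ari <- as.numeric(persons$drug == "aripiprazole")
  olz <- 1 - ari
  test_rate <- config$testing_rate[persons$drug]
  oc_base <- oc$intercept[persons$diagnosis] + oc$aripiprazole * ari +
    oc$age_over45 * persons$age_over45
  ad_base <- ad[["intercept"]] + ad[["olanzapine"]] * olz
  vc_base <- vc[["intercept"]] + vc[["olanzapine"]] * olz

  com_m <- test_m <- acute_m <- matrix(NA_integer_, n, H)
  y_m <- vacc_m <- matrix(NA_integer_, n, H)
  censor_month <- rep(NA_integer_, n)
  censor_cause <- rep(NA_character_, n)
  event_month <- rep(NA_integer_, n)
  vacc_month <- rep(NA_integer_, n)

  com <- persons$comorbid0
  active <- rep(TRUE, n)
  for (t in seq_len(H)) {
    idx <- which(active)
    if (length(idx) == 0) break
    com_m[idx, t] <- com[idx]
    test_m[idx, t] <- stats::rbinom(length(idx), 1, test_rate[idx])
    acute_m[idx, t] <- stats::rbinom(
      length(idx), 1,
      config$acute_rate[["base"]] +
        config$acute_rate[["comorbid_extra"]] * com[idx])
    # censoring resolves before the outcome: death, turning 65, coverage
    # loss (months 7+), then the monotherapy-end hazard (months 2+)
    death <- stats::rbinom(length(idx), 1, cr[["death"]]) == 1
    a65 <- !is.na(persons$age65_month[idx]) & persons$age65_month[idx] == t
    cov_loss <- if (t >= 7)
      stats::rbinom(length(idx), 1, cr[["coverage_loss"]]) == 1
    else rep(FALSE, length(idx))
    mono <- if (t >= 2)
      stats::runif(length(idx)) <
        stats::plogis(ad_base[idx] + ad[["comorbid"]] * com[idx])
    else rep(FALSE, length(idx))
    cens <- death | a65 | cov_loss | mono
    if (any(cens)) {
      who <- idx[cens]
      cause <- ifelse(death[cens], "death",
                      ifelse(a65[cens], "age_65",
                             ifelse(cov_loss[cens], "coverage_loss", "mono")))
      is_mono <- cause == "mono"
      if (any(is_mono))
        cause[is_mono] <- sample(MONO_CAUSES, sum(is_mono), replace = TRUE,
                                 prob = config$monotherapy_end_mix)
      censor_month[who] <- t
      censor_cause[who] <- cause
      active[who] <- FALSE
    }
    surv <- idx[!cens]
    if (length(surv) > 0) {
      at_risk <- surv[is.na(event_month[surv])]
      if (length(at_risk) > 0) {
        h <- stats::plogis(oc_base[at_risk] +
                             oc$comorbid * com[at_risk] +
                             oc$metabolic_test * test_m[at_risk, t] +
                             oc$month * (t - 1) +
                             oc$aripiprazole_month * ari[at_risk] * (t - 1))
        ev <- stats::rbinom(length(at_risk), 1, h) == 1
        y_m[at_risk, t] <- as.integer(ev)
        event_month[at_risk[ev]] <- t
      }
      v_risk <- surv[is.na(vacc_month[surv])]
      if (length(v_risk) > 0) {
        hv <- stats::plogis(vc_base[v_risk] + vc[["comorbid"]] * com[v_risk])
        vv <- stats::rbinom(length(v_risk), 1, hv) == 1
        vacc_m[v_risk, t] <- as.integer(vv)
        vacc_month[v_risk[vv]] <- t
      }
      on <- which(com[surv] == 0)
      if (length(on) > 0)
        com[surv[on]] <- stats::rbinom(length(on), 1, config$comorbid_onset)
    }
  }
  persons$event_month <- event_month
  persons$censor_month <- ifelse(is.na(censor_month), H, censor_month)
  persons$censor_cause <- ifelse(is.na(censor_cause), "study_end",
                                 censor_cause)
  persons$administrative_end <- is.na(censor_cause)
  persons$vacc_month <- vacc_month
  list(persons = persons, com = com_m, test = test_m, acute = acute_m,
       y = y_m, vacc = vacc_m)
}

# long person-month data frame; truncate_at "diabetes" ends rows at the
# event month, "vaccination" at the first vaccination, "none" at censoring
assemble_panel <- function(sim, config, truncate_at = "diabetes") {
  p <- sim$persons
  H <- config$horizon
  obs_end <- ifelse(p$administrative_end, H, p$censor_month)
  last <- switch(truncate_at,
    diabetes = pmin(ifelse(is.na(p$event_month), H, p$event_month), obs_end),
    vaccination = pmin(ifelse(is.na(p$vacc_month), H, p$vacc_month), obs_end),
    none = obs_end)
  i <- rep(seq_len(nrow(p)), last)
  month <- sequence(last)
  flat <- cbind(i, month)
  censored <- !p$administrative_end[i] & month == p$censor_month[i]
  mono_cause <- p$censor_cause[i] %in% MONO_CAUSES
  out <- data.frame(
    person_id = p$person_id[i], month = month,
    diagnosis = p$diagnosis[i], age = p$age[i],
    age_over45 = p$age_over45[i], female = p$female[i], white = p$white[i],
    state = p$state[i], index_year = p$index_year[i],
    prior_days = p$prior_days[i], drug = p$drug[i],
    comorbid = sim$com[flat], acute_care = sim$acute[flat],
    metabolic_test = sim$test[flat],
    A = as.integer(!(censored & mono_cause)),
    C = as.integer(censored),
    cause = ifelse(censored, p$censor_cause[i], NA_character_),
    Y = ifelse(censored, NA_integer_, sim$y[flat]),
    stringsAsFactors = FALSE)
  if (truncate_at != "diabetes") {
    out$Y <- ifelse(censored, NA_integer_,
                    as.integer(!is.na(p$event_month[i]) &
                                 month == p$event_month[i]))
    out$vacc <- ifelse(censored, NA_integer_,
                       as.integer(!is.na(p$vacc_month[i]) &
                                    month == p$vacc_month[i]))
  }
  out
}

#' Negative-control panel: time to first influenza vaccination
#'
#' Rebuilds the person-month panel of a [generate_panel()] simulation with
#' the first influenza vaccination as the absorbing outcome (`Y`), keeping
#' the same censoring process. Diabetes onset does not end follow-up here.
#'
#' @param sim a `"mono_sim"` object from [generate_panel()].
#' @return A person-month data frame with the same columns as `sim$panel`.
#' @export
vaccination_panel <- function(sim) {
  stopifnot(inherits(sim, "mono_sim"))
  fp <- sim$full_panel
  p <- sim$persons
  last <- pmin(ifelse(is.na(p$vacc_month), sim$config$horizon, p$vacc_month),
               ifelse(p$administrative_end, sim$config$horizon,
                      p$censor_month))
  keep <- fp$month <= last[match(fp$person_id, p$person_id)]
  out <- fp[keep, setdiff(names(fp), "Y")]
  names(out)[names(out) == "vacc"] <- "Y"
  rownames(out) <- NULL
  out
}
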