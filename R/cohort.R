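#' Identify the index episode for one person's fill history
#'
#' Scans a person's pharmacy fills (sorted by day) for the first index-drug
#' fill that satisfies the relatively-new-user rules: (a) no fill of any
#' other antipsychotic in the 180 days before it, and (b) no 90-day window
#' inside that 180-day pre-period containing more than 30 days supplied of
#' the index drug.
#'
#' @param fills data frame of one person's fills with columns `day`,
#'   `drug_class`, `days_supplied`.
#' @param observed_from optional first observable day: only fills whose full
#'   180-day pre-period is observed (`day >= observed_from + 180`) can anchor
#'   an episode. `NULL` places no constraint.
#' @return A list (`person_id` if present, `index_day`, `index_drug`,
#'   `prior_days` = index-drug days supplied in the 180-day pre-period) of
#'   class `"index_episode"`, or `NULL` if no fill qualifies.
#' @export
#' @examples
#' fills <- data.frame(day = 0, drug_class = "index_aripiprazole",
#'                     days_supplied = 30)
#' identify_index_episode(fills)
identify_index_episode <- function(fills, observed_from = NULL) {
  if (any(fills$days_supplied <= 0))
    stop("days_supplied must be positive", call. = FALSE)
  idx <- fills[fills$drug_class %in% paste0("index_", DRUGS), , drop = FALSE]
  idx <- idx[order(idx$day), , drop = FALSE]
  other <- fills$day[fills$drug_class == "other_antipsychotic"]
  for (k in seq_len(nrow(idx))) {
    d0 <- idx$day[k]
    if (!is.null(observed_from) && d0 < observed_from + 180) next
    if (any(other >= d0 - 180 & other < d0)) next
    if (supply_rule_violated(idx, d0)) next
    pre <- idx$day >= d0 - 180 & idx$day < d0
    ep <- list(person_id = idx$person_id[k], index_day = d0,
               index_drug = sub("^index_", "", idx$drug_class[k]),
               prior_days = sum(idx$days_supplied[pre]))
    class(ep) <- "index_episode"
    return(ep)
  }
  NULL
}

# TRUE when the index-drug fills observed up to the candidate day (its own
# fill included) put more than 30 days supplied into some 90-day window:
# with more than one fill observed, the sum of days supplied may not exceed
# 30 in any 90-day period
supply_rule_violated <- function(idx_fills, d0) {
  pre <- idx_fills[idx_fills$day >= d0 - 180 & idx_fills$day <= d0, ,
                   drop = FALSE]
  if (nrow(pre) < 2) return(FALSE)
  for (s in pre$day) {
    win <- pre$day >= s & pre$day < s + 90
    if (sum(pre$days_supplied[win]) > 30) return(TRUE)
  }
  FALSE
}

#' Eligibility screening for a candidate index episode
#'
#' Applies the cohort inclusion rules in a fixed order and reports the first
#' failure: pre-period other-antipsychotic use, the new-user supply rule,
#' continuous enrolment over days `[-180, +180)` around the index fill,
#' pre-period diabetes/cardiometabolic conditions, pre-period polycystic
#' ovarian syndrome, and index age 18-64.
#'
#' @param episode list with `index_day` (and optionally `index_drug`).
#' @param fills,dx_claims,enrolment,demographics this person's claims rows.
#' @return list of class `"eligibility_result"` with `eligible` (flag) and
#'   `reason`, one of `other_antipsychotic_pre_period`, `not_new_user`,
#'   `enrolment_gap`, `prior_diabetes_or_cardiometabolic`, `pcos`,
#'   `age_out_of_range`, `none`.
#' @export
apply_eligibility <- function(episode, fills, dx_claims, enrolment,
                              demographics) {
  stopifnot(!is.null(episode))
  d0 <- episode$index_day
  res <- function(reason) structure(
    list(eligible = identical(reason, "none"), reason = reason),
    class = "eligibility_result")
  other <- fills$day[fills$drug_class == "other_antipsychotic"]
  if (any(other >= d0 - 180 & other < d0))
    return(res("other_antipsychotic_pre_period"))
  idx <- fills[fills$drug_class %in% paste0("index_", DRUGS), , drop = FALSE]
  if (supply_rule_violated(idx, d0))
    return(res("not_new_user"))
  if (!interval_covered(enrolment, d0 - 180, d0 + 180))
    return(res("enrolment_gap"))
  pre_dx <- dx_claims[dx_claims$day >= d0 - 180 & dx_claims$day < d0, ,
                      drop = FALSE]
  if (any(pre_dx$code_group %in% c("type2_diabetes",
                                   "excluded_cardiometabolic")))
    return(res("prior_diabetes_or_cardiometabolic"))
  if (any(pre_dx$code_group == "pcos"))
    return(res("pcos"))
  if (is.na(demographics$birth_day))
    stop("missing birth date for person ", demographics$person_id,
         call. = FALSE)
  age <- (d0 - demographics$birth_day) %/% 365
  if (age < 18 || age > 64)
    return(res("age_out_of_range"))
  res("none")
}

# is [from, to) fully covered by the union of enrolment spans?
interval_covered <- function(enrolment, from, to) {
  sp <- enrolment[order(enrolment$start_day), , drop = FALSE]
  cur <- from
  for (k in seq_len(nrow(sp))) {
    if (sp$start_day[k] > cur) break
    cur <- max(cur, sp$end_day[k])
    if (cur >= to) return(TRUE)
  }
  cur >= to
}

#' Ascertain incident type 2 diabetes from post-index claims
#'
#' The event month is the month of the first qualifying evidence:
#' (i) an in-patient claim with a primary type 2 diabetes code;
#' (ii) two out-patient claims (primary or secondary) within any 365-day
#' window, dated at the first of the pair; or (iii) one out-patient claim
#' together with an oral antidiabetic fill anywhere in follow-up. Persons
#' whose only antidiabetic exposure is insulin never qualify through (iii);
#' insulin-only treatment is taken to indicate type 1 diabetes.
#'
#' @param dx_claims,fills this person's claims rows (any days; only rows on
#'   or after `index_day` are used).
#' @param index_day index fill day anchoring the 30-day months.
#' @return list of class `"outcome_result"`: `event_month` (`NA` if none) and
#'   `rule`, one of `inpatient_primary`, `two_outpatient_12mo`,
#'   `outpatient_plus_oral_antidiabetic`, `none`.
#' @export
ascertain_outcome <- function(dx_claims, fills, index_day) {
  dm <- dx_claims[dx_claims$code_group == "type2_diabetes" &
                    dx_claims$day >= index_day, , drop = FALSE]
  cand <- data.frame(day = numeric(0), rule = character(0))
  inpt <- dm$day[dm$setting == "inpatient" & dm$position == "primary"]
  if (length(inpt))
    cand <- rbind(cand, data.frame(day = min(inpt),
                                   rule = "inpatient_primary"))
  outp <- sort(dm$day[dm$setting == "outpatient"])
  if (length(outp) >= 2) {
    gap_ok <- which(diff(outp) < 365)
    if (length(gap_ok))
      cand <- rbind(cand, data.frame(day = outp[gap_ok[1]],
                                     rule = "two_outpatient_12mo"))
  }
  oral <- any(fills$drug_class == "oral_antidiabetic" &
                fills$day >= index_day)
  if (length(outp) >= 1 && oral)
    cand <- rbind(cand, data.frame(
      day = outp[1], rule = "outpatient_plus_oral_antidiabetic"))
  if (nrow(cand) == 0)
    return(structure(list(event_month = NA_integer_, rule = "none"),
                     class = "outcome_result"))
  cand <- cand[order(cand$day), , drop = FALSE]
  structure(list(event_month = month_of_day(cand$day[1], index_day),
                 rule = cand$rule[1]),
            class = "outcome_result")
}

# 30-day months anchored at the index fill; day windows are half-open, so
# the index day itself is in month 1
month_of_day <- function(day, index_day) {
  as.integer((day - index_day) %/% 30L) + 1L
}

#' Resolve competing censoring events by the fixed cause hierarchy
#'
#' Given candidate censoring events, returns the earliest; same-month ties
#' break by the fixed cause order `death, study_end, age_65, coverage_loss,
#' discontinuation, augmentation, switch`. With no event before the horizon
#' the result is administrative: `(horizon, study_end)`.
#'
#' @param events data frame with columns `month` and `cause` (may be empty).
#' @param horizon follow-up horizon in months.
#' @return list of class `"censoring_outcome"` with `month`, `cause` and
#'   `administrative` (TRUE when nothing occurred before the horizon).
#' @export
determine_censoring <- function(events, horizon) {
  if (nrow(events) > 0 && !all(events$cause %in% CENSOR_CAUSES))
    stop("unknown censoring cause: ",
         paste(setdiff(events$cause, CENSOR_CAUSES), collapse = ", "),
         call. = FALSE)
  events <- events[events$month <= horizon, , drop = FALSE]
  if (nrow(events) == 0)
    return(structure(list(month = as.integer(horizon), cause = "study_end",
                          administrative = TRUE),
                     class = "censoring_outcome"))
  o <- order(events$month, match(events$cause, CENSOR_CAUSES))
  structure(list(month = as.integer(events$month[o[1]]),
                 cause = events$cause[o[1]], administrative = FALSE),
            class = "censoring_outcome")
}

#' Standardised mean difference between drug groups
#'
#' SMD = (mean in the olanzapine group minus mean in the aripiprazole group)
#' divided by the aripiprazole-group standard deviation; binary variables are
#' treated as 0/1 means. Absolute values above 0.10 are flagged as
#' unbalanced.
#'
#' @param cohort data frame with a `drug` column.
#' @param variable name of a numeric or logical column of `cohort`.
#' @return list of class `"covariate_balance"`: `variable`, `mean_aripiprazole`,
#'   `mean_olanzapine`, `sd_aripiprazole`, `smd`, `unbalanced`.
#' @export
compute_smd <- function(cohort, variable) {
  x <- as.numeric(cohort[[variable]])
  ari <- x[cohort$drug == "aripiprazole"]
  olz <- x[cohort$drug == "olanzapine"]
  if (length(ari) == 0 || length(olz) == 0)
    stop("variable must be observed in both drug groups", call. = FALSE)
  s <- stats::sd(ari)
  smd <- if (is.na(s) || s == 0) NA_real_ else (mean(olz) - mean(ari)) / s
  structure(list(variable = variable, mean_aripiprazole = mean(ari),
                 mean_olanzapine = mean(olz), sd_aripiprazole = s,
                 smd = smd,
                 unbalanced = if (is.na(smd)) NA else abs(smd) > 0.10),
            class = "covariate_balance")
}
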