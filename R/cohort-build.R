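#' Build the analytic cohort from raw claims
#'
#' Runs the full new-user pipeline over a claims bundle: candidate index
#' episode per person (the first index-drug fill whose 180-day pre-period is
#' enrolled, falling back to the first fill so a failed enrolment check is
#' reported as such), ordered eligibility screening, outcome ascertainment,
#' censoring adjudication, the monthly exposure panel, an attrition table and
#' baseline covariate balance.
#'
#' Continuous monotherapy is interpreted as medication availability: a month
#' counts as covered when any index-drug supply interval (carrying over
#' unused supply, stockpile capped at 30 days, plus `grace` extra days)
#' intersects it. The first uncovered month is a discontinuation unless an
#' other-antipsychotic fill occurs no later, in which case the person is
#' censored for augmentation (index supply continues past that fill) or
#' switching (it does not).
#'
#' @param bundle a `"mono_claims"` bundle ([generate_claims()] or
#'   [read_claims()]).
#' @param horizon follow-up horizon in 30-day months.
#' @param grace extra days of supply allowed before a coverage gap counts
#'   as discontinuation (default 0).
#' @param origin_year calendar year of day 0 of the claims stream, used only
#'   to label the index year covariate.
#' @return A list of class `"mono_cohort"`: `cohort` (one row per eligible
#'   person), `panel` (the person-month analytic panel, same columns as
#'   `generate_panel()$panel`), `attrition` (counts per exclusion reason) and
#'   `balance` (SMD table for the baseline covariates).
#' @export
build_cohort <- function(bundle, horizon = 24, grace = 0,
                         origin_year = 2008) {
  ids <- bundle$demographics$person_id
  f <- function(d) {
    if (is.null(d)) return(rep(list(NULL), length(ids)))
    split(d, factor(d$person_id, levels = ids))
  }
  fills_by <- f(bundle$fills)
  dx_by <- f(bundle$dx_claims)
  enr_by <- f(bundle$enrolment)
  proc_by <- f(bundle$procedures)

  empty_fills <- data.frame(day = numeric(0), drug_class = character(0),
                            days_supplied = numeric(0))
  reasons <- c("other_antipsychotic_pre_period", "not_new_user",
               "enrolment_gap", "prior_diabetes_or_cardiometabolic", "pcos",
               "age_out_of_range")
  excl <- stats::setNames(integer(length(reasons) + 1),
                          c(reasons, "no_index_fill"))
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    demo <- bundle$demographics[k, ]
    fl <- fills_by[[k]] %||% empty_fills
    dxk <- dx_by[[k]] %||%
      data.frame(day = numeric(0), setting = character(0),
                 position = character(0), code_group = character(0))
    enr <- enr_by[[k]] %||%
      data.frame(start_day = numeric(0), end_day = numeric(0))
    ep <- candidate_episode(fl, enr)
    if (is.null(ep)) {
      excl["no_index_fill"] <- excl["no_index_fill"] + 1L
      next
    }
    elig <- apply_eligibility(ep, fl, dxk, enr, demo)
    if (!elig$eligible) {
      excl[elig$reason] <- excl[elig$reason] + 1L
      next
    }
    rows[[k]] <- screen_person(ids[k], ep, fl, dxk, enr, demo,
                               proc_by[[k]], horizon, grace, origin_year)
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  attrition <- data.frame(reason = c("eligible", names(excl)),
                          n = c(nrow(cohort), unname(excl)))
  panel <- build_monthly_panel(cohort, bundle, horizon = horizon,
                               grace = grace)
  out <- list(cohort = cohort, panel = panel, attrition = attrition,
              balance = balance_table(cohort))
  class(out) <- "mono_cohort"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# first index-drug fill with an enrolled 180-day pre-period; falls back to
# the first index-drug fill so eligibility can name the failing check
candidate_episode <- function(fills, enrolment) {
  idx <- fills[fills$drug_class %in% paste0("index_", DRUGS), , drop = FALSE]
  if (nrow(idx) == 0) return(NULL)
  idx <- idx[order(idx$day), , drop = FALSE]
  k <- which(vapply(idx$day, function(d)
    interval_covered(enrolment, d - 180, d), logical(1)))
  k <- if (length(k)) k[1] else 1L
  d0 <- idx$day[k]
  pre <- idx$day >= d0 - 180 & idx$day < d0
  structure(list(index_day = d0,
                 index_drug = sub("^index_", "", idx$drug_class[k]),
                 prior_days = sum(idx$days_supplied[pre])),
            class = "index_episode")
}

screen_person <- function(id, ep, fills, dxk, enr, demo, procs, horizon,
                          grace, origin_year = 2008) {
  d0 <- ep$index_day
  oc <- ascertain_outcome(dxk, fills, d0)
  cens <- censoring_events(ep, fills, enr, demo, horizon, grace)
  smi <- dxk[startsWith(dxk$code_group, "smi_") & dxk$day < d0, ,
             drop = FALSE]
  diagnosis <- if (nrow(smi)) sub("^smi_", "", smi$code_group[
    which.max(smi$day)]) else NA_character_
  age <- as.integer((d0 - demo$birth_day) %/% 365)
  vacc <- if (!is.null(procs))
    procs$day[procs$kind == "influenza_vaccination" & procs$day >= d0]
  else numeric(0)
  event_observed <- !is.na(oc$event_month) &&
    (cens$administrative || oc$event_month < cens$month) &&
    oc$event_month <= horizon
  data.frame(person_id = id, index_day = d0, drug = ep$index_drug,
             diagnosis = diagnosis, age = age,
             age_over45 = as.integer(age > 45),
             female = demo$female, white = demo$white, state = demo$state,
             index_year = origin_year + d0 %/% 365L,
             prior_days = ep$prior_days,
             comorbid0 = as.integer(any(
               dxk$code_group == "chronic_comorbidity" & dxk$day < d0)),
             event_month = if (event_observed) oc$event_month else
               NA_integer_,
             outcome_rule = if (event_observed) oc$rule else "none",
             censor_month = cens$month, censor_cause = cens$cause,
             administrative_end = cens$administrative,
             vacc_month = if (length(vacc))
               month_of_day(min(vacc), d0) else NA_integer_,
             stringsAsFactors = FALSE)
}

# candidate censoring events for one person; the monotherapy-end cause is
# adjudicated first (augmentation/switch take the month of the first
# other-antipsychotic fill when it is no later than the first coverage gap)
censoring_events <- function(ep, fills, enr, demo, horizon, grace) {
  d0 <- ep$index_day
  ev <- list()
  if (!is.na(demo$death_day) && demo$death_day >= d0)
    ev$death <- data.frame(month = month_of_day(demo$death_day, d0),
                           cause = "death")
  days_to_65 <- demo$birth_day + 65L * 365L - d0
  if (days_to_65 <= 30L * horizon)
    ev$age65 <- data.frame(month = (days_to_65 - 1L) %/% 30L + 1L,
                           cause = "age_65")
  for (t in seq_len(horizon)) {
    ms <- d0 + 30 * (t - 1)
    if (!interval_covered(enr, ms, ms + 30)) {
      ev$coverage <- data.frame(month = t, cause = "coverage_loss")
      break
    }
  }
  idx <- fills[fills$drug_class == paste0("index_", ep$index_drug) &
                 fills$day >= d0, , drop = FALSE]
  u <- first_uncovered_month(idx[, c("day", "days_supplied")], d0, horizon,
                             cap = 30, grace = grace)
  other <- fills$day[fills$drug_class == "other_antipsychotic" &
                       fills$day >= d0]
  v_day <- if (length(other)) min(other) else NA
  v <- if (!is.na(v_day)) month_of_day(v_day, d0) else NA_integer_
  u_eff <- if (is.na(u)) horizon + 1L else u
  if (!is.na(v) && v <= u_eff && v <= horizon) {
    cont <- supply_covers_day(idx[, c("day", "days_supplied")], d0, v_day,
                              cap = 30, grace = grace)
    ev$mono <- data.frame(month = v,
                          cause = if (cont) "augmentation" else "switch")
  } else if (!is.na(u)) {
    ev$mono <- data.frame(month = u, cause = "discontinuation")
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(month = integer(0), cause = character(0))
  determine_censoring(events, horizon)
}

# coverage intervals implied by fills with carryover (unused supply capped
# at `cap` days of stockpile) and a grace extension
supply_intervals <- function(fills, start_day, cap = 30, grace = 0) {
  fills <- fills[order(fills$day), , drop = FALSE]
  fills <- fills[fills$day >= start_day, , drop = FALSE]
  if (nrow(fills) == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  segs <- list()
  seg_start <- fills$day[1]
  supply_end <- fills$day[1]
  for (k in seq_len(nrow(fills))) {
    d <- fills$day[k]
    s <- fills$days_supplied[k]
    if (d > supply_end + grace) {
      segs[[length(segs) + 1]] <- c(seg_start, supply_end)
      seg_start <- d
      supply_end <- d + s
    } else {
      leftover <- min(max(supply_end - d, 0), cap)
      supply_end <- d + leftover + s
    }
  }
  segs[[length(segs) + 1]] <- c(seg_start, supply_end)
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1], end = m[, 2] + grace)
}

# first month in 1..horizon whose [start, end) window no supply interval
# intersects; NA when all months are covered
first_uncovered_month <- function(fills, index_day, horizon, cap = 30,
                                  grace = 0) {
  iv <- supply_intervals(fills, index_day, cap = cap, grace = grace)
  for (t in seq_len(horizon)) {
    ms <- index_day + 30 * (t - 1)
    if (!any(iv$start < ms + 30 & iv$end > ms)) return(t)
  }
  NA_integer_
}

supply_covers_day <- function(fills, index_day, day, cap = 30, grace = 0) {
  iv <- supply_intervals(fills, index_day, cap = cap, grace = grace)
  any(iv$start <= day & iv$end > day)
}

#' Assemble the person-month exposure panel for a screened cohort
#'
#' One row per person-month from month 1 through the earliest of the outcome
#' month, the censoring month and the horizon. Adherence `A` is 1 on every
#' row except a monotherapy-end censoring row; `C` flags the censoring row
#' with its `cause`; the outcome `Y` is unobserved (`NA`) on censoring rows.
#' Time-varying covariates are derived from claims: `comorbid` (any chronic
#' comorbidity claim before the end of the month, absorbing), `acute_care`
#' (any non-diabetes in-patient claim in the month) and `metabolic_test`
#' (any metabolic-test procedure in the month).
#'
#' @param cohort the screened cohort data frame from [build_cohort()].
#' @param bundle the claims bundle the cohort was screened from.
#' @inheritParams build_cohort
#' @return The person-month panel data frame.
#' @export
build_monthly_panel <- function(cohort, bundle, horizon = 24, grace = 0) {
  if (is.null(cohort) || nrow(cohort) == 0) return(NULL)
  obs_end <- ifelse(cohort$administrative_end, horizon, cohort$censor_month)
  last <- pmin(ifelse(is.na(cohort$event_month), horizon,
                      cohort$event_month), obs_end)
  if (any(last < 1)) stop("panel rows after an absorbing event",
                          call. = FALSE)
  i <- rep(seq_len(nrow(cohort)), last)
  month <- sequence(last)
  ms <- cohort$index_day[i] + 30L * (month - 1L)
  censored <- !cohort$administrative_end[i] & month == cohort$censor_month[i]
  mono <- cohort$censor_cause[i] %in% MONO_CAUSES

  pid <- cohort$person_id
  dxc <- bundle$dx_claims
  chronic <- dxc[dxc$code_group == "chronic_comorbidity" &
                   dxc$person_id %in% pid, , drop = FALSE]
  first_chronic <- tapply(chronic$day, chronic$person_id, min)
  fc <- first_chronic[match(cohort$person_id, names(first_chronic))][i]
  comorbid <- as.integer(!is.na(fc) & fc < ms + 30L)

  acute_claims <- dxc[dxc$setting == "inpatient" &
                        dxc$code_group != "type2_diabetes" &
                        dxc$person_id %in% pid, , drop = FALSE]
  acute <- month_flag(acute_claims, cohort, i, month)
  tests <- bundle$procedures
  tests <- if (is.null(tests)) NULL else
    tests[tests$kind == "metabolic_test" & tests$person_id %in% pid, ,
          drop = FALSE]
  testing <- month_flag(tests, cohort, i, month)

  data.frame(
    person_id = cohort$person_id[i], month = month,
    diagnosis = cohort$diagnosis[i], age = cohort$age[i],
    age_over45 = cohort$age_over45[i], female = cohort$female[i],
    white = cohort$white[i], state = cohort$state[i],
    index_year = cohort$index_year[i], prior_days = cohort$prior_days[i],
    drug = cohort$drug[i], comorbid = comorbid, acute_care = acute,
    metabolic_test = testing,
    A = as.integer(!(censored & mono)), C = as.integer(censored),
    cause = ifelse(censored, cohort$censor_cause[i], NA_character_),
    Y = ifelse(censored, NA_integer_,
               as.integer(!is.na(cohort$event_month[i]) &
                            month == cohort$event_month[i])),
    stringsAsFactors = FALSE)
}

# 0/1 flag: any claim for this person in this 30-day month
month_flag <- function(claims, cohort, i, month) {
  if (is.null(claims) || nrow(claims) == 0) return(integer(length(i)))
  j <- match(claims$person_id, cohort$person_id)
  keep <- !is.na(j)
  key <- paste(j[keep], month_of_day(claims$day[keep],
                                     cohort$index_day[j[keep]]))
  as.integer(paste(i, month) %in% key)
}

balance_table <- function(cohort) {
  vars <- c("age", "age_over45", "female", "white", "comorbid0",
            "prior_days")
  for (g in DX_GROUPS) {
    cohort[[paste0("dx_", g)]] <- as.integer(cohort$diagnosis == g)
    vars <- c(vars, paste0("dx_", g))
  }
  do.call(rbind, lapply(vars, function(v) {
    b <- tryCatch(compute_smd(cohort, v), error = function(e) NULL)
    if (is.null(b))
      return(data.frame(variable = v, mean_aripiprazole = NA_real_,
                        mean_olanzapine = NA_real_, smd = NA_real_,
                        unbalanced = NA, stringsAsFactors = FALSE))
    data.frame(variable = v, mean_aripiprazole = b$mean_aripiprazole,
               mean_olanzapine = b$mean_olanzapine, smd = b$smd,
               unbalanced = b$unbalanced, stringsAsFactors = FALSE)
  }))
}

#' @export
print.mono_cohort <- function(x, ...) {
  cat("<mono_cohort>", nrow(x$cohort), "eligible persons,",
      nrow(x$panel), "person-months\n")
  print(x$attrition)
  invisible(x)
}
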