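#' Generate raw synthetic claims streams
#'
#' Maps a simulated cohort (see [generate_panel()]) to the five raw claims
#' tables a cohort builder consumes -- pharmacy fills, diagnosis claims,
#' enrolment spans, procedures and demographics -- such that the implied
#' exposure, eligibility, censoring and outcome status reproduce the latent
#' panel. Optionally appends distractor persons who each violate one
#' eligibility rule, cycling through the exclusion reasons.
#'
#' Code groups are symbolic labels, not real ICD-9/NDC vocabularies:
#' `type2_diabetes`, `excluded_cardiometabolic`, `pcos`, `chronic_comorbidity`,
#' `smi_<diagnosis>` and `other` for diagnoses; drug classes
#' `index_aripiprazole`, `index_olanzapine`, `other_antipsychotic`,
#' `oral_antidiabetic`, `insulin`, `other`.
#'
#' Days are integers with day 0 the first of January of the earliest index
#' year; enrolment spans are half-open `[start_day, end_day)`.
#'
#' @param config a [dgp_config()]; `config$distractor_frac` controls the
#'   proportion of planted ineligible persons.
#' @param seed integer master seed (defaults to `config$seed`).
#' @return A list of class `"mono_claims"` with data frames `fills`
#'   (`person_id, day, drug_code, drug_class, days_supplied`), `dx_claims`
#'   (`person_id, day, setting, position, code_group`), `enrolment`
#'   (`person_id, start_day, end_day`), `procedures` (`person_id, day, kind`),
#'   `demographics` (`person_id, birth_day, female, white, state, death_day`),
#'   plus `latent` (the generating `"mono_sim"`, kept for round-trip testing)
#'   and `config`.
#' @export
#' @examples
#' bundle <- generate_claims(dgp_config(n_subjects = 50, seed = 1))
#' head(bundle$fills)
generate_claims <- function(config, seed = config$seed) {
  sim <- generate_panel(config, seed = seed)
  p <- sim$persons
  n <- nrow(p)
  H <- config$horizon
  m_start <- function(i, t) p$index_day[i] + 30L * (t - 1L)

  cm <- ifelse(p$administrative_end, H + 1L, p$censor_month)
  cause <- p$censor_cause
  # last month with an index fill: supply always covers month 1..last_fill
  last_fill <- ifelse(p$administrative_end, H,
                      ifelse(cause %in% c("death", "age_65", "augmentation"),
                             p$censor_month, p$censor_month - 1L))

  fills <- list()
  dx <- list()
  procs <- list()

  # index-drug fills, every 30 days with 30 days supplied
  nf <- pmax(last_fill, 0L)
  i <- rep(seq_len(n), nf)
  t <- sequence(nf)
  fills$index <- data.frame(
    person_id = p$person_id[i], day = m_start(i, t),
    drug_code = p$drug[i],
    drug_class = paste0("index_", p$drug[i]),
    days_supplied = 30L, stringsAsFactors = FALSE)

  # pre-period index-drug exposure (a single fill of <= 30 days supplied
  # keeps every 90-day pre-period window at or below the 30-day cap)
  pe <- which(p$prior_days > 0)
  fills$prior <- data.frame(
    person_id = p$person_id[pe], day = p$index_day[pe] - 120L,
    drug_code = p$drug[pe], drug_class = paste0("index_", p$drug[pe]),
    days_supplied = p$prior_days[pe], stringsAsFactors = FALSE)

  # monotherapy-ending other-antipsychotic fills: augmentation while index
  # supply continues past the fill, switch after index supply has stopped
  aug <- which(cause == "augmentation")
  fills$aug <- data.frame(
    person_id = p$person_id[aug], day = m_start(aug, p$censor_month[aug]) + 15L,
    drug_code = "risperidone", drug_class = "other_antipsychotic",
    days_supplied = 30L, stringsAsFactors = FALSE)
  sw <- which(cause == "switch")
  fills$sw <- data.frame(
    person_id = p$person_id[sw], day = m_start(sw, p$censor_month[sw]) + 3L,
    drug_code = "risperidone", drug_class = "other_antipsychotic",
    days_supplied = 30L, stringsAsFactors = FALSE)

  # pre-period SMI diagnosis claim assigning the diagnosis group
  dx$smi <- data.frame(
    person_id = p$person_id, day = p$index_day - 150L,
    setting = "outpatient", position = "primary",
    code_group = paste0("smi_", p$diagnosis), stringsAsFactors = FALSE)

  # chronic comorbidity: baseline claim in the pre-period, onset claim in the
  # first month the latent flag switches on
  cb <- which(p$comorbid0 == 1)
  dx$com0 <- data.frame(
    person_id = p$person_id[cb], day = p$index_day[cb] - 100L,
    setting = "outpatient", position = "secondary",
    code_group = "chronic_comorbidity", stringsAsFactors = FALSE)
  com_m <- sim_com_matrix(sim)
  first_on <- apply(com_m == 1L, 1, function(z) {
    w <- which(z)
    if (length(w)) w[1] else NA_integer_
  })
  on <- which(p$comorbid0 == 0 & !is.na(first_on))
  dx$onset <- data.frame(
    person_id = p$person_id[on], day = m_start(on, first_on[on]) + 1L,
    setting = "outpatient", position = "secondary",
    code_group = "chronic_comorbidity", stringsAsFactors = FALSE)

  # acute-care months: one non-diabetes inpatient claim
  fp <- sim$full_panel
  ai <- which(fp$acute_care == 1)
  pid_idx <- match(fp$person_id[ai], p$person_id)
  dx$acute <- data.frame(
    person_id = fp$person_id[ai],
    day = m_start(pid_idx, fp$month[ai]) + 5L,
    setting = "inpatient", position = "secondary", code_group = "other",
    stringsAsFactors = FALSE)

  # diabetes outcome evidence, one qualifying rule per event
  ev <- which(!is.na(p$event_month) &
                (p$administrative_end | p$event_month < p$censor_month))
  if (length(ev) > 0) {
    rule <- sample(c("inpatient_primary", "two_outpatient_12mo",
                     "outpatient_plus_oral_antidiabetic"),
                   length(ev), replace = TRUE, prob = c(0.3, 0.4, 0.3))
    d0 <- m_start(ev, p$event_month[ev])
    r1 <- rule == "inpatient_primary"
    if (any(r1))
      dx$ev_inpt <- data.frame(
        person_id = p$person_id[ev[r1]], day = d0[r1] + 2L,
        setting = "inpatient", position = "primary",
        code_group = "type2_diabetes", stringsAsFactors = FALSE)
    r2 <- rule == "two_outpatient_12mo"
    if (any(r2))
      dx$ev_two <- data.frame(
        person_id = rep(p$person_id[ev[r2]], 2),
        day = c(d0[r2] + 2L, d0[r2] + 12L),
        setting = "outpatient",
        position = rep(c("primary", "secondary"), each = sum(r2)),
        code_group = "type2_diabetes", stringsAsFactors = FALSE)
    r3 <- rule == "outpatient_plus_oral_antidiabetic"
    if (any(r3)) {
      dx$ev_oral <- data.frame(
        person_id = p$person_id[ev[r3]], day = d0[r3] + 2L,
        setting = "outpatient", position = "primary",
        code_group = "type2_diabetes", stringsAsFactors = FALSE)
      fills$oral <- data.frame(
        person_id = p$person_id[ev[r3]], day = d0[r3] + 2L,
        drug_code = "metformin", drug_class = "oral_antidiabetic",
        days_supplied = 30L, stringsAsFactors = FALSE)
    }
  }

  # procedures: metabolic tests and the first influenza vaccination
  ti <- which(fp$metabolic_test == 1)
  tid <- match(fp$person_id[ti], p$person_id)
  procs$test <- data.frame(
    person_id = fp$person_id[ti], day = m_start(tid, fp$month[ti]) + 8L,
    kind = "metabolic_test", stringsAsFactors = FALSE)
  vi <- which(!is.na(p$vacc_month))
  procs$vacc <- data.frame(
    person_id = p$person_id[vi], day = m_start(vi, p$vacc_month[vi]) + 10L,
    kind = "influenza_vaccination", stringsAsFactors = FALSE)

  enrol_end <- ifelse(cause == "coverage_loss" & !p$administrative_end,
                      p$index_day + 30L * (p$censor_month - 1L) + 15L,
                      p$index_day + 30L * H + 40L)
  enrolment <- data.frame(person_id = p$person_id,
                          start_day = p$index_day - 210L,
                          end_day = enrol_end, stringsAsFactors = FALSE)

  death_day <- ifelse(cause == "death" & !p$administrative_end,
                      p$index_day + 30L * (p$censor_month - 1L) + 12L,
                      NA_integer_)
  demographics <- data.frame(
    person_id = p$person_id, birth_day = p$birth_day, female = p$female,
    white = p$white, state = p$state, death_day = death_day,
    stringsAsFactors = FALSE)

  bundle <- list(fills = rbind_all(fills), dx_claims = rbind_all(dx),
                 enrolment = enrolment, procedures = rbind_all(procs),
                 demographics = demographics, latent = sim, config = config)
  if (config$distractor_frac > 0)
    bundle <- add_distractors(bundle, config)
  bundle$fills <- order_claims(bundle$fills)
  bundle$dx_claims <- order_claims(bundle$dx_claims)
  bundle$procedures <- order_claims(bundle$procedures)
  check_window(bundle, config)
  class(bundle) <- "mono_claims"
  bundle
}

rbind_all <- function(lst) {
  lst <- Filter(function(d) is.data.frame(d) && nrow(d) > 0, lst)
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

order_claims <- function(d) {
  if (is.null(d)) return(d)
  d <- d[order(d$person_id, d$day), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# comorbid flag matrix (persons x months) recovered from the full panel
sim_com_matrix <- function(sim) {
  fp <- sim$full_panel
  p <- sim$persons
  m <- matrix(NA_integer_, nrow(p), sim$config$horizon)
  m[cbind(match(fp$person_id, p$person_id), fp$month)] <- fp$comorbid
  m
}

check_window <- function(bundle, config) {
  end <- calendar_window_end(config)
  days <- c(bundle$fills$day, bundle$dx_claims$day, bundle$procedures$day)
  if (length(days) && (min(days) < -365L || max(days) >= end))
    stop("claims fall outside the simulated calendar window", call. = FALSE)
  invisible(TRUE)
}

# one extra ineligible person per listed reason, cycled up to the requested
# fraction of the cohort size
add_distractors <- function(bundle, config) {
  n_extra <- round(config$distractor_frac * config$n_subjects)
  if (n_extra == 0) return(bundle)
  reasons <- c("other_antipsychotic_pre_period", "not_new_user",
               "enrolment_gap", "prior_diabetes_or_cardiometabolic", "pcos",
               "age_out_of_range")
  reason <- rep_len(reasons, n_extra)
  max_index <- calendar_window_end(config) - 30L * config$horizon - 60L
  idx_day <- 180L + sample.int(max_index - 180L + 1L, n_extra, TRUE) - 1L
  id <- sprintf("D%05d", seq_len(n_extra))
  drug <- sample(DRUGS, n_extra, replace = TRUE)
  age <- ifelse(reason == "age_out_of_range", 66L, 40L)
  demo <- data.frame(person_id = id,
                     birth_day = idx_day - age * 365L - 100L,
                     female = stats::rbinom(n_extra, 1, 0.5),
                     white = stats::rbinom(n_extra, 1, 0.67),
                     state = "S1", death_day = NA_integer_,
                     stringsAsFactors = FALSE)
  enrol <- data.frame(person_id = id,
                      start_day = ifelse(reason == "enrolment_gap",
                                         idx_day - 150L, idx_day - 210L),
                      end_day = idx_day + 30L * config$horizon + 40L,
                      stringsAsFactors = FALSE)
  fills <- data.frame(person_id = id, day = idx_day, drug_code = drug,
                      drug_class = paste0("index_", drug),
                      days_supplied = 30L, stringsAsFactors = FALSE)
  extra_fill <- which(reason %in% c("other_antipsychotic_pre_period",
                                    "not_new_user"))
  if (length(extra_fill)) {
    ef <- reason[extra_fill] == "other_antipsychotic_pre_period"
    fills <- rbind(fills, data.frame(
      person_id = rep(id[extra_fill], ifelse(ef, 1L, 2L)),
      day = unlist(mapply(function(k, iso, d0) {
        if (iso) d0 - 60L else c(d0 - 80L, d0 - 50L)
      }, extra_fill, ef, idx_day[extra_fill], SIMPLIFY = FALSE)),
      drug_code = unlist(mapply(function(k, iso, dg) {
        if (iso) "risperidone" else rep(dg, 2)
      }, extra_fill, ef, drug[extra_fill], SIMPLIFY = FALSE)),
      drug_class = unlist(mapply(function(k, iso, dg) {
        if (iso) "other_antipsychotic" else rep(paste0("index_", dg), 2)
      }, extra_fill, ef, drug[extra_fill], SIMPLIFY = FALSE)),
      days_supplied = 30L, stringsAsFactors = FALSE))
  }
  dxr <- data.frame(person_id = id, day = idx_day - 150L,
                    setting = "outpatient", position = "primary",
                    code_group = paste0(
                      "smi_", sample(DX_GROUPS, n_extra, TRUE)),
                    stringsAsFactors = FALSE)
  bad <- which(reason == "prior_diabetes_or_cardiometabolic")
  if (length(bad))
    dxr <- rbind(dxr, data.frame(
      person_id = id[bad], day = idx_day[bad] - 90L,
      setting = "outpatient", position = "primary",
      code_group = "type2_diabetes", stringsAsFactors = FALSE))
  pc <- which(reason == "pcos")
  if (length(pc))
    dxr <- rbind(dxr, data.frame(
      person_id = id[pc], day = idx_day[pc] - 60L,
      setting = "outpatient", position = "secondary",
      code_group = "pcos", stringsAsFactors = FALSE))
  bundle$fills <- rbind(bundle$fills, fills)
  bundle$dx_claims <- rbind(bundle$dx_claims, dxr)
  bundle$enrolment <- rbind(bundle$enrolment, enrol)
  bundle$demographics <- rbind(bundle$demographics, demo)
  bundle$distractors <- data.frame(person_id = id, reason = reason,
                                   stringsAsFactors = FALSE)
  bundle
}

#' @export
print.mono_claims <- function(x, ...) {
  cat("<mono_claims>", nrow(x$demographics), "persons |",
      nrow(x$fills), "fills,", nrow(x$dx_claims), "dx claims,",
      nrow(x$procedures), "procedures\n")
  invisible(x)
}

#' Write / read a claims bundle as delimited tables
#'
#' `write_claims()` writes `fills.csv`, `dx_claims.csv`, `enrolment.csv`,
#' `procedures.csv`, `demographics.csv`, the latent `panel.csv`, and the
#' exact counterfactual truth as `truth.json` to a directory;
#' `read_claims()` reads the five claims tables back (the latent panel and
#' truth are simulation-side artefacts and are not reloaded).
#'
#' @param bundle a `"mono_claims"` bundle from [generate_claims()].
#' @param dir directory to write to / read from (created if missing).
#' @return `write_claims()` the directory, invisibly; `read_claims()` a
#'   `"mono_claims"` list without `latent`.
#' @export
write_claims <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("fills", "dx_claims", "enrolment", "procedures",
               "demographics"))
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(bundle$latent)) {
    utils::write.csv(bundle$latent$panel, file.path(dir, "panel.csv"),
                     row.names = FALSE)
    tr <- bundle$latent$truth
    jsonlite::write_json(
      list(curve = tr$curve, contrasts = tr$contrasts,
           rmst = as.list(tr$rmst), rmst_diff = tr$rmst_diff),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_claims
#' @export
read_claims <- function(dir) {
  out <- lapply(c(fills = "fills", dx_claims = "dx_claims",
                  enrolment = "enrolment", procedures = "procedures",
                  demographics = "demographics"),
                function(nm) utils::read.csv(file.path(dir,
                                                       paste0(nm, ".csv")),
                                             stringsAsFactors = FALSE))
  class(out) <- "mono_claims"
  out
}
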