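#' E-value for unmeasured confounding on the risk-ratio scale
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need with both treatment and
#' outcome to fully explain away an observed risk ratio. Protective ratios
#' are inverted first (`RR* = 1/RR` when `RR < 1`); the point E-value is
#' `RR* + sqrt(RR* (RR* - 1))`. The confidence-limit E-value uses the limit
#' closest to the null and is 1 when the interval contains 1.
#'
#' @param rr observed risk ratio (> 0).
#' @param ci_lo,ci_hi optional 95% confidence limits around `rr`.
#' @return list of class `"evalue_result"`: `rr`, `e_point`, `e_ci`
#'   (`NA` when no interval is supplied), and `ci_limit_used`.
#' @export
#' @examples
#' e_value(0.77, 0.62, 0.92)
e_value <- function(rr, ci_lo = NA_real_, ci_hi = NA_real_) {
  if (!is.numeric(rr) || rr <= 0)
    stop("risk ratio must be positive", call. = FALSE)
  has_ci <- !is.na(ci_lo) && !is.na(ci_hi)
  if (has_ci) {
    if (ci_lo <= 0 || ci_hi <= 0)
      stop("confidence limits must be positive", call. = FALSE)
    if (ci_lo > rr || ci_hi < rr)
      stop("confidence limits must bracket the risk ratio", call. = FALSE)
  }
  e_of <- function(r) {
    rs <- if (r < 1) 1 / r else r
    rs + sqrt(rs * (rs - 1))
  }
  e_point <- e_of(rr)
  e_ci <- NA_real_
  limit <- NA_real_
  if (has_ci) {
    if (ci_lo <= 1 && ci_hi >= 1) {
      e_ci <- 1
    } else {
      limit <- if (ci_hi < 1) ci_hi else ci_lo
      e_ci <- e_of(limit)
    }
  }
  structure(list(rr = rr, e_point = e_point, e_ci = e_ci,
                 ci_limit_used = limit),
            class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  cat(sprintf("RR %.3f -> E-value %.3f (CI limit: %s)\n", x$rr, x$e_point,
              ifelse(is.na(x$e_ci), "none", sprintf("%.3f", x$e_ci))))
  invisible(x)
}

#' Per-month E-values for a fitted risk-curve contrast
#'
#' Computes the month-by-month risk-ratio E-values (point and
#' confidence-limit) from a two-arm [tmle_survival()] fit.
#'
#' @param fit a `"mono_tmle"` fit covering both drugs.
#' @return data frame: month, rr, rr_lo, rr_hi, e_point, e_ci.
#' @export
e_value_curve <- function(fit) {
  c_o <- survival_curve(fit, "olanzapine")
  c_a <- survival_curve(fit, "aripiprazole")
  rows <- lapply(fit$months, function(m) {
    ct <- contrast(c_o, c_a, m)
    if (is.na(ct$rr) || ct$rr <= 0 || is.na(ct$rr_lo))
      return(data.frame(month = m, rr = ct$rr, rr_lo = NA_real_,
                        rr_hi = NA_real_, e_point = NA_real_,
                        e_ci = NA_real_))
    ev <- e_value(ct$rr, ct$rr_lo, ct$rr_hi)
    data.frame(month = m, rr = ct$rr, rr_lo = ct$rr_lo, rr_hi = ct$rr_hi,
               e_point = ev$e_point, e_ci = ev$e_ci)
  })
  do.call(rbind, rows)
}

#' Negative-control outcome analysis: influenza vaccination
#'
#' Reruns the full longitudinal TMLE with the first influenza vaccination
#' as the absorbing outcome under the same continuous-monotherapy regime.
#' The index drugs should not affect vaccination, so a nonzero
#' vaccination-free RMST difference signals unmeasured differences between
#' the groups (for example in healthcare contact frequency).
#'
#' @param panel a person-month panel whose `Y` column is the vaccination
#'   outcome (see [vaccination_panel()]), or a `"mono_sim"` object.
#' @param sl an [sl_control()] for the nuisance fits.
#' @param ... passed to [tmle_survival()].
#' @return list of class `"negative_control_result"`: the
#'   `"rmst_difference"` for vaccination-free months and the underlying
#'   `"mono_tmle"` fit.
#' @export
negative_control_analysis <- function(panel, sl = sl_control("logistic"),
                                      ...) {
  if (inherits(panel, "mono_sim")) panel <- vaccination_panel(panel)
  if (all(is.na(panel$Y) | panel$Y == 0)) {
    # no vaccinations anywhere: both survival curves are identically 1
    H <- max(panel$month)
    zero <- structure(list(rmst = H, se = 0, lo = H, hi = H,
                           drug = NA, horizon = H, inf = NULL),
                      class = "rmst_estimate")
    return(structure(list(rmst_diff = structure(
      list(olanzapine = zero, aripiprazole = zero, diff = 0, se = 0,
           lo = 0, hi = 0), class = "rmst_difference"), fit = NULL),
      class = "negative_control_result"))
  }
  fit <- tmle_survival(panel, sl = sl, ...)
  d <- rmst_difference(survival_curve(fit, "olanzapine"),
                       survival_curve(fit, "aripiprazole"))
  structure(list(rmst_diff = d, fit = fit),
            class = "negative_control_result")
}

#' @export
print.negative_control_result <- function(x, ...) {
  d <- x$rmst_diff
  cat(sprintf(
    "vaccination-free RMST difference (olz - ari): %+.3f [%.3f, %.3f]\n",
    d$diff, d$lo, d$hi))
  invisible(x)
}

#' Metabolic-testing rates per drug group
#'
#' The proportion of observed person-months with a metabolic (lipid or
#' glucose) test, by drug group: a check on whether clinicians were
#' watching one group's cardiometabolic risk more closely.
#'
#' @param panel a person-month panel with `drug` and `metabolic_test`.
#' @return data frame: drug, person_months, tested, rate.
#' @export
testing_rates <- function(panel) {
  out <- do.call(rbind, lapply(DRUGS, function(d) {
    rows <- panel[panel$drug == d, , drop = FALSE]
    if (nrow(rows) == 0)
      return(data.frame(drug = d, person_months = 0L, tested = 0L,
                        rate = NA_real_))
    data.frame(drug = d, person_months = nrow(rows),
               tested = sum(rows$metabolic_test),
               rate = mean(rows$metabolic_test))
  }))
  rownames(out) <- NULL
  out
}

#' Restrict to young initiators with no previous index-drug exposure
#'
#' Keeps persons aged 18-45 at the index fill with zero pre-period
#' index-drug days supplied: the subgroup with the least opportunity for
#' unobserved diabetes risk factors and clinician risk signals, re-estimated
#' with unchanged downstream machinery.
#'
#' @param cohort,panel cohort and person-month tables sharing `person_id`.
#' @param age_range inclusive index-age bounds (default `c(18, 45)`).
#' @return list with the restricted `cohort` and `panel`.
#' @export
subgroup_filter <- function(cohort, panel, age_range = c(18, 45)) {
  keep <- cohort$age >= age_range[1] & cohort$age <= age_range[2] &
    cohort$prior_days == 0
  ids <- cohort$person_id[keep]
  list(cohort = cohort[keep, , drop = FALSE],
       panel = panel[panel$person_id %in% ids, , drop = FALSE])
}
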