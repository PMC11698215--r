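#' Default run configuration
#'
#' Assembles the full configuration for an end-to-end run: the generative
#' world (`dgp` block, see [dgp_config()]), cohort rules, Super Learner
#' settings, estimator settings and sensitivity toggles. The configuration
#' round-trips through YAML unchanged and unknown keys are rejected.
#'
#' @param n_subjects cohort size for the simulate stage.
#' @param seed master seed, fanned out to every stage.
#' @return nested list of class `"run_config"`.
#' @export
default_run_config <- function(n_subjects = 2000, seed = 1) {
  structure(list(
    seed = seed,
    dgp = list(n_subjects = n_subjects, horizon = 24,
               distractor_frac = 0.0),
    cohort = list(horizon = 24, grace = 0, origin_year = 2008),
    superlearner = list(library = "logistic", folds = 2, clip = 1e-6),
    estimator = list(months = 24, clip = 0.005,
                     strata = c("schizophrenia", "bipolar", "severe_mdd")),
    sensitivity = list(evalues = TRUE, negative_control = TRUE,
                       testing_rates = TRUE, subgroup = FALSE),
    stages = list(simulate = TRUE, build_cohort = TRUE, estimate = TRUE,
                  sensitivity = TRUE, report = TRUE)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' `read_run_config()` validates against the [default_run_config()] schema:
#' any unknown key is an error naming the key.
#'
#' @param path YAML file path.
#' @param config a `"run_config"` list.
#' @return `read_run_config()` a validated `"run_config"`;
#'   `write_run_config()` the path, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  ref <- unclass(default_run_config())
  check_keys <- function(x, template, where) {
    extra <- setdiff(names(x), names(template))
    if (length(extra))
      stop("unknown configuration key", if (length(extra) > 1) "s", " ",
           paste0(where, extra, collapse = ", "), call. = FALSE)
    for (nm in names(x))
      if (is.list(template[[nm]]) && !is.null(names(template[[nm]])))
        check_keys(x[[nm]], template[[nm]], paste0(where, nm, "$"))
  }
  check_keys(config, ref, "")
  merged <- utils::modifyList(ref, config)
  structure(merged, class = "run_config")
}

# polynomial rolling hash over the serialised configuration; only a
# fingerprint for the run manifest, not cryptographic
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  bytes <- bytes[-(1:14)]  # skip the version-dependent header
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline: simulate, build cohort, estimate, sensitivity
#'
#' Executes the enabled stages in order on one master seed and returns (and
#' optionally writes) a report bundle: per-stratum risk, contrast and RMST
#' tables, the attrition and balance tables, sensitivity outputs, and a run
#' manifest carrying the seed and a configuration hash that every table
#' cross-references.
#'
#' @param config a `"run_config"` (see [default_run_config()]).
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV/JSON files.
#' @param seed overrides `config$seed`.
#' @return list of class `"report_bundle"`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         seed = NULL) {
  config <- validate_run_config(unclass(config))
  if (!is.null(seed)) config$seed <- seed
  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("monotmle")))
  bundle <- list(manifest = manifest, config = config)
  class(bundle) <- "report_bundle"
  st <- config$stages

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(paste0("FAILED at stage ", name, ": ",
                          conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (isTRUE(st$simulate)) {
    bundle$claims <- stage("simulate", {
      dgp_args <- config$dgp
      dgp_args$seed <- config$seed
      cfg <- do.call(dgp_config, dgp_args)
      generate_claims(cfg)
    })
  }
  if (isTRUE(st$build_cohort) && !is.null(bundle$claims)) {
    bundle$cohort <- stage("build_cohort", {
      do.call(build_cohort, c(list(bundle$claims),
                              config$cohort[c("horizon", "grace",
                                              "origin_year")]))
    })
  }
  sl <- do.call(sl_control,
                c(config$superlearner[c("library", "folds", "clip")],
                  list(seed = config$seed + 1)))
  if (isTRUE(st$estimate) && !is.null(bundle$cohort)) {
    bundle$estimates <- stage("estimate", {
      est <- config$estimator
      panel <- bundle$cohort$panel
      strata <- intersect(est$strata, unique(panel$diagnosis))
      lapply(stats::setNames(strata, strata), function(s)
        estimate_stratum(panel[panel$diagnosis == s, , drop = FALSE],
                         months = seq_len(est$months), sl = sl,
                         clip = est$clip))
    })
  }
  if (isTRUE(st$sensitivity) && !is.null(bundle$cohort)) {
    bundle$sensitivity <- stage("sensitivity", {
      sens <- list()
      panel <- bundle$cohort$panel
      if (isTRUE(config$sensitivity$testing_rates))
        sens$testing_rates <- testing_rates(panel)
      if (isTRUE(config$sensitivity$evalues) && !is.null(bundle$estimates))
        sens$evalues <- do.call(rbind, lapply(
          names(bundle$estimates), function(s)
            cbind(stratum = s, e_value_curve(bundle$estimates[[s]]$fit))))
      if (isTRUE(config$sensitivity$negative_control) &&
          !is.null(bundle$claims$latent))
        sens$negative_control <- negative_control_analysis(
          bundle$claims$latent, sl = sl)
      if (isTRUE(config$sensitivity$subgroup)) {
        sub <- subgroup_filter(bundle$cohort$cohort, panel)
        if (nrow(sub$cohort) > 20)
          sens$subgroup <- estimate_stratum(
            sub$panel, months = seq_len(config$estimator$months), sl = sl,
            clip = config$estimator$clip)
      }
      sens
    })
  }
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# full two-arm estimation for one stratum: risks, contrasts, RMST
estimate_stratum <- function(panel, months, sl, clip) {
  fit <- tmle_survival(panel, months = months, sl = sl, clip = clip)
  c_o <- survival_curve(fit, "olanzapine")
  c_a <- survival_curve(fit, "aripiprazole")
  contrasts <- do.call(rbind, lapply(months, function(m) {
    ct <- contrast(c_o, c_a, m)
    data.frame(month = m, risk_olz = ct$risk_olz, risk_ari = ct$risk_ari,
               rd_pp = ct$rd_pp, rd_lo = ct$rd_lo, rd_hi = ct$rd_hi,
               rr = ct$rr, rr_lo = ct$rr_lo, rr_hi = ct$rr_hi)
  }))
  rd <- rmst_difference(c_o, c_a)
  list(fit = fit,
       risks = rbind(fit$olanzapine$risks, fit$aripiprazole$risks),
       contrasts = contrasts,
       rmst = data.frame(
         drug = c("olanzapine", "aripiprazole", "difference"),
         rmst = c(rd$olanzapine$rmst, rd$aripiprazole$rmst, rd$diff),
         se = c(rd$olanzapine$se, rd$aripiprazole$se, rd$se),
         lo = c(rd$olanzapine$lo, rd$aripiprazole$lo, rd$lo),
         hi = c(rd$olanzapine$hi, rd$aripiprazole$hi, rd$hi)),
       n = fit$olanzapine$n)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  wr <- function(df, name) {
    if (is.null(df)) return()
    df$manifest_hash <- bundle$manifest$config_hash
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  if (!is.null(bundle$claims)) write_claims(bundle$claims, out_dir)
  if (!is.null(bundle$cohort)) {
    wr(bundle$cohort$cohort, "cohort.csv")
    wr(bundle$cohort$attrition, "attrition.csv")
    wr(bundle$cohort$balance, "balance.csv")
  }
  for (s in names(bundle$estimates)) {
    wr(bundle$estimates[[s]]$risks, paste0("risks_", s, ".csv"))
    wr(bundle$estimates[[s]]$contrasts, paste0("contrasts_", s, ".csv"))
    wr(bundle$estimates[[s]]$rmst, paste0("rmst_", s, ".csv"))
  }
  if (!is.null(bundle$sensitivity$testing_rates))
    wr(bundle$sensitivity$testing_rates, "testing_rates.csv")
  if (!is.null(bundle$sensitivity$evalues))
    wr(bundle$sensitivity$evalues, "evalues.csv")
  if (!is.null(bundle$sensitivity$negative_control)) {
    d <- bundle$sensitivity$negative_control$rmst_diff
    jsonlite::write_json(
      list(rmst_diff = d$diff, se = d$se, lo = d$lo, hi = d$hi,
           manifest_hash = bundle$manifest$config_hash),
      file.path(out_dir, "negative_control.json"), auto_unbox = TRUE,
      digits = NA)
  }
  if (!is.null(bundle$estimates) && length(bundle$estimates) > 0)
    writeLines(render_report(bundle), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Human-readable summary of a report bundle
#'
#' One line per headline quantity, mirroring the shape of the main results:
#' per-stratum RMST for each drug, the RMST difference, the final-month risk
#' per drug, and the final-month risk difference and risk ratio, each with
#' its 95% CI at full precision (lines parse back to the numeric tables
#' exactly). A null result (risk-ratio CI covering 1) is flagged.
#'
#' @param bundle a `"report_bundle"` from [run_pipeline()].
#' @return character vector of report lines.
#' @export
render_report <- function(bundle) {
  if (is.null(bundle$estimates) || length(bundle$estimates) == 0)
    stop("report bundle has no estimate tables", call. = FALSE)
  num <- function(x) sprintf("%.17g", x)
  lines <- c(sprintf("manifest_hash=%s seed=%s",
                     bundle$manifest$config_hash, bundle$manifest$seed))
  for (s in names(bundle$estimates)) {
    est <- bundle$estimates[[s]]
    rm <- est$rmst
    for (k in seq_len(nrow(rm)))
      lines <- c(lines, sprintf(
        "stratum=%s rmst_%s=%s lo=%s hi=%s", s, rm$drug[k],
        num(rm$rmst[k]), num(rm$lo[k]), num(rm$hi[k])))
    ct <- est$contrasts[nrow(est$contrasts), ]
    lines <- c(lines, sprintf(
      "stratum=%s month=%s risk_olanzapine=%s risk_aripiprazole=%s", s,
      ct$month, num(ct$risk_olz), num(ct$risk_ari)))
    lines <- c(lines, sprintf(
      "stratum=%s month=%s rd_pp=%s lo=%s hi=%s", s, ct$month,
      num(ct$rd_pp), num(ct$rd_lo), num(ct$rd_hi)))
    null_flag <- if (!is.na(ct$rr_lo) && ct$rr_lo <= 1 && ct$rr_hi >= 1)
      " null_not_rejected" else ""
    lines <- c(lines, sprintf(
      "stratum=%s month=%s rr=%s lo=%s hi=%s%s", s, ct$month, num(ct$rr),
      num(ct$rr_lo), num(ct$rr_hi), null_flag))
  }
  lines
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> seed", x$manifest$seed, "hash",
      x$manifest$config_hash, "\n")
  if (!is.null(x$estimates))
    cat("  strata:", paste(names(x$estimates), collapse = ", "), "\n")
  invisible(x)
}
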