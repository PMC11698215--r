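# Shared fixtures: a fully enumerable two-period world with one baseline and
# one time-varying binary confounder, its brute-force g-formula oracle, and a
# hand-written claims fixture covering every exclusion reason, every outcome
# rule and a same-month censoring tie.

# Structure: W baseline; drug depends on W; month-1 outcome depends on
# (W, drug); L2 depends on (W, drug) among survivors; staying on regime in
# month 2 depends on (W, L2); month-2 outcome depends on (W, L2, drug).
make_two_period_world <- function(n, seed) {
  set.seed(seed)
  w <- rbinom(n, 1, 0.5)
  olz <- rbinom(n, 1, plogis(-0.2 + 0.8 * w))
  drug <- ifelse(olz == 1, "olanzapine", "aripiprazole")
  ari <- 1 - olz
  y1 <- rbinom(n, 1, plogis(-2.2 + 0.5 * w + 0.4 * ari))
  l2 <- rbinom(n, 1, plogis(-0.5 + 0.8 * w + 0.3 * ari))
  r2 <- rbinom(n, 1, plogis(1.2 - 0.6 * w - 0.8 * l2))
  y2 <- rbinom(n, 1, plogis(-2.0 + 0.5 * w + 0.4 * ari + 0.7 * l2))
  id <- sprintf("P%05d", seq_len(n))
  m1 <- data.frame(person_id = id, month = 1L, w = w, l = 0L, drug = drug,
                   A = 1L, C = 0L, cause = NA_character_, Y = y1,
                   stringsAsFactors = FALSE)
  s <- which(y1 == 0)
  m2 <- data.frame(person_id = id[s], month = 2L, w = w[s], l = l2[s],
                   drug = drug[s], A = r2[s], C = 1L - r2[s],
                   cause = ifelse(r2[s] == 1, NA_character_,
                                  "discontinuation"),
                   Y = ifelse(r2[s] == 1, y2[s], NA_integer_),
                   stringsAsFactors = FALSE)
  rbind(m1, m2)
}

# exhaustive-stratification (nonparametric MLE) g-formula for the two-period
# world: psi_a(2) = E_W[ h1(W) + (1 - h1(W)) sum_l P(l | W, a, Y1 = 0)
# h2(W, l) ]
gformula_two_period <- function(panel, arm) {
  m1 <- panel[panel$month == 1, ]
  m2 <- panel[panel$month == 2 & panel$C == 0, ]
  h1 <- function(w) mean(m1$Y[m1$w == w & m1$drug == arm])
  h2 <- function(w, l) mean(m2$Y[m2$w == w & m2$l == l & m2$drug == arm])
  psi_w <- vapply(0:1, function(w) {
    s <- panel[panel$month == 2 & panel$w == w & panel$drug == arm, ]
    p_l <- table(factor(s$l, levels = 0:1)) / nrow(s)
    h1(w) + (1 - h1(w)) * sum(vapply(0:1, function(l)
      p_l[[l + 1]] * h2(w, l), numeric(1)))
  }, numeric(1))
  mean(psi_w[m1$w + 1])
}

# hand-written claims bundle, index day 400 for everyone, day 0 = 2008-01-01.
# P01-P05 eligible (four outcome patterns and a death/switch same-month tie);
# P06-P11 each violate exactly one eligibility rule.
make_claims_fixture <- function() {
  d0 <- 400L
  fill <- function(id, day, code, class, days = 30L)
    data.frame(person_id = id, day = day, drug_code = code,
               drug_class = class, days_supplied = days,
               stringsAsFactors = FALSE)
  dxc <- function(id, day, setting, position, group)
    data.frame(person_id = id, day = day, setting = setting,
               position = position, code_group = group,
               stringsAsFactors = FALSE)
  idx_fills <- function(id, drug, months)
    fill(id, d0 + 30L * (months - 1L), drug, paste0("index_", drug))

  fills <- rbind(
    idx_fills("P01", "aripiprazole", 1:24),
    idx_fills("P02", "olanzapine", 1:24),
    idx_fills("P03", "aripiprazole", 1:24),
    idx_fills("P04", "olanzapine", 1:9),
    fill("P04", 525L, "insulin_glargine", "insulin"),
    idx_fills("P05", "aripiprazole", 1:4),
    fill("P05", 523L, "risperidone", "other_antipsychotic"),
    idx_fills("P06", "olanzapine", 1),
    fill("P06", 370L, "risperidone", "other_antipsychotic"),
    idx_fills("P07", "aripiprazole", 1),
    fill("P07", 320L, "aripiprazole", "index_aripiprazole"),
    fill("P07", 350L, "aripiprazole", "index_aripiprazole"),
    idx_fills("P08", "olanzapine", 1),
    idx_fills("P09", "aripiprazole", 1),
    idx_fills("P10", "olanzapine", 1),
    idx_fills("P11", "aripiprazole", 1),
    fill("P03", 505L, "metformin", "oral_antidiabetic"))

  smi <- do.call(rbind, lapply(sprintf("P%02d", 1:11), function(id)
    dxc(id, 300L, "outpatient", "primary", "smi_schizophrenia")))
  dx_claims <- rbind(
    smi,
    dxc("P01", 582L, "inpatient", "primary", "type2_diabetes"),
    dxc("P02", 522L, "outpatient", "primary", "type2_diabetes"),
    dxc("P02", 880L, "outpatient", "secondary", "type2_diabetes"),
    dxc("P03", 500L, "outpatient", "primary", "type2_diabetes"),
    dxc("P04", 520L, "outpatient", "primary", "type2_diabetes"),
    dxc("P09", 350L, "outpatient", "primary", "type2_diabetes"),
    dxc("P10", 340L, "outpatient", "secondary", "pcos"))

  ids <- sprintf("P%02d", 1:11)
  enrolment <- data.frame(
    person_id = ids,
    start_day = ifelse(ids == "P08", d0 - 150L, d0 - 210L),
    end_day = 1200L, stringsAsFactors = FALSE)
  ages <- c(40, 40, 40, 40, 40, 40, 40, 40, 40, 40, 66)
  demographics <- data.frame(
    person_id = ids, birth_day = d0 - ages * 365L - 100L,
    female = rep(c(1L, 0L), length.out = 11),
    white = 1L, state = "S1",
    death_day = ifelse(ids == "P05", 530L, NA_integer_),
    stringsAsFactors = FALSE)
  structure(list(fills = fills, dx_claims = dx_claims,
                 enrolment = enrolment,
                 procedures = data.frame(person_id = character(0),
                                         day = numeric(0),
                                         kind = character(0)),
                 demographics = demographics),
            class = "mono_claims")
}

# small DGP configs used across tests
small_cfg <- function(n = 300, seed = 1, ...) {
  dgp_config(n_subjects = n, seed = seed, ...)
}

null_effect_cfg <- function(n = 2000, seed = NULL) {
  cfg <- dgp_config(n_subjects = n, seed = seed)
  cfg$outcome$aripiprazole <- 0
  cfg$outcome$aripiprazole_month <- 0
  cfg
}
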