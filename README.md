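# monotmle

Comparative-safety analysis of second-generation antipsychotics on
administrative claims: longitudinal targeted minimum loss-based estimation
(TMLE) of monthly type 2 diabetes risk under **continuous aripiprazole or
olanzapine monotherapy**, for biostatisticians and pharmacoepidemiologists
working with new-user cohort designs.

## What it computes

For the static regime "start drug *a*, stay on continuous monotherapy,
remain uncensored", the package estimates the counterfactual cumulative risk
`psi_a(t)` for each 30-day month `t = 1..24`, and summarises:

* the survival curve `S_a(t) = 1 - psi_a(t)` (isotonised);
* the **restricted mean survival time** `RMST_a = sum_t S_a(t)` — the
  expected number of diabetes-free months over the 24-month horizon — and
  its olanzapine-minus-aripiprazole difference;
* per-month **risk differences** (percentage points) and **risk ratios**,
  all with 95% confidence intervals from the estimated efficient influence
  function.

The estimator is a sequential-regression (iterated conditional expectation)
longitudinal TMLE. All nuisance regressions — the drug-assignment model, the
per-month probability of remaining adherent and uncensored, and the iterated
outcome regressions — go through a from-scratch cross-validated Super
Learner over {mean, linear, logistic, CART, random forest, neural network}.

Around the estimator sit:

* a **cohort builder** implementing the new-user, active-comparator design
  on raw claims tables: relatively-new-user index episodes (no other
  antipsychotics in the 180-day pre-period; at most 30 days supplied per
  90-day window), ordered eligibility screening, the three-rule diabetes
  outcome algorithm (insulin-only evidence never qualifies), the
  seven-cause censoring hierarchy, and SMD covariate balance;
* a **synthetic claims generator** with exactly computed counterfactual
  truth (`true_counterfactual_risk()`, `true_rmst()`), used to validate the
  whole pipeline end to end;
* a **sensitivity suite**: E-values, a negative-control outcome (influenza
  vaccination), metabolic-testing rates, and the young no-prior-exposure
  subgroup;
* a **pipeline orchestrator** (`run_pipeline()`, `render_report()`) and a
  thin CLI at `inst/cli/monotmle.R`.

## Worked example

```r
library(monotmle)

cfg <- dgp_config(n_subjects = 2000, seed = 1)   # synthetic SMI cohort
sim <- generate_panel(cfg)

fit   <- tmle_survival(sim$panel, sl = sl_control("logistic"))
c_olz <- survival_curve(fit, "olanzapine")
c_ari <- survival_curve(fit, "aripiprazole")

rmst_difference(c_olz, c_ari)
contrast(c_olz, c_ari, month = 24)
sim$truth
```

Output from this exact run:

```
RMST olz 23.18 [22.91, 23.46]
RMST ari 23.07 [22.79, 23.34]
RMST diff 0.115 [-0.275, 0.504]
month 24: RD -1.30 pp [-4.43, 1.82], RR 0.822 [0.511, 1.321]
<truth_report> diabetes
  month-24 risk: aripiprazole 0.0793, olanzapine 0.0618
  RMST: aripiprazole 23.012, olanzapine 23.232, diff +0.220
```

Reading it: in this simulated world aripiprazole carries the higher
diabetes hazard, so olanzapine buys about 0.22 extra diabetes-free months
over two years (the exact truth attached to the simulation); at `n = 2000`
one replicate estimates the month-24 risk ratio at 0.82 and the RMST
difference at 0.12 months, with intervals covering the truth. Bias and
confidence coverage over repeated replicates are asserted in
`tests/testthat/test-acceptance.R`.

E-values quantify how strong an unmeasured confounder would have to be, on
the risk-ratio scale, to explain an observed association away:

```r
e_value(0.77, 0.62, 0.92)
#> RR 0.770 -> E-value 1.922 (CI limit: 1.394)
```

For the full claims-level pipeline (simulate -> build cohort -> estimate per
stratum -> sensitivity -> report):

```r
bundle <- run_pipeline(default_run_config(n_subjects = 2000, seed = 1),
                       out_dir = "run1")
writeLines(render_report(bundle))
```

## Scope notes

Code groups are symbolic labels mapped in configuration, not real ICD-9/NDC
vocabularies; dose is not modelled (duration only); dynamic regimes and
competing-risk decompositions of the censoring causes are out of scope. See
`vignettes/methods.Rmd` for the model, its assumptions, the synthetic
world's design and the package's conventions where the underlying study
design leaves gaps.
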