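# pkswarm

Pharmacokinetic analysis and swarm-initialized neural-network concentration
prediction for single-dose studies of delayed-release oral formulations,
modelled on a published study of 20 mg omeprazole enteric-coated tablets in
47 healthy Chinese adults.

Omeprazole plasma concentrations vary widely between individuals, and age
and gender shift systemic exposure enough to matter clinically. `pkswarm`
packages the complete analysis workflow such a study uses, so that each
stage is reusable and testable:

* **Synthetic cohort generator** — a one-compartment model with first-order
  absorption and an absolute lag time (the enteric coating delays absorption
  until the small intestine),

  `C(t) = D·ka / (V·(ka − ke)) · (e^{−ke·(t−tlag)} − e^{−ka·(t−tlag)})`, `ke = CL/V`,

  with per-gender truncated-normal covariates, log-normal between-subject
  variability, multiplicative covariate effects on CL/F and V/F,
  proportional + additive assay error and LLOQ censoring. Defaults are
  calibrated to the published cohort's demographics and PK summaries; the
  subject-level data themselves are not public.
* **Noncompartmental analysis** — Cmax, Tmax (earliest maximum), linear
  trapezoidal AUC0–t, terminal slope λz by best-adjusted-R² point selection,
  t½ = ln 2/λz, AUC0–∞ = AUC0–t + Clast/λz.
* **Group statistics** — pooled-variance Student's t comparisons of low- vs
  high-age (split at the 26-year median) and male vs female groups, plus the
  percent-change arithmetic used to report them.
* **PCA covariate reduction** — eigendecomposition of the correlation matrix
  of the 12 standardized inputs (10 laboratory/demographic covariates,
  gender code, sampling time); components kept until the accumulated
  contribution rate reaches 90%.
* **Feedforward network** — PCA scores → one log-sigmoid hidden layer
  (13 nodes) → linear output, inputs and targets min–max normalized to
  [−1, 1], trained by Levenberg–Marquardt with validation early stopping.
* **Metaheuristic initializers** — particle swarm (pop 50, 100 iterations,
  c1 = c2 = 1.49445, position/velocity bounds [−5, 5]/[−1, 1]), whale
  optimization and a real-coded genetic algorithm searching the flattened
  weight vector; the best vector seeds the gradient trainer.
* **Mean impact value (MIV) importance** — each raw input is perturbed
  ±10%, both tables are pushed through the full prediction function and the
  mean prediction difference is the variable's signed impact.

## Worked example

```r
library(pkswarm)

res <- run_pipeline(list(n_subjects = 47, seed = 101), outdir = "run1")

subset(res$tests, parameter == "auc_0t")
#>   parameter comparison         t df            p pct_change
#> 1    auc_0t        age 6.3200715 45 1.044159e-07   48.17175
#> 2    auc_0t     gender 0.9687178 45 3.378640e-01   12.97571

res$comparison
#>   optimizer        r2      mae     rmse budget best
#> 1       pso 0.8880291 31.00699 47.02887   5000 TRUE

head(res$miv[order(res$miv$rank), ], 4)
#>    variable       miv sign rank
#> 1       age -56.08066   -1    1
#> 2       bmi  38.20186    1    2
#> 12   time_h -36.71439   -1    3
#> 4       rbc  34.66642    1    4
```

In this cohort the age comparison finds significantly lower exposure in the
high-age group (AUC0–t reduced by ~48%, p < 1e-6) while the gender contrast
points the designed way without reaching significance at n = 47; the fitted
network explains ~89% of the held-out test variance; and the impact ranking
recovers the designed directions — age depresses predicted concentrations,
BMI raises them, and sampling time matters because concentration–time
profiles peak and decay.

`run1/` afterwards contains every artifact table: `covariates.csv`,
`concentrations.csv`, `nca_results.csv`, `group_summary.csv`,
`group_tests.csv`, `pca_table.csv`, `optimizer_trace.csv`,
`optimizer_comparison.csv`, `training_report.json`, `miv_table.csv`,
`model.json` and `run_log.json`.

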