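# radgrowth

Tumour growth and radiotherapy response modelling with ordinary and Caputo
fractional differential equations.

## What this is for

Quantitative oncology groups routinely fit simple growth laws to sparse
tumour-volume measurements taken over a course of fractionated radiotherapy
(here: 66–70 Gy in 2 Gy weekday fractions, with volumes at planning,
immediately pre-treatment, then weekly). `radgrowth` packages that whole
workflow:

* **Growth laws** — exponential (`dv/dt = a v`), logistic
  (`dv/dt = a v (1 − v/K)`, `K = 2 v₀` fixed when fitting), and
  exponential-linear
  (`dv/dt = λ₀ v (1 + (λ₀ v/λ₁)^ψ)^{−1/ψ}`, `ψ = 20`).
* **A continuous radiation death rate** — each 2 Gy fraction's
  linear-quadratic kill `v (1 − e^{−αd−βd²})` (with `α/β = 10` Gy) is
  spread over a 15-minute treatment window switched by smoothed (tanh)
  Heaviside steps:

  `dv/dt = growth(v) − v (1 − SF) Σᵢ [Ĥ(t−τᵢ) − Ĥ(t−τᵢ−tw)] / tw`.

  This keeps the right-hand side continuous — the property that makes the
  fractional models well-posed and gradient-based fitting fast — while each
  window still removes exactly one LQ kill.
* **Caputo fractional variants** (`D^μ v = …`, `0 < μ ≤ 1`) solved with the
  Adams–Bashforth–Moulton predictor–corrector (compiled; O(N) at `μ = 1`),
  validated against a series-summed Mittag–Leffler oracle, plus the
  classical impulsive (stop-and-restart, `v → v·SF`) comparator on an
  adaptive RK45 with bounded step.
* **Fitting** — bounded multistart quasi-Newton SSR minimization
  reproducing the published parameterization procedure (bounds `(0.001, 1)`
  for rates and `μ`, `v₀` pinned to the first measurement).
* **Model selection** — AICc, BIC, Δᵢ, Akaike weights, tie-averaged
  rankings, cohort tallies, and Lilliefors (seeded Monte-Carlo null) +
  Shapiro–Wilk residual-normality checks.
* **Sensitivity analysis** — dynamic relative sensitivity coefficients
  `S(t) = Δv/v · p/Δp` under one-sided 1% perturbations.
* **A synthetic cohort generator** that emulates the (undeposited)
  19-patient clinical dataset's structure so every step above is testable
  offline.

## Worked example

```r
library(radgrowth)

cfg <- cohort_config(n_patients = 1, sigma = 0.05, seed = 7)
pat <- generate_patient(cfg, 7)     # 66-70 Gy weekday course + 9 measurements
print(round(as.data.frame(pat$series), 2))
#>   day volume_cm3
#> 1   0      10.63
#> 2   7      14.86
#> ...
#> 9  53      15.79

fit_exp <- fit_model(pat$series, "exponential", proto = pat$protocol,
                     config = fit_config(n_starts = 8, seed = 1))
fit_exp
#> <rg_fit> exponential | SSR = 3.8647 (n = 9, k = 2)
#>   fitted: a = 0.035959, alpha = 0.019493
```

The fitted growth rate and radiosensitivity sit close to this virtual
patient's ground truth (`a = 0.040`, `α = 0.0208`); the SSR of 3.86 cm⁶
over 9 points is the 5%-noise floor. Comparing against the logistic law:

```r
fit_log <- fit_model(pat$series, "logistic", proto = pat$protocol,
                     config = fit_config(n_starts = 8, seed = 1))
comparison_table(list(exponential = fit_exp, logistic = fit_log), patient = 1)
#>   k    ssr    aicc delta_aicc weight rank_aicc
#> 1 2 3.8647 -1.6081     0.0000 0.8607         1
#> 2 2 5.7925  2.0341     3.6421 0.1393         2
```

AICc puts 86% of the evidence weight on the exponential model for this
patient. Finally, the dynamic sensitivity of the prediction to `α`:

```r
s <- relative_sensitivity(growth_parameters("exponential", a = fit_exp$parameters$a),
                          radiation_parameters(fit_exp$parameters$alpha),
                          pat$protocol, pat$series$volumes[1], "alpha", t_end = 50)
tail(s$S, 1)
#> [1] -1.374
```

`S(50) ≈ −1.37`: a 1% increase in radiosensitivity lowers the predicted
end-of-course volume by about 1.37% — negative, and growing in magnitude
with every fraction delivered, as it must.

A command-line interface covering the same operations ships in
`inst/cli/radgrowth` (`simulate`, `fit`, `compare`, `sensitivity`,
`cohort`, `benchmark`).

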