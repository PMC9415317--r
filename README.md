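# bwestim

Body-weight estimation for sheep (and similar livestock) from seven
depth-sensor biometric measurements, using an adjustable-degree
multivariate polynomial fitted by metaheuristic search.

Weighing animals on a scale is slow and stressful; their weight can instead
be estimated from body measurements readable off a side-view depth image:
height at withers (HWK), rump height (RHK), body length (BLK), diagonal
body length (BDLK), total body length (BTLK), girth semi-circumference
(GSCK) and abdomen semi-circumference (ASCK), all in cm. `bwestim`
implements:

* **The model.** An adjustable-degree polynomial
  `BW^ = Σ_{i=1..7} a_i (x_i / s_i)^{e_i}` with coefficients
  `a_i ∈ [0, 1]` and integer exponents `e_i ∈ {0, …, 5}` both free (14
  parameters), over per-cohort normalized variables; the normalization
  scales `s_i` travel with the fitted model.
* **Two matched-budget optimizers.** A genetic algorithm with elitism
  (rank selection under 85% biological pressure, single-point crossover,
  30% per-individual mutation, 10% elitism) and cuckoo search with Lévy
  flights (Pa = 0.25, Mantegna steps, β = 1.5), both minimizing the
  normalized RMSE under a shared fitness-evaluation budget (default
  40,000) that each consumes exactly — so comparisons between them are
  fair by construction.
* **The depth-image measurement chain.** Z-threshold segmentation
  (1.2–1.8 m), pinhole back-projection, flattening to a 1 cm/pixel planar
  histogram and Euclidean landmark measurement, validated end-to-end on
  synthetic ellipsoid phantoms rendered by an exact ray-traced forward
  model.
* **A synthetic cohort generator.** Correlated allometric biometrics with
  a known ground-truth weight law, multiplicative sensor noise calibrated
  to ~0.90 true-vs-sensor Pearson correlation, and rare gross outliers —
  so every stage is testable without any data download.
* **Classical baselines.** Schaeffer's and Agarwal's girth-and-length
  formulas and logistic / Gompertz / von Bertalanffy growth curves, in
  their native units.

## Worked example

```r
library(bwestim)

co <- generate_cohort(cohort_config(n = 56, seed = 2024))
co <- inject_outliers(co, seed = 2024)
print(co)
#> synthetic cohort: 56 animals, BW 30.36 +/- 7.98 kg (3 outliers)

cmp <- run_comparison(co, budget = 40000, seed = 1)
print(cmp)
#> matched-budget comparison (budget 40000, seed 1)
#>  algorithm rmse_raw rmse_pct   r2_pct    mbe_pct mape_pct  n
#>         ga 1.823462 6.006388 94.68241 0.02291699 5.220469 56
#>        csa 1.758117 5.791145 95.05670 0.06850899 4.970037 56
#> fitness evaluations: GA 40000, CSA 40000

print(cmp$ga$best_model)
#> Adjustable-degree polynomial weight model
#>   +0.06419 * (HWK/74.69)^4
#>   +0.08314 * (RHK/72.52)^3
#>   +0.05231 * (BLK/72.83)^3
#>   +0.2251 * (BDLK/79.64)^2
#>   +0.1866 * (BTLK/112.8)^5
#>   +0.2245 * (GSCK/47.4)^3
#>   +0.2354 * (ASCK/55.16)^2
#>   weight scale: 49.89 kg
```

The cohort is a 56-animal synthetic population (weights 30.36 ± 7.98 kg)
whose sensor channel carries calibrated noise plus three gross outliers.
Both optimizers, given exactly 40,000 fitness evaluations each, fit the
14-parameter polynomial to the sensor channel: the genetic algorithm
reaches an RMSE of 6.0% of mean body weight (R² 94.7%), cuckoo search
5.8% (R² 95.1%) — two different local optima of similar quality, which is
the point of running both. `predict(cmp$ga$best_model, records)` returns
weights in kg; `write_model_json()` makes a fitted model portable.

For the measurement side:

```r
res <- measure_phantom(phantom_spec(semi_axes = c(50, 30, 18), distance = 1.5))
max(res$rel_error_pct)
#> [1] 2.5
```

renders a 100 × 60 cm ellipsoid phantom at 1.5 m, runs segmentation,
flattening and landmark measurement, and reports at most 2.5% relative
error over the five landmark pairs.

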