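# bloodt1 — blood-pool correction of native myocardial T1

Native myocardial T1 from MOLLI cardiovascular MR is a quantitative
biomarker for diffuse myocardial disease, but every septal voxel contains
a few percent of intramyocardial blood whose T1 is long, variable between
subjects (hematocrit, sex, oxygenation), and therefore a source of
between-subject noise in the myocardial measurement. `bloodt1` implements
the standard remedy as a reusable pipeline for clinical physicists and
imaging statisticians: measure the blood pool on the same maps, convert to
relaxation rates, and regress the blood-explained component out.

The core model: with blood predictors $X_j$ (mean LV+RV blood
$R_1 = 1/T_1$ and $R_1^* = 1/T_1^*$ by default), OLS in a derivation
cohort gives constants $c_j$, and any subject is corrected as

$$T_{1,\mathrm{corr}} = T_{1,\mathrm{uncorr}} + \sum_j c_j (\bar X_j - X_j),$$

with $\bar X_j$ frozen at the derivation-cohort means so the model is
portable. In-sample the SD shrinks by exactly $\sqrt{1-R^2}$; applied to
an independent cohort, the achieved SD reduction is the measure of model
validity. The package quantifies the consequences: variance-ratio F-tests
on the SD change, sex-gap analysis before/after correction,
extreme-quartile comparisons (hematocrit, wall thickness), range
reduction, and the sample-size implication of the precision gain.

Because no patient data can ship with the package, two synthetic layers
make the whole workflow runnable and testable:

* a **calibrated cohort generator** (`simulate_cohort()` with the
  `patient_derivation`, `patient_validation` and `volunteer` presets)
  reproducing the joint structure the analysis assumes — sex-stratified
  hematocrit, hematocrit-driven blood R1, a myocardium/blood correlation
  near −0.45 and a two-predictor R² near 0.26;
* a **MOLLI digital phantom** (`build_phantom()`, `acquire_maps()`,
  `measure_rois()`, `molli_demo()`) that synthesizes 5(3)3
  inversion-recovery samples per pixel, fits the three-parameter model
  $S(t) = A - B e^{-t/T_1^*}$, applies the Look-Locker correction
  $T_1 = T_1^*(B/A - 1)$, and extracts the septal and blood-pool ROI
  means that feed the statistical pipeline.

See the methods vignette (`vignettes/blood-correction-methods.Rmd`) for
the generative model, calibration rationale, and statistical conventions.

## Worked example

```r
library(bloodt1)
report <- run_full_study(run_config(seed = 42, n = 200,
                                    volunteer = "volunteer"))
print(report)
```

```
== bloodt1 run report ==
package 0.1.0, seed 42, config hash 7083537e4b6966842d80cf14243f3993
conventions: pooled t-test, independent variance test, linear-interpolation (type 7) percentiles

model: mean_blood_r1 + mean_blood_r1star on n = 200, R^2 = 0.297

-- derivation cohort (n = 200, 111 male) --
  myocardial T1: 1030 +/- 41.7 ms uncorrected, 1030 +/- 35.0 ms corrected
  SD reduction 16.2% (independent (variance-ratio F), p = 0.013)
  sex gap (F - M): 15.9 ms (p = 0.0071) -> -3.0 ms (p = 0.54) after correction
  hematocrit quartile cuts: <37.2% vs >42.7%, uncorrected p = <0.001, corrected p = 0.41
  sample size for a 50 ms difference: 22 -> 16 total
  range reduction 8.8%

-- validation cohort (n = 200, 92 male) --
  myocardial T1: 1042 +/- 46.0 ms uncorrected, 1040 +/- 38.1 ms corrected
  SD reduction 17.2% (independent (variance-ratio F), p = 0.0079)
  sex gap (F - M): 25.3 ms (p = <0.001) -> 6.9 ms (p = 0.20) after correction
  hematocrit quartile cuts: <36.5% vs >42.2%, uncorrected p = <0.001, corrected p = 0.88
  sample size for a 50 ms difference: 28 -> 20 total
  range reduction 22.5%

-- volunteer cohort (n = 77, 36 male) --
  myocardial T1: 1036 +/- 37.1 ms uncorrected, 1035 +/- 36.2 ms corrected
  SD reduction 2.4% (independent (variance-ratio F), p = 0.84)
  sex gap (F - M): 14.7 ms (p = 0.083) -> -5.4 ms (p = 0.51) after correction
  hematocrit quartile cuts: <37.5% vs >41.5%, uncorrected p = 0.14, corrected p = 0.13
  sample size for a 50 ms difference: 18 -> 18 total
  range reduction -0.1%
```

Reading the report: the model is fitted on the derivation cohort only
(here R² = 0.297, so the in-sample SD shrinks by
$1-\sqrt{1-0.297} \approx 16\%$) and then applied *frozen* to the other
cohorts. In the validation cohort the SD reduction transfers
(46.0 → 38.1 ms, F-test p = 0.0079), the sex gap shrinks from 25.3 ms to
a non-significant 6.9 ms, the myocardial T1 difference between the
extreme hematocrit quartiles disappears after correction, and detecting a
50 ms T1 difference needs 20 instead of 28 subjects. In the homogeneous
volunteer cohort the same model changes the SD by an insignificant 2.4 %
(p = 0.84) — correction only helps where blood variability exists.
Individual cohorts at n = 200 fluctuate; the calibration midpoints
(r ≈ −0.45, R² ≈ 0.26) are recovered as averages across seeds, which is
what `scripts/acceptance.R` computes.

A command-line front end over the same functions is installed at
`system.file("cli", "bloodt1.R", package = "bloodt1")` with subcommands
`simulate`, `molli-demo`, `derive`, `apply`, `full-study` and `power`.

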