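# shellcolor

Colour analysis of blue-green chicken eggshells: from raw colorimeter
readings to a one-line grading index.

Blue-green eggshells (pigmented by biliverdin with variable
protoporphyrin IX) span light, blue, green and olive subtypes.  Visual
grading by a trained panel is the ground truth but is slow and
subjective; a Minolta-style colorimeter gives objective CIELab readings
(L\* lightness, a\* red-green, b\* yellow-blue).  `shellcolor` implements
the full workflow that connects the two for a panel of four observers
scoring each egg into ordinal classes (1 Light, 2 Blue, 3 Green,
4 Olive; panel mean `AveObs`):

1. **Batch correction** — parametric empirical-Bayes (ComBat-style)
   location/scale correction of L\*, a\*, b\* across collection batches,
   with `AveObs` preserved as a covariate; corrected value of egg *j* in
   batch *i* is `(x_ij - alpha_i) / gamma_i` around the covariate-adjusted
   grand model.  Diagnostics: CV of batch means before/after and the
   reduction rate.
2. **Classification** — first-principles multi-class LDA with extractable
   discriminant functions (scalings sphere the pooled within-class
   covariance; proportion of trace = eigenvalue shares), plus random
   forest, radial SVM and a 10-unit single-layer neural network behind one
   surface, evaluated with confusion-matrix metrics (accuracy, macro
   precision/recall/F1, Cohen's kappa), Gaussian noise sensitivity and
   throughput.
3. **Index construction** — existing indices `C* = sqrt(a*^2 + b*^2)` and
   `SCI = L* - a* - b*`, the simplified families `L* - k b*` and
   `L* - k C*` with a 0.1-step grid scan for the optimal k against
   `AveObs`, Fisher-Z comparison of correlation magnitudes
   (`z = (atanh|r2| - atanh|r1|) / sqrt(2/(n-3))`), and threshold grading
   on `v = L* - 4 C*` with a\* auxiliary (LIGHT `v>40, a*>-5`; BLUE
   `v>40, a*<-6`; GREEN `v<30, a*<-6`; OLIVE `v<30, a*>-5`; boundary band
   INDETERMINATE).
4. **Synthetic data** — a calibrated generator (7 batches, 2274 eggs,
   class-conditional trivariate normals, batch distortions, a
   four-observer adjacent-class confusion model yielding about 38 %
   unanimous panels) so the whole pipeline is testable without access to
   a scored egg table.

## Worked example

```r
library(shellcolor)

ds <- generate_dataset(default_config())   # synthetic study, 2274 eggs
corrected <- apply_combat(fit_combat(ds), ds)

rbind(before = batch_cv(ds), after = batch_cv(corrected))
#>               L         a        b
#> before 1.804052 5.0995542 8.573761
#> after  0.175580 0.3904341 1.358914

summarize_colors(corrected)
#> <color_summary> n = 2274
#>           L      a      b
#> mean 81.751 -6.727  9.871
#> sd    4.246  1.630  3.990
#> cv%   5.194 24.231 40.428
#> correlations:
#>        L      a      b
#> L  1.000 -0.084 -0.723
#> a -0.084  1.000  0.441
#> b -0.723  0.441  1.000
#> correlation with AveObs:
#>      L      a      b
#> -0.712  0.231  0.771
```

Batch correction removes most batch-to-batch variability (CVs drop about
an order of magnitude) while leaving the biological colour-score signal
intact: b\* is the strongest single predictor of the panel score (r about
0.77), L\* a strong negative one, a\* weak.

```r
k_scan(corrected, "L_MINUS_KB")
#> <scan_result> L_MINUS_KB: best k = 1.8 (r = -0.803) over k in [0.0, 10.0]
k_scan(corrected, "L_MINUS_KC")
#> <scan_result> L_MINUS_KC: best k = 2.7 (r = -0.807) over k in [0.0, 10.0]

fisher_compare(-0.782, -0.810, n = 2274)
#> <correlation_comparison> |r| 0.782 vs 0.810 (n = 2274): z = 2.579, p = 0.009912
```

The simplified one-coefficient indices correlate with the panel score
more strongly than SCI; the Fisher comparison of |r| = 0.810 vs 0.782 at
n = 2274 is significant at p < 0.05.  (The `L - kC*` scan curve is nearly
flat for k above 3, so the minimum's depth is sharp while its location is
loose — use the correlation, not the third decimal of k.)

```r
cons <- scenario_subset(corrected, "consistent")   # unanimous panels
sp <- split_dataset(cons, fraction = 0.7, seed = 1)
x <- as.matrix(as.data.frame(sp$train)[, c("L", "a", "b")])
lda_fit <- fit_lda(x, factor(aveobs(sp$train)))
lda_fit
#> <egg_lda> 4 classes, 3 features
#> discriminant coefficients:
#>      LD1   LD2    LD3
#> L -0.117 0.212 -0.344
#> a  0.114 0.730  0.570
#> b  0.370 0.039 -0.410
#> proportion of trace: 0.7932 0.2018 0.0050

xt <- as.matrix(as.data.frame(sp$test)[, c("L", "a", "b")])
metrics(confusion(factor(aveobs(sp$test)), predict(lda_fit, xt)))
#> <metrics_report> n = 261
#> accuracy 0.900 | macro P 0.905 R 0.860 F1 0.880 | kappa 0.839 (Pe 0.382)

table(grade_egg(corrected$L, corrected$a, corrected$b))
#>         LIGHT          BLUE         GREEN         OLIVE INDETERMINATE
#>           112           632           628           207           695
```

The leading discriminant is dominated by b\* (positive) and L\*
(negative) and carries about 79 % of the between-class variance — the
structure that motivates the simplified `L* - k b*` / `L* - k C*`
families in the first place.  On unanimous panels the three colour
channels alone classify about 90 % of eggs correctly; the grading rule
assigns every egg a grade, with the deliberate boundary band reported as
INDETERMINATE rather than silently forced into a class.

`run_full_analysis(run_config(...))` chains all of the above (three data
scenarios x four algorithms, scans, comparisons, grading) from one seed
and writes eight CSV/JSON report files.

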