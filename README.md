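# anespulse

Detecting anesthesia from the shape of the finger-pulse waveform.

Anesthetic agents act on vascular tone, so they reshape the
photoplethysmogram (PPG) — the optical pulse waveform that every bedside
oximeter already records. `anespulse` implements a complete temporal
pulse-marker pipeline for the binary task *anesthesia vs non-anesthesia*:

1. **Segment** continuous PPG recordings into 5-s windows and screen them
   automatically for flatlines, sensor saturation, broadband noise, and
   undetectable beats.
2. **Pre-process** each window: Savitzky–Golay smoothing (order 4, 21-sample
   frame), respiratory baseline-wander removal by an onset-anchored cubic
   spline, beat delineation from slope sign changes (with prominence and
   refractory rules that reject dicrotic maxima), and **2D normalization** of
   every beat — onset value 0, peak value 1, resampled to a fixed 100
   samples — so markers are invariant to gain and sampling rate.
3. **Extract 13 temporal markers** per beat, averaged per window: the rising
   time *t*<sub>rise</sub> (onset→peak, as a fraction of the beat), the total
   pulse area ∫y dt by the trapezoid rule, and the pulse widths
   *w*<sub>f</sub> at f = 10…90 % of the normalized amplitude
   (first-rise/last-fall crossings with linear interpolation).
4. **Select markers** by point-biserial correlation with the class label,
   r = (M₁ − M₀)/s<sub>x</sub> · √(n₁n₀/n²), keeping |r| > 0.6, with Welch
   t-tests reported alongside.
5. **Classify and evaluate** with three classifiers — k-nearest neighbors
   (Minkowski-family metrics, uniform or inverse-distance voting; the
   headline method), Gaussian discriminant analysis with a
   classification-cost decision rule ŷ = argmin<sub>y</sub> Σ<sub>k</sub>
   P(k|x)C(y|k), and a soft-margin SVM trained by sequential minimal
   optimization to a 10⁻³ primal–dual feasibility gap — using
   subject-grouped data splits, tenfold subject-grouped cross-validation,
   a 30-iteration Gaussian-process (expected-improvement) hyperparameter
   search, confusion metrics (error, sensitivity, FPR, specificity,
   precision, Cohen's κ) and ROC/AUC.

Because clinical waveform databases cannot be bundled, the package ships a
**synthetic PPG cohort generator**: seeded two-class cohorts (default 32 + 32
subjects, 60 s each, one class at 100 Hz and the other at 125 Hz to emulate
recordings pooled from two monitor databases) whose classes differ in rising
time and upper pulse widths but are matched on pulse area, with respiratory
baseline wander, powerline noise, white noise, and saturation artefacts.
Every stage of the pipeline is tested against this generator and against
closed-form oracles.

## Worked example

```r
library(anespulse)

cfg <- run_config(
  seed = 42,
  cohort = default_cohort_config(seed = 42, n_subjects_per_class = 16,
                                 record_seconds = 45),
  opt_iterations = 15)
run <- run_pipeline(cfg)
print(run)
```

```
<ppg_run> 264 segments, 32 subjects
selected markers: rising_time, width_10, width_40, width_60, width_70, width_75, width_80
classifier features: rising_time, width_10, width_40, width_60, width_70, width_75, width_80
tuned KNN: k=2 metric=euclidean weighting=inverse (CV error 0.135)
  knn            accuracy=0.954 AUC=0.999 kappa=0.908
  discriminant   accuracy=0.863 AUC=0.917 kappa=0.725
  svm_linear     accuracy=0.878 AUC=0.865 kappa=0.755
```

Reading the output: feature selection kept rising time and a band of pulse
widths but rejected `total_area` (point-biserial r = 0.095 here — the
generator matches pulse area between classes, so area carries no class
signal). The tuned KNN classifies held-out *subjects* (never seen in
training) with 95 % accuracy and AUC 0.999, and beats the linear
discriminant and linear-SVM presets — the locally clustered, non-linearly
separable class structure favors the neighborhood method.

`print(run$selection)` shows the full 13-marker score table;
`run_pipeline(cfg, out_dir = "out")` additionally writes the feature table
(CSV), selection report (JSON), serialized models (JSON), evaluation report,
tuning trace, and the resolved configuration (YAML) for exact reruns.

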