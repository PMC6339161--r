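# flowpick

Predicting the momentary emotion and task engagement of warehouse order
pickers from wearable sensors.

Order picking — collecting listed items from shelves into delivery boxes,
one list per minute — is short, repetitive, physically intense work whose
quality depends on the worker's affective state. `flowpick` implements a
complete, tested pipeline for estimating that state without questionnaires:

* **emotion** on the circumplex model of affect, a 7 × 7 grid of a
  pleasant–unpleasant axis and an arousal–sleepy axis (integers −3..+3);
* **engagement** on a 5-point scale, dichotomized into concentration (CR)
  vs boredom (BR).

The pipeline is: synthesize (or load) per-session wearable streams — a
1000 Hz pulse wave with a chest IMU, eleven 50 Hz joint rotation streams,
40 Hz gaze/pupil and 100 Hz head inertials — extract a time-series feature
battery, screen features with the Brunner–Munzel rank test at α = 0.01,
train a feedforward regressor (3 hidden layers × 100 rectifier units,
dropout 0.5, optional layer-wise autoencoder pretraining), and evaluate
with the scale-normalized error

```
Error = mean |y' − y| / L,   L = 7 (emotion axes) or 5 (engagement)
```

under leave-one-subject-out (generalized model) and leave-one-session-out
(personalized model) cross-validation. A one-point miss scores 1/7 ≈ 0.14
or 1/5 = 0.2; the working accuracy claim is a mean error of 0.12 or less
from motion-detector features.

Because no dataset of this kind is public, the package ships a first-class
synthetic-study generator (`effect_config()`, `generate_dataset()`) with
known latent flow/affect states and the documented group-difference
directions planted in the streams; every stage is tested against it. See
`vignettes/flowpick-methods.Rmd` for the models, assumptions and numerical
choices.

## A worked example

```r
library(flowpick)

# a small study: 4 workers x 12 sessions, default strong-effect condition
cfg <- effect_config(n_subjects = 4, n_sessions = 12)
fm  <- simulate_feature_matrix(cfg, seed = 1, device_group = "motion")
fm
#> <feature_matrix> motion group: 48 sessions x 1714 features

# which features separate concentrated from bored sessions?
sel <- select_features(fm, target = "engagement")
head(sel[order(sel$p_value), c("feature", "p_value", "mean_neg", "mean_pos")], 3)
#>               feature  p_value mean_neg mean_pos
#> 393   c(v(r_y^LA,0.3)) 8.84e-07 280.9333 2.16e+02
#> 1037       f(r_z^BT,5) 2.96e-06   0.0239 9.85e-03
#> 338  c(v(r_x^LA,0.25)) 3.21e-06 296.2000 2.30e+02

# generalized model: hold each worker out in turn
cv <- loso_cv(fm, "engagement", network_spec(seed = 2), seed = 3)
cv
#> <cv_result> loso / engagement / motion: mean normalized error 0.1750 over 4 folds
```

The screening table reads: concentrated sessions show fewer adopted
left-arm rotation extrema (`c(v(r_y^LA, 0.3))`: 281 bored vs 216
concentrated) and less low-frequency buttocks-rotation power — engaged
workers move less wastefully. The mean normalized error of 0.175 means the
held-out engagement prediction is off by about 0.88 points on the 5-point
scale at this toy size (48 sessions); at the full study size of 544
sessions the same pipeline reaches 0.11 (see below).

`run_all(run_config(...))` executes the whole study — simulate, extract,
screen, cross-validate — for every device group × target × design and
returns an 18-cell summary table; with `out_dir` set it writes features,
selection tables, per-fold errors and run metadata (all stamped with the
configuration hash) as CSV/JSON.

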