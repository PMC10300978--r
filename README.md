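# wristflex

Detecting the occurrence of finger and wrist flexion–extension movements
from a single wrist-worn inertial measurement unit (IMU).

## The problem

Daily counts of hand movements matter clinically — dosing hand
rehabilitation after stroke, monitoring overuse injuries such as carpal
tunnel syndrome, tracking recovery after hand surgery — but most wearable
solutions instrument the hand itself with a magnetic or inertial ring.
`wristflex` implements the ringless alternative: active finger/wrist
movements propagate brief vibration transients through the forearm that a
watch-like 6-axis IMU (3-axis accelerometer in G, 3-axis gyroscope in
deg/s, nominal 52.6 Hz) can pick up at the wrist.

The pipeline:

1. **Features** — a Madgwick orientation filter yields the gravity
   direction g in the sensor frame; the nine channels are linear
   acceleration a − g, angular velocity ω, and g.
2. **Windows** — 150 samples (≈ 2.85 s) with stride 50; a window is
   positive iff any per-sample label falls in its last 50 samples (the
   ≈ 0.95 s decision slot), the first 100 samples being context.
3. **Spectrograms** — per channel, a Hann STFT with window 20 and hop 1:
   a 131 × 11 × 9 tensor per window.
4. **Normalization** — per-channel Box–Cox transform
   y = ((x + ε)^λ − 1)/λ with λ chosen by maximizing the Box–Cox
   log-likelihood, then per-(channel, bin) standardization; fitted on
   training data only.
5. **Classifier** — a compact 7-layer CNN (3×3 convolutions, batch norm,
   ReLU, dropout, global average pooling, sigmoid head) trained with
   binary cross-entropy and Adam; kNN / RBF-SVM / MLP baselines operate
   on the flattened spectrograms.
6. **Evaluation** — subject-grouped cross-validation (leave one
   impairment category out, or repeated random 80/20 subject splits),
   precision/recall/F1/accuracy, ROC/AUC, daily-count Pearson
   correlation, and speed-stratified class-balanced confusion analyses.

Because reference labels in the wild come from an imperfect labeler
(≈ 85% accurate), observed agreement only brackets the true accuracy.
By total probability,

    P(correct) = P(agree | labeler right) · P(labeler right) + q · (1 − P(labeler right)),

with q = P(correct | labeler wrong) unknown in [0, 1]; `wristflex`
reports the resulting bounds (width exactly 1 − P(labeler right)).

Real wrist-IMU study recordings are private, so the package includes a
seeded synthetic-session generator (90 s movement bouts at 0.5–1 events/s
separated by 15 s rests; damped-sinusoid vibration bursts for hand
movements; gravity reorientation plus low-frequency acceleration for arm
movements) and a 5-subject benchmark with ground-truth event counts.
Marker-trajectory simulation, joint-angle computation, and
peak-threshold calibration reproduce the motion-capture labeling path.

## Worked example

Train on one simulated day, test on a second day of the same subject:

```r
library(wristflex)

day_cfg <- function(seed) sim_config(bout_structure = list(
  list(type = "hand_only", duration_s = 90), list(type = "rest", duration_s = 15),
  list(type = "arm_only", duration_s = 90), list(type = "rest", duration_s = 15)),
  event_rate_hz = 0.75, seed = seed)

train_ses <- simulate_session(day_cfg(42), subject_id = "S01")
test_ses  <- simulate_session(day_cfg(43), subject_id = "S01")
train_ses$recording
#> <imu_recording> subject S01, device synthetic: 11046 samples @ 52.6 Hz (210.0 s), 1072 positive-labeled samples

train_raw <- preprocess_recording(train_ses$recording)
train_raw
#> <spectrogram_set> 218 samples of 131x11x9 (raw), 1 subjects, 39.0% positive

norm  <- fit_normalization(train_raw)
train <- apply_normalization(train_raw, norm)
test  <- apply_normalization(preprocess_recording(test_ses$recording), norm)

clf  <- train_classifier(build_cnn(cnn_config(epochs = 4, seed = 1)), train)
prob <- predict_proba(clf, test)
metrics_from_counts(confusion(test$label, as.integer(prob >= 0.5)),
                    auc = roc_auc(test$label, prob)$auc)
#> <metrics_report> [all] n=218 acc=0.839 prec=0.713 rec=1.000 f1=0.833 auc=0.976
```

Four training epochs on a single 3.5-minute session already rank nearly
all held-out windows correctly (AUC 0.976); the 0.839 accuracy at the
0.5 threshold comes from false positives on vigorous arm-only motion,
the method's characteristic confound. The full 5-subject benchmark
(`make_benchmark()`, ~2,200 windows) with subject-grouped 5-fold
cross-validation (`grouped_kfold()`, 6 iterations, 8 epochs) reaches
mean accuracy 0.977 and AUC 0.996, with held-out daily counts tracking
the generated ground truth at r² = 0.97.

The label-noise bound for an in-the-wild deployment scored against a
labeler that is right 85% of the time, with 77% observed agreement:

```r
bayes_accuracy_bounds(p_match = 0.77, p_hand = 0.85)
#> <bayes_bound> true accuracy in [0.654, 0.804] (65-80%) given agreement 0.77 with a labeler of accuracy 0.85
```

A thin command-line wrapper for simulation and the end-to-end pipeline
lives at `inst/cli/wristflex.R`:

```sh
Rscript inst/cli/wristflex.R simulate --seed 1 --out session.csv
Rscript inst/cli/wristflex.R run --seed 1 --scheme kfold --out run_dir
```

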