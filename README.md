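# mrcpdecode

Decoding attempted arm and hand movements from low-frequency EEG in
persons with spinal cord injury (SCI).

Movement-related cortical potentials (MRCPs) are slow (< 3 Hz) EEG
deflections over sensorimotor cortex around a movement attempt. Even
when the spinal cord no longer relays the command, the cortical signal
remains decodable: five attempted movements — hand open, palmar grasp,
lateral grasp, pronation, supination — differ in the amplitude and
latency of the early positive (cue-processing) and later negative
(movement-related) peak of the Cz potential. `mrcpdecode` implements the
complete analysis chain for this problem, for researchers in
brain-computer interfacing and neural engineering:

* **Synthetic sessions** (`generate_offline_session()`,
  `generate_online_training_session()`, `generate_online_test_session()`)
  reproduce the cue-based offline paradigm (9 runs × 40 trials, 72
  trials/class), the go-cue training paradigm (150 movement trials + 4
  rest runs) and the 60-s self-paced test paradigm, with class-dependent
  two-peak MRCP templates, 1/f noise, 50 Hz interference, blinks and
  transient artifacts — so every stage has ground truth.
* **Preprocessing** (`preprocess_recording()` and its parts): bad-channel
  flagging, extended-Infomax ICA on robustly masked broadband data with
  EOG/spectral component screening, amplitude/joint-probability/kurtosis
  trial rejection, zero-phase and causal Butterworth filtering, common
  average reference.
* **Decoding** (`fit_slda()`, `sliding_accuracy()`, `confusion_at()`):
  multiclass LDA with an analytic Ledoit–Wolf shrinkage of the pooled
  covariance towards ν·I, softmax class probabilities, lagged-sample
  features (8 lags × 200 ms) in a window slid at 1/16-s steps, repeated
  stratified trial-based 10×10 cross-validation.
* **Group statistics** (`difference_topoplots()`,
  `permutation_max_stat()`, `peak_features()`, `friedman_by_class()`,
  `t_ci()`, `significance_threshold()`): mean absolute pairwise class
  difference maps in 250-ms segments with a max-statistic permutation
  mask, Cz peak analysis, and adjusted-Wald better-than-chance
  thresholds.
* **Online detection** (`select_t_train()`,
  `build_five_class_training()`, `run_detector()`, `select_tp_offset()`,
  `evaluate_online()`): a causal 5-class classifier (two movements, rest,
  pre, post) gating a detection state machine — pre-probability > 0.7 for
  ≥ 150 ms, movement probability > 0.9, post-probability > 0.7 for
  ≥ 150 ms in three ordered windows, 2-s refractory — evaluated by TPR,
  FP/min and 2-class accuracy inside a 2-s true-positive window whose
  offset is chosen by a detection-ratio search.

`run_offline_analysis()` and `run_online_experiment()` orchestrate the
two experiments end to end from a configuration and a seed.

## A worked example

```r
library(mrcpdecode)

cfg <- offline_run_config(
  n_participants = 2, montage = "reduced",
  folds = 10, repeats = 2, times = c(0.75, 1, 1.25),
  n_perm = 50, seed = 7)
rep <- run_offline_analysis(cfg)

round(rep$peak_accuracy, 1)           # 52.2  (% correct, 5 classes)
round(rep$significance_threshold, 1)  # 25.5  (% adjusted-Wald bound)
round(rep$confusion["pronation", ], 1)
#     hand_open lateral_grasp palmar_grasp pronation supination
#          10.8           8.0          8.7      62.8        9.7
sum(rep$topoplots$mask)               # 76 of 264 grid cells significant
```

Two simulated participants (72 trials per class each, 19-channel reduced
montage) yield a cross-validated 5-class peak accuracy of about 52% near
1 s after the class cue — far above the 25.5% threshold that accounts for
the trial count and the number of tested time points (chance is 20%).
The confusion row shows where pronation trials go when misclassified,
and the permutation mask flags the central-channel segments carrying the
class differences. With `amp_scale = 0` (no MRCP) the same pipeline
stays inside the chance band.

For the online proof-of-concept:

```r
rep2 <- run_online_experiment(online_run_config(seed = 1))
rep2$t_train              # time of peak 3-class training accuracy (s)
rep2$detection_delay      # t_train + 0.575 s
rep2$evaluation           # P, TP, TPR %, FP/min, accuracy %
```

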