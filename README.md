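# eegensemble

Deep ensembles with uncertainty-aware epoch rejection for subject-level
binary EEG classification.

The package is aimed at EEG / machine-learning researchers who want a fully
reproducible, CPU-scale implementation of the following experiment: predict
a binary subject label (the reference task is sex classification, class 1 =
female) directly from multi-channel resting-state EEG with compact
convolutional networks, combine the networks into ensembles, and use the
ensemble's disagreement to *abstain* from the least trustworthy 2-second
epochs before voting.

## The method

A recording is cleaned (channels with amplitude SD > 75 µV or no variation
are excluded and interpolated; recordings losing > 30% of channels are
rejected; 1–45 Hz zero-phase band-pass), cut into non-overlapping 2 s
epochs after discarding the first 30 s, and classified epoch by epoch. For
a subject with epochs *e₁…eₙ* and an ensemble of *N* members producing
class-1 probabilities *p₍ᵢⱼ₎* (member *i*, epoch *j*):

* **per-subject vote** — epoch *j* is class 1 if *pⱼ ≥ 0.5*; the subject
  takes the majority class (ties: mean probability vs 0.5, then class 1);
* **Ensemble-Subject** — each member votes per subject, the member verdicts
  are combined by majority;
* **Ensemble-Epoch** — probabilities are averaged over members per epoch,
  *p̄ⱼ = (1/N) Σᵢ p₍ᵢⱼ₎*, then the subject majority is taken;
* **uncertainty** — the per-epoch score is the population variance
  *Var(p₍·ⱼ₎)*; for a rejection percentage *p*, the ⌊p/100·n⌋
  highest-variance epochs of each subject are removed and the vote is
  re-run. Accuracy changes are reported as the relative error decrease
  *((100−acc₀) − (100−acc₁))/(100−acc₀) × 100*.

Ensembles are built five ways: random-uniform or random-normal weight
re-initialization (5 members), depths 2/4/6/8/10 of the Inception-style
network, Monte Carlo dropout over an appended 32-unit dense + dropout(0.5)
head (50 stochastic forward passes), heterogeneous model pools, and
per-frequency-band training (delta through gamma, keeping the top 3 bands
by validation accuracy). Evaluation uses subject-stratified 5-fold
cross-validation (train 3 / validate 1 / test 1, every subject tested
exactly once) with mean ± Student-t 95% CI, plus rank-based AUC.

Everything upstream of a real dataset is covered by a synthetic-cohort
generator whose class signal is injected into chosen frequency bands, so
the whole pipeline is testable end-to-end without any data download.

## Worked example

Sixty synthetic subjects, with class 1 carrying 50% more alpha-band
amplitude; band-restricted models under 5-fold cross-validation:

```r
library(eegensemble)

spec <- cohort_spec(
  n_subjects    = 60,
  n_channels    = 8,
  sampling_rate = 100,
  duration      = 70,
  band_effects  = list(alpha = c(1, 1.5)),  # class 1 has 50% more alpha power
  seed          = 11
)
cohort <- generate_cohort(spec)
cohort[[1]]
#> <eeg_recording> S0001 | label 0 | 8 ch x 7000 samples @ 100 Hz

res <- band_cv(
  cohort, bands = c("alpha", "gamma"),
  base_model = model_spec("inception", depth = 2, n_filters = 2,
                          kernel_sizes = c(7, 15, 31)),
  training   = training_config(max_iterations = 20, early_stop_patience = 6,
                               lr_patience = 3, lr_init = 0.01,
                               batch_size = 256),
  seed = 7
)
summarize_cv(dplyr::select(res, band, fold, per_subject_accuracy, auc))
#> # A tibble: 4 × 5
#>   band  metric                 mean ci95_halfwidth n_folds
#>   <chr> <chr>                 <dbl>          <dbl>   <int>
#> 1 alpha auc                   0.896         0.0874       5
#> 2 alpha per_subject_accuracy 65            22.4          5
#> 3 gamma auc                   0.576         0.0686       5
#> 4 gamma per_subject_accuracy 55             9.25         5
```

The alpha-band model recovers the injected effect (AUC ≈ 0.90, per-subject
accuracy above chance), while the gamma band — which carries no class
signal — stays near 0.5/50%. At this deliberately small cohort size the
fold-to-fold confidence intervals are wide; the shipped verification runs
use 200 subjects.

Ensembles and uncertainty follow the same grammar: build members with
`build_weight_ensemble()` / `build_depth_ensemble()` /
`build_frequency_ensemble()` / `mcd_predict()`, predict a members × epochs
tensor with `ensemble_predict()`, then `evaluate_tensor()`,
`rejection_curve()` and `summarize_error_decrease()`. `autoplot()` methods
plot rejection curves, band reports and training histories;
`run_experiment()` orchestrates the full simulate → preprocess → folds →
train → evaluate → uncertainty loop from one `experiment_config()` (or a
YAML file via `read_experiment_config()`, also exposed as a CLI script in
`inst/cli/run_experiment.R`).

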