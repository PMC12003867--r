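# swadr — gastrointestinal slow-wave drug response and adverse drug reactions

`swadr` is an R package for asking whether drug-induced changes in
gastrointestinal pacemaker ("slow-wave") activity predict a drug's adverse
drug reactions (ADRs) — nausea, vomiting, diarrhoea and constipation. It
implements the full analysis as a reproducible pipeline:

* a **synthetic cohort generator** for 60-channel microelectrode-array
  recordings (720 s, 8×8 grid, drug administered at ~300 s) with
  tissue-specific dominant frequencies, concentration-scaled drug effects,
  channel dropout, artifacts and missing data — so the whole analysis runs
  without access to restricted recordings;
* the **preprocessing chain**: ±1500 µV amplitude masking, anti-aliased
  decimation to 10 Hz, zero-phase 2–60 cpm band-pass, Welch
  dominant-frequency (DF) estimation with channel retention at DF ≥ 11 cpm
  (intestine) / ≥ 4 cpm (stomach), stability-ranked reference
  normalization, 4-neighbour augmentation of failed channels, truncation
  into 2000 × 60 baseline (50–250 s) and post-drug (500–700 s) matrices,
  exclusion above 1.6% missing entries, and the summated **interference
  matrix** `baseline + postdrug` used as model input;
* **labelling** from a SIDER-like annotation table (side-effect ⇒ class 1,
  indication overrides to class 0, unannotated drugs held out), balanced
  chunking with disjoint majority samples, stratified 8:2 splits, and
  shuffled-label negative controls;
* **classifiers**: CNN-, FCN- and InceptionTime-style 1-D convolutional
  networks (implemented in-package with Adam and validated against
  finite-difference gradients) over interference matrices with frozen
  tissue/concentration embeddings added to the input;
* **ensembling and evaluation**: a logistic regression over five replicate
  classifiers' validation probabilities, by-drug aggregation at the ≥ 0.5
  cutoff, accuracy / class-1 precision / midrank AUROC and the composite

  ```
  score = (accuracy + precision(class 1) + AUROC) / 3
  ```

  evaluated on **time-shifted external validation** sets built by
  re-windowing the post-drug recording ±10 s (490–690 s and 510–710 s) and
  re-summing with the original baseline, plus Student's t and
  ANOVA/Tukey comparisons and a > 0.7 risk table for held-out drugs.

## A worked example

```r
library(swadr)

cfg <- default_config("ci", seed = 2024)   # 16 drugs x 12 datasets
cfg$train$label_modes <- c("correct", "shuffled")
res <- run_pipeline(cfg, adrs = "nausea")

ts <- subset(res$reports, prediction_set != "validation" &
                          !grepl("ensemble", model_id))
aggregate(auroc ~ label_mode, ts, mean)
```

On this seed the run simulates and preprocesses 192 recordings (all 192
pass the 1.6% missing-data rule), builds two balanced nausea chunks, trains
five InceptionTime-style classifiers per chunk under correct and shuffled
labels, and evaluates all 20 of them by drug on both time-shifted sets. The
printout:

```
  label_mode     auroc
1    correct 0.9047619
2   shuffled 0.6214286
```

Correct-label models rank ADR-positive above ADR-negative drugs on
time-shifted data (mean AUROC 0.90), while shuffled-label models stay
inside the permutation-null band — the planted class signal is learnable
and destroyed by label permutation. `res$risk_table` lists the six held-out
drugs with their mean class-1 probability from the two best ensembles and a
risk flag at > 0.7 (none of them crosses it on this seed);
`res$manifest` records stage-by-stage dataset counts and the configuration
hash.

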