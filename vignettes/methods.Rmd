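---
title: "Modelling adverse drug reactions from gastrointestinal slow-wave recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adverse drug reactions from gastrointestinal slow-wave recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Gastrointestinal pacemaker activity ("slow waves") is the rhythmic electrical
activity, generated by the interstitial cells of Cajal, that paces gut
motility. Drugs that perturb it are plausible candidates for
gastrointestinal adverse drug reactions (ADRs): nausea, vomiting, diarrhoea
and constipation. `swadr` implements, end to end, an analysis that asks
whether multichannel slow-wave recordings taken before and after a drug
administration carry a signal that predicts a drug's ADR profile — and
whether that signal survives two controls: training on shuffled labels
(which should destroy it) and evaluation on time-shifted re-windowings of
the post-drug recording (which should not).

Because the underlying ex-vivo recordings are not redistributable, the
package ships a synthetic cohort generator with the same geometry and
statistical structure, so every stage is testable from scratch on any
machine.

## The recording model

One experiment ("dataset") is a 60-channel voltage trace recorded on an
8 × 8 microelectrode array (the four corners are unused, the conventional
layout for this platform) for 720 s at a nominal 1 kHz, with the drug
administered at approximately 300 s (the generator jitters the time
uniformly in [295, 305] s). Each dataset carries three covariates: the drug
`d`, the tissue `t` (stomach, duodenum, ileum, colon) and the concentration
`c` (low, medium, high). Higher and lower concentrations are only run on
intestinal segments, so stomach data are about three times rarer — the
generator's design table mirrors this.

The synthetic waveform is deliberately minimal: per channel, a fundamental
sinusoid at a tissue-specific dominant frequency (stomach 5–8 cpm,
intestine 12–20 cpm, drawn per recording) plus a 0.3-weighted second
harmonic, with phase lags across the grid, channel amplitudes drawn from
50–500 µV (inside the stated ±25–1200 µV physiological range), and additive
white Gaussian noise of 5 µV (inside the stated ±10 µV noise band). This is
not a biophysical model of the pacemaker network; it is the minimal
structure that exercises every preprocessing rule (dominant-frequency
filtering, amplitude masking, stability ranking, normalization,
augmentation) and carries a controllable class signal.

The class signal: every recording receives a small drug-independent
nuisance perturbation after `t_drug` (dominant-frequency jitter of
sd 0.3 cpm, amplitude factor of sd 5%); drugs with any positive ADR flag
additionally apply a latent signature — a dominant-frequency shift drawn
around +3 cpm and an amplitude scaling around 1.4, both scaled by
concentration (0.5×, 1×, 1.5×). The signature is latent: models only ever
see the preprocessed matrices. With the shift set to 0 and the scaling to
1, class labels are independent of the data, which is how the null
calibration in the test suite is built. Degradations are injected at
configurable rates: dead channels (noise only, 5%), out-of-range artifacts
(|v| > 1500 µV, 10⁻⁵ per sample) and missing-value runs of ~0.2 s
(0.2% of samples).

What the generator does **not** emulate: slow-wave propagation dynamics,
dysrhythmias, electrode drift, baseline wander, species- or region-specific
waveform morphology, and any relationship between a real drug's
pharmacology and its signature. A passing test suite therefore shows that
the pipeline recovers the structure this generator plants at realistic
signal-to-noise ratios — not that the real biological effect exists.

## Preprocessing

The chain, per recording:

1. **Amplitude masking.** Samples strictly above +1500 µV or strictly below
   −1500 µV become missing. The bound itself is kept.
2. **Decimation to the 10 Hz working rate** by contiguous block means
   (factor 100 from 1 kHz). The boxcar pre-filter has exact DC gain and
   < 0.2% droop at 15 cpm; a decimated sample whose entire support block is
   missing stays missing, and the full missing-value support is carried
   forward separately. All slow-wave content lives below 1 Hz, far from the
   5 Hz output Nyquist.
3. **Zero-phase band-pass, 2–60 cpm**: order-2 Butterworth high-pass and
   low-pass sections applied forward–backward, i.e. a 4th-order magnitude
   response with no phase distortion. The band brackets both tissue
   dominant-frequency ranges and the 2–40 cpm stability denominator. The
   filter runs at the working rate because a 0.033–1 Hz band-pass expressed
   in transfer-function form at 1 kHz is numerically degenerate; below 1 Hz
   the two orderings are equivalent.
4. **Dominant frequency (DF)** per channel over the 0–300 s baseline:
   Welch-averaged periodograms of mean-removed, Hann-windowed 2048-sample
   segments (50% overlap), zero-padded 8× with parabolic interpolation of
   the peak, searched in 1–60 cpm, reported to 0.01 cpm. The rounding makes
   integer-frequency boundary cases deterministic at the thresholds.
5. **Channel filter**: a channel is retained when DF ≥ 11 cpm (intestinal
   segments) or DF ≥ 4 cpm (stomach). Channels with undefined DF fail.
6. **Stability** per channel: spectral power within ±1 cpm of the DF
   divided by power in the fixed 2–40 cpm band; ties rank by lower channel
   index.
7. **Reference amplitudes**: the three most stable passing channels
   contribute local peaks and troughs (minimum separation half a dominant
   period) whose means define the reference pair.
8. **Augmentation**: each failed channel is replaced by the mean of its
   passing 4-neighbours on the grid (diagonals excluded, the conservative
   reading of adjacency); a failed channel with no passing neighbour stays
   missing, which usually excludes the dataset at the cleaning step.
9. **Normalization**: `(x − 1.1·trough) / (1.1·peak − 1.1·trough)`, one
   affine map per dataset, so 110% of the average extrema map to 0 and 1.
10. **Windowing** into half-open windows at 10 Hz — baseline [50, 250) s,
    post-drug [500, 700) s, and the shifted windows [490, 690) s (forward)
    and [510, 710) s (backward) — each exactly 2000 × 60 (time × channel).
11. **Cleaning**: a matched dataset is excluded when either matrix has
    strictly more than 1.6% missing entries.
12. **Interference**: the elementwise sum baseline + post-drug is the model
    input; the shifted sums re-use the *original* baseline. Residual
    missing entries (≤ 1.6%) become 0 in normalized units only at
    model-input preparation, so the conservation identity
    interference = baseline + post-drug holds for the stored matrices.

## Labelling, chunking, controls

A SIDER-like TSV (`drug_id`, `adr`, `relation`) drives per-ADR labels: a
`side_effect` row means class 1, an `indication` row overrides to class 0
(to avoid false-positive labels), an annotated drug with neither row is
class 0, and a drug absent from the table is held out of all training and
used only for external drug prediction.

Balanced chunks contain every minority-class dataset plus an equally sized
random majority sample, disjoint across chunks of the same ADR. Two chunks
are built for nausea, vomiting and diarrhoea; constipation, whose classes
are nearly balanced by construction (prevalence 0.5), uses a single chunk
that retains all datasets (a majority at most 25% larger than the minority
is kept unsampled). Each chunk splits 8:2 into training and validation at
the dataset level, stratified by class — plain random sampling can produce
degenerate validation sets at desk scale. The negative control permutes the
*training* labels only.

## Classifiers and ensemble

Three 1-D convolutional architectures sit behind one interface: a simple
CNN (two conv/pool stages), an FCN (three conv blocks, kernels 8/5/3) and
an InceptionTime-style network (inception modules with a bottleneck,
parallel kernels, a max-pool branch, residual shortcut every third module).
No deep-learning framework exists in this R stack, so the engine —
im2col-based convolutions, global average pooling, softmax cross-entropy
and Adam — is implemented in the package from matrix primitives and
validated against finite-difference gradients in the test suite.

Tissue and concentration enter as **fixed embeddings**: one length-60
vector per code, drawn once from a seeded normal (sd 0.1) and added to the
input across the channel axis at every time step — the only addition
compatible with a 2000 × 60 input without extra assumptions — and never
updated by training. Training uses mini-batches of 30 and Adam (learning
rate 10⁻³, the toolkit convention) for 200 epochs at full scale; five
replicate classifiers are trained per chunk. A logistic regression fitted
on the five members' validation class-1 probabilities forms the ensemble,
so members that are more accurate on validation receive larger weights.

The desk-scale ("ci") profile — used by the test suite and stated here as
the package's own choice of problem size — is 16 drugs × 12 datasets
generated at 20 Hz (every analysis constant, window and the 10 Hz working
rate are unchanged; all signal content is below 1 Hz, so the decimated
representation is identical to the 1 kHz path, which is itself exercised on
a full-scale recording in the tests), a depth-3 InceptionTime with 4
filters per branch, 20 epochs, and a 4× subsampled time axis with kernels
10/5/3 — the reference 40/20/10 kernels scaled by the same factor, so the
receptive field in seconds is preserved.

## Evaluation

Per-dataset class-1 probabilities are averaged per drug (optionally within
tissue or concentration), classified at the ≥ 0.5 cutoff, and scored by
accuracy, class-1 precision and midrank AUROC, combined into
`score = (accuracy + precision + AUROC) / 3`. Precision with zero positive
predictions is reported missing and excluded from averages. External
validation evaluates every classifier on both time-shifted interference
sets, giving 2 chunks × 5 classifiers × 2 sets = 20 reports per ADR (10 for
the single-chunk ADR). Conditions are compared with two-sided Student's
t tests (paired for ensemble-vs-member comparisons) and, for tissue or
concentration groupings, one-way ANOVA with Tukey's HSD. Held-out drugs are
scored by the two highest-scoring ensembles; a mean probability strictly
above 0.7 flags risk.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed through named substreams, so
  any single object can be regenerated in isolation.
* DF estimation fails (and the channel fails the filter) for all-missing or
  zero-variance channels; a zero stability denominator yields stability 0.
* Normalization rejects a degenerate dynamic range (peak ≤ trough); a
  dataset with no passing channels is rejected and recorded as excluded.
* Aliased (perfectly collinear) ensemble members drop out of the logistic
  fit with zero weight.
* t-test comparisons with (numerically) zero variance return p = 1 for
  identical groups and a certain direction for a constant nonzero paired
  difference.
* Recording containers are RDS files with CSV/TSV sidecars; no HDF5
  binding is available in this R stack, and the container is deliberately
  format-light.

## Known limitations

The synthetic effect is a stationary frequency/amplitude change; real drug
effects are dynamic and heterogeneous. The ensemble is fitted and reported
on the same validation split, as in the original protocol — a leakage the
time-shifted sets mitigate but do not remove; a clean-holdout variant is a
one-line change (fit on one chunk's validation set, report on the other's).
Desk-scale AUROCs on the synthetic cohort are near-ceiling because the
planted effect at medium concentration is strong; they are not estimates of
real-data performance, whose reproduction is explicitly out of scope.
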