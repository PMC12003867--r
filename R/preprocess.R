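#' Default preprocessing parameters
#'
#' Every numeric default is the analysis value: +/-1500 uV amplitude mask,
#' dominant-frequency (DF) retention thresholds of 11 cpm for intestinal
#' segments and 4 cpm for stomach, a 2048-sample FFT window at the 10 Hz
#' working rate, 1.6% missing-value exclusion, baseline window 50-250 s,
#' post-drug window 500-700 s, and time-shifted windows 490-690 s (forward)
#' and 510-710 s (backward).
#'
#' @param mask_uV amplitude magnitude bound; strictly larger values are
#'   masked to NA.
#' @param df_intestine,df_stomach DF retention thresholds in cpm (channel
#'   passes when DF >= threshold).
#' @param nan_thresh maximum tolerated NaN fraction in the baseline or
#'   post-drug matrix (strictly larger excludes the dataset).
#' @param target_rate working rate in Hz after decimation; the decimation
#'   factor is `sf / target_rate` (100 for 1 kHz input).
#' @param bin_size FFT segment length at the working rate.
#' @param band band-pass edges in cpm for the zero-phase filter.
#' @param windows list of `[start, end)` windows in seconds.
#' @return list of parameters.
#' @export
preprocess_params <- function(mask_uV = 1500,
                              df_intestine = 11, df_stomach = 4,
                              nan_thresh = 0.016,
                              target_rate = 10,
                              bin_size = 2048,
                              band = c(2, 60),
                              windows = list(baseline = c(50, 250),
                                             postdrug = c(500, 700),
                                             forward = c(490, 690),
                                             backward = c(510, 710))) {
  list(mask_uV = mask_uV, df_intestine = df_intestine,
       df_stomach = df_stomach, nan_thresh = nan_thresh,
       target_rate = target_rate, bin_size = bin_size, band = band,
       windows = windows)
}

#' Mask out-of-range samples
#'
#' Samples strictly exceeding `+bound` uV or strictly below `-bound` uV are
#' set to NA; values at exactly the bound are kept.
#'
#' @param x numeric vector or matrix in uV.
#' @param bound magnitude bound in uV.
#' @return `x` with out-of-range samples replaced by NA.
#' @export
mask_amplitude <- function(x, bound = 1500) {
  x[!is.na(x) & (x > bound | x < -bound)] <- NA_real_
  x
}

# Linear interpolation over NA runs (constant extrapolation at edges);
# all-NA input is returned unchanged.
interp_na <- function(x) {
  if (!anyNA(x)) return(x)
  if (all(is.na(x))) return(x)
  as.numeric(zoo::na.approx(x, na.rm = FALSE, rule = 2))
}

#' Anti-aliased decimation by block averaging
#'
#' Decimates a channel by an integer factor using contiguous block means: a
#' boxcar anti-alias pre-filter with exact DC gain and negligible droop at
#' slow-wave frequencies (< 0.2% at 15 cpm for factor 100 from 1 kHz); the
#' subsequent zero-phase band-pass at the working rate removes out-of-band
#' residue. An output sample is NA whenever its whole support block is NA;
#' partial blocks average the available samples, and
#' [decimate_nan_mask()] carries the full NA support forward.
#'
#' @param x numeric vector.
#' @param factor integer decimation factor; trailing remainder samples are
#'   truncated.
#' @return decimated vector of length `floor(length(x) / factor)`.
#' @export
downsample <- function(x, factor = 100) {
  stopifnot(factor >= 1, factor == round(factor))
  n_out <- floor(length(x) / factor)
  x <- x[seq_len(n_out * factor)]
  if (factor == 1) return(x)
  y <- .colMeans(matrix(x, nrow = factor), factor, n_out, na.rm = TRUE)
  y[is.nan(y)] <- NA_real_
  y
}

# Block-mean decimation of a channels x samples matrix in one pass.
downsample_mat <- function(sig, factor) {
  n_ch <- nrow(sig)
  n_out <- floor(ncol(sig) / factor)
  if (factor == 1) return(sig[, seq_len(n_out), drop = FALSE])
  m <- matrix(t(sig[, seq_len(n_out * factor), drop = FALSE]), nrow = factor)
  y <- .colMeans(m, factor, n_out * n_ch, na.rm = TRUE)
  y[is.nan(y)] <- NA_real_
  t(matrix(y, nrow = n_out, ncol = n_ch))
}

#' Propagate missing-value support through decimation
#'
#' An output sample is NA when any raw sample in its length-`factor` block
#' is NA.
#'
#' @param na_mask logical vector of raw-rate NA positions.
#' @param factor decimation factor.
#' @return logical vector at the decimated rate.
#' @export
decimate_nan_mask <- function(na_mask, factor = 100) {
  n_out <- floor(length(na_mask) / factor)
  m <- matrix(na_mask[seq_len(n_out * factor)], nrow = factor)
  colSums(m) > 0
}

#' Zero-phase band-pass filter
#'
#' Order-2 Butterworth high-pass and low-pass sections applied
#' forward-backward (`filtfilt`), giving a 4th-order zero-phase magnitude
#' response with no phase distortion. NA positions are interpolated for
#' filtering and restored afterwards; an all-NA channel passes through
#' unmodified.
#'
#' @param x numeric vector at `sf` Hz.
#' @param sf sampling frequency, Hz.
#' @param band pass band in cpm (default 2-60 cpm, bracketing both tissue
#'   DF bands and the 2-40 cpm stability denominator).
#' @return filtered vector, NA positions preserved.
#' @export
bandlimit_filter <- function(x, sf, band = c(2, 60)) {
  if (all(is.na(x))) return(x)
  na_pos <- is.na(x)
  y <- bandlimit_filter_mat(cbind(interp_na(x)), sf, band)[, 1]
  y[na_pos] <- NA_real_
  y
}

# filtfilt for a samples x channels matrix: reflective edge padding, then
# forward and reverse passes; one C-level filter call covers all channels.
filtfilt_mat <- function(b, a, X) {
  n <- nrow(X)
  npad <- min(n - 1, 3 * max(length(a), length(b)) * 2)
  pre <- 2 * X[rep(1, npad), , drop = FALSE] - X[npad + 1 - seq_len(npad), ,
                                                 drop = FALSE]
  post <- 2 * X[rep(n, npad), , drop = FALSE] - X[n - seq_len(npad), ,
                                                  drop = FALSE]
  Xp <- rbind(pre, X, post)
  one_pass <- function(M) {
    y <- stats::filter(M, b / a[1], method = "convolution", sides = 1)
    y[is.na(y)] <- 0
    if (length(a) > 1) {
      y <- stats::filter(y, -a[-1] / a[1], method = "recursive")
    }
    matrix(as.numeric(y), nrow = nrow(M))
  }
  y <- one_pass(Xp)
  y <- one_pass(y[rev(seq_len(nrow(y))), , drop = FALSE])
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y[npad + seq_len(n), , drop = FALSE]
}

# Band-pass a samples x channels matrix (finite entries) at sf Hz.
bandlimit_filter_mat <- function(X, sf, band = c(2, 60)) {
  nyq <- sf / 2
  lo <- (band[1] / 60) / nyq
  hi <- (band[2] / 60) / nyq
  hp <- signal::butter(2, lo, type = "high")
  Y <- filtfilt_mat(hp$b, hp$a, X)
  if (hi < 1) {
    lp <- signal::butter(2, hi, type = "low")
    Y <- filtfilt_mat(lp$b, lp$a, Y)
  }
  Y
}

#' Dominant frequency by Welch periodogram
#'
#' Computes an averaged periodogram from mean-removed, Hann-windowed
#' segments of `bin_size` samples (50% overlap), zero-padded 8x, and
#' locates the power maximum inside the physiological search band with
#' parabolic interpolation of the peak. The DF is reported in cpm, rounded
#' to 0.01 cpm.
#'
#' @param x channel signal (working rate); NA interpolated internally.
#' @param sf sampling frequency of `x` in Hz.
#' @param bin_size FFT segment length (default 2048).
#' @param search_band DF search band in cpm.
#' @return list with `DF` (cpm, NA if undefined), `freq_cpm`, `power`.
#' @export
compute_dominant_frequency <- function(x, sf, bin_size = 2048,
                                       search_band = c(1, 60)) {
  failed <- list(DF = NA_real_, freq_cpm = numeric(0), power = numeric(0))
  if (all(is.na(x))) return(failed)
  x <- interp_na(x)
  if (sd(x) == 0) return(failed)
  seg_len <- min(bin_size, length(x))
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, length(x) - seg_len + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  nfft <- 8 * bin_size
  pxx <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- fft(c(seg, numeric(nfft - seg_len)))
    pxx <- pxx + Mod(sp[seq_len(nfft %/% 2 + 1)])^2
  }
  pxx <- pxx / length(starts)
  freq_cpm <- (seq_len(nfft %/% 2 + 1) - 1) * sf / nfft * 60
  inband <- which(freq_cpm >= search_band[1] & freq_cpm <= search_band[2])
  if (!length(inband) || all(pxx[inband] == 0)) return(failed)
  i <- inband[which.max(pxx[inband])]
  df <- freq_cpm[i]
  # parabolic interpolation on log power refines the peak position
  if (i > 1 && i < length(pxx) && pxx[i - 1] > 0 && pxx[i + 1] > 0) {
    la <- log(pxx[i - 1]); lb <- log(pxx[i]); lc <- log(pxx[i + 1])
    den <- la - 2 * lb + lc
    if (den < 0) {
      delta <- 0.5 * (la - lc) / den
      df <- df + delta * (sf / nfft * 60)
    }
  }
  list(DF = round(df, 2), freq_cpm = freq_cpm, power = pxx)
}

#' Dominant-frequency channel filter
#'
#' A channel is retained when its baseline DF meets the tissue threshold:
#' >= 11 cpm for intestinal segments (duodenum, ileum, colon) and >= 4 cpm
#' for the stomach. Channels whose DF is undefined fail.
#'
#' @param df_values numeric vector of per-channel DFs (cpm; NA = failed).
#' @param tissue integer tissue code.
#' @param params [preprocess_params()].
#' @return logical pass mask.
#' @export
filter_channels_by_df <- function(df_values, tissue,
                                  params = preprocess_params()) {
  stopifnot(tissue %in% TISSUES)
  thr <- if (tissue == TISSUES[["stomach"]]) params$df_stomach else
    params$df_intestine
  !is.na(df_values) & df_values >= thr
}

#' Baseline channel stability
#'
#' Ratio of spectral power within +/-1 cpm of the dominant frequency to the
#' power in the fixed 2-40 cpm band, computed over the baseline window.
#' Returns 0 when the denominator is zero.
#'
#' @param power periodogram power vector.
#' @param freq_cpm matching frequency axis in cpm.
#' @param DF dominant frequency in cpm.
#' @return stability ratio (in `[0, 1]` when the DF band lies inside
#'   2-40 cpm).
#' @export
channel_stability <- function(power, freq_cpm, DF) {
  if (is.na(DF) || !length(power)) return(0)
  num <- sum(power[freq_cpm >= DF - 1 & freq_cpm <= DF + 1])
  den <- sum(power[freq_cpm >= 2 & freq_cpm <= 40])
  if (den == 0) return(0)
  num / den
}

#' Reference peak and trough amplitudes
#'
#' Selects the three most stable passing channels over the baseline window
#' (ties broken by lower channel index; all passing channels with a warning
#' if fewer than three pass), detects local peaks and troughs with a
#' minimum separation of half the dominant period, and averages them.
#'
#' @param baseline matrix channels x samples (filtered, working rate, uV).
#' @param sf working rate in Hz.
#' @param df_values per-channel DFs (cpm).
#' @param stability per-channel stability values.
#' @param pass logical pass mask from [filter_channels_by_df()].
#' @return list with `avg_peak`, `avg_trough`, `source_channels`.
#' @export
compute_reference_amplitudes <- function(baseline, sf, df_values, stability,
                                         pass) {
  idx <- which(pass)
  if (!length(idx)) stop("no channels pass the DF filter; dataset rejected")
  ord <- idx[order(-stability[idx], idx)]
  if (length(ord) < 3) {
    warning("fewer than 3 passing channels; using all of them")
  }
  src <- head(ord, 3)
  peaks <- c(); troughs <- c()
  for (ch in src) {
    x <- interp_na(baseline[ch, ])
    min_dist <- max(1, floor(0.5 * 60 / df_values[ch] * sf))
    pk <- pracma::findpeaks(x, minpeakdistance = min_dist,
                            minpeakheight = 0)
    tr <- pracma::findpeaks(-x, minpeakdistance = min_dist,
                            minpeakheight = 0)
    peaks <- c(peaks, if (!is.null(pk)) pk[, 1] else max(x))
    troughs <- c(troughs, if (!is.null(tr)) -tr[, 1] else min(x))
  }
  list(avg_peak = mean(peaks), avg_trough = mean(troughs),
       source_channels = src)
}

#' Normalize to 110% of the reference amplitudes
#'
#' Affine map `(x - avg_trough * 1.1) / (avg_peak * 1.1 - avg_trough * 1.1)`
#' so that values at 110% of the average trough map to 0 and values at 110%
#' of the average peak map to 1. NA is preserved.
#'
#' @param x numeric vector or matrix (uV).
#' @param ref list with `avg_peak`, `avg_trough` (see
#'   [compute_reference_amplitudes()]).
#' @return normalized values.
#' @export
normalize_signal <- function(x, ref) {
  lo <- ref$avg_trough * 1.1
  hi <- ref$avg_peak * 1.1
  if (hi <= lo) stop("degenerate dynamic range: avg_peak <= avg_trough")
  (x - lo) / (hi - lo)
}

#' Augment failed channels from grid neighbours
#'
#' Replaces each failed channel's trace by the elementwise mean of its
#' passing 4-neighbours on the 8x8 array; failed channels with no passing
#' neighbour become all-NA. The result is independent of channel order.
#'
#' @param sig matrix channels x samples.
#' @param pass logical pass mask (FALSE = failed).
#' @param layout array layout data.frame (see [array_layout()]).
#' @return list with `signal` (augmented matrix) and `augmented` (indices
#'   of replaced channels).
#' @export
augment_channels <- function(sig, pass, layout = array_layout()) {
  nbs <- channel_neighbours(layout)
  out <- sig
  augmented <- integer(0)
  for (ch in which(!pass)) {
    good <- nbs[[ch]][pass[nbs[[ch]]]]
    if (length(good)) {
      out[ch, ] <- colMeans(sig[good, , drop = FALSE])
      augmented <- c(augmented, ch)
    } else {
      out[ch, ] <- NA_real_
    }
  }
  list(signal = out, augmented = augmented)
}

#' Extract a half-open time window as a time x channel matrix
#'
#' @param sig matrix channels x samples at `sf` Hz, time 0 at sample 1.
#' @param sf sampling rate in Hz.
#' @param window `c(start, end)` in seconds; samples with
#'   `start <= t < end` are taken (`t = (i - 1) / sf`).
#' @return matrix (end-start)*sf x channels.
#' @export
extract_window <- function(sig, sf, window) {
  i0 <- round(window[1] * sf) + 1
  i1 <- round(window[2] * sf)
  if (i1 > ncol(sig)) stop("recording too short for requested window")
  t(sig[, i0:i1, drop = FALSE])
}

#' Summated interference matrix
#'
#' Elementwise sum of a baseline and a (possibly time-shifted) post-drug
#' matrix; this is the model input representation.
#'
#' @param baseline,postdrug matrices of identical dimension (2000 x 60 in
#'   the standard pipeline).
#' @param shift one of "none", "forward", "backward".
#' @return matrix of the same dimension with attribute `shift`.
#' @export
make_interference <- function(baseline, postdrug, shift = "none") {
  if (!all(dim(baseline) == dim(postdrug))) {
    stop("baseline and post-drug matrices must have identical dimensions")
  }
  out <- baseline + postdrug
  attr(out, "shift") <- shift
  out
}

#' Missing-value exclusion rule
#'
#' A matched dataset is retained iff neither its baseline nor its post-drug
#' matrix has a NaN fraction strictly above the threshold (default 1.6%).
#'
#' @param nan_frac_baseline,nan_frac_postdrug NaN fractions in `[0, 1]`.
#' @param threshold exclusion threshold (strict `>` excludes).
#' @return logical: TRUE when retained.
#' @export
retain_dataset <- function(nan_frac_baseline, nan_frac_postdrug,
                           threshold = 0.016) {
  nan_frac_baseline <= threshold & nan_frac_postdrug <= threshold
}

#' Full preprocessing of one raw recording
#'
#' Pipeline: amplitude masking (uV, raw rate) -> NA-support bookkeeping ->
#' anti-aliased decimation to the 10 Hz working rate -> zero-phase band-pass
#' -> per-channel Welch DF + stability over the 0-300 s baseline ->
#' tissue DF filter -> reference peak/trough amplitudes from the three most
#' stable channels -> neighbour augmentation of failed channels ->
#' normalization -> window truncation into 2000 x 60 baseline (50-250 s),
#' post-drug (500-700 s) and time-shifted (490-690 / 510-710 s) matrices ->
#' interference sums.
#'
#' @param rec an `sw_recording`.
#' @param params [preprocess_params()].
#' @return an `sw_matched` list: matrices `baseline`, `postdrug`,
#'   `interference`, `forward`, `backward` (2000 x 60; interference NA-free,
#'   residual NaN replaced by 0 in normalized units at model-input creation),
#'   NaN fractions, `retained` flag and a per-channel `report`.
#' @export
preprocess_recording <- function(rec, params = preprocess_params()) {
  sf <- rec$sf
  factor <- sf / params$target_rate
  if (factor != round(factor)) stop("sf must be a multiple of target_rate")
  n_ch <- nrow(rec$signal)

  masked <- mask_amplitude(rec$signal, params$mask_uV)
  nd <- floor(ncol(masked) / factor)
  na_raw <- is.na(masked)
  na_ds <- t(apply(na_raw, 1, decimate_nan_mask, factor = factor))
  all_na <- rowSums(!na_raw) == 0
  ds <- downsample_mat(masked, factor)
  # partial-NA blocks already averaged; interpolate any fully missing blocks
  for (ch in which(!all_na)) {
    if (anyNA(ds[ch, ])) ds[ch, ] <- interp_na(ds[ch, ])
  }
  ds[all_na, ] <- 0
  ds <- t(bandlimit_filter_mat(t(ds), params$target_rate, params$band))
  ds[all_na, ] <- NA_real_

  wr <- params$target_rate
  base_idx <- seq_len(min(300 * wr, nd))
  spectra <- vector("list", n_ch)
  df_values <- rep(NA_real_, n_ch)
  stability <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    if (all_na[ch]) next
    sp <- compute_dominant_frequency(ds[ch, base_idx], wr, params$bin_size)
    spectra[[ch]] <- sp
    df_values[ch] <- sp$DF
    stability[ch] <- channel_stability(sp$power, sp$freq_cpm, sp$DF)
  }
  pass <- filter_channels_by_df(df_values, rec$tissue, params)

  ref <- compute_reference_amplitudes(ds[, base_idx, drop = FALSE], wr,
                                      df_values, stability, pass)
  aug <- augment_channels(ds, pass, rec$layout)
  norm <- normalize_signal(aug$signal, ref)
  # restore NA support on surviving (non-augmented) channels
  keep <- pass
  norm[keep, ][na_ds[keep, , drop = FALSE]] <- NA_real_

  w <- params$windows
  baseline <- extract_window(norm, wr, w$baseline)
  postdrug <- extract_window(norm, wr, w$postdrug)
  forward <- extract_window(norm, wr, w$forward)
  backward <- extract_window(norm, wr, w$backward)

  nfb <- mean(is.na(baseline))
  nfp <- mean(is.na(postdrug))
  structure(list(
    dataset_id = rec$dataset_id, drug = rec$drug,
    tissue = rec$tissue, conc = rec$conc,
    baseline = baseline, postdrug = postdrug,
    interference = make_interference(baseline, postdrug, "none"),
    forward = make_interference(baseline, forward, "forward"),
    backward = make_interference(baseline, backward, "backward"),
    nan_frac_baseline = nfb, nan_frac_postdrug = nfp,
    retained = retain_dataset(nfb, nfp, params$nan_thresh),
    reference = ref, augmented_channels = aug$augmented,
    report = data.frame(channel = seq_len(n_ch), DF = df_values,
                        stability = stability, pass = pass)
  ), class = "sw_matched")
}

#' Preprocess a whole cohort lazily
#'
#' Simulates and preprocesses one recording at a time (raw signals are never
#' held simultaneously), keeping only the 2000 x 60 matrices and the
#' processing report.
#'
#' @param spec a [cohort_spec()].
#' @param params [preprocess_params()].
#' @param drugs optional pre-generated drug library (must match `spec`).
#' @param verbose print progress.
#' @return list with `matched` (list of `sw_matched`, retained and excluded),
#'   `report` (per-dataset data.frame), `design`, `drugs`, `annotations`.
#' @export
preprocess_cohort <- function(spec, params = preprocess_params(),
                              drugs = NULL, verbose = FALSE) {
  if (is.null(drugs)) {
    drugs <- generate_drug_library(
      spec$n_drugs, spec$adr_prevalence, spec$annotated_fraction, spec$seed,
      spec$indication_rate, spec$effect_shift_cpm, spec$effect_amp_scale)
    names(drugs) <- vapply(drugs, `[[`, "", "drug_id")
  }
  design <- cohort_design(spec)
  matched <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    rec <- simulate_recording(drugs[[design$drug[k]]], design$tissue[k],
                              design$conc[k], spec, design$sim_seed[k],
                              design$dataset_id[k])
    matched[[k]] <- tryCatch(
      preprocess_recording(rec, params),
      error = function(e) structure(list(
        dataset_id = rec$dataset_id, drug = rec$drug, tissue = rec$tissue,
        conc = rec$conc, baseline = NULL, postdrug = NULL,
        interference = NULL, forward = NULL, backward = NULL,
        nan_frac_baseline = 1, nan_frac_postdrug = 1, retained = FALSE,
        augmented_channels = integer(0), failure = conditionMessage(e)
      ), class = "sw_matched"))
    if (verbose && k %% 20 == 0) message(sprintf("  %d / %d", k, nrow(design)))
  }
  names(matched) <- design$dataset_id
  report <- data.frame(
    dataset_id = design$dataset_id,
    drug = design$drug, tissue = design$tissue, conc = design$conc,
    nan_frac_baseline = vapply(matched, `[[`, 0, "nan_frac_baseline"),
    nan_frac_postdrug = vapply(matched, `[[`, 0, "nan_frac_postdrug"),
    retained = vapply(matched, `[[`, TRUE, "retained"),
    n_augmented = vapply(matched, function(m) length(m$augmented_channels),
                         0L),
    row.names = NULL
  )
  list(matched = matched, report = report, design = design, drugs = drugs,
       annotations = annotation_table(drugs))
}
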