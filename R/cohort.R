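#' Cohort specification for the synthetic slow-wave generator
#'
#' Describes a synthetic cohort of multi-electrode slow-wave experiments:
#' how many drugs, how many datasets per drug, the ADR prevalences used to
#' draw drug profiles, and the physical parameters of the simulated
#' recordings. Defaults follow the recording conventions of the real
#' microelectrode-array platform (720 s at 1 kHz, 60 channels on an 8x8
#' grid, signal range within +/-25..1200 uV, noise within +/-10 uV, drug at
#' approximately 300 s) at a desk-scale cohort size.
#'
#' @param n_drugs number of drugs in the cohort.
#' @param datasets_per_drug experiments per drug (the real database holds at
#'   least 60; the synthetic default is scaled down).
#' @param adr_prevalence named vector of per-ADR probabilities in (0,1) that
#'   a drug induces each of nausea, vomiting, diarrhoea, constipation.
#' @param annotated_fraction fraction of drugs present in the annotation
#'   table (emulating the 95/172 overlap with the side-effect database).
#' @param indication_rate probability that an annotated drug carries an
#'   `indication` relation for an ADR (such drugs are corrected to class 0).
#' @param seed master seed for the cohort.
#' @param sf sampling frequency in Hz. Must be a multiple of 10.
#' @param duration recording length in seconds.
#' @param noise_sd additive noise standard deviation in uV (noise band is
#'   +/-10 uV).
#' @param baseline_amplitude_range admissible slow-wave amplitude range, uV.
#' @param dropout_rate fraction of dead channels (noise only, no slow wave).
#' @param artifact_rate per-sample probability of an out-of-range
#'   (|v| > 1500 uV) artifact.
#' @param nan_rate expected fraction of missing samples, injected as short
#'   runs.
#' @param effect_shift_cpm mean class-1 post-drug dominant-frequency shift
#'   (cpm) at medium concentration; 0 disables the class signal.
#' @param effect_amp_scale mean class-1 post-drug amplitude scaling factor.
#' @return an object of class `sw_cohort_spec`.
#' @export
cohort_spec <- function(n_drugs = 16L,
                        datasets_per_drug = 12L,
                        adr_prevalence = c(nausea = 0.25, vomiting = 0.25,
                                           diarrhoea = 0.25,
                                           constipation = 0.5),
                        annotated_fraction = 0.8,
                        indication_rate = 0.1,
                        seed = 1L,
                        sf = 1000,
                        duration = 720,
                        noise_sd = 5,
                        baseline_amplitude_range = c(25, 1200),
                        dropout_rate = 0.05,
                        artifact_rate = 1e-5,
                        nan_rate = 0.002,
                        effect_shift_cpm = 3,
                        effect_amp_scale = 1.4) {
  stopifnot(n_drugs >= 2, datasets_per_drug >= 1)
  if (sf %% 10 != 0) stop("sf must be a multiple of 10 Hz")
  for (a in names(adr_prevalence)) {
    p <- adr_prevalence[[a]]
    if (!is.finite(p) || p <= 0 || p >= 1) {
      stop(sprintf("invalid prevalence for ADR '%s': must lie in (0,1)", a))
    }
  }
  rates <- c(dropout_rate, artifact_rate, nan_rate)
  stopifnot(all(rates >= 0 & rates <= 1))
  stopifnot(length(baseline_amplitude_range) == 2,
            baseline_amplitude_range[1] > 0,
            baseline_amplitude_range[1] < baseline_amplitude_range[2])
  structure(list(
    n_drugs = as.integer(n_drugs),
    datasets_per_drug = as.integer(datasets_per_drug),
    adr_prevalence = adr_prevalence,
    annotated_fraction = annotated_fraction,
    indication_rate = indication_rate,
    seed = as.integer(seed),
    sf = sf, duration = duration,
    noise_sd = noise_sd,
    baseline_amplitude_range = baseline_amplitude_range,
    dropout_rate = dropout_rate,
    artifact_rate = artifact_rate,
    nan_rate = nan_rate,
    effect_shift_cpm = effect_shift_cpm,
    effect_amp_scale = effect_amp_scale
  ), class = "sw_cohort_spec")
}

#' 8x8 microelectrode array layout with unused corners
#'
#' Maps the 60 recorded channels onto an 8x8 grid; the four corner positions
#' are not recorded, the conventional layout of this array platform.
#'
#' @return data.frame with columns `channel`, `row`, `col`.
#' @export
array_layout <- function() {
  g <- expand.grid(col = 1:8, row = 1:8)[, c("row", "col")]
  corner <- (g$row %in% c(1, 8)) & (g$col %in% c(1, 8))
  g <- g[!corner, ]
  g$channel <- seq_len(nrow(g))
  rownames(g) <- NULL
  g[, c("channel", "row", "col")]
}

# 4-neighbour (von Neumann) adjacency on the layout; list over channels.
channel_neighbours <- function(layout = array_layout()) {
  key <- paste(layout$row, layout$col)
  lapply(seq_len(nrow(layout)), function(i) {
    r <- layout$row[i]; c <- layout$col[i]
    nb <- paste(c(r - 1, r + 1, r, r), c(c, c, c - 1, c + 1))
    layout$channel[match(nb, key, nomatch = 0)]
  })
}

#' Generate a library of synthetic drug profiles
#'
#' Draws, per drug, independent per-ADR class flags at the configured
#' prevalence, an annotation indicator (whether the drug appears in the
#' SIDER-like table), `indication` relations that force the corrected class
#' to 0, and latent waveform-signature parameters (dominant-frequency shift
#' in cpm and amplitude scaling) realized in class-1 post-drug segments.
#'
#' @param n_drugs number of drugs (>= 2).
#' @param adr_prevalence named per-ADR probabilities in (0,1).
#' @param annotated_fraction fraction of drugs annotated, in (0,1].
#' @param seed integer seed; output is a pure function of the arguments.
#' @param indication_rate probability of an indication relation per ADR for
#'   annotated drugs.
#' @param effect_shift_cpm,effect_amp_scale mean signature parameters.
#' @return list of `sw_drug_profile` objects.
#' @export
generate_drug_library <- function(n_drugs, adr_prevalence,
                                  annotated_fraction = 1.0,
                                  seed = 1L,
                                  indication_rate = 0.1,
                                  effect_shift_cpm = 3,
                                  effect_amp_scale = 1.4) {
  stopifnot(n_drugs >= 2, annotated_fraction > 0, annotated_fraction <= 1)
  prev <- setNames(rep(0.3, length(ADRS)), ADRS)
  for (a in names(adr_prevalence)) {
    p <- adr_prevalence[[a]]
    if (!is.finite(p) || p <= 0 || p >= 1) {
      stop(sprintf("invalid prevalence for ADR '%s': must lie in (0,1)", a))
    }
    if (!a %in% ADRS) stop(sprintf("unknown ADR '%s'", a))
    prev[a] <- p
  }
  with_seed(derive_seed(seed, "drug_library"), {
    lapply(seq_len(n_drugs), function(i) {
      drug_id <- sprintf("drug%03d", i)
      raw <- setNames(as.integer(runif(length(ADRS)) < prev), ADRS)
      annotated <- runif(1) < annotated_fraction
      indication <- setNames(runif(length(ADRS)) < indication_rate, ADRS)
      if (!annotated) indication[] <- FALSE
      flags <- raw
      flags[indication] <- 0L          # indication relation corrects to class 0
      shift <- max(0.5, rnorm(1, effect_shift_cpm, 0.5))
      amp <- max(1.05, rnorm(1, effect_amp_scale, 0.1))
      structure(list(
        drug_id = drug_id,
        adr_flags = flags,
        raw_flags = raw,
        annotated = annotated,
        indication_flags = indication,
        signature_params = list(shift_cpm = shift, amp_scale = amp),
        # concentration scaling of the latent effect; tissue-independent
        effect_size = function(tissue, conc) c(0.5, 1, 1.5)[conc]
      ), class = "sw_drug_profile")
    })
  })
}

# Deterministic allocation of (tissue, concentration) cells for one drug.
# Higher and lower concentrations are only run on intestinal segments, so
# stomach experiments (medium only) are about 3x rarer than intestinal ones.
tissue_conc_cells <- function() {
  cells <- rbind(
    c(TISSUES[["stomach"]], CONCENTRATIONS[["medium"]]),
    do.call(rbind, lapply(c("duodenum", "ileum", "colon"), function(tt) {
      cbind(TISSUES[[tt]], as.integer(CONCENTRATIONS))
    }))
  )
  colnames(cells) <- c("tissue", "conc")
  cells
}

#' Deterministic design table for a synthetic cohort
#'
#' Lays out which (drug, tissue, concentration) each dataset records, plus
#' the per-dataset simulation seed, without simulating any signals. The
#' design is a pure function of the spec, so recordings can be generated
#' lazily one at a time.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `dataset_id`, `drug`, `tissue`, `conc`,
#'   `sim_seed`.
#' @export
cohort_design <- function(spec) {
  cells <- tissue_conc_cells()
  rows <- lapply(seq_len(spec$n_drugs), function(i) {
    drug_id <- sprintf("drug%03d", i)
    idx <- ((seq_len(spec$datasets_per_drug) - 1) %% nrow(cells)) + 1
    data.frame(
      dataset_id = sprintf("%s_t%d_c%d_r%02d", drug_id,
                           cells[idx, "tissue"], cells[idx, "conc"],
                           seq_len(spec$datasets_per_drug)),
      drug = drug_id,
      tissue = cells[idx, "tissue"],
      conc = cells[idx, "conc"],
      stringsAsFactors = FALSE
    )
  })
  design <- do.call(rbind, rows)
  design$sim_seed <- vapply(seq_len(nrow(design)), function(k) {
    derive_seed(spec$seed, "recording", k)
  }, integer(1))
  design
}

#' Simulate one raw multi-electrode slow-wave recording
#'
#' The waveform model is a per-channel sum of a fundamental sinusoid at a
#' tissue-specific dominant frequency plus two harmonics, with phase lags
#' across the 8x8 grid, additive broadband plus slow (AR-smoothed) noise,
#' dead channels, out-of-range artifacts, and missing-value runs. After the
#' drug administration time the dominant frequency and amplitude are
#' modulated: every recording receives a small drug-independent nuisance
#' perturbation, and recordings of drugs with any positive ADR flag
#' additionally receive the drug's latent signature (frequency shift and
#' amplitude scaling) scaled by `effect_size(tissue, conc)`.
#'
#' @param profile a `sw_drug_profile`.
#' @param tissue integer tissue code (1 stomach, 2 duodenum, 3 ileum,
#'   4 colon).
#' @param conc integer concentration code (1 low, 2 medium, 3 high).
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the recording is a pure function of arguments.
#' @param dataset_id optional identifier.
#' @return an `sw_recording`: list with `signal` (60 x sf*duration matrix,
#'   uV), `sf`, `duration`, `tissue`, `conc`, `drug`, `t_drug`, `layout`.
#' @export
simulate_recording <- function(profile, tissue, conc, spec, seed,
                               dataset_id = NULL) {
  stopifnot(tissue %in% TISSUES, conc %in% CONCENTRATIONS)
  layout <- array_layout()
  n_ch <- nrow(layout)
  n <- round(spec$sf * spec$duration)
  with_seed(seed, {
    t_drug <- runif(1, 295, 305)
    df0 <- if (tissue == TISSUES[["stomach"]]) runif(1, 5, 8) else
      runif(1, 12, 20)
    # post-drug dominant frequency: nuisance jitter for everyone, plus the
    # class signature when any ADR flag is set
    is_class1 <- any(profile$adr_flags == 1L)
    esize <- profile$effect_size(tissue, conc)
    shift <- rnorm(1, 0, 0.3) +
      if (is_class1) profile$signature_params$shift_cpm * esize else 0
    amp_mod <- rnorm(1, 1, 0.05) *
      if (is_class1) 1 + (profile$signature_params$amp_scale - 1) * esize else 1
    df1 <- max(1, df0 + shift)

    # instantaneous frequency with a 10 s ramp at t_drug; continuous phase
    tt <- seq_len(n) / spec$sf
    ramp <- pmin(pmax((tt - t_drug) / 10, 0), 1)
    fvec <- df0 + (df1 - df0) * ramp            # cpm
    phase <- 2 * pi * cumsum(fvec / 60) / spec$sf
    gain <- 1 + (amp_mod - 1) * ramp

    amp_lo <- max(spec$baseline_amplitude_range[1] * 2, 50)
    amp_hi <- min(spec$baseline_amplitude_range[2] * 0.42, 500)
    amps <- runif(n_ch, amp_lo, amp_hi)
    phis <- 2 * pi * 0.02 * (layout$row + layout$col) + rnorm(n_ch, 0, 0.1)
    dropout <- runif(n_ch) < spec$dropout_rate

    sig <- if (spec$noise_sd > 0) {
      matrix(rnorm(n * n_ch, sd = spec$noise_sd), nrow = n_ch)
    } else matrix(0, nrow = n_ch, ncol = n)
    for (ch in which(!dropout)) {
      ph <- phase + phis[ch]
      wave <- sin(ph) + 0.3 * sin(2 * ph)
      sig[ch, ] <- sig[ch, ] + amps[ch] * gain * wave
    }

    if (spec$artifact_rate > 0) {
      n_art <- rbinom(1, n * n_ch, spec$artifact_rate)
      if (n_art > 0) {
        pos <- sample.int(n * n_ch, n_art)
        sig[pos] <- sample(c(-1, 1), n_art, replace = TRUE) *
          runif(n_art, 1600, 3000)
      }
    }
    if (spec$nan_rate > 0) {
      mean_len <- max(2, round(0.2 * spec$sf))     # runs of ~0.2 s
      n_runs <- max(1, round(spec$nan_rate * n * n_ch / mean_len))
      ch_r <- sample.int(n_ch, n_runs, replace = TRUE)
      st_r <- sample.int(n - 2 * mean_len, n_runs, replace = TRUE)
      len_r <- pmax(2, round(runif(n_runs, 0.5, 1.5) * mean_len))
      for (k in seq_len(n_runs)) {
        sig[ch_r[k], st_r[k]:(st_r[k] + len_r[k] - 1)] <- NA_real_
      }
    }

    structure(list(
      dataset_id = dataset_id %||%
        sprintf("%s_t%d_c%d", profile$drug_id, tissue, conc),
      signal = sig, sf = spec$sf, duration = spec$duration,
      tissue = as.integer(tissue), conc = as.integer(conc),
      drug = profile$drug_id, t_drug = t_drug,
      layout = layout, dropout = which(dropout), df_baseline = df0
    ), class = "sw_recording")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sw_recording <- function(x, ...) {
  cat(sprintf(
    "<sw_recording %s> drug=%s tissue=%d conc=%d %d ch x %d samples @ %g Hz, drug at %.1f s\n",
    x$dataset_id, x$drug, x$tissue, x$conc, nrow(x$signal), ncol(x$signal),
    x$sf, x$t_drug))
  invisible(x)
}

#' Build the SIDER-like annotation table for a drug library
#'
#' Annotated drugs contribute one `side_effect` row per positive raw ADR
#' flag and one `indication` row per indication relation; unannotated drugs
#' are absent (and therefore held out from training downstream).
#'
#' @param drugs list of `sw_drug_profile`.
#' @return data.frame with columns `drug_id`, `adr`, `relation`.
#' @export
annotation_table <- function(drugs) {
  rows <- list()
  for (d in drugs) {
    if (!d$annotated) next
    for (a in ADRS) {
      if (d$raw_flags[[a]] == 1L) {
        rows[[length(rows) + 1]] <- data.frame(
          drug_id = d$drug_id, adr = a, relation = "side_effect",
          stringsAsFactors = FALSE)
      }
      if (isTRUE(d$indication_flags[[a]])) {
        rows[[length(rows) + 1]] <- data.frame(
          drug_id = d$drug_id, adr = a, relation = "indication",
          stringsAsFactors = FALSE)
      }
    }
    if (!any(d$raw_flags == 1L) && !any(d$indication_flags)) {
      # keep the drug visible in the table so it is annotated class 0
      rows[[length(rows) + 1]] <- data.frame(
        drug_id = d$drug_id, adr = "none", relation = "side_effect",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic cohort
#'
#' Draws the drug library, lays out the design, simulates every recording
#' and (optionally) writes the recording container: one RDS file per
#' dataset plus `metadata.csv` and `annotations.tsv` sidecars.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir if non-NULL, write recordings and sidecars here and return
#'   file paths instead of in-memory recordings.
#' @return list with `drugs`, `design` (metadata), `annotations`, and either
#'   `recordings` (list of `sw_recording`) or `files`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  drugs <- generate_drug_library(
    spec$n_drugs, spec$adr_prevalence, spec$annotated_fraction, spec$seed,
    spec$indication_rate, spec$effect_shift_cpm, spec$effect_amp_scale)
  names(drugs) <- vapply(drugs, `[[`, "", "drug_id")
  design <- cohort_design(spec)
  ann <- annotation_table(drugs)
  if (is.null(out_dir)) {
    recs <- lapply(seq_len(nrow(design)), function(k) {
      simulate_recording(drugs[[design$drug[k]]], design$tissue[k],
                         design$conc[k], spec, design$sim_seed[k],
                         design$dataset_id[k])
    })
    names(recs) <- design$dataset_id
    return(list(drugs = drugs, design = design, annotations = ann,
                recordings = recs))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(design))
  for (k in seq_len(nrow(design))) {
    rec <- simulate_recording(drugs[[design$drug[k]]], design$tissue[k],
                              design$conc[k], spec, design$sim_seed[k],
                              design$dataset_id[k])
    files[k] <- file.path(out_dir, paste0(design$dataset_id[k], ".rds"))
    saveRDS(rec, files[k])
  }
  meta <- cbind(design[, c("dataset_id", "drug", "tissue", "conc")],
                file = basename(files))
  write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  write_annotations(ann, file.path(out_dir, "annotations.tsv"))
  list(drugs = drugs, design = design, annotations = ann, files = files,
       out_dir = out_dir)
}

#' Read / write the SIDER-like annotation TSV
#'
#' @param path file path.
#' @return data.frame with columns `drug_id`, `adr`, `relation`.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_id", "adr", "relation") %in% names(df)))
  stopifnot(all(df$relation %in% c("side_effect", "indication")))
  df
}

#' @rdname read_annotations
#' @param ann annotation data.frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
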