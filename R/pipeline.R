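#' Default run configuration
#'
#' Aggregates every stage's parameters. Numeric analysis constants (mask
#' bound 1500 uV, NaN threshold 1.6%, DF thresholds 11/4 cpm, windows,
#' 8:2 split, batch size 30) are identical in every profile; the profile
#' only scales problem size (cohort size, sampling rate, epochs, network
#' width).
#'
#' @param profile "ci" (desk-scale) or "paper_scale".
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(profile = c("ci", "paper_scale"), seed = 1L) {
  profile <- match.arg(profile)
  ci <- profile == "ci"
  list(
    profile = profile,
    seed = as.integer(seed),
    cohort = list(
      n_drugs = if (ci) 16L else 172L,
      datasets_per_drug = if (ci) 12L else 60L,
      adr_prevalence = list(nausea = 0.25, vomiting = 0.25,
                            diarrhoea = 0.25, constipation = 0.5),
      annotated_fraction = 0.8,
      sf = if (ci) 20 else 1000,
      noise_sd = 5, dropout_rate = 0.05, artifact_rate = 1e-5,
      nan_rate = 0.002, effect_shift_cpm = 3, effect_amp_scale = 1.4
    ),
    preprocess = list(mask_uV = 1500, nan_thresh = 0.016,
                      df_intestine = 11, df_stomach = 4, target_rate = 10),
    label = list(adrs = ADRS,
                 n_chunks = list(nausea = 2L, vomiting = 2L, diarrhoea = 2L,
                                 constipation = 1L),
                 ratio = 0.8),
    train = list(arch = "ict", replicates = 5L,
                 epochs = if (ci) 20L else 200L, batch_size = 30L,
                 n_filters = if (ci) 4L else 32L,
                 depth = if (ci) 3L else 6L,
                 subsample = if (ci) 4L else 1L,
                 kernels = if (ci) c(10L, 5L, 3L) else c(40L, 20L, 10L),
                 label_modes = "correct"),
    evaluate = list(grouping = "all", risk_threshold = 0.7, top_k = 2L)
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @return configuration list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

cohort_spec_from_config <- function(config) {
  ch <- config$cohort
  cohort_spec(
    n_drugs = ch$n_drugs, datasets_per_drug = ch$datasets_per_drug,
    adr_prevalence = unlist(ch$adr_prevalence),
    annotated_fraction = ch$annotated_fraction,
    seed = config$seed, sf = ch$sf,
    noise_sd = ch$noise_sd, dropout_rate = ch$dropout_rate,
    artifact_rate = ch$artifact_rate, nan_rate = ch$nan_rate,
    effect_shift_cpm = ch$effect_shift_cpm,
    effect_amp_scale = ch$effect_amp_scale)
}

preprocess_params_from_config <- function(config) {
  pp <- config$preprocess
  preprocess_params(mask_uV = pp$mask_uV, df_intestine = pp$df_intestine,
                    df_stomach = pp$df_stomach, nan_thresh = pp$nan_thresh,
                    target_rate = pp$target_rate)
}

#' Train the classifiers and ensemble for one ADR chunk
#'
#' Builds the stratified 8:2 split, trains `replicates` classifiers (with
#' shuffled training labels when `label_mode = "shuffled"`), fits the
#' logistic ensemble on the validation-set member probabilities, and
#' returns validation reports (by-drug aggregation) for members and
#' ensemble.
#'
#' @param chunk an `sw_chunk`.
#' @param matched list of `sw_matched` keyed by dataset id.
#' @param metadata cohort metadata.
#' @param drug_labels named 0/1 drug-level truth for this ADR.
#' @param config run configuration.
#' @param label_mode "correct" or "shuffled".
#' @return list with `classifiers`, `ensemble`, `val_ids`,
#'   `member_val_probs`, `reports`.
#' @export
train_chunk_models <- function(chunk, matched, metadata, drug_labels,
                               config, label_mode = "correct") {
  tr <- config$train
  split <- split_train_val(chunk, config$label$ratio, config$seed)
  meta_i <- function(ids) match(ids, metadata$dataset_id)
  train_ids <- split$train_ids; val_ids <- split$val_ids
  y_train <- chunk$labels[train_ids]
  if (label_mode == "shuffled") {
    y_train <- shuffle_labels(y_train,
                              derive_seed(config$seed, chunk$adr,
                                          chunk$chunk_index, "neg"))
  }
  y_val <- chunk$labels[val_ids]
  x_train <- lapply(matched[train_ids], `[[`, "interference")
  names(x_train) <- train_ids
  x_val <- lapply(matched[val_ids], `[[`, "interference")
  names(x_val) <- val_ids
  it <- meta_i(train_ids); iv <- meta_i(val_ids)
  embedding <- make_embedding_table(config$seed)
  classifiers <- list()
  val_probs <- matrix(NA_real_, length(val_ids), tr$replicates)
  reports <- list()
  for (r in seq_len(tr$replicates)) {
    spec <- train_spec(tr$arch, epochs = tr$epochs,
                       batch_size = tr$batch_size,
                       n_filters = tr$n_filters, depth = tr$depth,
                       kernels = tr$kernels, subsample = tr$subsample,
                       seed = derive_seed(config$seed, chunk$adr,
                                          chunk$chunk_index, label_mode, r),
                       label_mode = label_mode)
    mid <- sprintf("%s_chunk%d_%s_tr%d", chunk$adr, chunk$chunk_index,
                   label_mode, r)
    mdl <- train_classifier(x_train, y_train, metadata$tissue[it],
                            metadata$conc[it], embedding, spec)
    classifiers[[mid]] <- mdl
    pv <- predict_proba(mdl, x_val, metadata$tissue[iv], metadata$conc[iv])
    val_probs[, r] <- pv$p1
    agg <- aggregate_by_drug(pv, metadata, config$evaluate$grouping)
    ev <- evaluate_predictions(agg$mean_p1, drug_labels[agg$drug])
    reports[[length(reports) + 1]] <- cbind(
      data.frame(model_id = mid, adr = chunk$adr,
                 chunk = chunk$chunk_index, label_mode = label_mode,
                 prediction_set = "validation",
                 grouping = config$evaluate$grouping,
                 stringsAsFactors = FALSE), ev)
  }
  ens <- fit_ensemble(val_probs, y_val)
  ep <- predict_ensemble(ens, val_probs)
  agg <- aggregate_by_drug(data.frame(dataset_id = val_ids, p1 = ep),
                           metadata, config$evaluate$grouping)
  ev <- evaluate_predictions(agg$mean_p1, drug_labels[agg$drug])
  reports[[length(reports) + 1]] <- cbind(
    data.frame(model_id = sprintf("%s_chunk%d_%s_ensemble", chunk$adr,
                                  chunk$chunk_index, label_mode),
               adr = chunk$adr, chunk = chunk$chunk_index,
               label_mode = label_mode, prediction_set = "validation",
               grouping = config$evaluate$grouping,
               stringsAsFactors = FALSE), ev)
  list(classifiers = classifiers, ensemble = ens, split = split,
       member_val_probs = val_probs, reports = do.call(rbind, reports))
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> clean -> label -> chunk/split -> train ->
#' ensemble -> validate (including time-shifted external validation) ->
#' held-out drug risk table, as one reproducible run driven by a single
#' configuration and master seed.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir optional output directory for reports CSV, risk table and
#'   manifest JSON.
#' @param adrs subset of ADRs to model (default: from config).
#' @param verbose print stage progress.
#' @return list with `reports` (tidy data.frame), `risk_table`, `manifest`,
#'   plus the fitted `models` and the preprocessing `prep` bundle.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         adrs = NULL, verbose = FALSE) {
  adrs <- adrs %||% config$label$adrs
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- cohort_spec_from_config(config)
  params <- preprocess_params_from_config(config)

  say("simulating and preprocessing %d recordings",
      spec$n_drugs * spec$datasets_per_drug)
  prep <- preprocess_cohort(spec, params, verbose = verbose)
  retained <- prep$report$dataset_id[prep$report$retained]
  if (!length(retained)) {
    stop("data cleaning excluded every dataset (NaN fractions above the ",
         "threshold); no inputs remain for modelling")
  }
  meta <- prep$design
  meta_retained <- meta[meta$dataset_id %in% retained, ]
  ann <- prep$annotations

  models <- list(); reports <- list(); risk <- NULL
  for (adr in adrs) {
    say("ADR %s: labelling and chunking", adr)
    drug_labels_chr <- assign_class(unique(meta$drug), adr, ann)
    drug_labels <- suppressWarnings(
      setNames(as.integer(drug_labels_chr), names(drug_labels_chr)))
    chunks <- make_balanced_chunks(meta_retained, adr, ann,
                                   config$label$n_chunks[[adr]] %||% 2L,
                                   config$seed)
    ensembles <- list()
    for (ch in chunks) {
      for (mode in config$train$label_modes) {
        say("ADR %s chunk %d [%s]: training %d x %s", adr, ch$chunk_index,
            mode, config$train$replicates, config$train$arch)
        fit <- train_chunk_models(ch, prep$matched, meta, drug_labels,
                                  config, mode)
        key <- sprintf("%s_chunk%d_%s", adr, ch$chunk_index, mode)
        models[[key]] <- fit
        reports[[length(reports) + 1]] <- fit$reports
        ts <- timeshift_validate(
          fit$classifiers, prep$matched, ch$dataset_ids, meta, drug_labels,
          adr = adr, chunk = ch$chunk_index, label_mode = mode,
          grouping = config$evaluate$grouping)
        reports[[length(reports) + 1]] <- ts
        if (mode == "correct") {
          ens_score <- fit$reports$score[
            fit$reports$prediction_set == "validation" &
              grepl("ensemble", fit$reports$model_id)]
          ensembles[[length(ensembles) + 1]] <- list(
            ensemble = fit$ensemble, members = fit$classifiers,
            score = ens_score, adr = adr, chunk = ch$chunk_index)
        }
      }
    }
    held <- names(drug_labels_chr)[drug_labels_chr == "held_out"]
    held_ids <- meta_retained$dataset_id[meta_retained$drug %in% held]
    if (length(held_ids) && length(ensembles)) {
      say("ADR %s: external prediction for %d held-out drugs", adr,
          length(held))
      rt <- external_drug_prediction(
        ensembles, prep$matched, held_ids, meta,
        top_k = config$evaluate$top_k,
        threshold = config$evaluate$risk_threshold)
      rt$adr <- adr
      risk <- rbind(risk, rt)
    }
  }
  reports <- do.call(rbind, reports)

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed, profile = config$profile,
    n_recordings = nrow(meta),
    n_retained = length(retained),
    n_excluded = nrow(meta) - length(retained),
    n_annotated_drugs = length(unique(ann$drug_id)),
    n_held_out_drugs = length(setdiff(unique(meta$drug),
                                      unique(ann$drug_id))),
    adrs = as.list(setNames(
      lapply(adrs, function(a) {
        sub <- reports[reports$adr == a, ]
        list(n_models = length(unique(sub$model_id)),
             n_reports = nrow(sub))
      }), adrs))
  )
  unlink(cfg_file)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(reports, file.path(out_dir, "reports.csv"), row.names = FALSE)
    if (!is.null(risk)) {
      write.csv(risk, file.path(out_dir, "risk_table.csv"),
                row.names = FALSE)
    }
    write.csv(prep$report, file.path(out_dir, "preprocessing_report.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(reports = reports, risk_table = risk, manifest = manifest,
       models = models, prep = prep, config = config)
}
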