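#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation with midrank tie correction:
#' `AUROC = (R1 - n1 (n1 + 1) / 2) / (n0 n1)` where `R1` is the rank sum of
#' the positive-class scores.
#'
#' @param scores numeric prediction scores (higher = more class 1).
#' @param labels 0/1 truth.
#' @return AUROC in `[0, 1]`, or NA when one class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Classification metrics and composite score
#'
#' Accuracy and class-1 precision at the 0.5 cutoff (probability >= 0.5 is
#' class 1), rank-based AUROC, and the composite
#' `score = (accuracy + precision_class1 + auroc) / 3`. Precision is NA when
#' nothing is predicted positive; AUROC is NA for one-class truth; the score
#' is the mean of the available components only when all three exist.
#'
#' @param p1 class-1 probabilities.
#' @param truth 0/1 truth labels.
#' @param cutoff classification cutoff (class 1 when `p1 >= cutoff`).
#' @return one-row data.frame: `accuracy`, `precision_class1`, `auroc`,
#'   `score`, `n`.
#' @export
evaluate_predictions <- function(p1, truth, cutoff = 0.5) {
  truth <- as.integer(truth)
  pred <- as.integer(p1 >= cutoff)
  acc <- mean(pred == truth)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  auc <- auroc(p1, truth)
  score <- if (anyNA(c(acc, prec, auc))) NA_real_ else (acc + prec + auc) / 3
  data.frame(accuracy = acc, precision_class1 = prec, auroc = auc,
             score = score, n = length(truth))
}

#' Composite model score
#'
#' `score = (accuracy + precision_class1 + auroc) / 3`, the ranking
#' statistic used to order trained models.
#'
#' @param accuracy,precision_class1,auroc metric values in `[0, 1]`.
#' @return the composite score.
#' @export
composite_score <- function(accuracy, precision_class1, auroc) {
  (accuracy + precision_class1 + auroc) / 3
}

#' ROC curve points
#'
#' @param p1 class-1 probabilities.
#' @param truth 0/1 truth labels.
#' @return data.frame with `threshold`, `fpr`, `tpr` (exportable curve).
#' @export
roc_points <- function(p1, truth) {
  truth <- as.integer(truth)
  th <- c(Inf, sort(unique(p1), decreasing = TRUE), -Inf)
  do.call(rbind, lapply(th, function(t) {
    pred <- p1 >= t
    data.frame(threshold = t,
               fpr = sum(pred & truth == 0) / max(1, sum(truth == 0)),
               tpr = sum(pred & truth == 1) / max(1, sum(truth == 1)))
  }))
}

#' Aggregate dataset predictions by drug
#'
#' The prediction probability of a drug is the arithmetic mean of its
#' datasets' class-1 probabilities, either across all datasets
#' (`grouping = "all"`) or clustered by tissue or concentration. The 0.5
#' cutoff assigns the predicted class (mean >= 0.5 is class 1).
#'
#' @param records data.frame with `dataset_id` and `p1`.
#' @param metadata data.frame with `dataset_id`, `drug`, `tissue`, `conc`.
#' @param grouping "all", "by_tissue" or "by_concentration".
#' @return data.frame with `drug`, `group`, `mean_p1`, `n_datasets`,
#'   `predicted_class`.
#' @export
aggregate_by_drug <- function(records, metadata,
                              grouping = c("all", "by_tissue",
                                           "by_concentration")) {
  grouping <- match.arg(grouping)
  i <- match(records$dataset_id, metadata$dataset_id)
  if (anyNA(i)) stop("unresolvable dataset ids in prediction records")
  df <- data.frame(drug = metadata$drug[i],
                   group = switch(grouping,
                                  all = "all",
                                  by_tissue = as.character(metadata$tissue[i]),
                                  by_concentration =
                                    as.character(metadata$conc[i])),
                   p1 = records$p1, stringsAsFactors = FALSE)
  agg <- aggregate(p1 ~ drug + group, df, mean)
  cnt <- aggregate(p1 ~ drug + group, df, length)
  out <- data.frame(drug = agg$drug, group = agg$group, mean_p1 = agg$p1,
                    n_datasets = cnt$p1,
                    predicted_class = as.integer(agg$p1 >= 0.5),
                    stringsAsFactors = FALSE)
  out[order(out$drug, out$group), ]
}

#' Fit the logistic-regression ensemble over five classifiers
#'
#' A logistic regression taking the five member classifiers' class-1
#' probabilities on the validation set as features and the validation
#' targets as response; members that are more accurate on validation
#' receive larger weights.
#'
#' @param member_probs matrix n_val x n_members of class-1 probabilities.
#' @param targets 0/1 validation targets.
#' @return an `sw_ensemble` with `coef` (intercept + member weights).
#' @export
fit_ensemble <- function(member_probs, targets) {
  targets <- as.integer(targets)
  if (length(unique(targets)) < 2) {
    stop("single-class validation targets: ensemble cannot be fitted")
  }
  member_probs <- as.matrix(member_probs)
  df <- as.data.frame(member_probs)
  names(df) <- paste0("m", seq_len(ncol(member_probs)))
  df$y <- targets
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  structure(list(coef = coef(fit), n_members = ncol(member_probs)),
            class = "sw_ensemble")
}

#' Ensemble class-1 probabilities
#'
#' @param ensemble an `sw_ensemble`.
#' @param member_probs matrix n x n_members of member class-1 probabilities.
#' @return numeric class-1 probabilities.
#' @export
predict_ensemble <- function(ensemble, member_probs) {
  member_probs <- as.matrix(member_probs)
  stopifnot(ncol(member_probs) == ensemble$n_members)
  co <- ensemble$coef
  co[is.na(co)] <- 0        # aliased members (perfect collinearity) drop out
  eta <- co[1] + member_probs %*% co[-1]
  as.numeric(plogis(eta))
}

#' Time-shifted external validation
#'
#' Evaluates every classifier on the forward- (490-690 s) and backward-
#' (510-710 s) shifted interference sets with by-drug aggregation, yielding
#' one report per (classifier, shifted set): 20 reports per ADR for two
#' chunks of five classifiers, 10 for a single-chunk ADR.
#'
#' @param classifiers named list of `sw_classifier` (names become
#'   `model_id`).
#' @param matched list of `sw_matched` keyed by dataset id.
#' @param dataset_ids datasets to evaluate on.
#' @param metadata cohort metadata (`dataset_id`, `drug`, `tissue`, `conc`).
#' @param drug_labels named 0/1 vector of drug-level truth.
#' @param adr,chunk,label_mode bookkeeping tags copied into the report.
#' @param grouping by-drug grouping mode.
#' @return data.frame of evaluation reports (one row per model x shift).
#' @export
timeshift_validate <- function(classifiers, matched, dataset_ids, metadata,
                               drug_labels, adr = NA, chunk = NA,
                               label_mode = "correct", grouping = "all") {
  out <- list()
  for (shift in c("forward", "backward")) {
    xs <- lapply(matched[dataset_ids], `[[`, shift)
    names(xs) <- dataset_ids
    i <- match(dataset_ids, metadata$dataset_id)
    for (mid in names(classifiers)) {
      pr <- predict_proba(classifiers[[mid]], xs, metadata$tissue[i],
                          metadata$conc[i])
      agg <- aggregate_by_drug(pr, metadata, grouping)
      truth <- drug_labels[agg$drug]
      ev <- evaluate_predictions(agg$mean_p1, truth)
      out[[length(out) + 1]] <- cbind(
        data.frame(model_id = mid, adr = adr, chunk = chunk,
                   label_mode = label_mode,
                   prediction_set = paste0(shift, "_shifted"),
                   grouping = grouping, stringsAsFactors = FALSE),
        ev)
    }
  }
  do.call(rbind, out)
}

#' Compare model-performance conditions
#'
#' Two-sided Student's t test (paired or unpaired) on a metric between two
#' report sets, with significance stars at 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param a,b numeric metric vectors.
#' @param paired paired test (requires aligned observations).
#' @return list with `statistic`, `p_value`, `direction` (sign of
#'   mean(a) - mean(b)), `stars`.
#' @export
compare_conditions <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires aligned observations")
  }
  eps <- 1e-10 * max(1, abs(mean(a)), abs(mean(b)))
  if (sd(c(a, b)) < eps || (paired && sd(a - b) < eps)) {
    delta <- mean(a) - mean(b)
    if (paired && sd(a - b) < eps && abs(delta) > eps) {
      # constant nonzero difference: direction certain, t degenerate
      return(list(statistic = sign(delta) * Inf, p_value = 0,
                  direction = sign(delta), stars = "****"))
    }
    return(list(statistic = 0, p_value = 1, direction = 0, stars = ""))
  }
  tt <- t.test(a, b, paired = paired)
  p <- tt$p.value
  stars <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 1e-2) "**" else if (p < 0.05) "*" else ""
  list(statistic = unname(tt$statistic), p_value = p,
       direction = sign(mean(a) - mean(b)), stars = stars)
}

#' One-way ANOVA with Tukey's HSD for >2 groups
#'
#' @param values numeric metric values.
#' @param groups group factor (e.g. tissue or concentration).
#' @return list with the ANOVA `p_value` and a data.frame `tukey` of
#'   pairwise comparisons (`diff`, `p_adj`, `stars`).
#' @export
compare_groups_tukey <- function(values, groups) {
  df <- data.frame(v = values, g = factor(groups))
  fit <- aov(v ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  stars <- vapply(tk[, "p adj"], function(p) {
    if (p < 1e-4) "****" else if (p < 1e-3) "***" else
      if (p < 1e-2) "**" else if (p < 0.05) "*" else ""
  }, "")
  list(p_value = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], stars = stars,
                          row.names = NULL))
}

#' Risk table for held-out drugs
#'
#' Predicts held-out drugs (never seen in training) with the top-k ensembles
#' ranked by score, averages class-1 probability per drug across all tissues
#' and concentrations, and flags risk at probability strictly greater than
#' 0.7.
#'
#' @param ensembles list of entries, each with `ensemble` (an
#'   `sw_ensemble`), `members` (named list of classifiers) and `score`.
#' @param matched list of `sw_matched` keyed by dataset id.
#' @param dataset_ids held-out dataset ids.
#' @param metadata cohort metadata.
#' @param top_k number of ensembles used (default 2, ties by list order).
#' @param threshold risk threshold (strict `>`).
#' @return data.frame with `drug`, `mean_p1`, `n_datasets`, `risk`.
#' @export
external_drug_prediction <- function(ensembles, matched, dataset_ids,
                                     metadata, top_k = 2, threshold = 0.7) {
  if (!length(dataset_ids)) stop("no held-out datasets supplied")
  ord <- order(-vapply(ensembles, `[[`, 0, "score"))
  use <- ensembles[ord[seq_len(min(top_k, length(ensembles)))]]
  xs <- lapply(matched[dataset_ids], `[[`, "interference")
  names(xs) <- dataset_ids
  i <- match(dataset_ids, metadata$dataset_id)
  p_sets <- lapply(use, function(e) {
    mp <- vapply(e$members, function(m) {
      predict_proba(m, xs, metadata$tissue[i], metadata$conc[i])$p1
    }, numeric(length(dataset_ids)))
    predict_ensemble(e$ensemble, mp)
  })
  p1 <- rowMeans(do.call(cbind, p_sets))
  agg <- aggregate_by_drug(
    data.frame(dataset_id = dataset_ids, p1 = p1), metadata, "all")
  data.frame(drug = agg$drug, mean_p1 = agg$mean_p1,
             n_datasets = agg$n_datasets, risk = agg$mean_p1 > threshold,
             stringsAsFactors = FALSE)
}
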