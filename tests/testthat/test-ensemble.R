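test_that("AUROC equals the Mann-Whitney statistic and handles ties", {
  set.seed(21)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(40), 2)      # ties likely
    # brute-force pairwise comparison probability with midrank ties
    pos <- s[y == 1]; neg <- s[y == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auroc(s, y), brute)
  }
  expect_true(is.na(auroc(runif(5), rep(1, 5))))
})

test_that("AUROC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60) + y
  ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
  expect_equal(auroc(s, y), ref, tolerance = 1e-12)
})

test_that("metrics follow their definitions at the 0.5 cutoff", {
  p1 <- c(0.9, 0.6, 0.5, 0.4, 0.2, 0.1)
  y <- c(1, 0, 1, 1, 0, 0)
  ev <- evaluate_predictions(p1, y)
  # cutoff is >=: 0.5 predicts class 1
  expect_equal(ev$accuracy, 4 / 6)
  expect_equal(ev$precision_class1, 2 / 3)
  expect_equal(ev$score, (ev$accuracy + ev$precision_class1 + ev$auroc) / 3)
  perfect <- evaluate_predictions(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision_class1, 1)
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$score, 1)
  # nothing predicted positive: precision undefined
  none <- evaluate_predictions(c(0.1, 0.2), c(0, 1))
  expect_true(is.na(none$precision_class1))
})

test_that("by-drug aggregation averages probabilities and applies >= 0.5", {
  meta <- data.frame(dataset_id = c("a1", "a2", "b1"),
                     drug = c("dA", "dA", "dB"),
                     tissue = c(1, 2, 2), conc = c(2, 2, 3),
                     stringsAsFactors = FALSE)
  rec <- data.frame(dataset_id = c("a1", "a2", "b1"), p1 = c(0.2, 0.8, 0.9),
                    stringsAsFactors = FALSE)
  agg <- aggregate_by_drug(rec, meta, "all")
  expect_equal(agg$mean_p1[agg$drug == "dA"], 0.5)
  expect_equal(agg$predicted_class[agg$drug == "dA"], 1L)  # >= 0.5 is class 1
  expect_equal(agg$mean_p1[agg$drug == "dB"], 0.9)
  expect_equal(agg$n_datasets, c(2, 1))
  # grouped means equal a brute-force groupby on random records
  set.seed(3)
  n <- 50
  meta2 <- data.frame(dataset_id = sprintf("d%02d", 1:n),
                      drug = sample(c("x", "y", "z"), n, TRUE),
                      tissue = sample(1:4, n, TRUE),
                      conc = sample(1:3, n, TRUE), stringsAsFactors = FALSE)
  rec2 <- data.frame(dataset_id = meta2$dataset_id, p1 = runif(n),
                     stringsAsFactors = FALSE)
  agg2 <- aggregate_by_drug(rec2, meta2, "by_tissue")
  for (r in seq_len(nrow(agg2))) {
    sel <- meta2$drug == agg2$drug[r] &
      as.character(meta2$tissue) == agg2$group[r]
    expect_equal(agg2$mean_p1[r], mean(rec2$p1[sel]))
    expect_equal(agg2$n_datasets[r], sum(sel))
  }
  # aggregation conservation: group sizes sum to the per-drug totals
  tot <- tapply(agg2$n_datasets, agg2$drug, sum)
  expect_equal(as.numeric(tot[c("x", "y", "z")]),
               as.numeric(table(meta2$drug)[c("x", "y", "z")]))
})

test_that("the logistic ensemble upweights the informative member", {
  set.seed(12)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  probs <- cbind(plogis(4 * (y - 0.5) + rnorm(n, sd = 0.5)),  # informative
                 matrix(runif(n * 4), n, 4))                  # noise
  ens <- fit_ensemble(probs, y)
  w <- ens$coef[-1]
  expect_equal(unname(which.max(abs(w))), 1)
  # deterministic refit
  expect_identical(ens$coef, fit_ensemble(probs, y)$coef)
  expect_error(fit_ensemble(probs, rep(1, n)), "single-class")
})

test_that("identical members yield a rank-preserving ensemble", {
  set.seed(2)
  y <- rbinom(80, 1, 0.5)
  p <- plogis(2 * (y - 0.5) + rnorm(80))
  probs <- cbind(p, p, p, p, p)
  ens <- fit_ensemble(probs, y)
  out <- predict_ensemble(ens, probs)
  expect_equal(order(out), order(p))
})

test_that("t-test comparisons behave at the boundaries and under power", {
  a <- c(1, 2, 3, 4)
  r <- compare_conditions(a, a)
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0)
  set.seed(6)
  r2 <- compare_conditions(rnorm(20, 3), rnorm(20, 0))
  expect_lt(r2$p_value, 0.001)
  expect_equal(r2$direction, 1)
  # paired constant difference: certain positive direction
  x <- rnorm(10)
  r3 <- compare_conditions(x + 2, x, paired = TRUE)
  expect_equal(r3$direction, 1)
  expect_lt(r3$p_value, 1e-4)
})

test_that("Tukey comparison flags the shifted group", {
  set.seed(4)
  v <- c(rnorm(15), rnorm(15), rnorm(15, 2))
  g <- rep(c("stomach", "duodenum", "colon"), each = 15)
  r <- compare_groups_tukey(v, g)
  expect_lt(r$p_value, 0.001)
  hit <- grepl("colon", r$tukey$comparison)
  expect_true(all(r$tukey$p_adj[hit] < 0.01))
  expect_true(all(r$tukey$stars[hit] != ""))
})

test_that("ROC curve runs from (0,0) to (1,1) and is monotone", {
  set.seed(5)
  y <- rbinom(30, 1, 0.5)
  p <- runif(30)
  rc <- roc_points(p, y)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})
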