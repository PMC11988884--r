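test_that("confusion matrix counts partition the predictions", {
  # 82-sample test set: 39 positives correct, 2 positives missed,
  # 1 negative misclassified, 40 negatives correct
  truth <- c(rep("pes_planus", 41), rep("not_pes_planus", 41))
  pred <- c(rep("pes_planus", 39), rep("not_pes_planus", 2),
            "pes_planus", rep("not_pes_planus", 40))
  cm <- confusion_matrix(truth, pred)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(39, 2, 1, 40))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 82)

  # all correct: no off-diagonal counts
  cm <- confusion_matrix(truth, truth)
  expect_equal(c(cm$fp, cm$fn), c(0, 0))
  expect_equal(cm$tp + cm$tn, 82)

  # swapping the positive class swaps tp<->tn and fp<->fn
  a <- confusion_matrix(truth, pred, positive = "pes_planus")
  b <- confusion_matrix(truth, pred, positive = "not_pes_planus")
  expect_equal(c(a$tp, a$fp, a$fn, a$tn), c(b$tn, b$fn, b$fp, b$tp))

  expect_vitelm_error(confusion_matrix(c("pes_planus", "flatfoot"),
                                       c("pes_planus", "pes_planus"),
                                       classes = c("pes_planus",
                                                   "not_pes_planus")),
                      "invalid_input")
  expect_vitelm_error(confusion_matrix(truth, pred[1:3]), "invalid_input")
})

test_that("metrics_from_cm implements the diagnostic formulas", {
  m <- metrics_from_cm(cm_from_counts(tp = 39, fp = 1, fn = 2, tn = 40))
  expect_equal(m$accuracy, 100 * 79 / 82, tolerance = 1e-12)
  expect_equal(m$sensitivity, 100 * 39 / 41, tolerance = 1e-12)
  expect_equal(m$specificity, 100 * 40 / 41, tolerance = 1e-12)
  expect_equal(m$recall, m$sensitivity)
  expect_equal(m$precision, 100 * 39 / 40, tolerance = 1e-12)
  expect_equal(m$f1, 100 * 2 * (39 / 40) * (39 / 41) / (39 / 40 + 39 / 41),
               tolerance = 1e-12)

  perfect <- metrics_from_cm(cm_from_counts(41, 0, 0, 41))
  expect_true(all(unlist(perfect) == 100))

  pooled <- metrics_from_cm(cm_from_counts(201, 4, 4, 201))
  expect_equal(pooled$accuracy, 100 * 402 / 410, tolerance = 1e-12)

  # zero denominators report 0 with a warning
  expect_warning(m0 <- metrics_from_cm(cm_from_counts(0, 0, 5, 5)),
                 "zero denominator")
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$f1, 0)

  expect_vitelm_error(metrics_from_cm(cm_from_counts(0, 0, 0, 0)),
                      "invalid_input")
})

test_that("fold plans are patient-disjoint partitions with a fixed test set", {
  # 12 patients x 2 images, one sixth held out: five folds of 2 patients
  pid <- rep(sprintf("P%02d", 1:12), each = 2)
  plan <- make_fold_plan(pid, k = 5, test_fraction = 1 / 6, seed = 4)
  expect_equal(lengths(plan$fold_patients), setNames(rep(2L, 5), 1:5))
  expect_length(plan$test_patients, 2L)

  # property loop: partition, disjointness, balance, determinism
  set.seed(31)
  for (i in 1:6) {
    n_pat <- sample(12:40, 1)
    k <- sample(2:5, 1)
    pats <- sprintf("Q%03d", seq_len(n_pat))
    pid <- rep(pats, each = 2)
    seed <- sample.int(1000, 1)
    plan <- make_fold_plan(pid, k = k, test_fraction = 0.15, seed = seed)
    folds <- plan$fold_patients
    all_cv <- unlist(folds, use.names = FALSE)
    expect_equal(sort(c(all_cv, plan$test_patients)), pats)
    expect_equal(anyDuplicated(c(all_cv, plan$test_patients)), 0L)
    expect_lte(diff(range(lengths(folds))), 1L)
    expect_length(intersect(plan$test_patients, all_cv), 0L)
    plan2 <- make_fold_plan(pid, k = k, test_fraction = 0.15, seed = seed)
    expect_identical(plan2$fold_patients, folds)
  }

  expect_vitelm_error(make_fold_plan(rep("A", 4), k = 2, test_fraction = 0),
                      "invalid_config")
})

test_that("aggregation uses the mean and population standard deviation", {
  t1 <- reported_table1()
  agg <- aggregate_metrics(t1[c("accuracy", "sensitivity")])
  expect_equal(agg$accuracy[1], 98.048, tolerance = 1e-3)
  # the printed fold values reproduce the reported spreads to 3 decimals
  expect_equal(round(agg$accuracy[2], 3), 0.976)
  expect_equal(round(agg$sensitivity[2], 3), 1.826)

  same <- metrics_from_cm(cm_from_counts(40, 1, 1, 40))
  agg <- aggregate_metrics(dplyr::bind_rows(same, same, same))
  expect_true(all(agg[agg$statistic == "sd", -1] == 0))

  expect_vitelm_error(aggregate_metrics(tibble::tibble()), "invalid_input")
})

test_that("cross-validation trains per fold and scores the fixed test set", {
  feats <- gen_feature_clusters(n = 72, d = 8, separation = 5, seed = 12)
  # grouped: pairs of rows share a patient
  feats$patient_id <- rep(sprintf("G%02d", 1:36), each = 2)
  plan <- make_fold_plan(feats$patient_id, k = 5, test_fraction = 1 / 6,
                         seed = 12)
  cv <- run_crossval(feats, plan,
                     oelm_config(L = 30, solver = "ridge", seed = 12))
  expect_equal(nrow(cv$per_fold), 5L)
  n_test <- sum(feats$patient_id %in% plan$test_patients)
  # every fold evaluates exactly the full fixed test set
  expect_equal(rowSums(cv$per_fold[c("tp", "fp", "fn", "tn")]),
               rep(n_test, 5))
  expect_equal(cv$summary$accuracy[1], mean(cv$per_fold$accuracy))

  # degenerate single-fold plan: summary equals the fold, sd 0
  plan1 <- make_fold_plan(feats$patient_id, k = 1, test_fraction = 1 / 6,
                          seed = 12)
  cv1 <- run_crossval(feats, plan1,
                      oelm_config(L = 30, solver = "ridge", seed = 12))
  expect_equal(cv1$summary$accuracy[1], cv1$per_fold$accuracy[1])
  expect_equal(cv1$summary$accuracy[2], 0)

  # a plan whose test set matches no sample is rejected
  plan_bad <- plan
  plan_bad$test_patients <- character(0)
  expect_vitelm_error(run_crossval(feats[feats$patient_id %in%
                                           unlist(plan$fold_patients), ],
                                   plan_bad,
                                   oelm_config(L = 5, solver = "ridge")),
                      "invalid_config")

  gl <- glance(cv)
  expect_equal(gl$k, 5L)
  expect_named(tidy(cv), names(cv$per_fold))
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("ROC/PR sweep matches trapezoid and Mann-Whitney oracles", {
  # perfectly separated scores
  truth <- rep(c("pes_planus", "not_pes_planus"), each = 5)
  curves <- roc_pr_curves(c(runif(5, 0.8, 1), runif(5, 0, 0.2)), truth)
  expect_equal(curves$auc_roc, 1)
  expect_equal(curves$roc$fpr[1], 0)
  expect_equal(curves$roc$tpr[1], 0)
  expect_equal(unlist(tail(curves$roc, 1)[c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))

  # uninformative scores
  curves <- roc_pr_curves(rep(0.5, 10), truth)
  expect_equal(curves$auc_roc, 0.5)

  # 6-sample hand case: AUC = concordant pairs / (n_pos * n_neg),
  # counted exhaustively with half credit for ties
  scores <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  truth6 <- c("pes_planus", "pes_planus", "not_pes_planus",
              "pes_planus", "not_pes_planus", "not_pes_planus")
  pos <- scores[truth6 == "pes_planus"]
  neg <- scores[truth6 == "not_pes_planus"]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + (p > q) + 0.5 * (p == q)
  }
  curves <- roc_pr_curves(scores, truth6)
  expect_equal(curves$auc_roc, conc / (length(pos) * length(neg)))

  # property: agreement with the Mann-Whitney normalisation on random draws
  set.seed(77)
  for (i in 1:5) {
    n <- sample(8:20, 1)
    truth_r <- sample(rep(c("pes_planus", "not_pes_planus"), length.out = n))
    scores_r <- round(runif(n), 2) # ties likely
    pos <- scores_r[truth_r == "pes_planus"]
    neg <- scores_r[truth_r == "not_pes_planus"]
    u <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_pr_curves(scores_r, truth_r)$auc_roc, u,
                 tolerance = 1e-12)
  }

  expect_vitelm_error(roc_pr_curves(runif(4), rep("pes_planus", 4)),
                      "invalid_input")
  expect_vitelm_error(roc_pr_curves(c(0.2, 1.4), c("pes_planus",
                                                   "not_pes_planus")),
                      "invalid_input")

  expect_s3_class(autoplot(curves, "roc"), "ggplot")
  expect_s3_class(autoplot(curves, "pr"), "ggplot")
  expect_named(glance(curves), c("auc_roc", "auc_pr"))
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(88)
  for (i in 1:3) {
    n <- 30
    truth <- sample(rep(c("pes_planus", "not_pes_planus"), 15))
    scores <- runif(n)
    ours <- roc_pr_curves(scores, truth)$auc_roc
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(truth, scores, levels = c("not_pes_planus", "pes_planus"),
                direction = "<")
    )))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("cv summaries export per-fold rows plus aggregates", {
  feats <- gen_feature_clusters(n = 48, d = 6, separation = 5, seed = 13)
  feats$patient_id <- rep(sprintf("H%02d", 1:24), each = 2)
  plan <- make_fold_plan(feats$patient_id, k = 3, test_fraction = 0.2,
                         seed = 13)
  cv <- run_crossval(feats, plan, oelm_config(L = 10, solver = "ridge"))
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_cv_summary(cv, csv_path = csv, json_path = json)
  tab <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(tab), 3 + 2) # folds + mean + sd
  expect_equal(tab$fold, c("1", "2", "3", "mean", "sd"))
  js <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(js$n_test, cv$n_test)
  expect_equal(nrow(js$per_fold), 3)
})
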