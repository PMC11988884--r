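# Diagnostic evaluation: confusion-matrix metrics, patient-grouped k-fold
# cross-validation with a fixed held-out test set, mean +/- population-sd
# aggregation, and threshold-sweep ROC / precision-recall curves.

METRIC_NAMES <- c("accuracy", "sensitivity", "specificity", "recall",
                  "precision", "f1")

#' Binary confusion matrix
#'
#' @param truth,predicted Equal-length label vectors drawn from the two
#'   known classes.
#' @param positive The positive class (default `"pes_planus"`).
#' @param classes Optional explicit class pair; derived from the labels
#'   otherwise.
#' @return A `confusion_matrix` object with counts `tp`, `fp`, `fn`, `tn`
#'   (their sum is the number of samples).
#' @export
confusion_matrix <- function(truth, predicted, positive = "pes_planus",
                             classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort_vitelm("`truth` and `predicted` must have equal length",
                 "invalid_input")
  }
  classes <- classes %||% {
    u <- unique(c(truth, predicted, positive))
    if (all(u %in% DEFAULT_CLASSES)) DEFAULT_CLASSES else sort(u)
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0 || length(classes) != 2L || !positive %in% classes) {
    abort_vitelm("labels must be drawn from the two known classes",
                 "invalid_input")
  }
  pos_t <- truth == positive
  pos_p <- predicted == positive
  structure(
    list(tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
         fn = sum(pos_t & !pos_p), tn = sum(!pos_t & !pos_p),
         positive = positive, classes = classes),
    class = "confusion_matrix"
  )
}

#' Build a confusion matrix directly from counts
#'
#' Convenience constructor for reported count tables.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @inheritParams confusion_matrix
#' @return A `confusion_matrix` object.
#' @export
cm_from_counts <- function(tp, fp, fn, tn, positive = "pes_planus",
                           classes = DEFAULT_CLASSES) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != trunc(counts))) {
    abort_vitelm("counts must be non-negative integers", "invalid_input")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, positive = positive,
                 classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive = %s\n", x$positive))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(paste("true", c("pos", "neg")),
                              paste("pred", c("pos", "neg"))))
  print(m)
  invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/n`, sensitivity (= recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, and F1
#' `2*Pre*Rec/(Pre+Rec)`, all as percentages in `[0, 100]`. A zero
#' denominator yields 0 with a warning.
#'
#' @param cm A [confusion_matrix()] with at least one sample.
#' @return One-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `recall`, `precision`, `f1`.
#' @export
metrics_from_cm <- function(cm) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0) abort_vitelm("confusion matrix has no samples", "invalid_input")
  rate <- function(num, den, what) {
    if (den == 0) {
      warn(paste0("zero denominator for ", what, "; reporting 0"))
      return(0)
    }
    num / den
  }
  sens <- rate(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- rate(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- rate(cm$tp, cm$tp + cm$fp, "precision")
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  tibble(
    accuracy = 100 * (cm$tp + cm$tn) / n,
    sensitivity = 100 * sens, specificity = 100 * spec,
    recall = 100 * sens, precision = 100 * prec, f1 = 100 * f1
  )
}

#' Patient-grouped fold plan with a fixed held-out test set
#'
#' Shuffles the unique patients under `seed`, reserves a test set (explicit
#' patient ids or a fraction of patients), and partitions the remaining
#' patients into `k` folds balanced in patient count to within one. Grouping
#' is by patient, so no patient's images ever straddle partitions, and the
#' test set never intersects any CV fold.
#'
#' @param patient_id Character vector of per-sample patient ids, or a tibble
#'   with a `patient_id` column.
#' @param k Number of CV folds.
#' @param test_fraction Fraction of patients reserved for the fixed test set
#'   (ignored when `test_patients` is given).
#' @param test_patients Optional explicit test-set patient ids.
#' @param seed Shuffle seed.
#' @return A `fold_plan` with `k`, `fold_patients` (list of k disjoint
#'   character vectors) and `test_patients`.
#' @export
make_fold_plan <- function(patient_id, k = 5L, test_fraction = 0.1,
                           test_patients = NULL, seed = NULL) {
  if (is.data.frame(patient_id)) patient_id <- patient_id$patient_id
  pats <- unique(as.character(patient_id))
  if (!is_count(k)) abort_vitelm("`k` must be a positive integer", "invalid_config")
  shuffled <- with_opt_seed(seed %||% 1L, sample(pats))
  if (is.null(test_patients)) {
    n_test <- ceiling(test_fraction * length(pats))
    test_patients <- head(shuffled, n_test)
  } else {
    test_patients <- as.character(test_patients)
    if (!all(test_patients %in% pats)) {
      abort_vitelm("unknown patient id in `test_patients`", "invalid_config")
    }
  }
  cv <- setdiff(shuffled, test_patients)
  if (k > length(cv)) {
    abort_vitelm("not enough patients for k nonempty folds after the test set",
                 "invalid_config")
  }
  fold_id <- rep_len(seq_len(k), length(cv))
  structure(
    list(k = as.integer(k),
         fold_patients = split(cv, fold_id),
         test_patients = test_patients,
         seed = seed),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds (%s patients) + fixed test set (%d patients)\n",
              x$k, paste(lengths(x$fold_patients), collapse = "/"),
              length(x$test_patients)))
  invisible(x)
}

#' Aggregate per-fold metric reports
#'
#' Arithmetic mean and population standard deviation (divisor `k`) per
#' metric -- the convention under which the study's printed fold accuracies
#' reproduce their reported spread.
#'
#' @param reports Tibble of per-fold metric rows (as from
#'   [metrics_from_cm()]).
#' @return Tibble with a `statistic` column (`"mean"`, `"sd"`) and one
#'   column per metric.
#' @export
aggregate_metrics <- function(reports) {
  if (NROW(reports) == 0) abort_vitelm("no reports to aggregate", "invalid_input")
  cols <- intersect(METRIC_NAMES, names(reports))
  m <- colMeans(reports[cols])
  s <- vapply(reports[cols], function(x) sqrt(mean((x - mean(x))^2)),
              numeric(1))
  bind_cols(tibble(statistic = c("mean", "sd")),
            as_tibble(rbind(m, s)))
}

#' Patient-grouped cross-validation with a fixed test set
#'
#' For each of the plan's `k` folds, trains the ELM head on the other
#' `k - 1` folds with the fold itself as the early-stopping validation set
#' (closed-form solvers ignore the validation part), then evaluates on the
#' plan's FIXED test set -- every fold scores the same held-out patients, as
#' in the study protocol. Each fold is trained from scratch with its own
#' derived seed.
#'
#' @param data Feature tibble with `f1, f2, ...` columns plus `label` and
#'   `patient_id`.
#' @param plan A [make_fold_plan()] covering `data`'s patients.
#' @param config An [oelm_config()].
#' @param positive Positive class for the confusion matrices.
#' @param classes Class order (default derived from the labels).
#' @return A `cv_result` with `per_fold` (fold counts + metrics tibble),
#'   `confusions` (list of k confusion matrices), `summary`
#'   (mean/population-sd rows), and bookkeeping fields.
#' @export
run_crossval <- function(data, plan, config = oelm_config(),
                         positive = "pes_planus", classes = NULL) {
  pid <- as.character(data$patient_id)
  known <- c(unlist(plan$fold_patients, use.names = FALSE), plan$test_patients)
  if (!all(pid %in% known)) {
    abort_vitelm("fold plan does not cover every patient in `data`",
                 "invalid_config")
  }
  test_idx <- pid %in% plan$test_patients
  if (!any(test_idx)) abort_vitelm("empty test set", "invalid_config")
  classes <- classes %||% default_classes(data$label)
  base_seed <- config$seed %||% 1L
  folds <- seq_len(plan$k)
  per_fold <- vector("list", plan$k)
  confusions <- vector("list", plan$k)
  fits <- vector("list", plan$k)
  test_data <- data[test_idx, ]
  for (f in folds) {
    val_idx <- pid %in% plan$fold_patients[[f]]
    train_idx <- !test_idx & !val_idx
    # degenerate k = 1 plan: the single fold is both train and monitor set
    if (plan$k == 1L) train_idx <- val_idx
    cfg <- config
    cfg$seed <- base_seed + f
    fit <- oelm(data[train_idx, ], validation = data[val_idx, ],
                config = cfg, classes = classes)
    pred <- predict(fit, test_data)
    cm <- confusion_matrix(test_data$label, pred$.pred_class,
                           positive = positive, classes = classes)
    confusions[[f]] <- cm
    fits[[f]] <- fit
    per_fold[[f]] <- bind_cols(
      tibble(fold = f, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn),
      metrics_from_cm(cm)
    )
  }
  per_fold <- list_rbind(per_fold)
  structure(
    list(per_fold = per_fold,
         confusions = confusions,
         summary = aggregate_metrics(per_fold),
         plan = plan, config = config, classes = classes,
         positive = positive, n_test = sum(test_idx), fits = fits),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, fixed test set of %d images\n",
              x$plan$k, x$n_test))
  print(x$per_fold[, c("fold", METRIC_NAMES)])
  cat("\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @export
glance.cv_result <- function(x, ...) {
  m <- x$summary[x$summary$statistic == "mean", METRIC_NAMES]
  s <- x$summary[x$summary$statistic == "sd", METRIC_NAMES]
  names(s) <- paste0(METRIC_NAMES, "_sd")
  bind_cols(tibble(k = x$plan$k, n_test = x$n_test), m, s)
}

#' Plot per-fold metrics of a cross-validation result
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot with one panel per metric, fold values as points and the
#'   mean as a dashed line.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_fold[, c("fold", METRIC_NAMES)],
                            all_of(METRIC_NAMES),
                            names_to = "metric", values_to = "value")
  means <- tidyr::pivot_longer(
    object$summary[object$summary$statistic == "mean", METRIC_NAMES],
    all_of(METRIC_NAMES), names_to = "metric", values_to = "mean")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$mean), linetype = 2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = "% on fixed test set") +
    ggplot2::theme_minimal()
}

#' Export a cross-validation summary
#'
#' Writes the per-fold metric rows followed by mean and population-sd rows
#' as CSV, and the same content as JSON.
#'
#' @param x A `cv_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_cv_summary <- function(x, csv_path = NULL, json_path = NULL) {
  folds <- x$per_fold[, c("fold", METRIC_NAMES)]
  folds$fold <- as.character(folds$fold)
  agg <- x$summary
  names(agg)[names(agg) == "statistic"] <- "fold"
  out <- bind_rows(folds, agg)
  if (!is.null(csv_path)) readr::write_csv(out, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_fold = x$per_fold, summary = x$summary, n_test = x$n_test),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(x)
}

#' ROC and precision-recall curves by threshold sweep
#'
#' Sweeps a "predict positive when score >= t" rule over the distinct scores
#' (plus sentinels so the ROC runs from (0,0) to (1,1)) and integrates both
#' curves by the trapezoidal rule. Tied scores collapse onto single sweep
#' points, so the ROC area equals the Mann-Whitney concordance probability
#' with the usual half-credit for ties.
#'
#' @param scores Positive-class scores in `[0, 1]`.
#' @param truth Labels; both classes must be present.
#' @param positive Positive class.
#' @return A `classifier_curves` object: tibbles `roc` (threshold, fpr, tpr)
#'   and `pr` (threshold, recall, precision), plus `auc_roc` and `auc_pr`.
#' @export
roc_pr_curves <- function(scores, truth, positive = "pes_planus") {
  truth <- as.character(truth)
  if (length(scores) != length(truth)) {
    abort_vitelm("`scores` and `truth` must have equal length", "invalid_input")
  }
  if (any(scores < -1e-9) || any(scores > 1 + 1e-9)) {
    abort_vitelm("scores must lie in [0, 1]", "invalid_input")
  }
  is_pos <- truth == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    abort_vitelm("both classes must be present", "invalid_input")
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sweep_pt <- function(t) {
    pred_pos <- scores >= t
    tp <- sum(pred_pos & is_pos); fp <- sum(pred_pos & !is_pos)
    c(tpr = tp / n_pos, fpr = fp / n_neg,
      precision = if (tp + fp == 0) 1 else tp / (tp + fp))
  }
  pts <- t(vapply(thresholds, sweep_pt, numeric(3)))
  roc <- tibble(threshold = thresholds, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  if (tail(roc$fpr, 1) < 1 || tail(roc$tpr, 1) < 1) {
    roc <- bind_rows(roc, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  auc_roc <- trapezoid(roc$fpr, roc$tpr)
  pr <- tibble(threshold = thresholds, recall = pts[, "tpr"],
               precision = pts[, "precision"])
  auc_pr <- trapezoid(pr$recall, pr$precision)
  structure(list(roc = roc, pr = pr, auc_roc = auc_roc, auc_pr = auc_pr,
                 positive = positive),
            class = "classifier_curves")
}

#' @export
print.classifier_curves <- function(x, ...) {
  cat(sprintf("<classifier_curves> ROC AUC %.4f, PR AUC %.4f (%d thresholds)\n",
              x$auc_roc, x$auc_pr, nrow(x$pr)))
  invisible(x)
}

#' @export
tidy.classifier_curves <- function(x, ...) {
  bind_rows(
    mutate(setNames(x$roc, c("threshold", "x", "y")), curve = "roc"),
    mutate(setNames(x$pr, c("threshold", "x", "y")), curve = "pr")
  )
}

#' @export
glance.classifier_curves <- function(x, ...) {
  tibble(auc_roc = x$auc_roc, auc_pr = x$auc_pr)
}

#' Plot ROC or precision-recall curve
#'
#' @param object A `classifier_curves` object.
#' @param curve `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classifier_curves <- function(object, curve = c("roc", "pr"), ...) {
  curve <- match.arg(curve)
  if (curve == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = 3) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    title = sprintf("ROC (AUC = %.3f)", object$auc_roc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall,
                                            y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "recall", y = "precision",
                    title = sprintf("Precision-Recall (AUC = %.3f)",
                                    object$auc_pr)) +
      ggplot2::theme_minimal()
  }
}
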