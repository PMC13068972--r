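# Evaluation primitives for binary benign/malignant classification.
# Malignant is the positive class throughout; all metrics are kept at full
# precision internally and only rounded by reporting helpers.

CLASSES <- c("benign", "malignant")

as_class <- function(x) {
  if (is.numeric(x)) x <- CLASSES[x]
  x <- as.character(x)
  if (!all(x %in% CLASSES))
    stop_gwovit("labels must be 'benign' or 'malignant'", "bad_labels")
  x
}

#' Confusion matrix for benign/malignant labels
#'
#' Benign is the negative class, malignant the positive class.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return object of class `confusion_matrix` with counts tn, fp, fn, tp.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as_class(y_true); y_pred <- as_class(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  structure(list(tn = sum(y_true == "benign" & y_pred == "benign"),
                 fp = sum(y_true == "benign" & y_pred == "malignant"),
                 fn = sum(y_true == "malignant" & y_pred == "benign"),
                 tp = sum(y_true == "malignant" & y_pred == "malignant"),
                 total = length(y_true)),
            class = "confusion_matrix")
}

#' @export
as.matrix.confusion_matrix <- function(x, ...) {
  matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
         dimnames = list(truth = CLASSES, predicted = CLASSES))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`, with the 0/0 convention F1 = 0.
#'
#' @param precision,recall values in \[0, 1\].
#' @return F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Per-class precision/recall/F1 and overall accuracy
#'
#' Malignant metrics use tp/fp/fn directly; benign metrics are the symmetric
#' counts. Zero-denominator cases return 0 and set the `degenerate` flag.
#'
#' @param cm a [confusion()] matrix.
#' @return object of class `class_metrics`: data.frame (class, precision,
#'   recall, f1) plus `accuracy` and `degenerate` attributes.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"), cm$total > 0)
  p_mal <- safe_div(cm$tp, cm$tp + cm$fp)
  r_mal <- safe_div(cm$tp, cm$tp + cm$fn)
  p_ben <- safe_div(cm$tn, cm$tn + cm$fn)
  r_ben <- safe_div(cm$tn, cm$tn + cm$fp)
  degenerate <- any(c(cm$tp + cm$fp, cm$tp + cm$fn, cm$tn + cm$fn,
                      cm$tn + cm$fp) == 0)
  df <- data.frame(class = CLASSES,
                   precision = c(p_ben, p_mal),
                   recall = c(r_ben, r_mal),
                   f1 = c(f1_score(p_ben, r_ben), f1_score(p_mal, r_mal)))
  structure(df, accuracy = (cm$tp + cm$tn) / cm$total, degenerate = degenerate,
            class = c("class_metrics", "data.frame"))
}

#' ROC curve and AUC
#'
#' Thresholds sweep the unique scores in descending order (equal scores are
#' grouped into a single step); AUC is computed by the trapezoid rule.
#'
#' @param y_true labels.
#' @param malignant_scores scores for the positive (malignant) class.
#' @return object of class `roc_curve`: data.frame (threshold, fpr, tpr)
#'   from (0,0) to (1,1), with an `auc` attribute.
#' @export
roc <- function(y_true, malignant_scores) {
  y <- as_class(y_true) == "malignant"
  stopifnot(all(is.finite(malignant_scores)),
            length(y) == length(malignant_scores))
  np <- sum(y); nn <- sum(!y)
  th <- sort(unique(malignant_scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) sum(y & malignant_scores >= t), 0)) /
    max(np, 1)
  fpr <- c(0, vapply(th, function(t) sum(!y & malignant_scores >= t), 0)) /
    max(nn, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(data.frame(threshold = c(Inf, th), fpr = fpr, tpr = tpr),
            auc = auc, class = c("roc_curve", "data.frame"))
}

#' Paired t-test on matched per-fold scores
#'
#' Two-sided paired t-test with the sample (n-1) standard deviation:
#' `t = mean(d) / (sd(d) / sqrt(n))`. Zero-variance differences flag the
#' result as degenerate instead of dividing by zero.
#'
#' @param a,b equal-length numeric score vectors (e.g. fold accuracies).
#' @return object of class `paired_ttest`: list with mean_difference,
#'   t_value, p_value, degrees_of_freedom, degenerate.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d < .Machine$double.eps * max(1, abs(mean(d)))) {
    return(structure(list(mean_difference = mean(d), t_value = NA_real_,
                          p_value = NA_real_, degrees_of_freedom = n - 1L,
                          degenerate = TRUE),
                     class = "paired_ttest"))
  }
  t_val <- mean(d) / (sd_d / sqrt(n))
  structure(list(mean_difference = mean(d), t_value = t_val,
                 p_value = 2 * stats::pt(-abs(t_val), df = n - 1),
                 degrees_of_freedom = n - 1L, degenerate = FALSE),
            class = "paired_ttest")
}

#' Mean and standard deviation of fold columns
#'
#' Reproduces the summary rows of published cross-validation tables: the
#' arithmetic mean and sample standard deviation of each numeric column,
#' rounded only at reporting precision.
#'
#' @param folds data.frame of per-fold metric columns.
#' @param digits reporting precision (default 1, the percent-scale table
#'   format).
#' @return data.frame with `mean` and `sd` rows (full precision) and a
#'   `rounded` attribute at the reporting precision.
#' @export
fold_summary <- function(folds, digits = 1) {
  num <- folds[vapply(folds, is.numeric, TRUE)]
  s <- data.frame(statistic = c("mean", "sd"),
                  rbind(colMeans(num), vapply(num, stats::sd, numeric(1))))
  names(s)[-1] <- names(num)
  attr(s, "rounded") <- cbind(s[1], round(s[-1], digits))
  s
}

# ---- stratified k-fold cross-validation -------------------------------------

make_stratified_folds <- function(manifest, k, seed) {
  fold <- integer(nrow(manifest))
  strata <- unique(manifest[, c("magnification", "class_label")])
  strata <- strata[order(strata$magnification, strata$class_label), ]
  for (s in seq_len(nrow(strata))) {
    idx <- which(manifest$magnification == strata$magnification[s] &
                   manifest$class_label == strata$class_label[s])
    if (length(idx) < k)
      stop_gwovit("stratum smaller than k; cannot build folds", "small_stratum")
    idx <- idx[order(manifest$path[idx])]
    perm <- with_seed(stream_seed(seed, "cv", strata$magnification[s],
                                  strata$class_label[s]),
                      sample(length(idx)))
    fold[idx[perm]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified within (magnification, class). Each fold trains on
#' the remaining k-1 folds — with an inner stratified validation carve-out —
#' and is scored on the held-out fold. The model contract is a factory:
#' `model_factory(train_rows, val_rows, tcfg)` must return a predictor
#' `function(rows) -> label vector`.
#'
#' @param manifest a `dataset_manifest`.
#' @param k folds (>= 2).
#' @param model_factory see above.
#' @param tcfg passed through to the factory (e.g. a [train_config()]).
#' @param seed fold-assignment seed.
#' @param val_fraction inner validation share of the training portion.
#' @return object of class `cv_report`: data.frame of per-fold train/val/test
#'   accuracy, test precision and F1 (percent scale), with `summary` rows.
#' @export
kfold_cv <- function(manifest, k = 5, model_factory, tcfg = NULL, seed = 42L,
                     val_fraction = 0.15) {
  stopifnot(k >= 2)
  fold <- make_stratified_folds(manifest, k, seed)
  rows <- list()
  for (f in seq_len(k)) {
    test <- manifest[fold == f, , drop = FALSE]
    rest <- manifest[fold != f, , drop = FALSE]
    n_val <- max(1L, round(val_fraction * nrow(rest)))
    vidx <- with_seed(stream_seed(seed, "cv-val", f),
                      sample(nrow(rest), n_val))
    val <- rest[vidx, , drop = FALSE]
    train <- rest[-vidx, , drop = FALSE]
    predictor <- model_factory(train, val, tcfg)
    acc <- function(part) mean(predictor(part) == part$class_label)
    cm <- confusion(test$class_label, predictor(test))
    m <- class_metrics(cm)
    rows[[f]] <- data.frame(fold = f,
                            train = 100 * acc(train),
                            val = 100 * acc(val),
                            test = 100 * attr(m, "accuracy"),
                            precision = 100 * m$precision[m$class == "malignant"],
                            f1 = 100 * m$f1[m$class == "malignant"])
  }
  report <- do.call(rbind, rows)
  structure(report, summary = fold_summary(report[-1]),
            class = c("cv_report", "data.frame"))
}
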