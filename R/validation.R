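#' Confusion matrix constructor
#'
#' Counts are stored with **rows = predicted** class and **columns =
#' observed** class, the orientation used throughout the package's reports.
#'
#' @param counts Square matrix of non-negative integer counts with matching
#'   row/column names, or dimnames supplied via `classes`.
#' @param classes Optional class labels (in order) if `counts` is unnamed.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, classes = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(classes)) dimnames(counts) <- list(classes, classes)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry class names (or pass `classes`)")
  if (nrow(counts) != ncol(counts) ||
      !identical(rownames(counts), colnames(counts)))
    stop("counts must be square with identical row and column classes")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = predicted, columns = observed\n")
  print(unclass(x))
  invisible(x)
}

#' Leave-one-out cross-validation of the quadratic discriminant classifier
#'
#' For each epoch in turn, fits the discriminant model on all remaining
#' epochs and predicts the held-out one; predictions are tallied into a
#' confusion matrix (rows predicted, columns observed). Deterministic given
#' its inputs. Folds in which some class would drop below 2 training rows
#' are counted and, if any exist, the run aborts reporting how many.
#'
#' @param fm A `feature_matrix`; every class must have at least 3 rows.
#' @param feature_subset Feature columns the classifier uses.
#' @param shrinkage,priors Passed to [fit_qda()].
#' @return A [confusion_matrix()] over the classes present, in canonical
#'   behaviour order.
#' @export
loocv <- function(fm, feature_subset, shrinkage = 1e-6,
                  priors = "frequency") {
  labels <- fm$behaviour
  classes <- intersect(BEHAVIOURS, unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes for validation")
  tab <- table(labels)
  if (min(tab) < 3)
    stop(sprintf(
      "every class needs >= 3 rows for leave-one-out; smallest is '%s' (%d)",
      names(tab)[which.min(tab)], min(tab)))
  n <- nrow(fm)
  untrainable <- 0L
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    train <- fm[-i, , drop = FALSE]
    if (min(table(train$behaviour)) < 2) {
      untrainable <- untrainable + 1L
      next
    }
    model <- fit_qda(train, feature_subset, shrinkage = shrinkage,
                     priors = priors)
    pred[i] <- predict_qda(model, fm[i, , drop = FALSE])$class
  }
  if (untrainable > 0)
    stop(sprintf("%d fold(s) untrainable: a class fell below 2 training rows",
                 untrainable))
  counts <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (i in seq_len(n)) counts[pred[i], labels[i]] <- counts[pred[i], labels[i]] + 1
  confusion_matrix(counts)
}

#' Per-class prediction accuracy
#'
#' The fraction of observed events of a class that were predicted as that
#' class: the diagonal count over the observed-column total. Identical to
#' one-vs-rest sensitivity.
#'
#' @param cm A [confusion_matrix()].
#' @param observed_class One class name, or `NULL` for all classes.
#' @return Named numeric fraction(s); a class observed zero times yields
#'   `NA` (undefined, not 0).
#' @export
prediction_accuracy <- function(cm, observed_class = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  classes <- colnames(cm)
  if (is.null(observed_class)) observed_class <- classes
  stopifnot(all(observed_class %in% classes))
  out <- vapply(observed_class, function(c) {
    tot <- sum(cm[, c])
    if (tot == 0) NA_real_ else cm[c, c] / tot
  }, numeric(1))
  out
}

#' One-vs-rest performance statistics from a confusion matrix
#'
#' For each class `c`: `TP = counts[c, c]`; `FN` = other predictions of
#' observed `c`; `FP` = predictions of `c` for other observed classes;
#' `TN` = everything else. Then
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and precision `TP/(TP+FP)`. Specificity uses the
#' standard true-negative-rate definition. Divisions by zero are reported
#' as `NA` (missing). The per-observed-class prediction accuracy is carried
#' alongside; it coincides with sensitivity by construction.
#'
#' @param cm A [confusion_matrix()] with a positive total.
#' @param percent If `TRUE`, also attach integer percentage columns
#'   (`*_pct`), rounded half away from zero as in the printed reference
#'   tables.
#' @return A data frame of class `performance_report`, one row per class.
#' @export
performance <- function(cm, percent = TRUE) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is all zero")
  classes <- colnames(cm)
  frac <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  rows <- lapply(classes, function(c) {
    TP <- cm[c, c]
    FN <- sum(cm[, c]) - TP
    FP <- sum(cm[c, ]) - TP
    TN <- total - TP - FN - FP
    data.frame(
      class = c, TP = TP, FP = FP, FN = FN, TN = TN,
      sensitivity = frac(TP, TP + FN),
      specificity = frac(TN, TN + FP),
      accuracy = frac(TP + TN, total),
      precision = frac(TP, TP + FP),
      prediction_accuracy = frac(TP, TP + FN)
    )
  })
  rep <- do.call(rbind, rows)
  if (percent) {
    for (m in c("sensitivity", "specificity", "accuracy", "precision",
                "prediction_accuracy"))
      rep[[paste0(m, "_pct")]] <- round_half_up(100 * rep[[m]])
  }
  rownames(rep) <- NULL
  class(rep) <- c("performance_report", "data.frame")
  rep
}

#' Run a full behaviour-classification analysis
#'
#' The end-to-end modelling sequence on an extracted feature matrix:
#' restrict to the analysis class set (Analysis I keeps lame walking and
#' lame grazing; Analysis II drops lame grazing), rank the fourteen features
#' by random-forest Gini importance, select the top `k`, run leave-one-out
#' cross-validation of the quadratic discriminant classifier on that subset,
#' and compute confusion-matrix performance statistics. Classes from the
#' analysis set that are absent from the data (e.g. no lying epochs in an
#' ear deployment) are dropped with a warning.
#'
#' @param fm A `feature_matrix`.
#' @param analysis `"I"` or `"II"`.
#' @param k Number of top-ranked features for the classifier (default 3).
#' @param ranking A [ranking_config()].
#' @param shrinkage,priors Passed to [fit_qda()] in every fold.
#' @return An `analysis_report` list: `$analysis`, `$classes`, `$ranking`,
#'   `$selected`, `$confusion`, `$performance`, `$config`.
#' @export
run_analysis <- function(fm, analysis = c("II", "I"), k = 3,
                         ranking = ranking_config(), shrinkage = 1e-6,
                         priors = "frequency") {
  analysis <- match.arg(analysis)
  wanted <- analysis_classes(analysis)
  absent <- setdiff(wanted, unique(fm$behaviour))
  if (length(absent))
    warning(sprintf("class(es) absent from data, dropped: %s",
                    paste(absent, collapse = ", ")))
  sub <- apply_analysis(fm, analysis)
  if (nrow(sub) == 0) stop("no rows left after analysis class restriction")
  rk <- rank_features(sub, config = ranking)
  selected <- top_k(rk, k)
  cm <- loocv(sub, selected, shrinkage = shrinkage, priors = priors)
  structure(
    list(analysis = analysis,
         classes = colnames(cm),
         ranking = rk,
         selected = selected,
         confusion = cm,
         performance = performance(cm),
         config = list(k = k, shrinkage = shrinkage, priors = priors,
                       ranking = unclass(ranking))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> Analysis %s, %d classes, features: %s\n",
              x$analysis, length(x$classes),
              paste(x$selected, collapse = ", ")))
  print(x$confusion)
  cat("\n")
  print(x$performance[, c("class", "sensitivity_pct", "specificity_pct",
                          "accuracy_pct", "precision_pct")], row.names = FALSE)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `confusion.csv` (rows predicted, columns observed),
#' `performance.json`, and `ranking.json` under `dir`. Output is
#' byte-deterministic for a fixed report.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- as.data.frame(unclass(report$confusion))
  cm <- cbind(predicted = rownames(cm), cm)
  write.csv(cm, file.path(dir, "confusion.csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(
    list(analysis = report$analysis,
         selected_features = report$selected,
         classes = report$classes,
         performance = report$performance,
         specificity_definition = "TN / (TN + FP)",
         config = report$config),
    file.path(dir, "performance.json"), auto_unbox = TRUE, digits = NA)
  write_ranking(report$ranking, file.path(dir, "ranking.json"))
  invisible(dir)
}
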