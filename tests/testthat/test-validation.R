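test_that("perfectly separated classes give a diagonal confusion matrix", {
  set.seed(50)
  fm <- as_feature_matrix(data.frame(
    Ax = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)),
    behaviour = rep(c("sound_standing", "sound_walking"), each = 10)))
  cm <- loocv(fm, "Ax")
  expect_equal(sum(cm), 20)
  expect_equal(sum(diag(cm)), 20)
})

test_that("confusion totals always equal the number of validated epochs", {
  fm <- gaussian_classes(n_per = 12, feats = c("Ax", "MV"), K = 3, sep = 1,
                         seed = 51)
  cm <- loocv(fm, c("Ax", "MV"))
  expect_equal(sum(cm), nrow(fm))
  # per-class marginals: observed column sums and predicted row sums
  for (c in colnames(cm)) {
    expect_equal(sum(cm[, c]), sum(fm$behaviour == c))
  }
})

test_that("leave-one-out matches an independent per-fold refit oracle", {
  skip_if_not_installed("MASS")
  fm <- gaussian_classes(n_per = 5, feats = c("Ax", "MV"), K = 3, sep = 3,
                         seed = 52)  # n = 15
  cm <- loocv(fm, c("Ax", "MV"), shrinkage = 0)
  classes <- colnames(cm)
  counts <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (i in seq_len(nrow(fm))) {
    train <- fm[-i, , drop = FALSE]
    ref <- MASS::qda(train[, c("Ax", "MV")],
                     grouping = factor(train$behaviour, levels = classes))
    p <- as.character(predict(ref, fm[i, c("Ax", "MV")])$class)
    counts[p, fm$behaviour[i]] <- counts[p, fm$behaviour[i]] + 1
  }
  expect_equal(unclass(cm), counts)
})

test_that("classes with too few epochs are rejected", {
  fm <- gaussian_classes(n_per = 4, feats = "Ax", K = 2, seed = 53)
  fm <- as_feature_matrix(fm[-(1:2), , drop = FALSE])  # one class down to 2
  expect_error(loocv(fm, "Ax"), ">= 3 rows")
})

test_that("prediction accuracy is the diagonal over the observed column", {
  cm <- confusion_matrix(diag(3) * 5,
                         classes = c("sound_grazing", "sound_walking",
                                     "lame_walking"))
  expect_equal(unname(prediction_accuracy(cm)), rep(1, 3))
  counts <- matrix(c(8, 2, 0, 4, 6, 0, 0, 0, 0), 3, 3)
  cm2 <- confusion_matrix(counts, classes = c("sound_grazing",
                                              "sound_walking",
                                              "lame_walking"))
  expect_equal(prediction_accuracy(cm2, "sound_grazing")[[1]], 0.8)
  # class never observed: undefined, not zero
  expect_true(is.na(prediction_accuracy(cm2, "lame_walking")))
})

test_that("prediction accuracy equals one-vs-rest sensitivity on random matrices", {
  set.seed(54)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    counts <- matrix(rpois(K * K, 20), K, K)
    cm <- confusion_matrix(counts, classes = BEHAVIOURS[1:K][sample(K)])
    perf <- performance(cm)
    pa <- prediction_accuracy(cm)
    expect_equal(unname(pa[perf$class]), perf$sensitivity)
    expect_equal(perf$prediction_accuracy, perf$sensitivity)
  }
})

test_that("performance counts partition the total and a perfect matrix scores 1", {
  set.seed(55)
  counts <- matrix(rpois(16, 15), 4, 4)
  cm <- confusion_matrix(counts, classes = BEHAVIOURS[1:4])
  perf <- performance(cm)
  expect_true(all(perf$TP + perf$FP + perf$FN + perf$TN == sum(cm)))
  perfect <- performance(confusion_matrix(diag(4) * 7,
                                          classes = BEHAVIOURS[1:4]))
  for (mcol in c("sensitivity", "specificity", "accuracy", "precision"))
    expect_equal(perfect[[mcol]], rep(1, 4))
  expect_error(performance(confusion_matrix(matrix(0, 2, 2),
                                            classes = BEHAVIOURS[1:2])),
               "all zero")
})

test_that("run_analysis produces an end-to-end report and flags absent classes", {
  eps <- balanced_epochs(per_class = 12, seed = 60)
  eps <- eps[vapply(eps, `[[`, "", "behaviour") != "sound_lying"]
  fm <- build_feature_matrix(eps)
  expect_warning(
    rep2 <- run_analysis(fm, "II", ranking = ranking_config(ntree = 50,
                                                            seed = 60)),
    "sound_lying")
  expect_identical(sort(rep2$classes),
                   sort(c("sound_grazing", "sound_standing", "sound_walking",
                          "lame_walking")))
  expect_equal(sum(rep2$confusion), nrow(apply_analysis(fm, "II")))
  expect_s3_class(rep2$performance, "performance_report")
  expect_length(rep2$selected, 3)
})

test_that("identical configuration and seed give byte-identical reports", {
  eps <- balanced_epochs(per_class = 12, seed = 61)
  fm <- build_feature_matrix(eps)
  r1 <- run_analysis(fm, "II", ranking = ranking_config(ntree = 50, seed = 61))
  r2 <- run_analysis(fm, "II", ranking = ranking_config(ntree = 50, seed = 61))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(r1, d1)
  write_report(r2, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})
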