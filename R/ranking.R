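#' Random-forest ranking configuration
#'
#' Defaults follow the reference analysis: 500 trees and 4 features tried
#' per split (about the square root of the 14 candidate features), minimum
#' node size 1 (unlimited depth, no pruning).
#'
#' @param ntree Number of trees (>= 1).
#' @param mtry Features tried per split, in `[1, 14]`.
#' @param min_node Minimum node size.
#' @param seed Integer seed for bootstrap and feature subsampling.
#' @return An object of class `ranking_config`.
#' @export
ranking_config <- function(ntree = 500, mtry = 4, min_node = 1, seed = 1) {
  stopifnot(ntree >= 1, mtry >= 1, mtry <= 14, min_node >= 1)
  structure(list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "ranking_config")
}

#' Rank features by random-forest mean decrease in Gini
#'
#' Grows a seeded classification forest (bootstrap resamples, CART Gini
#' splits over `mtry` randomly chosen features, unpruned trees) on the
#' behaviour labels and attributes to each feature the total Gini-impurity
#' decrease of the splits made on it, averaged over trees. The ranking — not
#' classification — is the purpose: the top-ranked subset feeds the
#' discriminant classifier.
#'
#' @param fm A `feature_matrix` (see [build_feature_matrix()]) with at least
#'   two behaviour classes and two rows per class.
#' @param config A [ranking_config()].
#' @param features Feature columns to rank; defaults to all fourteen.
#' @return An object of class `ranking_result`: `$importance` (named, >= 0),
#'   `$order` (feature names by decreasing importance, ties broken by
#'   canonical feature order), `$total_decrease` (ensemble-total Gini
#'   decrease; equals `sum(importance) * ntree`), `$config`.
#' @export
rank_features <- function(fm, config = ranking_config(),
                          features = feature_names()) {
  stopifnot(inherits(config, "ranking_config"))
  missing_cols <- setdiff(features, names(fm))
  if (length(missing_cols))
    stop(sprintf("feature matrix lacks columns: %s",
                 paste(missing_cols, collapse = ", ")))
  labels <- factor(fm$behaviour)
  if (nlevels(labels) < 2) stop("need at least 2 behaviour classes to rank")
  if (min(table(labels)) < 2) stop("need at least 2 rows per class")
  if (config$mtry > length(features)) stop("mtry exceeds feature count")

  x <- as.matrix(fm[, features])
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite feature values")
  res <- .gini_forest_cpp(x, as.integer(labels) - 1L, nlevels(labels),
                          config$ntree, config$mtry, config$min_node,
                          config$seed)
  imp <- setNames(res$importance, features)
  # ties broken by canonical feature-name order (position in `features`)
  ord <- features[order(-imp, seq_along(features))]
  structure(list(importance = imp, order = ord,
                 total_decrease = res$total_decrease, config = config),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %d features, ntree = %d, mtry = %d\n",
              length(x$importance), x$config$ntree, x$config$mtry))
  df <- data.frame(feature = x$order,
                   mean_decrease_gini = round(x$importance[x$order], 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Take the top-k ranked features
#'
#' @param result A `ranking_result`.
#' @param k How many features (default 3, as used for the discriminant
#'   classifier).
#' @return Character vector of `k` feature names.
#' @export
top_k <- function(result, k = 3) {
  stopifnot(inherits(result, "ranking_result"))
  if (k < 1 || k > length(result$order))
    stop(sprintf("k must be in [1, %d]", length(result$order)))
  result$order[seq_len(k)]
}

#' Serialize a ranking as JSON
#'
#' @param result A `ranking_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path) {
  jsonlite::write_json(
    list(importance = as.list(result$importance),
         order = result$order,
         total_decrease = result$total_decrease,
         config = unclass(result$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
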