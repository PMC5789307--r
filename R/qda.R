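#' Fit a quadratic discriminant model
#'
#' Class-conditional Gaussian model over a selected feature subset: per-class
#' sample mean, sample covariance (denominator `n_k - 1`) with a small
#' trace-scaled diagonal shrinkage, and priors from training frequencies (or
#' uniform). Shrinkage keeps near-degenerate classes (e.g. static behaviours
#' whose selected features barely vary) positive definite.
#'
#' @param fm A `feature_matrix` with a `behaviour` column.
#' @param feature_subset Non-empty character vector of feature columns.
#' @param shrinkage Diagonal regularisation weight `lambda`; each class
#'   covariance becomes `S_k + lambda * (tr(S_k)/d) * I` (with the scale
#'   falling back to 1 when the trace is zero). Default `1e-6`.
#' @param priors `"frequency"` (default) or `"uniform"`.
#' @return An object of class `qda_model`.
#' @export
fit_qda <- function(fm, feature_subset, shrinkage = 1e-6,
                    priors = c("frequency", "uniform")) {
  priors <- match.arg(priors)
  stopifnot(length(feature_subset) >= 1, shrinkage >= 0)
  missing_cols <- setdiff(feature_subset, names(fm))
  if (length(missing_cols))
    stop(sprintf("feature matrix lacks columns: %s",
                 paste(missing_cols, collapse = ", ")))
  labels <- fm$behaviour
  classes <- intersect(BEHAVIOURS, unique(labels))
  if (length(classes) == 0) classes <- sort(unique(labels))
  d <- length(feature_subset)
  x <- as.matrix(fm[, feature_subset, drop = FALSE])
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite feature values")

  n <- nrow(x)
  means <- covs <- chols <- vector("list", length(classes))
  names(means) <- names(covs) <- names(chols) <- classes
  nk <- setNames(integer(length(classes)), classes)
  for (k in classes) {
    xi <- x[labels == k, , drop = FALSE]
    nk[k] <- nrow(xi)
    if (nk[k] < 2)
      stop(sprintf("class '%s' has %d row(s); need at least 2", k, nk[k]))
    if (nk[k] <= d && shrinkage == 0)
      stop(sprintf(
        "class '%s' has %d rows for %d features; its covariance is singular. %s",
        k, nk[k], d, "Use shrinkage > 0 or more data."))
    means[[k]] <- colMeans(xi)
    S <- cov(xi)
    scale <- sum(diag(S)) / d
    if (scale <= 0) scale <- 1
    S <- S + shrinkage * scale * diag(d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop(sprintf(
        "covariance for class '%s' is not positive definite; increase shrinkage",
        k))
    covs[[k]] <- S
    chols[[k]] <- ch
  }
  pri <- if (priors == "uniform") {
    setNames(rep(1 / length(classes), length(classes)), classes)
  } else {
    nk / n
  }
  structure(
    list(classes = classes, mean = means, cov = covs, chol = chols,
         prior = pri, feature_names = feature_subset, shrinkage = shrinkage,
         n = n),
    class = "qda_model"
  )
}

#' @export
print.qda_model <- function(x, ...) {
  cat(sprintf(
    "<qda_model> %d classes on features (%s), n = %d, shrinkage = %g\n",
    length(x$classes), paste(x$feature_names, collapse = ", "), x$n,
    x$shrinkage))
  print(data.frame(class = x$classes, n = round(x$prior * x$n),
                   prior = round(x$prior, 4)), row.names = FALSE)
  invisible(x)
}

#' Predict behaviour classes with a quadratic discriminant model
#'
#' Evaluates, in the log domain, the quadratic discriminant score of each
#' class
#' \deqn{\delta_k(v) = -\tfrac12 \ln\det\Sigma_k
#'   - \tfrac12 (v-\mu_k)^\top \Sigma_k^{-1} (v-\mu_k) + \ln\pi_k}
#' using the stored Cholesky factors (triangular solves; no explicit matrix
#' inverse), assigns the argmax (ties broken by class order), and returns
#' posteriors as the softmax of the scores.
#'
#' @param model A `qda_model`.
#' @param features A numeric vector of length `d`, or an `n x d` matrix /
#'   data frame with the model's feature columns.
#' @return List with `$class` (character, length n) and `$posterior`
#'   (`n x K` matrix, rows summing to 1).
#' @export
predict_qda <- function(model, features) {
  stopifnot(inherits(model, "qda_model"))
  d <- length(model$feature_names)
  if (is.data.frame(features)) {
    missing_cols <- setdiff(model$feature_names, names(features))
    if (length(missing_cols))
      stop(sprintf("features lack columns: %s",
                   paste(missing_cols, collapse = ", ")))
    features <- as.matrix(features[, model$feature_names, drop = FALSE])
  }
  if (is.null(dim(features))) {
    if (length(features) != d)
      stop(sprintf("feature vector has length %d; model expects %d",
                   length(features), d))
    features <- matrix(features, nrow = 1)
  }
  if (ncol(features) != d)
    stop(sprintf("feature matrix has %d columns; model expects %d",
                 ncol(features), d))
  storage.mode(features) <- "double"
  if (!all(is.finite(features))) stop("non-finite feature values")

  n <- nrow(features)
  K <- length(model$classes)
  delta <- matrix(NA_real_, n, K, dimnames = list(NULL, model$classes))
  for (k in model$classes) {
    ch <- model$chol[[k]]
    logdet <- 2 * sum(log(diag(ch)))
    centered <- sweep(features, 2, model$mean[[k]])
    # Mahalanobis via triangular solve: ||L^-T (v - mu)||^2 with S = t(ch) %*% ch
    w <- backsolve(ch, t(centered), transpose = TRUE)
    maha <- colSums(w^2)
    delta[, k] <- -0.5 * logdet - 0.5 * maha + log(model$prior[[k]])
  }
  shift <- apply(delta, 1, max)
  post <- exp(delta - shift)
  post <- post / rowSums(post)
  cls <- model$classes[apply(delta, 1, which.max)]
  list(class = cls, posterior = post)
}

#' Serialize a quadratic discriminant model as JSON
#'
#' @param model A `qda_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qda <- function(model, path) {
  jsonlite::write_json(
    list(classes = model$classes,
         feature_names = model$feature_names,
         mean = model$mean,
         cov = model$cov,
         prior = as.list(model$prior),
         shrinkage = model$shrinkage,
         n = model$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
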