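#' Compute the fourteen movement metrics for one epoch
#'
#' Given a `T x 3` epoch of raw (gravity-inclusive) acceleration, computes:
#'
#' * `Ax`, `Ay`, `Az` — per-axis mean acceleration (g);
#' * `MV` — movement variation, the mean absolute sample-to-sample
#'   difference summed over the three axes:
#'   `(1/T) * (sum |x[i+1]-x[i]| + sum |y[i+1]-y[i]| + sum |z[i+1]-z[i]|)`;
#' * `SMA` — signal magnitude area,
#'   `(1/T) * (sum |x| + sum |y| + sum |z|)`;
#' * `AI` — average intensity, the mean instantaneous vector magnitude
#'   `(1/T) * sum sqrt(x^2 + y^2 + z^2)`;
#' * `Entropy` — `(1/T) * sum (1 + Ts_i) * ln(1 + Ts_i)` with
#'   `Ts_i = x_i + y_i + z_i` the per-sample axis sum;
#' * `Energy` — `(1/T) * sum (x_i^2 + y_i^2 + z_i^2)^2`;
#' * `MaxX..MinZ` — per-axis epoch extrema (g).
#'
#' No gravity separation or filtering is applied anywhere in the pipeline;
#' all metrics act on the raw signal.
#'
#' Because axes are in g and can be negative, `1 + Ts_i` can be non-positive,
#' where the entropy term's logarithm is undefined. By default the term is
#' evaluated as `(1 + Ts_i) * ln |1 + Ts_i|` with a warning
#' (`entropy_guard = "abs"`); with `entropy_guard = "reject"` such an epoch
#' is an error.
#'
#' @param epoch An [annotated_epoch()] or a `T x 3` numeric matrix
#'   (columns x, y, z), `T >= 2`.
#' @param entropy_guard `"abs"` (default) or `"reject"`; see Details.
#' @return Named numeric vector of length 14 (see [feature_names()]).
#' @examples
#' m <- cbind(rep(1, 120), rep(0, 120), rep(0, 120))
#' compute_features(m)["Entropy"]  # 2 * log(2)
#' @export
compute_features <- function(epoch, entropy_guard = c("abs", "reject")) {
  entropy_guard <- match.arg(entropy_guard)
  m <- if (inherits(epoch, "annotated_epoch")) epoch$samples else as.matrix(epoch)
  if (ncol(m) != 3L) stop("epoch must have exactly 3 axis columns")
  T_n <- nrow(m)
  if (T_n < 2L) stop("epoch must have at least 2 samples")
  if (!all(is.finite(m))) stop("non-finite values in epoch")

  x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
  mv <- (sum(abs(diff(x))) + sum(abs(diff(y))) + sum(abs(diff(z)))) / T_n
  sma <- (sum(abs(x)) + sum(abs(y)) + sum(abs(z))) / T_n
  ai <- sum(sqrt(x^2 + y^2 + z^2)) / T_n
  ts <- 1 + x + y + z
  if (any(ts <= 0)) {
    if (entropy_guard == "reject")
      stop("entropy undefined: some per-sample axis sum <= -1")
    warning("entropy term with non-positive argument; using log|1 + Ts|")
    ent <- sum(ifelse(ts == 0, 0, ts * log(abs(ts)))) / T_n
  } else {
    ent <- sum(ts * log(ts)) / T_n
  }
  tss <- x^2 + y^2 + z^2
  energy <- sum(tss^2) / T_n

  c(Ax = mean(x), Ay = mean(y), Az = mean(z),
    MV = mv, SMA = sma, AI = ai, Entropy = ent, Energy = energy,
    MaxX = max(x), MaxY = max(y), MaxZ = max(z),
    MinX = min(x), MinY = min(y), MinZ = min(z))
}

# Class sets per analysis. Analysis I keeps lame walking and lame grazing
# alongside all sound behaviours; Analysis II additionally drops lame
# grazing (it is too easily confused with sound grazing). Lame standing and
# lame lying are excluded from both (indistinguishable from their sound
# counterparts in a static posture).
analysis_classes <- function(analysis = c("none", "I", "II")) {
  analysis <- match.arg(as.character(analysis), c("none", "I", "II"))
  switch(analysis,
         none = BEHAVIOURS,
         I = c("sound_grazing", "sound_standing", "sound_walking",
               "sound_lying", "lame_walking", "lame_grazing"),
         II = c("sound_grazing", "sound_standing", "sound_walking",
                "sound_lying", "lame_walking"))
}

#' Build a feature matrix from labelled epochs
#'
#' One row of the fourteen metrics per epoch, in stable
#' `(animal_id, start_time)` order, with behaviour labels and animal groups
#' attached. Optionally restricts rows to an analysis class set: Analysis I
#' drops lame standing and lame lying; Analysis II also drops lame grazing.
#'
#' @param epochs List of [annotated_epoch()] objects, all from one
#'   deployment.
#' @param analysis `"none"` (keep all labels), `"I"` or `"II"`.
#' @param entropy_guard Passed to [compute_features()].
#' @return A data frame of class `feature_matrix`: 14 feature columns plus
#'   `behaviour`, `animal_id`, `deployment`, `start_time`.
#' @export
build_feature_matrix <- function(epochs, analysis = "none",
                                 entropy_guard = "abs") {
  stopifnot(length(epochs) > 0)
  deps <- unique(vapply(epochs, `[[`, character(1), "deployment"))
  if (length(deps) != 1L)
    stop(sprintf("epochs span multiple deployments: %s",
                 paste(deps, collapse = ", ")))
  ord <- order(vapply(epochs, `[[`, character(1), "animal_id"),
               vapply(epochs, function(e) e$start_time, numeric(1)))
  epochs <- epochs[ord]
  feats <- t(vapply(epochs, compute_features, numeric(14),
                    entropy_guard = entropy_guard))
  fm <- as.data.frame(feats)
  fm$behaviour <- vapply(epochs, `[[`, character(1), "behaviour")
  fm$animal_id <- vapply(epochs, `[[`, character(1), "animal_id")
  fm$deployment <- deps
  fm$start_time <- vapply(epochs, function(e) e$start_time, numeric(1))
  class(fm) <- c("feature_matrix", "data.frame")
  apply_analysis(fm, analysis)
}

#' Restrict a feature matrix to an analysis class set
#'
#' @param fm A `feature_matrix`.
#' @param analysis `"none"`, `"I"` or `"II"` (see [build_feature_matrix()]).
#' @return The filtered `feature_matrix`.
#' @export
apply_analysis <- function(fm, analysis) {
  keep <- analysis_classes(analysis)
  out <- fm[fm$behaviour %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Write / read a feature matrix CSV
#'
#' The on-disk interface between feature extraction and modelling: one row
#' per epoch, the fourteen feature columns under their canonical names, plus
#' `behaviour`, `animal_id`, `deployment`. Values are written with 15
#' significant digits so a round-trip preserves them to at least 12.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  cols <- c(feature_names(), "behaviour", "animal_id", "deployment")
  out <- fm[, cols]
  for (f in feature_names()) out[[f]] <- sprintf("%.15g", out[[f]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(c(feature_names(), "behaviour"), names(fm))
  if (length(missing_cols))
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")))
  if (anyNA(fm[, feature_names()])) stop("missing feature values")
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
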