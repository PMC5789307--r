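#' Tri-axial acceleration series
#'
#' A uniformly sampled tri-axial acceleration record for one sensor
#' deployment on one animal. Units are g throughout (sensor-native; gravity
#' has magnitude 1).
#'
#' @param times Sample times in seconds, strictly increasing, uniformly
#'   spaced at `1 / rate_hz` within 1e-6 s.
#' @param x,y,z Per-axis acceleration (g), same length as `times`.
#' @param rate_hz Sampling rate (Hz).
#' @param animal_id Animal identifier.
#' @param deployment `"ear"`, `"collar"` or `"leg"`.
#' @return An object of class `accel_series`.
#' @export
accel_series <- function(times, x, y, z, rate_hz, animal_id = "unknown",
                         deployment = "ear") {
  deployment <- match.arg(deployment, DEPLOYMENTS)
  n <- length(times)
  if (!(length(x) == n && length(y) == n && length(z) == n))
    stop("times, x, y, z must have equal lengths")
  if (n < 1) stop("empty series")
  if (!all(is.finite(times)) || !all(is.finite(x)) || !all(is.finite(y)) ||
      !all(is.finite(z)))
    stop("non-finite values in series")
  if (n > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1L
      stop(sprintf("times not strictly increasing at sample %d", bad))
    }
    if (any(abs(dt - 1 / rate_hz) > 1e-6)) {
      bad <- which(abs(dt - 1 / rate_hz) > 1e-6)[1] + 1L
      stop(sprintf(
        "sample spacing inconsistent with rate_hz = %g at sample %d",
        rate_hz, bad))
    }
  }
  structure(
    list(times = as.numeric(times), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z), rate_hz = rate_hz, animal_id = animal_id,
         deployment = deployment),
    class = "accel_series"
  )
}

#' @export
as.data.frame.accel_series <- function(x, ...) {
  data.frame(time_s = x$times, x_g = x$x, y_g = x$y, z_g = x$z)
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %d samples @ %g Hz (%.1f s), animal %s, %s\n",
              length(x$times), x$rate_hz, length(x$times) / x$rate_hz,
              x$animal_id, x$deployment))
  invisible(x)
}

#' Read a raw accelerometer CSV
#'
#' Parses a delimited text export with columns `time_s, x_g, y_g, z_g` (the
#' dialect [write_accel_csv()] writes). Malformed content is rejected with
#' the offending file line number (header is line 1).
#'
#' @param path CSV path.
#' @param rate_hz Expected sampling rate (Hz).
#' @param animal_id,deployment Metadata to attach.
#' @return An [accel_series()].
#' @export
read_accel_csv <- function(path, rate_hz, animal_id = "unknown",
                           deployment = "ear") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("time_s", "x_g", "y_g", "z_g")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop(sprintf("missing columns in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))
  if (nrow(raw) == 0) stop(sprintf("no data rows in %s", path))
  num <- suppressWarnings(
    lapply(raw[required], as.numeric)
  )
  for (col in required) {
    bad <- which(is.na(num[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column %s at line %d of %s",
                   col, bad[1] + 1L, path))
  }
  t <- num$time_s
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1L
      stop(sprintf("non-increasing time at line %d of %s", bad + 1L, path))
    }
  }
  accel_series(times = t, x = num$x_g, y = num$y_g, z = num$z_g,
               rate_hz = rate_hz, animal_id = animal_id,
               deployment = deployment)
}

#' Write an acceleration series as CSV
#'
#' @param series An [accel_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(series, path) {
  stopifnot(inherits(series, "accel_series"))
  df <- data.frame(
    time_s = sprintf("%.6f", series$times),
    x_g = sprintf("%.8f", series$x),
    y_g = sprintf("%.8f", series$y),
    z_g = sprintf("%.8f", series$z)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behaviour-annotation CSV
#'
#' Intervals are half-open `[start_s, end_s)` seconds, each carrying one
#' behaviour label (a recognised behaviour, or the reserved labels
#' `"unknown"` / `"transition"`, which downstream segmentation excludes).
#' Intervals are returned sorted by start; overlapping intervals are
#' rejected.
#'
#' @param path CSV path with columns
#'   `start_s, end_s, behaviour` (optionally `animal_id, phase, deployment`).
#' @return Data frame of intervals sorted by `start_s`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ann <- read.csv(path, check.names = FALSE)
  required <- c("start_s", "end_s", "behaviour")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols))
    stop(sprintf("missing columns in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))
  if (nrow(ann) == 0) stop(sprintf("no data rows in %s", path))
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  ok <- c(BEHAVIOURS, RESERVED_LABELS)
  bad <- setdiff(unique(ann$behaviour), ok)
  if (length(bad))
    stop(sprintf("unrecognised behaviour label(s): %s",
                 paste(bad, collapse = ", ")))
  if (any(!is.finite(ann$start_s)) || any(!is.finite(ann$end_s)))
    stop("non-finite interval bounds")
  if (any(ann$start_s >= ann$end_s))
    stop("every interval must satisfy start_s < end_s")
  ann <- ann[order(ann$start_s), , drop = FALSE]
  if (nrow(ann) > 1) {
    overlap <- ann$start_s[-1] < ann$end_s[-nrow(ann)]
    if (any(overlap)) {
      i <- which(overlap)[1]
      stop(sprintf("overlapping intervals: [%g, %g) and [%g, %g)",
                   ann$start_s[i], ann$end_s[i],
                   ann$start_s[i + 1], ann$end_s[i + 1]))
    }
  }
  rownames(ann) <- NULL
  ann
}

#' One labelled behaviour epoch
#'
#' @param samples `T x 3` numeric matrix of x, y, z acceleration (g).
#' @param behaviour Single behaviour label.
#' @param animal_id,deployment,start_time Provenance metadata.
#' @param rate_hz Sampling rate (Hz).
#' @return An object of class `annotated_epoch`.
#' @export
annotated_epoch <- function(samples, behaviour, animal_id = "unknown",
                            deployment = "ear", start_time = 0,
                            rate_hz = 12) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == 3L, nrow(samples) > 0L,
            length(behaviour) == 1L)
  if (!all(is.finite(samples))) stop("non-finite samples in epoch")
  colnames(samples) <- c("x", "y", "z")
  structure(
    list(samples = samples, behaviour = behaviour, animal_id = animal_id,
         deployment = deployment, start_time = start_time, rate_hz = rate_hz),
    class = "annotated_epoch"
  )
}

#' Segment a record into mutually exclusive single-behaviour epochs
#'
#' Cuts the record into consecutive non-overlapping windows of
#' `epoch_s * rate_hz` samples, phase-locked to the record start. A window
#' is kept iff every one of its samples falls inside annotated intervals of
#' one single behaviour that is not reserved (`"unknown"` / `"transition"`).
#' Mixed-label, partially annotated and trailing partial windows are
#' dropped entirely.
#'
#' @param series An [accel_series()].
#' @param annotations Annotation data frame (see [read_annotations()]);
#'   validated and sorted internally.
#' @param epoch_s Epoch length in seconds; `epoch_s * rate_hz` must be a
#'   whole number of samples.
#' @return List of [annotated_epoch()] objects.
#' @export
segment_epochs <- function(series, annotations, epoch_s = 10) {
  stopifnot(inherits(series, "accel_series"))
  annotations <- validate_annotations(as.data.frame(annotations))
  T_exact <- epoch_s * series$rate_hz
  T <- round(T_exact)
  if (abs(T_exact - T) > 1e-9 || T < 1)
    stop(sprintf(
      "epoch_s * rate_hz = %g is not a whole number of samples", T_exact))

  t <- series$times
  idx <- findInterval(t, annotations$start_s)
  label <- rep(NA_character_, length(t))
  inside <- idx > 0
  inside[inside] <- t[inside] < annotations$end_s[idx[inside]]
  label[inside] <- annotations$behaviour[idx[inside]]

  n_win <- length(t) %/% T
  out <- vector("list", n_win)
  kept <- 0L
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * T + 1L):(w * T)
    lab <- label[rows]
    if (anyNA(lab)) next
    u <- unique(lab)
    if (length(u) != 1L || u %in% RESERVED_LABELS) next
    kept <- kept + 1L
    out[[kept]] <- annotated_epoch(
      cbind(series$x[rows], series$y[rows], series$z[rows]),
      behaviour = u, animal_id = series$animal_id,
      deployment = series$deployment, start_time = t[rows[1]],
      rate_hz = series$rate_hz)
  }
  out[seq_len(kept)]
}
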