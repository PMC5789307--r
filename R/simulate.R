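#' Generate one behaviour's tri-axial acceleration signal
#'
#' Simulates the signal an animal-borne tri-axial accelerometer records
#' during a single behaviour. Each axis is modelled as
#' \deqn{a(t) = g + A [\sin(2\pi f t + \phi) + \alpha \sin(4\pi f t + 2\phi)] + \epsilon(t)}
#' where `g` is the static gravity projection, `A` the per-axis oscillation
#' amplitude, `f` the stride or head-oscillation frequency, `alpha` the
#' second-harmonic asymmetry (lame gait distorts the stride sinusoid), and
#' `epsilon` white Gaussian noise. Axes carry fixed phase offsets (0, 2/3 pi,
#' 4/3 pi) so the three channels are not collinear.
#'
#' @param params A [behaviour_params()] object.
#' @param duration_s Signal duration in seconds (> 0).
#' @param rate_hz Sampling rate in Hz (> 0); 12 Hz in the reference study.
#' @param seed Integer seed; identical `(params, seed)` give identical output.
#' @param animal_id,deployment Metadata carried on the returned series.
#'
#' @return An [accel_series()] with `floor(duration_s * rate_hz)` samples.
#' @examples
#' p <- default_behaviour_params("sound_walking")
#' s <- generate_behaviour_signal(p, duration_s = 10, rate_hz = 12, seed = 1)
#' nrow(as.data.frame(s))
#' @export
generate_behaviour_signal <- function(params, duration_s, rate_hz, seed = 1,
                                      animal_id = "animal_1",
                                      deployment = "ear") {
  stopifnot(inherits(params, "behaviour_params"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be a single positive number of seconds")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive sampling rate in Hz")
  n <- floor(duration_s * rate_hz)
  if (n < 1) stop("duration_s * rate_hz must yield at least one sample")
  t <- (seq_len(n) - 1) / rate_hz
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  sig <- matrix(0, nrow = n, ncol = 3)
  for (a in 1:3) {
    osc <- 0
    if (params$osc_freq_hz > 0 && params$osc_amp[a] > 0) {
      w <- 2 * pi * params$osc_freq_hz
      osc <- params$osc_amp[a] *
        (sin(w * t + phases[a]) +
           params$asymmetry * sin(2 * w * t + 2 * phases[a]))
    }
    sig[, a] <- params$gravity_orientation[a] + osc
  }
  if (params$noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(n * 3, sd = params$noise_sd), ncol = 3))
    sig <- sig + noise
  }
  accel_series(times = t, x = sig[, 1], y = sig[, 2], z = sig[, 3],
               rate_hz = rate_hz, animal_id = animal_id,
               deployment = deployment)
}

#' Generate a full synthetic deployment study
#'
#' Builds, for every animal x deployment in the configuration, a continuous
#' annotated acceleration record laid out as consecutive behaviour blocks.
#' Every block is an integer number of epochs long and aligned to the record
#' start, so downstream segmentation with the same epoch length recovers
#' exactly `epoch_counts` labelled epochs per behaviour. Consecutive blocks
#' are separated by one epoch labelled `"transition"`, which segmentation
#' excludes. Study-level epoch counts are split as evenly as possible across
#' animals; per-animal oscillation amplitudes are perturbed by a
#' multiplicative log-normal factor so animals differ.
#'
#' @param config A [study_config()].
#' @return An object of class `sim_study`: a list of records, each holding an
#'   `$series` ([accel_series()]) and an `$annotations` data frame
#'   (`start_s`, `end_s`, `behaviour`, `animal_id`, `phase`, `deployment`).
#' @examples
#' cfg <- study_config(animals = 1, epoch_counts = c(sound_walking = 5), seed = 1)
#' study <- generate_study(cfg)
#' length(study)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  rate <- config$sample_rate_hz
  epoch_s <- config$epoch_s
  counts <- config$epoch_counts[config$epoch_counts > 0]
  behaviours <- intersect(BEHAVIOURS, names(counts))

  # All randomness flows from the master seed: per-animal amplitude factors
  # and one sub-seed per (deployment, animal, block).
  n_blocks <- length(behaviours) + 1L  # +1 for transition noise seeds
  draws <- with_seed(config$seed, {
    list(
      animal_factor = exp(rnorm(config$animals, 0, config$per_animal_sd)),
      sub_seed = matrix(
        sample.int(.Machine$integer.max - 1L,
                   length(config$deployments) * config$animals * n_blocks,
                   replace = TRUE),
        nrow = length(config$deployments) * config$animals
      )
    )
  })

  split_counts <- function(total, animals) {
    base <- total %/% animals
    extra <- total %% animals
    base + (seq_len(animals) <= extra)
  }
  per_animal <- vapply(behaviours,
                       function(b) split_counts(counts[[b]], config$animals),
                       integer(config$animals))
  if (config$animals == 1L) per_animal <- matrix(per_animal, nrow = 1,
                                                 dimnames = list(NULL, behaviours))

  records <- list()
  row_i <- 0L
  for (dep in config$deployments) {
    for (an in seq_len(config$animals)) {
      row_i <- row_i + 1L
      animal_id <- sprintf("animal_%d", an)
      fac <- draws$animal_factor[an]
      pieces <- list()
      ann <- list()
      t0 <- 0
      blk <- 0L
      for (b in behaviours) {
        k <- per_animal[an, b]
        if (k == 0L) next
        blk <- blk + 1L
        if (length(pieces)) {   # transition epoch between blocks
          tp <- behaviour_params("sound_standing", noise_sd = 0.05)
          tseg <- generate_behaviour_signal(
            tp, epoch_s, rate, seed = draws$sub_seed[row_i, n_blocks],
            animal_id = animal_id, deployment = dep)
          pieces[[length(pieces) + 1L]] <- tseg
          ann[[length(ann) + 1L]] <- data.frame(
            start_s = t0, end_s = t0 + epoch_s, behaviour = "transition",
            animal_id = animal_id, phase = "sound", deployment = dep)
          t0 <- t0 + epoch_s
        }
        p <- config$params[[b]]
        p$osc_amp <- p$osc_amp * fac
        seg <- generate_behaviour_signal(
          p, k * epoch_s, rate, seed = draws$sub_seed[row_i, blk],
          animal_id = animal_id, deployment = dep)
        pieces[[length(pieces) + 1L]] <- seg
        ann[[length(ann) + 1L]] <- data.frame(
          start_s = t0, end_s = t0 + k * epoch_s, behaviour = b,
          animal_id = animal_id, phase = phase_of(b), deployment = dep)
        t0 <- t0 + k * epoch_s
      }
      xs <- unlist(lapply(pieces, `[[`, "x"))
      ys <- unlist(lapply(pieces, `[[`, "y"))
      zs <- unlist(lapply(pieces, `[[`, "z"))
      n <- length(xs)
      series <- accel_series(times = (seq_len(n) - 1) / rate,
                             x = xs, y = ys, z = zs, rate_hz = rate,
                             animal_id = animal_id, deployment = dep)
      records[[sprintf("%s_%s", dep, animal_id)]] <-
        list(series = series, annotations = do.call(rbind, ann))
    }
  }
  structure(records, class = "sim_study", config = config)
}

#' Extract one deployment's records from a study
#'
#' @param study A `sim_study` from [generate_study()].
#' @param deployment Deployment site to extract; must be present in the
#'   study's configuration.
#' @return A `sim_study` restricted to that deployment.
#' @export
study_records <- function(study, deployment) {
  stopifnot(inherits(study, "sim_study"))
  config <- attr(study, "config")
  if (!deployment %in% config$deployments)
    stop(sprintf("deployment '%s' was not generated; study has: %s",
                 deployment, paste(config$deployments, collapse = ", ")))
  keep <- vapply(study, function(r) r$series$deployment == deployment,
                 logical(1))
  structure(study[keep], class = "sim_study", config = config)
}

#' Segment every record of a study into labelled epochs
#'
#' Convenience wrapper running [segment_epochs()] over each record of one
#' deployment and concatenating the results.
#'
#' @inheritParams study_records
#' @param epoch_s Epoch length (seconds); defaults to the study's configured
#'   value.
#' @return List of `annotated_epoch` objects.
#' @export
study_epochs <- function(study, deployment, epoch_s = NULL) {
  config <- attr(study, "config")
  if (is.null(epoch_s)) epoch_s <- config$epoch_s
  recs <- study_records(study, deployment)
  out <- lapply(recs, function(r)
    segment_epochs(r$series, r$annotations, epoch_s = epoch_s))
  do.call(c, unname(out))
}

#' Write a study to disk as CSV file pairs
#'
#' One `<deployment>_<animal>_accel.csv` (columns `time_s, x_g, y_g, z_g`)
#' and `<deployment>_<animal>_annotations.csv` per record, plus a
#' `study_config.yaml` echoing the scalar configuration. Output is
#' byte-deterministic for a fixed study.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study)) {
    rec <- study[[nm]]
    write_accel_csv(rec$series, file.path(dir, paste0(nm, "_accel.csv")))
    ann <- rec$annotations
    ann$start_s <- sprintf("%.6f", ann$start_s)
    ann$end_s <- sprintf("%.6f", ann$end_s)
    write.csv(ann, file.path(dir, paste0(nm, "_annotations.csv")),
              row.names = FALSE, quote = FALSE)
  }
  config <- attr(study, "config")
  lines <- c(
    sprintf("animals: %d", config$animals),
    sprintf("sample_rate_hz: %g", config$sample_rate_hz),
    sprintf("deployments: [%s]", paste(config$deployments, collapse = ", ")),
    sprintf("seed: %d", config$seed),
    sprintf("per_animal_sd: %g", config$per_animal_sd),
    sprintf("epoch_s: %g", config$epoch_s),
    "epoch_counts:",
    sprintf("  %s: %d", names(config$epoch_counts),
            as.integer(config$epoch_counts))
  )
  writeLines(lines, file.path(dir, "study_config.yaml"))
  invisible(dir)
}
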