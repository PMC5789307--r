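#' Behaviour signal parameters
#'
#' Parameter set for one simulated behaviour regime. The generative model is
#' a static gravity component plus a two-harmonic oscillation plus white
#' Gaussian noise (see [generate_behaviour_signal()]).
#'
#' @param behaviour One of the eight behaviour labels (sound/lame crossed
#'   with grazing, standing, walking, lying).
#' @param gravity_orientation Unit 3-vector: the static gravity projection on
#'   the sensor axes (g). Normalised internally.
#' @param osc_freq_hz Stride or head-oscillation frequency (Hz); 0 for static
#'   states.
#' @param osc_amp Per-axis oscillation amplitude (g), length 3, non-negative.
#' @param asymmetry Second-harmonic distortion coefficient in \[0, 1\]. Lame
#'   gait distorts the sinusoidal stride signal; the distortion is modelled
#'   as an asymmetry-weighted second harmonic.
#' @param noise_sd Standard deviation of additive white Gaussian noise (g).
#'
#' @return An object of class `behaviour_params`.
#' @seealso [default_behaviour_params()]
#' @export
behaviour_params <- function(behaviour, gravity_orientation = c(0, 0, 1),
                             osc_freq_hz = 0, osc_amp = c(0, 0, 0),
                             asymmetry = 0, noise_sd = 0) {
  behaviour <- match.arg(behaviour, BEHAVIOURS)
  stopifnot(
    length(gravity_orientation) == 3L, all(is.finite(gravity_orientation)),
    length(osc_freq_hz) == 1L, osc_freq_hz >= 0,
    length(osc_amp) == 3L, all(osc_amp >= 0),
    length(asymmetry) == 1L, asymmetry >= 0, asymmetry <= 1,
    length(noise_sd) == 1L, noise_sd >= 0
  )
  nrm <- sqrt(sum(gravity_orientation^2))
  if (nrm == 0) stop("gravity_orientation must be a non-zero vector")
  structure(
    list(
      behaviour = behaviour,
      gravity_orientation = gravity_orientation / nrm,
      osc_freq_hz = osc_freq_hz,
      osc_amp = as.numeric(osc_amp),
      asymmetry = asymmetry,
      noise_sd = noise_sd
    ),
    class = "behaviour_params"
  )
}

#' Default parameters per behaviour regime
#'
#' One parameter set per behaviour, chosen to reproduce the qualitative
#' contrasts the pipeline is built around:
#' * standing/lying are static (gravity plus noise) and differ only in
#'   sensor orientation;
#' * grazing is a low-frequency (1 Hz) head oscillation on a head-down
#'   orientation;
#' * walking is a 2 Hz stride-frequency oscillation;
#' * lame walking keeps the stride frequency but has 1.8x the amplitude and
#'   a strong (0.4) second-harmonic asymmetry — the "head bobbing" signature
#'   of a quadruped refusing weight on one foreleg;
#' * lame grazing is grazing with the step component halved (a lame animal
#'   steps less while grazing), deliberately overlapping sound grazing;
#' * lame standing/lying are distributionally identical to their sound
#'   counterparts (a static posture does not betray lameness).
#'
#' @param behaviour Behaviour label; if missing, the full named list of all
#'   eight defaults is returned.
#' @return A `behaviour_params` object, or a named list of them.
#' @export
default_behaviour_params <- function(behaviour) {
  up <- c(0, 0, 1)
  head_down <- c(0.6, 0.15, 0.785)   # pitched-forward grazing orientation
  side <- c(0.1, 0.95, 0.3)          # recumbent orientation
  walk_amp <- c(0.45, 0.25, 0.35)
  graze_amp <- c(0.16, 0.10, 0.12)
  defaults <- list(
    sound_grazing = behaviour_params("sound_grazing", head_down,
                                     osc_freq_hz = 1.0, osc_amp = graze_amp,
                                     asymmetry = 0.05, noise_sd = 0.08),
    sound_standing = behaviour_params("sound_standing", up,
                                      noise_sd = 0.03),
    sound_walking = behaviour_params("sound_walking", up,
                                     osc_freq_hz = 2.0, osc_amp = walk_amp,
                                     asymmetry = 0.10, noise_sd = 0.10),
    sound_lying = behaviour_params("sound_lying", side,
                                   noise_sd = 0.02),
    lame_walking = behaviour_params("lame_walking", up,
                                    osc_freq_hz = 2.0,
                                    osc_amp = 1.8 * walk_amp,
                                    asymmetry = 0.40, noise_sd = 0.10),
    lame_grazing = behaviour_params("lame_grazing", head_down,
                                    osc_freq_hz = 1.0,
                                    osc_amp = 0.5 * graze_amp,
                                    asymmetry = 0.05, noise_sd = 0.08),
    lame_standing = behaviour_params("lame_standing", up,
                                     noise_sd = 0.03),
    lame_lying = behaviour_params("lame_lying", side,
                                  noise_sd = 0.02)
  )
  if (missing(behaviour)) return(defaults)
  behaviour <- match.arg(behaviour, BEHAVIOURS)
  defaults[[behaviour]]
}

#' Default epoch counts per deployment
#'
#' The number of complete, mutually exclusive 10 s behaviour epochs collected
#' per sensor deployment site in the reference sheep study; used as the
#' default study shape by [study_config()].
#'
#' @param deployment `"ear"`, `"collar"` or `"leg"`.
#' @return Named integer vector, behaviour -> epoch count.
#' @export
default_epoch_counts <- function(deployment = c("ear", "collar", "leg")) {
  deployment <- match.arg(deployment)
  counts <- list(
    collar = c(sound_walking = 95L, sound_standing = 106L,
               sound_grazing = 298L, sound_lying = 40L,
               lame_walking = 88L, lame_standing = 62L,
               lame_grazing = 171L, lame_lying = 236L),
    leg = c(sound_walking = 94L, sound_standing = 106L,
            sound_grazing = 298L, sound_lying = 46L,
            lame_walking = 92L, lame_standing = 93L,
            lame_grazing = 181L, lame_lying = 279L),
    ear = c(sound_walking = 274L, sound_standing = 862L,
            sound_grazing = 342L, sound_lying = 0L,
            lame_walking = 98L, lame_standing = 97L,
            lame_grazing = 182L, lame_lying = 279L)
  )
  counts[[deployment]]
}

#' Study configuration for the synthetic generator
#'
#' Describes the shape of a simulated deployment study: how many animals, at
#' what sampling rate, which sensor attachment sites, and how many 10 s
#' epochs of each behaviour the whole study should yield per deployment.
#'
#' @param animals Number of instrumented animals (>= 1).
#' @param sample_rate_hz Sampling rate (Hz), default 12.
#' @param epoch_counts Named vector, behaviour -> total epochs per deployment
#'   across all animals. Defaults to the reference study's counts for the
#'   first requested deployment.
#' @param deployments Character subset of `c("ear", "collar", "leg")`.
#' @param seed Integer master seed; every random draw in the study derives
#'   from it.
#' @param per_animal_sd Log-scale SD of the multiplicative per-animal
#'   perturbation applied to oscillation amplitudes, so animals differ and
#'   cross-validation cannot memorise a single waveform.
#' @param params Named list of `behaviour_params` overriding
#'   [default_behaviour_params()] entries.
#' @param epoch_s Epoch length in seconds (default 10).
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(animals = 5, sample_rate_hz = 12,
                         epoch_counts = NULL,
                         deployments = "ear", seed = 1,
                         per_animal_sd = 0.12,
                         params = list(), epoch_s = 10) {
  deployments <- match.arg(deployments, DEPLOYMENTS, several.ok = TRUE)
  if (is.null(epoch_counts)) epoch_counts <- default_epoch_counts(deployments[1])
  stopifnot(
    length(animals) == 1L, animals >= 1,
    length(sample_rate_hz) == 1L, sample_rate_hz > 0,
    all(names(epoch_counts) %in% BEHAVIOURS),
    all(epoch_counts >= 0),
    length(per_animal_sd) == 1L, per_animal_sd >= 0,
    epoch_s > 0
  )
  full <- default_behaviour_params()
  if (length(params)) {
    stopifnot(all(names(params) %in% BEHAVIOURS),
              all(vapply(params, inherits, logical(1), "behaviour_params")))
    full[names(params)] <- params
  }
  structure(
    list(
      animals = as.integer(animals),
      sample_rate_hz = sample_rate_hz,
      epoch_counts = epoch_counts,
      deployments = deployments,
      seed = as.integer(seed),
      per_animal_sd = per_animal_sd,
      params = full,
      epoch_s = epoch_s
    ),
    class = "study_config"
  )
}
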