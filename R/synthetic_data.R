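#' Specification for a synthetic DEAP-shaped study
#'
#' Defines a surrogate study whose trials carry class-dependent band-power
#' structure: each channel is a sum of one band-limited oscillator per EEG
#' band (theta, alpha, low beta, high beta, gamma) plus white Gaussian
#' noise. Calm trials carry elevated alpha power, stress trials elevated
#' beta/gamma power, the classic spectral signature of relaxed versus
#' aroused cognitive states. Defaults mirror the DEAP recording shape:
#' 32 channels at 128 Hz, 63 s per trial including a 3-s pre-trial
#' baseline.
#'
#' Band powers are relative mean-square amplitudes (oscillator amplitude is
#' `sqrt(2 * power)` so a power of p yields a sinusoid of mean square p).
#'
#' @param n_participants Number of participants.
#' @param n_trials Trials per participant.
#' @param n_channels Channels per trial (default 32).
#' @param fs Sampling rate, Hz (default 128).
#' @param duration_s Trial length in seconds including baseline (default 63).
#' @param baseline_s Pre-trial baseline length in seconds (default 3).
#' @param band_power_calm,band_power_stress Named numeric vectors of
#'   relative band powers over `theta`, `alpha`, `beta_low`, `beta_high`,
#'   `gamma`.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param class_balance Fraction of stress trials per participant, in (0,1).
#' @param seed Integer seed making the whole study reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_participants = 2,
                           n_trials = 10,
                           n_channels = 32,
                           fs = 128,
                           duration_s = 63,
                           baseline_s = 3,
                           band_power_calm = c(theta = 1, alpha = 2,
                                               beta_low = 0.4,
                                               beta_high = 0.4,
                                               gamma = 0.2),
                           band_power_stress = c(theta = 0.5, alpha = 0.5,
                                                 beta_low = 1.2,
                                                 beta_high = 1.2,
                                                 gamma = 0.8),
                           noise_sd = 3,
                           class_balance = 0.5,
                           seed = 1L) {
  bands <- names(eeg_bands())
  stopifnot(all(bands %in% names(band_power_calm)),
            all(bands %in% names(band_power_stress)),
            all(band_power_calm >= 0), all(band_power_stress >= 0),
            class_balance > 0, class_balance < 1,
            noise_sd >= 0, n_trials >= 2)
  if (abs(duration_s * fs - round(duration_s * fs)) > 1e-9) {
    stop("duration_s * fs must be an integer number of samples")
  }
  structure(
    list(n_participants = n_participants, n_trials = n_trials,
         n_channels = n_channels, fs = fs, duration_s = duration_s,
         baseline_s = baseline_s,
         band_power_calm = band_power_calm[bands],
         band_power_stress = band_power_stress[bands],
         noise_sd = noise_sd, class_balance = class_balance,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' The five EEG bands used throughout the package
#'
#' Delta (0-4 Hz) is absent from 4-45 Hz bandpassed recordings and is
#' deliberately not listed.
#'
#' @return Named list of `c(lo, hi)` frequency edges in Hz.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), beta_low = c(14, 16),
       beta_high = c(16, 32), gamma = c(32, 40))
}

#' Generate one synthetic trial for a given state
#'
#' Uses the session RNG; seed externally (or via [generate_study()]) for
#' reproducibility.
#'
#' @param state `"calm"` or `"stress"`.
#' @param spec A [synthetic_spec()].
#' @param participant_id,experiment_id Provenance ids stored on the trial.
#' @return An [eeg_trial()] with `baseline_samples` set from the spec.
#' @export
generate_trial <- function(state, spec, participant_id = 1L,
                           experiment_id = 1L) {
  if (!state %in% c("calm", "stress")) {
    stop("state must be 'calm' or 'stress', got '", state, "'")
  }
  powers <- if (state == "calm") spec$band_power_calm else spec$band_power_stress
  n <- round(spec$duration_s * spec$fs)
  t <- (0:(n - 1)) / spec$fs
  bands <- eeg_bands()
  data <- matrix(0, nrow = spec$n_channels, ncol = n)
  for (ch in seq_len(spec$n_channels)) {
    sig <- numeric(n)
    for (b in names(bands)) {
      a <- sqrt(2 * powers[[b]])
      if (a == 0) next
      f <- stats::runif(1, bands[[b]][1], bands[[b]][2])
      phi <- stats::runif(1, 0, 2 * pi)
      sig <- sig + a * sin(2 * pi * f * t + phi)
    }
    if (spec$noise_sd > 0) sig <- sig + stats::rnorm(n, sd = spec$noise_sd)
    data[ch, ] <- sig
  }
  eeg_trial(participant_id, experiment_id, data, fs = spec$fs,
            baseline_samples = round(spec$baseline_s * spec$fs))
}

#' Generate a full synthetic study: trials plus a consistent ratings table
#'
#' Every participant receives `round(class_balance * n_trials)` stress
#' trials (clamped to keep at least one trial of each class, so no
#' participant is ever excluded), shuffled over experiment ids. Ratings are
#' drawn uniformly inside the strict-threshold region of the trial's
#' generating state, so relabeling the ratings recovers the generating
#' states exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `trials` (list of [eeg_trial()]), `ratings` (data
#'   frame) and `states` (data frame of generating states, for reference).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_stress <- round(spec$class_balance * spec$n_trials)
  n_stress <- min(max(n_stress, 1L), spec$n_trials - 1L)
  trials <- list()
  ratings <- list()
  states <- list()
  for (pid in seq_len(spec$n_participants)) {
    st <- sample(c(rep("stress", n_stress),
                   rep("calm", spec$n_trials - n_stress)))
    for (eid in seq_len(spec$n_trials)) {
      trials[[length(trials) + 1L]] <-
        generate_trial(st[eid], spec, participant_id = pid,
                       experiment_id = eid)
      if (st[eid] == "calm") {
        v <- stats::runif(1, 4.1, 5.9); a <- stats::runif(1, 1.0, 3.9)
      } else {
        v <- stats::runif(1, 1.0, 2.9); a <- stats::runif(1, 5.1, 9.0)
      }
      ratings[[length(ratings) + 1L]] <-
        data.frame(participant_id = pid, experiment_id = eid,
                   valence = v, arousal = a)
      states[[length(states) + 1L]] <-
        data.frame(participant_id = pid, experiment_id = eid, state = st[eid])
    }
  }
  list(trials = trials,
       ratings = do.call(rbind, ratings),
       states = do.call(rbind, states))
}
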