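# Small configurations used across test files. Sizes are deliberately tiny;
# the statistics they feed are checked with generous tolerances.

tiny_config <- function(seed = 1, n_participants = 1, n_muscles = 4,
                        n_synergies = 2, n_directions = 8, n_repetitions = 1,
                        drive_bands = default_drive_bands(2), drive_gain = 0.7,
                        ...) {
  sim_config(
    n_participants = n_participants, n_muscles = n_muscles,
    n_synergies = n_synergies, directions = sphere_directions(n_directions),
    n_repetitions = n_repetitions, drive_bands = drive_bands,
    drive_gain = drive_gain, seed = seed, ...
  )
}

# a trial whose hold phase is an exact sinusoidal carrier (for conditioning
# oracles): amplitude `amp`, frequency `freq`, zero rest phase
sine_trial <- function(amp = 1, freq = 50, fs = 1000, rest_s = 1, hold_s = 3) {
  n_rest <- rest_s * fs
  n_hold <- hold_s * fs
  t <- seq_len(n_hold) / fs
  emg <- cbind(c(rep(0, n_rest), amp * sin(2 * pi * freq * t)))
  structure(list(
    participant_id = 1L, trial_id = 1L, direction = c(1, 0, 0),
    direction_id = 1L, repetition = 1L, emg = emg,
    phase_bounds = list(rest = c(1L, n_rest), hold = c(n_rest + 1L, n_rest + n_hold)),
    fs = fs
  ), class = "trial_recording")
}

# trial with prescribed per-muscle rest and hold standard deviations
variance_trial <- function(rest_sd, hold_sd, fs = 1000, rest_s = 1, hold_s = 3,
                           seed = 99) {
  set.seed(seed)
  n_rest <- rest_s * fs
  n_hold <- hold_s * fs
  nm <- length(rest_sd)
  rest <- sapply(seq_len(nm), function(m) rnorm(n_rest, sd = rest_sd[m]))
  hold <- sapply(seq_len(nm), function(m) rnorm(n_hold, sd = hold_sd[m]))
  structure(list(
    participant_id = 1L, trial_id = 1L, direction = c(1, 0, 0),
    direction_id = 1L, repetition = 1L, emg = rbind(rest, hold),
    phase_bounds = list(rest = c(1L, n_rest), hold = c(n_rest + 1L, n_rest + n_hold)),
    fs = fs
  ), class = "trial_recording")
}
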