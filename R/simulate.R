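#' Canonical frequency-band boundaries (Hz)
#'
#' Mean boundaries of the six data-driven frequency layers reported for the
#' 1--60 Hz intermuscular coherence spectrum: delta-theta, alpha, low-beta,
#' high-beta, low-gamma and high-gamma. Used as the default placement of
#' band-limited common drives in the synthetic-EMG generator so that layer
#' recovery can be checked against a known reference.
#'
#' @return Numeric vector of 7 boundary frequencies in Hz.
#' @export
canonical_band_edges <- function() {
  c(1, 8.7, 16.9, 25.7, 35.8, 48.6, 60)
}

#' Default drive bands from the canonical boundaries
#'
#' @param n_bands Number of leading bands to keep (1..6).
#' @return List of `c(f_lo, f_hi)` pairs in Hz.
#' @export
default_drive_bands <- function(n_bands = 6) {
  stopifnot(n_bands >= 1, n_bands <= 6)
  e <- canonical_band_edges()
  lapply(seq_len(n_bands), function(b) c(e[b], e[b + 1]))
}

#' Approximately uniform directions on the unit sphere
#'
#' Fibonacci-lattice placement of `n` unit vectors, emulating force targets
#' approximately uniformly distributed on a sphere.
#'
#' @param n Number of directions.
#' @return `n x 3` matrix of unit row vectors.
#' @export
sphere_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Configuration for the synthetic-EMG generator
#'
#' Defaults emulate the study design: 8 participants, 17 upper-limb muscles,
#' 6 muscle synergies, 32 force-target directions with 5 repetitions each
#' (160 trials per participant), EMG sampled at 1 kHz, a 3-s rest phase
#' followed by a 3-s hold phase, and one band-limited common drive per
#' canonical frequency band shared by the muscles of each synergy.
#'
#' @param n_participants Number of simulated participants.
#' @param n_muscles Number of muscles.
#' @param n_synergies Number of generative synergies.
#' @param directions Matrix of 3-D unit force-target directions (rows).
#' @param n_repetitions Repetitions per direction.
#' @param fs Sampling rate in Hz.
#' @param rest_duration Rest-phase duration in seconds. The default 3 s gives
#'   a rest window comparable to the hold window, which the activity rule
#'   needs; 0.3 s is also supported.
#' @param hold_duration Hold (static) phase duration in seconds.
#' @param drive_bands List of `c(f_lo, f_hi)` Hz intervals, disjoint, ordered,
#'   within \[1, 60\] Hz; each carries one independent common drive per synergy
#'   it is assigned to.
#' @param band_assignment Integer vector, one entry per synergy, giving the
#'   index of the drive band carrying that synergy's common drive. Default
#'   cycles through the bands.
#' @param drive_gain Common-drive strength kappa in \[0, 1\]: the intensity
#'   modulation depth of the shot-noise carrier by the synergy's shared
#'   band-limited drives. At 0 all muscle pairs are incoherent; coherence
#'   inside the drive bands grows monotonically with kappa.
#' @param noise_gain Scale of the muscle-specific broadband carrier noise
#'   added with weight `1 - kappa` (relative to the unit-variance shot
#'   carrier).
#' @param drive_peak_frac Fraction of each drive band's width actually
#'   occupied by its common drive, centered in the band. Physiological
#'   drives are band-centered oscillatory peaks rather than brick-wall
#'   bands; the default 0.5 keeps each drive's energy away from the
#'   neighboring bands' frequency bins given the 3.9-Hz analysis resolution.
#' @param rest_noise_frac Rest-phase (and sensor-floor) noise amplitude as a
#'   fraction of the mean hold envelope.
#' @param baseline,tuning_gain Cosine-tuning parameters of the synergy
#'   activation coefficients.
#' @param tuning_dev Amplitude (relative to `tuning_gain`) of a persistent
#'   per-(synergy, direction) tuning residual: a zero-mean Gaussian
#'   direction-preference map added to the cosine tuning, constant across
#'   repetitions. Real directional tuning is only approximately cosine;
#'   without such residuals the activations of all synergies span only a
#'   4-dimensional affine space (intercept plus the 3 direction components)
#'   and the generative synergy count is not expressed in the data. The
#'   residual map is zero-mean, so preferred-direction fits stay unbiased.
#' @param activation_noise SD of additive trial-to-trial motor variability on
#'   the per-muscle activation envelope (clipped at zero). Repetitions of the
#'   same target direction differ by this much in real data; because it acts
#'   at the muscle level it is not expressible by any synergy combination and
#'   sets the noise floor of the synergy model's explained variation.
#' @param mvc_headroom MVC is set to this multiple of each muscle's maximum
#'   envelope across directions.
#' @param seed Integer seed making the dataset reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 8,
                       n_muscles = 17,
                       n_synergies = 6,
                       directions = sphere_directions(32),
                       n_repetitions = 5,
                       fs = 1000,
                       rest_duration = 3,
                       hold_duration = 3,
                       drive_bands = default_drive_bands(),
                       band_assignment = NULL,
                       drive_gain = 0.6,
                       noise_gain = 1,
                       drive_peak_frac = 0.5,
                       rest_noise_frac = 0.05,
                       baseline = 0.2,
                       tuning_gain = 0.8,
                       tuning_dev = 1,
                       activation_noise = 0.18,
                       mvc_headroom = 1.25,
                       seed = 1L) {
  if (is.null(band_assignment)) {
    band_assignment <- ((seq_len(n_synergies) - 1L) %% length(drive_bands)) + 1L
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_muscles = as.integer(n_muscles),
    n_synergies = as.integer(n_synergies),
    directions = directions,
    n_repetitions = as.integer(n_repetitions),
    fs = fs,
    rest_duration = rest_duration,
    hold_duration = hold_duration,
    drive_bands = drive_bands,
    band_assignment = as.integer(band_assignment),
    drive_gain = drive_gain,
    noise_gain = noise_gain,
    drive_peak_frac = drive_peak_frac,
    rest_noise_frac = rest_noise_frac,
    baseline = baseline,
    tuning_gain = tuning_gain,
    tuning_dev = tuning_dev,
    activation_noise = activation_noise,
    mvc_headroom = mvc_headroom,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1, cfg$n_muscles >= 2, cfg$n_synergies >= 1)
  stopifnot(is.matrix(cfg$directions), ncol(cfg$directions) == 3)
  nrm <- sqrt(rowSums(cfg$directions^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("directions must be unit vectors")
  if (cfg$drive_gain < 0 || cfg$drive_gain > 1) {
    stop("drive_gain (kappa) must lie in [0, 1]")
  }
  bands <- cfg$drive_bands
  for (b in bands) {
    if (length(b) != 2 || b[1] >= b[2]) stop("each drive band must be (f_lo, f_hi) with f_lo < f_hi")
    if (b[1] < 1 || b[2] > 60) stop("drive bands must lie within [1, 60] Hz")
  }
  if (length(bands) > 1) {
    lo <- vapply(bands, `[`, numeric(1), 1)
    hi <- vapply(bands, `[`, numeric(1), 2)
    if (any(diff(lo) <= 0) || any(lo[-1] < hi[-length(hi)] - 1e-9)) {
      stop("drive bands must be disjoint and ordered")
    }
  }
  if (cfg$fs < 2 * max(vapply(bands, `[`, numeric(1), 2))) {
    stop("fs must be at least twice the highest band edge")
  }
  if (length(cfg$band_assignment) != cfg$n_synergies ||
      any(cfg$band_assignment < 1) || any(cfg$band_assignment > length(bands))) {
    stop("band_assignment must give one valid band index per synergy")
  }
  invisible(cfg)
}

#' Band-limited zero-mean unit-variance drive signal
#'
#' White Gaussian noise filtered with a zero-phase 4th-order Butterworth
#' band-pass (applied forward-backward), then standardized. Models a common
#' synaptic input confined to one frequency band.
#'
#' @param band `c(f_lo, f_hi)` in Hz, inside `(0, fs/2)`.
#' @param duration Seconds.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `duration * fs` samples, zero mean, unit variance.
#' @export
band_limited_drive <- function(band, duration, fs) {
  if (length(band) != 2 || band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop(sprintf(
      "drive band (%g, %g) Hz must lie strictly inside (0, %g) Hz (Nyquist)",
      band[1], band[2], fs / 2
    ))
  }
  n <- round(duration * fs)
  # pad so filtfilt transients do not bias the retained segment
  pad <- min(n, 2 * fs)
  w <- stats::rnorm(n + 2 * pad)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, w)
  y <- y[(pad + 1):(pad + n)]
  y <- y - mean(y)
  y / stats::sd(y)
}

#' Motor-unit-like shot-noise EMG carrier
#'
#' Zero-mean interference-like carrier built as a train of biphasic
#' MUAP-shaped wavelets whose event intensity is modulated by a common drive:
#' events occur at `rate * max(0, 1 + depth * d(t))` per second. A common
#' band-limited drive therefore modulates the firing density, which is where
#' shared neural input lives in surface EMG; the modulation survives the
#' rectification and Hilbert demodulation of the coherence pipeline and
#' produces intermuscular coherence confined to the drive's band.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param d Unit-variance modulating drive (length `n`), or `NULL` for an
#'   unmodulated carrier.
#' @param depth Intensity-modulation depth in \[0, 1\].
#' @param rate Mean event rate in events per second.
#' @param tau Wavelet time constant in seconds (biphasic width ~4 tau).
#' @return Numeric carrier, standardized to approximately unit variance.
#' @export
shot_noise_carrier <- function(n, fs, d = NULL, depth = 0, rate = 100,
                               tau = 0.003) {
  lam <- if (is.null(d) || depth == 0) rep(rate / fs, n) else {
    (rate / fs) * pmax(0, 1 + depth * d)
  }
  spikes <- as.numeric(stats::runif(n) < lam)
  tw <- seq(-0.01, 0.01, by = 1 / fs)
  w <- -tw / tau * exp(-(tw / tau)^2)
  w <- w / sqrt(sum(w^2))
  x <- stats::convolve(spikes, rev(w), type = "open")
  half <- (length(w) - 1) / 2
  x <- x[(half + 1):(half + n)]
  x / sqrt(rate / fs)
}

#' Cosine-tuned synergy activation
#'
#' Rectified cosine tuning of a synergy's activation coefficient with respect
#' to the force-target direction: `max(0, baseline + gain * <direction,
#' preferred>)`.
#'
#' @param direction,preferred 3-D unit vectors.
#' @param baseline,gain Tuning offset and modulation depth (`gain >= 0`).
#' @param normalize If `TRUE`, non-unit inputs are normalized; otherwise
#'   rejected.
#' @return Nonnegative scalar activation.
#' @export
cosine_tuned_activation <- function(direction, preferred, baseline, gain,
                                    normalize = TRUE) {
  stopifnot(length(direction) == 3, length(preferred) == 3, gain >= 0)
  nd <- sqrt(sum(direction^2)); np <- sqrt(sum(preferred^2))
  if (abs(nd - 1) > 1e-8 || abs(np - 1) > 1e-8) {
    if (!normalize) stop("direction and preferred must be unit vectors")
    direction <- direction / nd
    preferred <- preferred / np
  }
  max(0, baseline + gain * sum(direction * preferred))
}

#' Ground-truth synergy structure for one participant
#'
#' Each muscle is assigned one dominant synergy (round-robin) with weight near
#' 1 and small weights elsewhere, so that after per-muscle normalization every
#' synergy has muscles above the 0.75 weight threshold (synergistic pairs
#' exist) and cross-synergy weights fall below 0.25. Preferred directions are
#' spread on the sphere; per-synergy drive gains are jittered across
#' participants.
#'
#' @param config A `sim_config`.
#' @return List with `W_true` (muscles x synergies), `preferred_directions`
#'   (synergies x 3), `tuning_map` (synergies x directions residual map),
#'   `band_assignment`, `drive_gain_jitter`, `dominant_synergy`.
#' @export
make_ground_truth <- function(config) {
  nm <- config$n_muscles; ns <- config$n_synergies
  dom <- ((seq_len(nm) - 1L) %% ns) + 1L
  W <- matrix(stats::runif(nm * ns, 0, 0.10), nm, ns)
  W[cbind(seq_len(nm), dom)] <- stats::runif(nm, 0.85, 1)
  # antipodal pairs emulate the agonist-antagonist organization of
  # isometric force synergies and give a balanced preferred-direction set
  pd <- if (ns %% 2 == 0) {
    base <- sphere_directions(ns / 2)
    rbind(base, -base)
  } else {
    sphere_directions(ns)
  }
  tuning_map <- matrix(
    stats::rnorm(ns * nrow(config$directions),
                 sd = config$tuning_dev * config$tuning_gain),
    ns, nrow(config$directions)
  )
  list(
    W_true = W,
    preferred_directions = pd,
    tuning_map = tuning_map,
    band_assignment = config$band_assignment,
    drive_gain_jitter = stats::runif(ns, 0.8, 1.2),
    dominant_synergy = dom
  )
}

# synergy activation profile for one direction: rectified cosine tuning plus
# the participant's persistent per-direction tuning residual
activation_profile <- function(config, ground_truth, direction,
                               direction_id = NA_integer_) {
  vapply(seq_len(config$n_synergies), function(s) {
    dev <- if (!is.na(direction_id)) ground_truth$tuning_map[s, direction_id] else 0
    max(0, config$baseline +
          config$tuning_gain * sum(direction * ground_truth$preferred_directions[s, ]) +
          dev)
  }, numeric(1))
}

#' Simulate one trial of multi-muscle EMG
#'
#' The hold-phase EMG of muscle m is an envelope `a_m = sum_s W_true[m, s] *
#' c_s(direction)` (cosine-tuned synergy activations) modulating a zero-mean
#' carrier. The carrier is a motor-unit-like shot-noise process
#' ([shot_noise_carrier()]) whose event intensity is modulated with depth
#' `kappa = drive_gain` by the muscle's synergy-weighted mix of shared
#' band-limited drives, plus `(1 - kappa) * noise_gain` parts of
#' muscle-specific white noise. The rest phase contains only low-amplitude
#' noise; the same noise floor is also present during the hold phase.
#'
#' @param config A `sim_config`.
#' @param ground_truth Output of [make_ground_truth()].
#' @param direction 3-D unit force-target direction.
#' @param repetition Repetition index.
#' @param participant_id,trial_id Identifiers stored with the trial.
#' @param direction_id Index of the direction in `config$directions`.
#' @return A `trial_recording`: list with `emg` (samples x muscles, zero-mean
#'   arbitrary voltage units), `phase_bounds` (`rest`/`hold` sample index
#'   ranges), `direction`, `direction_id`, `repetition`, `fs`, ids.
#' @export
generate_trial <- function(config, ground_truth, direction, repetition,
                           participant_id = 1L, trial_id = 1L,
                           direction_id = NA_integer_) {
  fs <- config$fs
  n_rest <- round(config$rest_duration * fs)
  n_hold <- round(config$hold_duration * fs)
  nm <- config$n_muscles
  ns <- config$n_synergies
  gt <- ground_truth

  act <- activation_profile(config, gt, direction, direction_id)
  envelope <- as.numeric(gt$W_true %*% act)
  if (config$activation_noise > 0) {
    envelope <- pmax(0, envelope + stats::rnorm(nm, sd = config$activation_noise))
  }

  # one independent drive realization per synergy, confined to its band
  drives <- matrix(0, n_hold, ns)
  for (s in seq_len(ns)) {
    if (act[s] > 0) {
      band <- config$drive_bands[[gt$band_assignment[s]]]
      # drive realized as a band-centered peak occupying drive_peak_frac of
      # the band, so its energy stays clear of neighboring analysis bins
      ctr <- mean(band)
      hw <- config$drive_peak_frac * diff(band) / 2
      drives[, s] <- band_limited_drive(c(ctr - hw, ctr + hw),
                                        config$hold_duration, fs) *
        gt$drive_gain_jitter[s]
    }
  }
  # per-muscle common drive: L2-normalized synergy weights keep variance ~1
  Wn <- gt$W_true / sqrt(rowSums(gt$W_true^2))
  shared <- drives %*% t(Wn)

  kappa <- config$drive_gain
  carrier <- matrix(0, n_hold, nm)
  for (m in seq_len(nm)) {
    carrier[, m] <- shot_noise_carrier(n_hold, fs, shared[, m], depth = kappa) +
      (1 - kappa) * config$noise_gain * stats::rnorm(n_hold)
  }

  rest_level <- config$rest_noise_frac * mean_hold_envelope(config, gt)
  hold <- sweep(carrier, 2, envelope, `*`) +
    rest_level * matrix(stats::rnorm(n_hold * nm), n_hold, nm)
  rest <- rest_level * matrix(stats::rnorm(n_rest * nm), n_rest, nm)

  structure(list(
    participant_id = participant_id,
    trial_id = trial_id,
    direction = direction,
    direction_id = direction_id,
    repetition = repetition,
    emg = rbind(rest, hold),
    phase_bounds = list(rest = c(1L, n_rest), hold = c(n_rest + 1L, n_rest + n_hold)),
    fs = fs
  ), class = "trial_recording")
}

# mean hold-phase envelope over muscles and directions; sets the rest-noise scale
mean_hold_envelope <- function(config, ground_truth) {
  acts <- vapply(seq_len(nrow(config$directions)), function(di) {
    mean(ground_truth$W_true %*%
           activation_profile(config, ground_truth, config$directions[di, ], di))
  }, numeric(1))
  mean(acts)
}

#' Simulate a full multi-participant dataset
#'
#' Draws per-participant ground truth and generates all trials
#' (`n_participants x nrow(directions) x n_repetitions`). Fully reproducible
#' from `config$seed`.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_dataset` with `participants` (each holding
#'   `ground_truth`, `mvc`, `trials`), `config`, and `manifest`
#'   (plain-list summary serializable to JSON).
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nd <- nrow(config$directions)
  participants <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    gt <- make_ground_truth(config)
    # MVC: headroom times the muscle's peak envelope across directions
    env_by_dir <- vapply(seq_len(nrow(config$directions)), function(di) {
      as.numeric(gt$W_true %*%
                   activation_profile(config, gt, config$directions[di, ], di))
    }, numeric(config$n_muscles))
    mvc <- config$mvc_headroom * apply(env_by_dir, 1, max)
    trials <- vector("list", nd * config$n_repetitions)
    tid <- 0L
    for (di in seq_len(nd)) {
      for (rep in seq_len(config$n_repetitions)) {
        tid <- tid + 1L
        trials[[tid]] <- generate_trial(
          config, gt, config$directions[di, ], rep,
          participant_id = p, trial_id = tid, direction_id = di
        )
      }
    }
    participants[[p]] <- list(id = p, ground_truth = gt, mvc = mvc, trials = trials)
  }
  manifest <- list(
    config = list(
      n_participants = config$n_participants, n_muscles = config$n_muscles,
      n_synergies = config$n_synergies, n_directions = nd,
      n_repetitions = config$n_repetitions, fs = config$fs,
      rest_duration = config$rest_duration, hold_duration = config$hold_duration,
      drive_bands = config$drive_bands, drive_gain = config$drive_gain,
      noise_gain = config$noise_gain
    ),
    seed = config$seed,
    n_trials = config$n_participants * nd * config$n_repetitions
  )
  structure(list(participants = participants, config = config, manifest = manifest),
            class = "sim_dataset")
}

#' Write a simulated dataset to plain-text files
#'
#' One tab-delimited matrix per trial (one row per sample, one column per
#' muscle, header of muscle labels) plus a JSON manifest listing participants,
#' MVC values, ground truth, trial files, directions and phase bounds.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  muscles <- sprintf("muscle%02d", seq_len(dataset$config$n_muscles))
  trial_index <- list()
  for (p in dataset$participants) {
    for (tr in p$trials) {
      fname <- sprintf("p%02d_t%03d.tsv", p$id, tr$trial_id)
      path <- file.path(dir, fname)
      emg <- tr$emg
      colnames(emg) <- muscles
      utils::write.table(format(emg, digits = 6), path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      trial_index[[length(trial_index) + 1L]] <- list(
        participant_id = p$id, trial_id = tr$trial_id, file = fname,
        direction = as.numeric(tr$direction), repetition = tr$repetition,
        phase_bounds = tr$phase_bounds
      )
    }
  }
  manifest <- dataset$manifest
  manifest$participants <- lapply(dataset$participants, function(p) {
    list(id = p$id, mvc = stats::setNames(as.list(p$mvc), muscles),
         ground_truth = list(
           W_true = p$ground_truth$W_true,
           preferred_directions = p$ground_truth$preferred_directions,
           band_assignment = p$ground_truth$band_assignment
         ))
  })
  manifest$trials <- trial_index
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mpath)
}
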