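#' Analytic signal via the FFT
#'
#' @param x Numeric vector.
#' @return Complex vector: `x + i * H(x)` with `H` the Hilbert transform.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Demodulate a rectified EMG signal
#'
#' Removes the slow-varying amplitude of the signal by taking the cosine of
#' the instantaneous phase of its analytic signal (the four-quadrant angle,
#' equivalent to the arctangent of the Hilbert-transform ratio where that is
#' defined), then subtracting the mean. Demodulation enforces the
#' stationarity required by coherence estimation.
#'
#' @param x Numeric series (rectified hold-phase EMG).
#' @return Numeric series of the same length: `cos(phase)` minus its mean;
#'   values lie in \[-1, 1\] before mean subtraction.
#' @export
demodulate <- function(x) {
  if (length(x) == 0) stop("empty series")
  if (all(x == 0)) {
    warning("all-zero series; demodulated output is all zero")
    return(x)
  }
  xd <- cos(Arg(analytic_signal(x)))
  xd - mean(xd)
}

#' Detect muscles recruited during the hold phase
#'
#' A muscle's baseline is its rest-phase variance. A moving window of
#' rest-phase length slides over the hold phase in steps of `step_sec`
#' (clipped at the phase bounds); a window counts as active when its variance
#' is at least `ratio` times the baseline, and the muscle is recruited when
#' at least a fraction `frac` of windows are active.
#'
#' @param trial A `trial_recording`.
#' @param ratio Variance ratio defining an active window (1.5 = 50 % above
#'   baseline).
#' @param frac Minimum fraction of active windows for recruitment.
#' @param step_sec Window step in seconds.
#' @return List of class `activity_mask`: `recruited` (logical per muscle),
#'   `activity_fraction`, `baseline_var`.
#' @export
detect_active_muscles <- function(trial, ratio = 1.5, frac = 0.75, step_sec = 0.1) {
  emg <- trial$emg
  rest <- emg[trial$phase_bounds$rest[1]:trial$phase_bounds$rest[2], , drop = FALSE]
  hold <- emg[trial$phase_bounds$hold[1]:trial$phase_bounds$hold[2], , drop = FALSE]
  base <- apply(rest, 2, stats::var)
  zero <- base <= 0
  if (any(zero)) {
    warning("zero rest-phase variance; baseline floored at machine epsilon")
    base[zero] <- .Machine$double.eps
  }
  wlen <- min(nrow(rest), nrow(hold))
  step <- max(1L, round(step_sec * trial$fs))
  starts <- seq.int(1L, nrow(hold) - wlen + 1L, by = step)
  act <- matrix(FALSE, length(starts), ncol(emg))
  for (w in seq_along(starts)) {
    seg <- hold[starts[w]:(starts[w] + wlen - 1L), , drop = FALSE]
    act[w, ] <- apply(seg, 2, stats::var) >= ratio * base
  }
  fracs <- colMeans(act)
  structure(list(recruited = fracs >= frac, activity_fraction = fracs,
                 baseline_var = base),
            class = "activity_mask")
}

# Windowed segment FFTs of one or more equal-length signals.
# signals: n x s matrix. Returns array [length(keep_bins) x nseg x s].
segment_fft <- function(signals, fs, window_sec, overlap, nfft, keep_bins) {
  n <- nrow(signals)
  wlen <- round(window_sec * fs)
  if (n < wlen) stop("series shorter than one Welch window")
  step <- round(wlen * (1 - overlap))
  nseg <- floor((n - wlen) / step) + 1L
  win <- hamming_window(wlen)
  idx <- outer(seq_len(wlen), (seq_len(nseg) - 1L) * step, `+`)
  s <- ncol(signals)
  # segments of all signals side by side: [wlen x (nseg*s)]
  flat <- rep(as.vector(idx), s) + rep((seq_len(s) - 1L) * n, each = wlen * nseg)
  seg <- matrix(signals[flat], nrow = wlen)
  seg <- seg * win
  padded <- rbind(seg, matrix(0, nfft - wlen, ncol(seg)))
  F <- stats::mvfft(padded)[keep_bins, , drop = FALSE]
  array(F, dim = c(length(keep_bins), nseg, s))
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Indices (into an nfft-point FFT) of bins with centers in [fmin, fmax] Hz.
coherence_bins <- function(fs = 1000, nfft = 256, fmin = 1, fmax = 60) {
  centers <- (seq_len(nfft) - 1) * fs / nfft
  which(centers >= fmin & centers <= fmax)
}

#' Welch magnitude-squared coherence between two series
#'
#' Welch auto- and cross-spectra with Hamming windows of `window_sec` seconds,
#' `overlap` fractional overlap and FFT length `nfft`;
#' `C = |p_xy|^2 / (p_xx p_yy)` per frequency bin, restricted to bin centers
#' in `[fmin, fmax]` Hz. At the defaults (fs = 1000 Hz, 0.2-s windows, 50 %
#' overlap, nfft = 256) this yields 15 bins of width 3.90625 Hz in 1--60 Hz
#' and 29 segments for a 3-s series.
#'
#' @param x,y Equal-length numeric series (typically demodulated EMG).
#' @param fs Sampling rate in Hz.
#' @param window_sec,overlap,nfft Welch parameters.
#' @param fmin,fmax Retained frequency range in Hz.
#' @return List with `C` (coherence per bin, in \[0, 1\]), `Ns` (segment
#'   count), `bin_centers` (Hz).
#' @export
welch_coherence <- function(x, y, fs = 1000, window_sec = 0.2, overlap = 0.5,
                            nfft = 256, fmin = 1, fmax = 60) {
  stopifnot(length(x) == length(y))
  keep <- coherence_bins(fs, nfft, fmin, fmax)
  Fx <- segment_fft(cbind(x, y), fs, window_sec, overlap, nfft, keep)
  pxx <- rowMeans(abs(Fx[, , 1, drop = FALSE])^2)
  pyy <- rowMeans(abs(Fx[, , 2, drop = FALSE])^2)
  pxy <- rowMeans(Fx[, , 1] * Conj(Fx[, , 2]))
  C <- Mod(pxy)^2 / (pxx * pyy)
  list(C = pmin(pmax(C, 0), 1), Ns = dim(Fx)[2],
       bin_centers = (keep - 1) * fs / nfft)
}

#' Fisher normalization of coherence
#'
#' `Z = 2 Ns atanh(C)`, with `C` capped just below 1 to keep Z finite. The
#' conventional normalization `sqrt(2 Ns) atanh(sqrt(C))` is available for
#' sensitivity checks.
#'
#' @param C Coherence values in \[0, 1\].
#' @param Ns Number of Welch segments.
#' @param cap Cap applied to C before `atanh`.
#' @param conventional Use the conventional form instead.
#' @return Nonnegative Z values.
#' @export
fisher_z <- function(C, Ns, cap = 1 - 1e-12, conventional = FALSE) {
  C <- pmin(C, cap)
  if (conventional) sqrt(2 * Ns) * atanh(sqrt(C)) else 2 * Ns * atanh(C)
}

#' Phase-randomized surrogate of a series
#'
#' Fourier transform, independent uniform randomization of the phases of the
#' positive-frequency components with Hermitian symmetry preserved (DC and
#' Nyquist stay real), inverse transform. The surrogate has exactly the
#' original power spectrum but scrambled phase structure.
#'
#' @param x Numeric series.
#' @return Numeric series of the same length.
#' @export
phase_surrogate <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  if (half >= 1) {
    k <- 2:(half + 1)
    phi <- stats::runif(half, 0, 2 * pi)
    X[k] <- Mod(X[k]) * exp(1i * phi)
    X[n + 2 - k] <- Conj(X[k])
  }
  Re(stats::fft(X, inverse = TRUE) / n)
}

#' Per-bin surrogate significance threshold for a muscle pair
#'
#' Builds `n_surrogates` phase-randomized surrogates of each series (with
#' independent phase draws for the two), computes the Welch coherence of each
#' surrogate pair, and returns the per-bin `quantile` of the resulting chance
#' distribution.
#'
#' @param x,y Equal-length demodulated series.
#' @param n_surrogates Number of surrogate pairs (the study used 100).
#' @param quantile Percentile of the chance distribution (0.95).
#' @param ... Welch parameters passed to [welch_coherence()].
#' @return Numeric per-bin threshold.
#' @export
surrogate_threshold <- function(x, y, n_surrogates = 100, quantile = 0.95, ...) {
  stopifnot(n_surrogates >= 2)
  Cs <- vapply(seq_len(n_surrogates), function(s) {
    welch_coherence(phase_surrogate(x), phase_surrogate(y), ...)$C
  }, numeric(length(welch_coherence(x, y, ...)$C)))
  apply(Cs, 1, stats::quantile, probs = quantile, names = FALSE)
}

# Batched phase surrogates: returns n x s matrix of surrogates of x.
phase_surrogate_batch <- function(x, s) {
  n <- length(x)
  X <- stats::fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  S <- matrix(rep(X, s), n, s)
  if (half >= 1) {
    k <- 2:(half + 1)
    phi <- matrix(stats::runif(half * s, 0, 2 * pi), half, s)
    S[k, ] <- Mod(X[k]) * exp(1i * phi)
    S[n + 2 - k, ] <- Conj(S[k, ])
  }
  Re(stats::mvfft(S, inverse = TRUE) / n)
}

#' Surrogate-thresholded coherence spectra for all muscle pairs of a trial
#'
#' For every recruited muscle the rectified hold-phase EMG is demodulated and
#' `n_surrogates` phase-randomized surrogates are generated. For every pair
#' of simultaneously recruited muscles the true Welch coherence and the
#' per-bin 95th-percentile surrogate threshold are computed; bins at or below
#' threshold are set to zero in the Fisher-normalized spectrum `Z`. Pairs that
#' are not simultaneously active are emitted with all-zero spectra.
#'
#' @param trial A `trial_recording`.
#' @param mask An `activity_mask` from [detect_active_muscles()]; computed
#'   from the trial when `NULL`.
#' @param n_surrogates Surrogates per active muscle.
#' @param quantile Significance percentile.
#' @param window_sec,overlap,nfft,fmin,fmax Welch parameters.
#' @return List of class `coherence_trial`: `pairs` (data frame `i`, `j`,
#'   `co_active`), `C`, `Z`, `sig`, `threshold` (bins x pairs matrices), `Ns`,
#'   `bin_centers`, plus trial metadata.
#' @export
pair_coherence_for_trial <- function(trial, mask = NULL, n_surrogates = 100,
                                     quantile = 0.95, window_sec = 0.2,
                                     overlap = 0.5, nfft = 256,
                                     fmin = 1, fmax = 60) {
  if (is.null(mask)) mask <- detect_active_muscles(trial)
  fs <- trial$fs
  hold <- trial$emg[trial$phase_bounds$hold[1]:trial$phase_bounds$hold[2], ,
                    drop = FALSE]
  nm <- ncol(hold)
  keep <- coherence_bins(fs, nfft, fmin, fmax)
  nb <- length(keep)
  recruited <- which(mask$recruited)

  # per recruited muscle: demodulated signal + surrogates -> segment FFTs
  Fs <- vector("list", nm)
  Ns <- NULL
  for (m in recruited) {
    xd <- demodulate(abs(hold[, m]))
    sig_mat <- cbind(xd, phase_surrogate_batch(xd, n_surrogates))
    Fm <- segment_fft(sig_mat, fs, window_sec, overlap, nfft, keep)
    Ns <- dim(Fm)[2]
    Fs[[m]] <- Fm
  }
  pxx <- vector("list", nm)
  for (m in recruited) {
    A <- abs(Fs[[m]])^2
    pxx[[m]] <- colMeans(array(aperm(A, c(2, 1, 3)),
                               dim = c(dim(A)[2], nb * (n_surrogates + 1))))
  }

  pairs <- which(upper.tri(matrix(0, nm, nm)), arr.ind = TRUE)
  pairs <- data.frame(i = pairs[, 1], j = pairs[, 2])
  pairs <- pairs[order(pairs$i, pairs$j), ]
  rownames(pairs) <- NULL
  np <- nrow(pairs)
  Cm <- matrix(0, nb, np)
  Zm <- matrix(0, nb, np)
  sg <- matrix(FALSE, nb, np)
  th <- matrix(NA_real_, nb, np)
  co <- logical(np)
  for (p in seq_len(np)) {
    i <- pairs$i[p]; j <- pairs$j[p]
    if (!(mask$recruited[i] && mask$recruited[j])) next
    co[p] <- TRUE
    A <- Fs[[i]] * Conj(Fs[[j]])
    pxy <- colMeans(array(aperm(A, c(2, 1, 3)),
                          dim = c(dim(A)[2], nb * (n_surrogates + 1))))
    Call <- matrix(Mod(pxy)^2, nb) /
      (matrix(pxx[[i]], nb) * matrix(pxx[[j]], nb))
    Call <- pmin(pmax(Call, 0), 1)
    Ctrue <- Call[, 1]
    thr <- apply(Call[, -1, drop = FALSE], 1, stats::quantile,
                 probs = quantile, names = FALSE)
    s <- Ctrue > thr
    Z <- fisher_z(Ctrue, Ns)
    Z[!s] <- 0
    Cm[, p] <- Ctrue; Zm[, p] <- Z; sg[, p] <- s; th[, p] <- thr
  }
  if (is.null(Ns)) {
    # no recruited muscles: still report the grid
    wlen <- round(window_sec * fs)
    Ns <- floor((nrow(hold) - wlen) / round(wlen * (1 - overlap))) + 1L
  }
  structure(list(
    pairs = cbind(pairs, co_active = co),
    C = Cm, Z = Zm, sig = sg, threshold = th,
    Ns = Ns, bin_centers = (keep - 1) * fs / nfft,
    participant_id = trial$participant_id, trial_id = trial$trial_id,
    direction_id = trial$direction_id, repetition = trial$repetition
  ), class = "coherence_trial")
}

#' Coherence spectra for all trials of one participant
#'
#' Runs [detect_active_muscles()] and [pair_coherence_for_trial()] over a
#' list of trials and stacks the results.
#'
#' @param trials List of `trial_recording`s for one participant.
#' @param ... Passed to [pair_coherence_for_trial()].
#' @return List of class `coherence_set`: `Z`, `C`, `sig` (arrays
#'   bins x pairs x trials), `co_active` (pairs x trials logical), `pairs`
#'   (data frame), `trials` (metadata data frame), `bin_centers`, `Ns`,
#'   `participant_id`.
#' @export
coherence_participant <- function(trials, ...) {
  per_trial <- lapply(trials, function(tr) {
    pair_coherence_for_trial(tr, detect_active_muscles(tr), ...)
  })
  nb <- length(per_trial[[1]]$bin_centers)
  np <- nrow(per_trial[[1]]$pairs)
  nt <- length(per_trial)
  Z <- array(0, dim = c(nb, np, nt))
  C <- array(0, dim = c(nb, np, nt))
  sg <- array(FALSE, dim = c(nb, np, nt))
  co <- matrix(FALSE, np, nt)
  for (t in seq_len(nt)) {
    Z[, , t] <- per_trial[[t]]$Z
    C[, , t] <- per_trial[[t]]$C
    sg[, , t] <- per_trial[[t]]$sig
    co[, t] <- per_trial[[t]]$pairs$co_active
  }
  meta <- data.frame(
    trial_id = vapply(per_trial, function(x) as.integer(x$trial_id), integer(1)),
    direction_id = vapply(per_trial, function(x) as.integer(x$direction_id), integer(1)),
    repetition = vapply(per_trial, function(x) as.integer(x$repetition), integer(1))
  )
  structure(list(
    Z = Z, C = C, sig = sg, co_active = co,
    pairs = per_trial[[1]]$pairs[, c("i", "j")],
    trials = meta,
    bin_centers = per_trial[[1]]$bin_centers,
    Ns = per_trial[[1]]$Ns,
    participant_id = per_trial[[1]]$participant_id
  ), class = "coherence_set")
}
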