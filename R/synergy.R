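#' Extract muscle synergies at a fixed rank
#'
#' Best-of-restarts NMF of the nonnegative activation matrix (muscles x
#' trials) into muscle weights `W_m` and activation coefficients `C_m`.
#'
#' @param A Nonnegative activation matrix, muscles in rows, trials in columns.
#' @param n Number of synergies (1..muscles).
#' @param restarts Random restarts (the study used 10).
#' @param ... Passed to [nmf()].
#' @return List of class `synergy_model` with `W` (muscles x n), `C`
#'   (n x trials), `r2`, `n`, `restart_log`.
#' @export
extract_synergies <- function(A, n, restarts = 10, ...) {
  stopifnot(n >= 1, n <= nrow(A))
  fit <- nmf(A, n, restarts = restarts, ...)
  structure(list(W = fit$W, C = fit$H, r2 = fit$r2, n = n,
                 restart_log = fit$restart_log),
            class = "synergy_model")
}

#' Explained-variation curve over candidate synergy numbers
#'
#' Runs [extract_synergies()] for each candidate rank and reports the R2
#' values, made monotone non-decreasing by a running maximum (restart noise
#' can otherwise produce small inversions).
#'
#' @param A Nonnegative activation matrix (muscles x trials).
#' @param n_range Candidate ranks, default 1..muscles.
#' @param restarts Random restarts per rank.
#' @param ... Passed to [nmf()].
#' @return List with `r2` (named by rank), `models` (list of
#'   `synergy_model`s), `n_range`.
#' @export
synergy_r2_curve <- function(A, n_range = seq_len(nrow(A)), restarts = 10, ...) {
  models <- lapply(n_range, function(n) extract_synergies(A, n, restarts, ...))
  r2 <- vapply(models, `[[`, numeric(1), "r2")
  r2 <- cummax(r2)
  names(r2) <- n_range
  list(r2 = r2, models = models, n_range = n_range)
}

#' Select the number of synergies by the three-criterion rule
#'
#' Criterion (i): the smallest N with `R2 > r2_threshold`. Criterion (ii): the
#' first N for which the mean squared error of a least-squares line fitted to
#' `(n, R2(n))` for `n = N..n_muscles` falls below `mse_tol`. If the two
#' criteria agree, that N is selected; otherwise the candidate whose synergy
#' preferred directions are more uniformly distributed (smaller mean resultant
#' length of the preferred-direction unit vectors) wins.
#'
#' @param r2_curve Numeric R2 values for N = 1..n_muscles (monotone
#'   non-decreasing; enforced by running maximum).
#' @param preferred_dirs Optional. Either a list indexed by N of matrices
#'   (synergies x 3) of preferred-direction unit vectors, or a function
#'   `function(N)` returning such a matrix. Only consulted on mismatch.
#' @param r2_threshold Criterion-(i) threshold on R2.
#' @param mse_tol Criterion-(ii) tolerance on the linear-fit MSE (R2 scale).
#' @return List with `selected`, `n_r2` (criterion i), `n_slope` (criterion
#'   ii), `uniformity` (mean resultant lengths when consulted).
#' @export
select_num_synergies <- function(r2_curve, preferred_dirs = NULL,
                                 r2_threshold = 0.9, mse_tol = 1e-4) {
  r2 <- unname(cummax(r2_curve))
  nmax <- length(r2)
  n_r2 <- which(r2 > r2_threshold)[1]
  n_slope <- NA_integer_
  for (n in seq_len(nmax)) {
    idx <- n:nmax
    if (length(idx) < 3) { n_slope <- n; break }
    fit <- stats::lm.fit(cbind(1, idx), r2[idx])
    if (mean(fit$residuals^2) < mse_tol) { n_slope <- n; break }
  }
  if (is.na(n_r2)) {
    warning(sprintf("R2 never exceeds %g; falling back to the slope criterion",
                    r2_threshold))
    return(list(selected = n_slope, n_r2 = NA_integer_, n_slope = n_slope,
                uniformity = NULL))
  }
  if (n_r2 == n_slope) {
    return(list(selected = n_r2, n_r2 = n_r2, n_slope = n_slope, uniformity = NULL))
  }
  if (is.null(preferred_dirs)) {
    stop("criteria (i) and (ii) disagree; preferred_dirs needed for criterion (iii)")
  }
  get_dirs <- if (is.function(preferred_dirs)) preferred_dirs else {
    function(n) preferred_dirs[[n]]
  }
  unif <- vapply(c(n_r2, n_slope), function(n) {
    mean_resultant_length(get_dirs(n))
  }, numeric(1))
  names(unif) <- c(n_r2, n_slope)
  selected <- if (unif[1] <= unif[2]) n_r2 else n_slope
  list(selected = selected, n_r2 = n_r2, n_slope = n_slope, uniformity = unif)
}

#' Mean resultant length of a set of unit vectors
#'
#' `||sum_i p_i|| / n` for unit vectors `p_i`; 0 for a perfectly balanced
#' (uniform) set, 1 for identical vectors. Rows flagged untuned (all-NA) are
#' dropped.
#'
#' @param dirs Matrix of unit row vectors.
#' @return Scalar in \[0, 1\].
#' @export
mean_resultant_length <- function(dirs) {
  keep <- stats::complete.cases(dirs)
  dirs <- dirs[keep, , drop = FALSE]
  if (nrow(dirs) == 0) return(NA_real_)
  sqrt(sum(colSums(dirs)^2)) / nrow(dirs)
}

#' Fit cosine directional tuning to synergy activation coefficients
#'
#' Least-squares fit of `c = baseline + gain * <d, p>` over trials: linear in
#' `(baseline, g)` with `g = gain * p`, so the fit is a single linear
#' regression on the direction components; `gain = ||g||` and `p = g / gain`.
#'
#' @param activations Per-trial activation coefficients (numeric vector).
#' @param directions Per-trial 3-D unit direction vectors (trials x 3).
#' @param min_gain Gains below this (relative to the activation scale) flag
#'   the fit as untuned/unstable.
#' @return List of class `tuning_fit` with `preferred` (unit 3-vector, NA if
#'   untuned), `baseline`, `gain`, `r2`, `tuned`.
#' @export
fit_cosine_tuning <- function(activations, directions, min_gain = 1e-8) {
  stopifnot(length(activations) == nrow(directions))
  if (nrow(unique(round(directions, 10))) < 4) {
    stop("at least 4 distinct directions are required")
  }
  if (all(activations == 0)) {
    return(structure(list(preferred = rep(NA_real_, 3), baseline = 0,
                          gain = 0, r2 = NA_real_, tuned = FALSE),
                     class = "tuning_fit"))
  }
  X <- cbind(1, directions)
  fit <- stats::lm.fit(X, activations)
  b <- fit$coefficients
  g <- b[2:4]
  gain <- sqrt(sum(g^2))
  scale <- stats::sd(activations)
  tuned <- gain > min_gain * max(1, scale)
  preferred <- if (tuned) g / gain else rep(NA_real_, 3)
  ss_tot <- sum((activations - mean(activations))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  structure(list(preferred = unname(preferred), baseline = unname(b[1]),
                 gain = unname(gain), r2 = r2, tuned = tuned),
            class = "tuning_fit")
}

#' Preferred directions of all synergies at one candidate rank
#'
#' Convenience wrapper running [fit_cosine_tuning()] on each row of the
#' activation-coefficient matrix of a synergy model.
#'
#' @param model A `synergy_model`.
#' @param directions Per-trial direction matrix (trials x 3).
#' @return Matrix (synergies x 3) of preferred directions; untuned synergies
#'   give NA rows.
#' @export
preferred_directions <- function(model, directions) {
  t(vapply(seq_len(model$n), function(s) {
    fit <- fit_cosine_tuning(model$C[s, ], directions)
    if (fit$tuned) fit$preferred else rep(NA_real_, 3)
  }, numeric(3)))
}
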