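#' Concatenate coherence spectra into a frequency x (trial, pair) matrix
#'
#' Stacks the thresholded Fisher-normalized spectra of one participant over
#' trials and muscle pairs into a matrix with one row per frequency bin and
#' one column per (trial, pair), columns ordered trial-major. Zero columns
#' (non-co-active pairs) are retained.
#'
#' @param cohset A `coherence_set`, or a list of `coherence_trial`s sharing
#'   one bin grid.
#' @return List of class `coherence_matrix`: `M` (bins x columns), `cols`
#'   (data frame `trial_id`, `pair_i`, `pair_j`), `bin_centers`,
#'   `participant_id`.
#' @export
build_coherence_matrix <- function(cohset) {
  if (inherits(cohset, "coherence_trial")) cohset <- list(cohset)
  if (is.list(cohset) && !inherits(cohset, "coherence_set")) {
    if (length(cohset) == 0) stop("empty spectrum list")
    bc <- cohset[[1]]$bin_centers
    for (x in cohset) {
      if (!isTRUE(all.equal(x$bin_centers, bc))) {
        stop("all spectra must share one frequency-bin grid")
      }
    }
    M <- do.call(cbind, lapply(cohset, `[[`, "Z"))
    cols <- do.call(rbind, lapply(cohset, function(x) {
      data.frame(trial_id = x$trial_id, pair_i = x$pairs$i, pair_j = x$pairs$j)
    }))
    pid <- cohset[[1]]$participant_id
  } else {
    d <- dim(cohset$Z)
    M <- matrix(cohset$Z, d[1], d[2] * d[3])
    cols <- data.frame(
      trial_id = rep(cohset$trials$trial_id, each = d[2]),
      pair_i = rep(cohset$pairs$i, d[3]),
      pair_j = rep(cohset$pairs$j, d[3])
    )
    bc <- cohset$bin_centers
    pid <- cohset$participant_id
  }
  structure(list(M = M, cols = cols, bin_centers = bc, participant_id = pid),
            class = "coherence_matrix")
}

#' Decompose concatenated coherence spectra into frequency layers
#'
#' Best-of-restarts NMF of the coherence matrix into coherence patterns `W_c`
#' (bins x k) and edge weights `C_c` (k x columns). `W_c` columns are rescaled
#' to unit maximum (with compensating rescale of `C_c` rows) and ordered by
#' spectral center of mass, low to high frequency.
#'
#' @param cm A `coherence_matrix` (or a plain nonnegative matrix).
#' @param k Number of layers (1..bins).
#' @param restarts Random NMF restarts.
#' @param bin_centers Required when `cm` is a plain matrix.
#' @param ... Passed to [nmf()].
#' @return List of class `layer_model`: `W` (bins x k, unit max, frequency
#'   ordered), `C` (k x columns), `k`, `r2`, `bin_centers`, `participant_id`.
#' @export
decompose_layers <- function(cm, k, restarts = 10, bin_centers = NULL, ...) {
  if (inherits(cm, "coherence_matrix")) {
    M <- cm$M; bin_centers <- cm$bin_centers; pid <- cm$participant_id
  } else {
    M <- cm; pid <- NA
    if (is.null(bin_centers)) bin_centers <- seq_len(nrow(M))
  }
  stopifnot(k >= 1, k <= nrow(M))
  if (sum(M) == 0) stop("all-zero coherence matrix cannot be decomposed")
  fit <- nmf(M, k, restarts = restarts, ...)
  W <- fit$W; H <- fit$H
  mx <- apply(W, 2, max)
  mx[mx == 0] <- 1
  W <- sweep(W, 2, mx, `/`)
  H <- sweep(H, 1, mx, `*`)
  com <- as.numeric(crossprod(W, bin_centers) / pmax(colSums(W), .Machine$double.eps))
  ord <- order(com)
  structure(list(W = W[, ord, drop = FALSE], C = H[ord, , drop = FALSE],
                 k = k, r2 = fit$r2, bin_centers = bin_centers,
                 participant_id = pid),
            class = "layer_model")
}

#' Select the number of frequency layers by across-participant stability
#'
#' For each candidate k, the unit-max-normalized coherence patterns of all
#' participants are aligned by their spectral center-of-mass order (done in
#' [decompose_layers()]), and the standard deviation across participants is
#' computed per bin and layer, then averaged. The selected k is the deepest
#' interior local minimum of this aggregate SD curve (interior excludes the
#' boundary k = number of bins, where one-hot patterns are trivially
#' identical across participants — over-discretization, not consistency);
#' when no interior local minimum exists the global minimum is used, ties
#' resolved toward the smallest k with near-exact reconstruction.
#'
#' @param models List over participants; each element a list over k of
#'   `layer_model`s (k = index within the inner list).
#' @return List of class `layer_selection`: `k`, `curve` (aggregate SD per
#'   k), `k_range`.
#' @export
select_num_layers <- function(models) {
  if (length(models) < 2) stop("layer-count selection needs at least 2 participants")
  kmax <- min(vapply(models, length, integer(1)))
  curve <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Ws <- lapply(models, function(mp) mp[[k]]$W)
    arr <- simplify2array(Ws)                     # bins x k x participants
    sds <- apply(arr, c(1, 2), stats::sd)
    curve[k] <- mean(sds)
  }
  k_sel <- NA_integer_
  if (kmax >= 3) {
    interior <- 2:(kmax - 1)
    is_min <- curve[interior] < curve[interior - 1] &
      curve[interior] < curve[interior + 1]
    mins <- interior[is_min]
    if (length(mins)) k_sel <- mins[which.min(curve[mins])]
  }
  if (is.na(k_sel)) {
    minval <- min(curve)
    cand <- which(curve <= minval + 1e-12)
    r2s <- vapply(cand, function(k) models[[1]][[k]]$r2, numeric(1))
    good <- cand[r2s >= 0.999]
    k_sel <- if (length(good)) min(good) else cand[which.max(r2s)]
  }
  structure(list(k = as.integer(k_sel), curve = curve, k_range = seq_len(kmax)),
            class = "layer_selection")
}

#' Frequency bounds of each layer
#'
#' Assigns every bin to the layer with the maximal coherence-pattern value at
#' that bin (ties to the lower-frequency layer), enforces contiguity by
#' reassigning isolated off-run bins to the neighboring majority layer, and
#' expresses each layer's bounds as bin-edge frequencies so that the layers
#' tile the full analyzed range.
#'
#' @param model A `layer_model`.
#' @param range Outer frequency limits in Hz (default `c(1, 60)`).
#' @return List of class `layer_bounds`: `bounds` (data frame `layer`, `f1`,
#'   `f2`, `first_bin`, `last_bin`), `assignment` (layer index per bin),
#'   `bin_centers`.
#' @export
layer_bounds <- function(model, range = c(1, 60)) {
  W <- model$W
  bc <- model$bin_centers
  nb <- nrow(W)
  k <- ncol(W)
  assign <- apply(W, 1, which.max)          # ties -> first = lower-frequency layer
  if (k > 1) {
    # keep, for each layer, its longest run; reassign other bins to the
    # nearest kept run's layer so layers are contiguous
    repeat {
      r <- rle(assign)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      dup <- names(which(table(r$values) > 1))
      if (length(dup) == 0) break
      lay <- as.integer(dup[1])
      runs <- which(r$values == lay)
      keep_run <- runs[which.max(r$lengths[runs])]
      drop_runs <- setdiff(runs, keep_run)
      for (dr in drop_runs) {
        bins <- starts[dr]:ends[dr]
        kept_bins <- starts[keep_run]:ends[keep_run]
        for (b in bins) {
          # neighbor on the side away from the kept run
          nb_lay <- if (b < min(kept_bins)) {
            if (dr > 1) r$values[dr - 1] else r$values[dr + 1]
          } else {
            if (dr < length(r$values)) r$values[dr + 1] else r$values[dr - 1]
          }
          assign[b] <- nb_lay
        }
      }
    }
  }
  present <- unique(assign[order(seq_len(nb))])
  if (length(present) < k) {
    warning("degenerate layer(s) with no assigned bin were merged into neighbors")
  }
  r <- rle(assign)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dbin <- if (nb > 1) stats::median(diff(bc)) else diff(range)
  f1 <- pmax(range[1], bc[starts] - dbin / 2)
  f2 <- pmin(range[2], bc[ends] + dbin / 2)
  f1[1] <- range[1]
  f2[length(f2)] <- range[2]
  bounds <- data.frame(layer = seq_along(r$values), f1 = f1, f2 = f2,
                       first_bin = starts, last_bin = ends,
                       component = r$values)
  structure(list(bounds = bounds, assignment = assign, bin_centers = bc),
            class = "layer_bounds")
}

#' Layer-averaged Fisher-normalized coherence
#'
#' `I_Z(f1, f2) = (1 / (f2 - f1)) * integral of Z over [f1, f2]`, discretized
#' as the mean of the bin values whose centers fall inside the interval.
#'
#' @param Z Per-bin Z spectrum.
#' @param bounds `c(f1, f2)` in Hz with `f1 < f2`.
#' @param bin_centers Bin-center frequencies in Hz.
#' @return Scalar mean Z over the layer.
#' @export
layer_average_iz <- function(Z, bounds, bin_centers) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  inside <- bin_centers >= bounds[1] & bin_centers <= bounds[2]
  if (!any(inside)) {
    stop(sprintf("no bin center inside [%g, %g] Hz", bounds[1], bounds[2]))
  }
  mean(Z[inside])
}

#' Layer bounds on the canonical six-band grid
#'
#' Builds a `layer_bounds` object whose layers are the six canonical
#' frequency bands ([canonical_band_edges()]): delta-theta, alpha, low-beta,
#' high-beta, low-gamma, high-gamma. Useful as a fixed, participant-
#' independent reference grid for layer-averaged coherence when the
#' data-driven decomposition is not wanted, e.g. when comparing effects in
#' "the first three layers" across datasets whose spectral content does not
#' span all six bands.
#'
#' @param bin_centers Bin-center frequencies in Hz (default: the 15-bin grid
#'   of the standard Welch settings).
#' @return A `layer_bounds` object with six layers tiling 1--60 Hz.
#' @export
canonical_layer_bounds <- function(bin_centers = (1:15) * 1000 / 256) {
  e <- canonical_band_edges()
  assign <- vapply(bin_centers, function(f) max(which(e[1:6] <= f)), integer(1))
  first <- vapply(1:6, function(b) min(which(assign == b)), integer(1))
  last <- vapply(1:6, function(b) max(which(assign == b)), integer(1))
  structure(list(
    bounds = data.frame(layer = 1:6, f1 = e[1:6], f2 = e[2:7],
                        first_bin = first, last_bin = last, component = 1:6),
    assignment = assign, bin_centers = bin_centers
  ), class = "layer_bounds")
}
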